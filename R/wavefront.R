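# Forward scoring phase: anti-diagonal wavefront sweep. The compiled kernel
# (src/wavefront.cpp) does the work; this file exposes the engine contract
# (forward_score, reduce_best) and the Binary Masking Array activity model
# that describes which query columns are active on each anti-diagonal.
#
# Geometry: query residues index the columns (0-based j), reference residues
# the rows (0-based i); anti-diagonal I = i + j runs from 0 to n + m - 2.
# The engine requires |Q| <= |R|; align_pair()/align_pairs() swap roles
# internally when needed.

#' Active column window of an anti-diagonal
#'
#' For query length `n` and reference length `m` (with `n <= m`), the cells
#' of anti-diagonal `I` occupy columns `max(0, I - m + 1)` to
#' `min(I, n - 1)`. The window grows by one column per iteration while
#' `I < n`, stays at full width `n` while `n <= I < m`, and shrinks while
#' `I >= m`.
#'
#' @param I 0-based anti-diagonal index, `0 <= I <= n + m - 2`.
#' @param n query length (columns), `n >= 1`.
#' @param m reference length (rows), `m >= n`.
#' @return Named integer vector `c(lo, hi)`, 0-based inclusive columns.
#' @examples
#' active_range(0, 6, 9)
#' active_range(7, 6, 9)
#' @export
active_range <- function(I, n, m) {
  stopifnot(length(I) == 1L, length(n) == 1L, length(m) == 1L)
  if (n < 1L || m < n) {
    abort("contract violation: need 1 <= n <= m")
  }
  if (I < 0L || I > n + m - 2L) {
    abort(sprintf("contract violation: iteration I = %d outside [0, %d]",
                  as.integer(I), as.integer(n + m - 2L)))
  }
  c(lo = as.integer(max(0L, I - m + 1L)), hi = as.integer(min(I, n - 1L)))
}

#' Initialize a Binary Masking Array
#'
#' The BMA is a bit array of length `3 * n` that models which of the `n`
#' column slots are active at each wavefront iteration. At initialization,
#' bit `i` (0-based) is 1 iff `n <= i <= 2 * n`; column `j` reads bit
#' `2 * n + j`, so exactly column 0 is active at iteration 0. Advancing the
#' model is [bma_step()]; the active set is [bma_active()].
#'
#' @param n query length (number of column slots), `n >= 1`.
#' @param m reference length, `m >= n`.
#' @return A `bma_state` list with fields `bits`, `n`, `m`, `I`.
#' @examples
#' bma_active(bma_init(6, 9))
#' @export
bma_init <- function(n, m) {
  n <- check_nonneg_int(n, "n")
  m <- check_nonneg_int(m, "m")
  if (n < 1L || m < n) abort("contract violation: need 1 <= n <= m")
  bits <- integer(3L * n)
  bits[(n + 1L):(2L * n + 1L)] <- 1L  # 0-based positions n .. 2n
  structure(list(bits = bits, n = n, m = m, I = 0L), class = "bma_state")
}

#' Advance the Binary Masking Array to iteration I
#'
#' Shifts the bit array right by one exactly when the region condition
#' `C = (I < n) or (I >= m)` holds (the growing and shrinking phases of the
#' diagonal sweep), and clears the bit of any column that has already
#' computed the last cell of its column (a column's final cell lies on
#' anti-diagonal `j + m - 1`; on hardware such a lane masks itself out).
#' After the step, the active set equals [active_range()]`(I, n, m)`.
#'
#' @param state a `bma_state` at iteration `I - 1`.
#' @param I the iteration to advance to (consecutive steps expected).
#' @return The `bma_state` at iteration `I`.
#' @export
bma_step <- function(state, I) {
  stopifnot(inherits(state, "bma_state"))
  I <- check_nonneg_int(I, "I")
  n <- state$n
  m <- state$m
  if (I > n + m - 2L) {
    abort(sprintf("contract violation: iteration I = %d outside [0, %d]",
                  I, n + m - 2L))
  }
  bits <- state$bits
  if (I < n || I >= m) {
    bits <- c(0L, bits[-length(bits)])
  }
  done <- I - m  # columns j <= I - m have computed their last cell
  if (done >= 0L) {
    j_done <- 0L:min(done, n - 1L)
    bits[2L * n + j_done + 1L] <- 0L
  }
  structure(list(bits = bits, n = n, m = m, I = I), class = "bma_state")
}

#' Active columns under a BMA state
#'
#' @param state a `bma_state`.
#' @return 0-based integer vector of the columns whose bit is set.
#' @export
bma_active <- function(state) {
  stopifnot(inherits(state, "bma_state"))
  n <- state$n
  which(state$bits[(2L * n + 1L):(3L * n)] == 1L) - 1L
}

#' Forward scoring phase
#'
#' Computes the maximum local-alignment score and its end coordinates by
#' sweeping anti-diagonals, storing only the two most recent H diagonals,
#' the E/F carries and per-column running maxima: O(|Q|) working memory.
#' The score equals the maximum over the full Gotoh table with
#' zero-initialized first row and column; ties are broken to the smallest
#' query column, then the smallest reference row.
#'
#' This is the strict engine surface: it requires `|Q| <= |R|` and errors
#' otherwise. [align_pair()] and [align_pairs()] wrap it with automatic role
#' swapping and the reverse phase.
#'
#' @param query,reference residue strings; `nchar(query) >= 1`,
#'   `nchar(query) <= nchar(reference)`.
#' @inheritParams encode_sequence
#' @return An `alignment_ends` list: `score`, `query_end`, `ref_end`
#'   (0-based inclusive; -1 sentinels when `score == 0`), `aligned`, and a
#'   `work_ints` attribute counting the integers of allocated working state.
#' @examples
#' forward_score("ACGT", "AACGTT", dna_scheme())
#' @export
forward_score <- function(query, reference, scheme) {
  check_scheme(scheme)
  stopifnot(is.character(query), length(query) == 1L,
            is.character(reference), length(reference) == 1L)
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    abort("empty sequence: both query and reference must be non-empty")
  }
  a <- scheme_cpp_args(scheme)
  res <- .cpp_forward(query, reference, a$lut, a$dna_mode, a$match_score,
                      a$mismatch_penalty, a$n_plain, a$submat, a$gap_init,
                      a$gap_ext)
  structure(
    list(score = res$score, query_end = res$query_end,
         ref_end = res$ref_end, aligned = res$score > 0L),
    work_ints = res$work_ints,
    class = "alignment_ends"
  )
}

#' @export
print.alignment_ends <- function(x, ...) {
  if (x$aligned) {
    cat(sprintf("<alignment_ends> score %d, end (query %d, ref %d)\n",
                x$score, x$query_end, x$ref_end))
  } else {
    cat("<alignment_ends> no positive-scoring local alignment\n")
  }
  invisible(x)
}

#' Reduce per-column maxima to the best cell
#'
#' The final reduction of the forward phase: given each column's running
#' maximum H and the (smallest) row where it was first attained, returns the
#' global best under the deterministic tie-break -- the smallest column
#' index wins across columns. An all-zero input yields the unaligned
#' sentinel result.
#'
#' @param col_max a data frame with columns `column` (0-based query column),
#'   `row` (0-based reference row of the column maximum, -1 if the column
#'   maximum is 0) and `max` (the column's running maximum H).
#' @return An `alignment_ends` list (see [forward_score()]).
#' @examples
#' reduce_best(tibble::tibble(column = 0:2, row = c(1L, 0L, 2L),
#'                            max = c(5L, 9L, 9L)))
#' @export
reduce_best <- function(col_max) {
  stopifnot(is.data.frame(col_max),
            all(c("column", "row", "max") %in% names(col_max)))
  best <- max(0L, col_max$max)
  if (best == 0L) {
    ends <- list(score = 0L, query_end = -1L, ref_end = -1L, aligned = FALSE)
  } else {
    hit <- col_max[col_max$max == best, , drop = FALSE]
    hit <- hit[which.min(hit$column), , drop = FALSE]
    ends <- list(score = as.integer(best),
                 query_end = as.integer(hit$column),
                 ref_end = as.integer(hit$row), aligned = TRUE)
  }
  structure(ends, class = "alignment_ends")
}
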