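# Reverse scoring: recover alignment start coordinates without traceback.
# The prefixes ending at the forward phase's best cell are reversed and
# re-scored with the same kernel; by the symmetry of the optimal alignment
# the reverse maximum equals the forward maximum and its end coordinates,
# flipped back, are the start coordinates.

#' Recover start coordinates by reverse scoring
#'
#' Re-scores the reversed prefixes `query[0..query_end]` and
#' `reference[0..ref_end]` with the forward kernel. The reverse-phase
#' maximum must equal `ends$score` (an internal-consistency error signals an
#' engine bug); the start coordinates are
#' `query_start = query_end - reverse_query_end` and
#' `ref_start = ref_end - reverse_ref_end`. Only the prefixes up to the best
#' cell are re-scored -- the reverse table never has more cells than the
#' forward one.
#'
#' @param query,reference the original residue strings.
#' @param ends an `alignment_ends` with `aligned = TRUE`
#'   (see [forward_score()]).
#' @inheritParams encode_sequence
#' @return Named integer vector `c(query_start, ref_start)`, 0-based.
#' @examples
#' s <- dna_scheme()
#' e <- forward_score("CGT", "AACGTAA", s)
#' reverse_score("CGT", "AACGTAA", e, s)
#' @export
reverse_score <- function(query, reference, ends, scheme) {
  check_scheme(scheme)
  if (!is.list(ends) || !isTRUE(ends$aligned)) {
    abort("contract violation: reverse_score() requires an aligned result (score > 0)")
  }
  a <- scheme_cpp_args(scheme)
  res <- .cpp_reverse(query, reference, ends$score, ends$query_end,
                      ends$ref_end, a$lut, a$dna_mode, a$match_score,
                      a$mismatch_penalty, a$n_plain, a$submat, a$gap_init,
                      a$gap_ext)
  c(query_start = res$query_start, ref_start = res$ref_start)
}

#' Align one query/reference pair
#'
#' Composes the forward wavefront phase and, when `with_start = TRUE` and a
#' positive-scoring alignment exists, the reverse scoring phase, into a
#' complete local-alignment result. Roles are swapped internally when the
#' query is longer than the reference; reported coordinates always refer to
#' the arguments as given. With `with_start = FALSE` the reverse phase is
#' skipped and the start fields stay at -1 (forward-only mode).
#'
#' @param query,reference non-empty residue strings.
#' @inheritParams encode_sequence
#' @param with_start compute start coordinates via reverse scoring?
#' @return A `pairwise_alignment` list with fields `score`, `query_start`,
#'   `query_end`, `ref_start`, `ref_end`, `aligned` (all coordinates 0-based
#'   inclusive; -1 sentinels when not computed or not aligned).
#' @examples
#' align_pair("ACGT", "ACGT", dna_scheme())
#' @export
align_pair <- function(query, reference, scheme, with_start = TRUE) {
  check_scheme(scheme)
  stopifnot(is.character(query), length(query) == 1L,
            is.character(reference), length(reference) == 1L)
  if (is.na(query) || is.na(reference) || nchar(query) == 0L ||
      nchar(reference) == 0L) {
    abort("empty sequence: both query and reference must be non-empty")
  }
  a <- scheme_cpp_args(scheme)
  res <- .cpp_align_batch(query, reference, a$lut, a$dna_mode, a$match_score,
                          a$mismatch_penalty, a$n_plain, a$submat,
                          a$gap_init, a$gap_ext, with_start,
                          TRUE, FALSE, 0L)
  structure(
    list(score = res$score[1],
         query_start = res$query_start[1], query_end = res$query_end[1],
         ref_start = res$ref_start[1], ref_end = res$ref_end[1],
         aligned = res$score[1] > 0L),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  if (x$aligned) {
    cat(sprintf("<pairwise_alignment> score %d, query [%d, %d], ref [%d, %d]\n",
                x$score, x$query_start, x$query_end, x$ref_start, x$ref_end))
  } else {
    cat("<pairwise_alignment> no positive-scoring local alignment\n")
  }
  invisible(x)
}

#' @describeIn align_pair one-row tibble of the result fields.
#' @param x a `pairwise_alignment`.
#' @param ... unused.
#' @method tidy pairwise_alignment
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble(
    score = x$score,
    query_start = x$query_start, query_end = x$query_end,
    ref_start = x$ref_start, ref_end = x$ref_end,
    aligned = x$aligned
  )
}
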