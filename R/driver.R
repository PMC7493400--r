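# Batch driver: validate one-to-one pair batches, split them evenly across
# abstract workers, chunk each share into sub-batches, align, and reassemble
# in input order. Scheduling is observationally invisible: the results are a
# pure function of (pairs, scheme, with_start) -- workers and batch_size
# never change a bit of output.

#' Build a one-to-one pair batch from two sequence tables
#'
#' Pairs row i of `queries` with row i of `references` (alignment is
#' strictly index-to-index). Errors before any work if the two sets differ
#' in length.
#'
#' @param queries,references data frames with columns `id` and `seq`, as
#'   returned by [read_sequences()] or [simulate_pairs()] output split in
#'   two.
#' @return A tibble with columns `query_id`, `query`, `ref_id`, `ref`, ready
#'   for [align_pairs()].
#' @export
pair_sequences <- function(queries, references) {
  stopifnot(is.data.frame(queries), is.data.frame(references))
  for (nm in c("id", "seq")) {
    if (!nm %in% names(queries) || !nm %in% names(references)) {
      abort(sprintf("both sequence tables need an `%s` column", nm))
    }
  }
  if (nrow(queries) != nrow(references)) {
    abort(sprintf(
      "batch error: %d query sequences but %d reference sequences (one-to-one pairing requires equal counts)",
      nrow(queries), nrow(references)
    ))
  }
  tibble(query_id = queries$id, query = queries$seq,
         ref_id = references$id, ref = references$seq)
}

#' Partition N pairs evenly across workers
#'
#' Splits the index range `[0, N)` into `workers` contiguous half-open
#' ranges whose sizes differ by at most one, larger shares going to lower
#' worker ids. Pairs are never reordered.
#'
#' @param n_pairs number of pairs, `>= 0`.
#' @param workers number of abstract parallel workers, `>= 1`.
#' @return A tibble with columns `worker` (1-based id), `lo` (inclusive,
#'   0-based), `hi` (exclusive), `size`.
#' @examples
#' partition_work(10, 4)
#' @export
partition_work <- function(n_pairs, workers) {
  n_pairs <- check_nonneg_int(n_pairs, "n_pairs")
  if (length(workers) != 1L || is.na(workers) || workers < 1L ||
      workers != as.integer(workers)) {
    abort("config error: `workers` must be a single integer >= 1")
  }
  workers <- as.integer(workers)
  base <- n_pairs %/% workers
  sizes <- rep(base, workers) + (seq_len(workers) <= n_pairs %% workers)
  hi <- cumsum(sizes)
  tibble(worker = seq_len(workers), lo = hi - sizes, hi = hi, size = sizes)
}

#' Align a batch of one-to-one sequence pairs
#'
#' The driver entry point: one call aligns every row of `pairs` (query i
#' against reference i) and returns one result row per pair, in input
#' order. Work is split evenly across `workers` abstract lanes and each
#' share is processed in sub-batches of at most `batch_size` pairs;
#' neither setting affects any output value.
#'
#' By default the longer sequence of each pair is used as the reference
#' (`enforce_query_shorter = TRUE`): roles are swapped internally and the
#' reported coordinates always refer to the original query/reference roles.
#' With enforcement off, a pair whose query is longer than its reference is
#' an error.
#'
#' Errors in individual pairs (empty sequence, residue outside the scheme's
#' alphabet) abort the run with the pair index by default;
#' `on_error = "permissive"` records a failed-pair sentinel row (NA score
#' and coordinates) and continues.
#'
#' @param pairs a data frame with columns `query` and `ref` (residue
#'   strings) and optionally `query_id` / `ref_id`; see [pair_sequences()].
#' @inheritParams encode_sequence
#' @param workers number of abstract parallel lanes (`>= 1`).
#' @param batch_size maximal pairs per sub-batch (`>= 1`, default 20000).
#' @param with_start compute start coordinates via the reverse phase?
#' @param enforce_query_shorter swap roles per pair so the query is never
#'   the longer sequence?
#' @param on_error `"abort"` (default) or `"permissive"`.
#' @param warn_query_len warn when a query exceeds this length (flags inputs
#'   outside the design envelope of the thread-per-column mapping).
#' @param verbose print per-chunk progress and a final throughput line?
#' @return An `alignment_tbl` tibble with columns `pair_index` (0-based),
#'   `query_id`, `ref_id`, `score`, `query_start`, `query_end`, `ref_start`,
#'   `ref_end`, `aligned`, plus attributes `total_cells` (sum over pairs of
#'   |Q| * |R| for the forward phase) and `elapsed_s` (kernel wall time).
#' @examples
#' pairs <- tibble::tibble(query = c("ACGT", "CGT"),
#'                         ref = c("AACGTT", "AACGTAA"))
#' align_pairs(pairs, dna_scheme())
#' @export
align_pairs <- function(pairs, scheme, workers = 1L, batch_size = 20000L,
                        with_start = TRUE, enforce_query_shorter = TRUE,
                        on_error = c("abort", "permissive"),
                        warn_query_len = 1024L, verbose = FALSE) {
  check_scheme(scheme)
  on_error <- match.arg(on_error)
  stopifnot(is.data.frame(pairs))
  if (!all(c("query", "ref") %in% names(pairs))) {
    abort("`pairs` must have `query` and `ref` columns")
  }
  if (length(batch_size) != 1L || is.na(batch_size) || batch_size < 1L) {
    abort("config error: `batch_size` must be a single integer >= 1")
  }
  batch_size <- as.integer(batch_size)

  n <- nrow(pairs)
  query <- toupper(as.character(pairs$query))
  ref <- toupper(as.character(pairs$ref))
  query_id <- if ("query_id" %in% names(pairs)) as.character(pairs$query_id) else sprintf("q%d", seq_len(n) - 1L)
  ref_id <- if ("ref_id" %in% names(pairs)) as.character(pairs$ref_id) else sprintf("r%d", seq_len(n) - 1L)

  n_long <- sum(!is.na(query) & nchar(query) > warn_query_len)
  if (n_long > 0L) {
    warn(sprintf("%d quer%s longer than %d residues (outside the design envelope of the column-per-residue mapping)",
                 n_long, if (n_long == 1L) "y is" else "ies are", warn_query_len))
  }

  assignment <- partition_work(n, workers)
  a <- scheme_cpp_args(scheme)
  permissive <- on_error == "permissive"

  chunks <- list()
  total_cells <- 0
  elapsed <- 0
  ci <- 0L
  for (w in seq_len(nrow(assignment))) {
    lo <- assignment$lo[w]
    hi <- assignment$hi[w]
    while (lo < hi) {
      top <- min(lo + batch_size, hi)
      idx <- (lo + 1L):top
      t0 <- proc.time()[["elapsed"]]
      res <- .cpp_align_batch(query[idx], ref[idx], a$lut, a$dna_mode,
                              a$match_score, a$mismatch_penalty, a$n_plain,
                              a$submat, a$gap_init, a$gap_ext, with_start,
                              enforce_query_shorter, permissive, lo)
      elapsed <- elapsed + (proc.time()[["elapsed"]] - t0)
      total_cells <- total_cells + res$total_cells
      ci <- ci + 1L
      if (verbose) {
        message(sprintf("worker %d: aligned pairs [%d, %d) (chunk %d)",
                        w, lo, top, ci))
      }
      failed <- res$status != 0L
      chunks[[ci]] <- tibble(
        pair_index = idx - 1L,
        query_id = query_id[idx], ref_id = ref_id[idx],
        score = res$score,
        query_start = res$query_start, query_end = res$query_end,
        ref_start = res$ref_start, ref_end = res$ref_end,
        aligned = ifelse(failed, NA, res$score > 0L)
      )
      lo <- top
    }
  }

  out <- if (length(chunks) == 0L) {
    tibble(pair_index = integer(0), query_id = character(0),
           ref_id = character(0), score = integer(0),
           query_start = integer(0), query_end = integer(0),
           ref_start = integer(0), ref_end = integer(0),
           aligned = logical(0))
  } else {
    dplyr::bind_rows(chunks)
  }
  if (verbose) {
    message(sprintf(
      "aligned %d pairs, %.0f cells in %.2f s (informational throughput: %.3f GCUPS)",
      n, total_cells, elapsed, if (elapsed > 0) gcups(total_cells, elapsed) else NA_real_))
  }
  structure(out,
            class = c("alignment_tbl", class(out)),
            total_cells = total_cells, elapsed_s = elapsed,
            with_start = with_start)
}

#' Giga cell updates per second
#'
#' The standard throughput metric for alignment kernels:
#' `total_cells / seconds / 1e9`, where `total_cells` is the sum over pairs
#' of |Q| * |R| for the forward phase.
#'
#' @param total_cells number of dynamic-programming cells computed.
#' @param seconds forward-scoring wall time, `> 0`.
#' @return Throughput in GCUPS.
#' @examples
#' gcups(1e9, 1)
#' @export
gcups <- function(total_cells, seconds) {
  stopifnot(length(total_cells) == 1L, length(seconds) == 1L)
  if (!is.finite(seconds) || seconds <= 0) {
    abort("measurement error: `seconds` must be positive")
  }
  if (total_cells < 0) abort("`total_cells` must be non-negative")
  total_cells / seconds / 1e9
}

#' @describeIn align_pairs one-row summary of a result table: pair counts,
#'   aligned fraction, score summary, total cells and informational GCUPS.
#' @param x an `alignment_tbl`.
#' @param ... unused.
#' @method glance alignment_tbl
#' @export
glance.alignment_tbl <- function(x, ...) {
  cells <- attr(x, "total_cells")
  secs <- attr(x, "elapsed_s")
  tibble(
    n_pairs = nrow(x),
    n_aligned = sum(x$aligned, na.rm = TRUE),
    n_failed = sum(is.na(x$aligned)),
    mean_score = mean(x$score, na.rm = TRUE),
    max_score = if (nrow(x) > 0L) max(x$score, na.rm = TRUE) else NA_integer_,
    total_cells = if (is.null(cells)) NA_real_ else cells,
    elapsed_s = if (is.null(secs)) NA_real_ else secs,
    gcups = if (!is.null(cells) && !is.null(secs) && secs > 0) {
      gcups(cells, secs)
    } else {
      NA_real_
    }
  )
}

#' @describeIn align_pairs score distribution plot, split by alignment
#'   status.
#' @param object an `alignment_tbl`.
#' @method autoplot alignment_tbl
#' @export
autoplot.alignment_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df$status <- ifelse(is.na(df$aligned), "failed",
                      ifelse(df$aligned, "aligned", "unaligned"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::labs(x = "local alignment score", y = "pairs",
                  title = "Alignment score distribution") +
    ggplot2::theme_minimal()
}
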