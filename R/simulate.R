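# Synthetic pair generation and the full-matrix reference aligner.
#
# The generator emulates the structure of read-vs-contig and
# protein-vs-protein evaluation sets: each query is a mutated substring of
# its reference, with pairs binned by query length. Defaults mirror a
# short-read bin (queries 150-200 against references up to 779) at 95%
# identity with 1% indels -- a typical read-versus-assembled-contig error
# profile.

DNA_BASES <- c("A", "C", "G", "T")
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate synthetic query/reference pairs
#'
#' For each pair a random reference is drawn, a substring of query length is
#' extracted, and point substitutions (at rate `1 - identity`, uniform over
#' the alphabet minus the original residue) and length-1 indels (at rate
#' `indel_rate`, split evenly between insertions and deletions) are applied
#' to form the query. Identical arguments and seed give byte-identical
#' output.
#'
#' @param n_pairs number of pairs to generate.
#' @param query_len inclusive integer range of query lengths; per pair the
#'   range is truncated to the drawn reference length.
#' @param ref_len inclusive integer range of reference lengths;
#'   `max(query_len) <= max(ref_len)` is required.
#' @param identity fraction of substring positions left unsubstituted, in
#'   \[0, 1\].
#' @param indel_rate per-position probability of a length-1 indel, in
#'   \[0, 1\].
#' @param alphabet `"dna"` (A/C/G/T) or `"protein"` (20 amino acids).
#' @param seed optional integer; when given, generation is a pure function
#'   of the arguments.
#' @return A tibble with columns `query_id`, `query`, `ref_id`, `ref`,
#'   ready for [align_pairs()].
#' @examples
#' simulate_pairs(3, seed = 1)
#' @export
simulate_pairs <- function(n_pairs, query_len = c(150L, 200L),
                           ref_len = c(99L, 779L), identity = 0.95,
                           indel_rate = 0.01,
                           alphabet = c("dna", "protein"), seed = NULL) {
  alphabet <- match.arg(alphabet)
  n_pairs <- check_nonneg_int(n_pairs, "n_pairs")
  check_range <- function(x, what) {
    if (length(x) != 2L || anyNA(x) || x[1] < 1L || x[2] < x[1]) {
      abort(sprintf("spec error: `%s` must be an increasing positive range c(min, max)", what))
    }
    as.integer(x)
  }
  query_len <- check_range(query_len, "query_len")
  ref_len <- check_range(ref_len, "ref_len")
  if (query_len[2] > ref_len[2]) {
    abort("spec error: max(query_len) must not exceed max(ref_len) (queries are substrings of references)")
  }
  for (p in c(identity = identity, indel_rate = indel_rate)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      abort("spec error: `identity` and `indel_rate` must lie in [0, 1]")
    }
  }
  letters_ <- if (alphabet == "dna") DNA_BASES else AA_RESIDUES

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }

  # sample() treats a length-1 vector as 1:x; draw ranges explicitly
  draw <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L

  query <- character(n_pairs)
  ref <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    rl <- draw(ref_len[1], ref_len[2])
    r <- sample(letters_, rl, replace = TRUE)
    qmax <- min(query_len[2], rl)
    qmin <- min(query_len[1], qmax)
    ql <- draw(qmin, qmax)
    start <- draw(0L, rl - ql)
    q <- r[(start + 1L):(start + ql)]
    # substitutions: uniform over the alphabet minus the original residue
    sub_at <- which(stats::runif(ql) > identity)
    for (p in sub_at) {
      q[p] <- sample(setdiff(letters_, q[p]), 1L)
    }
    # length-1 indels, insertions and deletions equally likely
    ind_at <- which(stats::runif(length(q)) < indel_rate)
    if (length(ind_at) > 0L) {
      ins <- stats::runif(length(ind_at)) < 0.5
      for (k in rev(seq_along(ind_at))) {  # right-to-left keeps positions valid
        p <- ind_at[k]
        q <- if (ins[k]) {
          append(q, sample(letters_, 1L), after = p)
        } else {
          q[-p]
        }
      }
    }
    query[i] <- paste(q, collapse = "")
    ref[i] <- paste(r, collapse = "")
  }
  tibble(
    query_id = sprintf("q%d", seq_len(n_pairs) - 1L),
    query = query,
    ref_id = sprintf("r%d", seq_len(n_pairs) - 1L),
    ref = ref
  )
}

#' Full-matrix reference alignment (validation oracle)
#'
#' An independent Smith-Waterman/Gotoh implementation that stores the
#' complete E/F/H tables, fills them row by row (or column by column),
#' locates the maximum under the same tie-break as the wavefront engine,
#' counts the cells attaining it, and recovers the start by walking the
#' optimal path back to a zero cell. It shares no code with the wavefront
#' kernel and exists to validate it; it uses O(|Q| x |R|) memory by design.
#'
#' @param query,reference non-empty residue strings.
#' @inheritParams encode_sequence
#' @param fill table fill order, `"row"` or `"column"` (results must not
#'   depend on it).
#' @return A list with `score`, `query_start`, `query_end`, `ref_start`,
#'   `ref_end` (0-based inclusive, -1 sentinels when unaligned) and
#'   `n_optimal_cells`, the number of cells attaining the maximum score
#'   (1 marks a unique-optimum instance).
#' @examples
#' full_matrix_align("ACGT", "ACGT", dna_scheme())
#' @export
full_matrix_align <- function(query, reference, scheme,
                              fill = c("row", "column")) {
  check_scheme(scheme)
  fill <- match.arg(fill)
  stopifnot(is.character(query), length(query) == 1L,
            is.character(reference), length(reference) == 1L)
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    abort("empty sequence: both query and reference must be non-empty")
  }
  a <- scheme_cpp_args(scheme)
  .cpp_oracle(query, reference, a$lut, a$dna_mode, a$match_score,
              a$mismatch_penalty, a$n_plain, a$submat, a$gap_init, a$gap_ext,
              fill == "column")
}
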