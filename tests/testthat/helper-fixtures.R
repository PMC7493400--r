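# Shared fixtures: schemes, random sequence draws, and a comparison helper
# that pits the wavefront engine against the full-matrix oracle.

default_dna <- function() dna_scheme()  # 6 / 4 / 4 / 1
default_protein <- function() protein_scheme()  # BLOSUM62, 6 / 1

# stress schemes: extension dearer than opening, and an all-negative matrix
ext_heavy_dna <- function() {
  suppressWarnings(dna_scheme(match = 3, mismatch = 2, gap_open = 1, gap_extend = 3))
}

all_negative_scheme <- function() {
  m <- matrix(-2L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  protein_scheme(matrix = m, gap_open = 3, gap_extend = 1)
}

RESULT_COLS <- function() {
  c("pair_index", "query_id", "ref_id", "score", "query_start", "query_end",
    "ref_start", "ref_end", "aligned")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# engine vs oracle over a pair table; returns counts of disagreements
compare_engine_oracle <- function(pairs, scheme, with_start = TRUE) {
  res <- align_pairs(pairs, scheme, with_start = with_start)
  bad_score <- 0L; bad_ends <- 0L; bad_start <- 0L; n_unique <- 0L
  for (i in seq_len(nrow(pairs))) {
    o <- full_matrix_align(pairs$query[i], pairs$ref[i], scheme)
    if (res$score[i] != o$score) bad_score <- bad_score + 1L
    if (res$aligned[i] &&
        (res$query_end[i] != o$query_end || res$ref_end[i] != o$ref_end)) {
      bad_ends <- bad_ends + 1L
    }
    if (with_start && res$aligned[i] && o$n_optimal_cells == 1L) {
      n_unique <- n_unique + 1L
      if (res$query_start[i] != o$query_start ||
          res$ref_start[i] != o$ref_start) {
        bad_start <- bad_start + 1L
      }
    }
  }
  list(n = nrow(pairs), bad_score = bad_score, bad_ends = bad_ends,
       bad_start = bad_start, n_unique = n_unique)
}
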