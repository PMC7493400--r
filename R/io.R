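# Readers and writers: NCBI-format substitution matrices, FASTA/FASTQ
# sequence sets, and the TSV result table.

#' Read an NCBI-format substitution matrix
#'
#' Parses the whitespace-delimited scoring matrix format distributed by
#' NCBI: '#' comment lines and blank lines are ignored, the first remaining
#' line is the residue header, and each following line is a residue label
#' and one integer per header residue. Residues are normalized to upper
#' case. An asymmetric table triggers a warning (not an error); a missing
#' row or a short row is a parse error.
#'
#' @param path path to the matrix file.
#' @return Square integer matrix with identical residue row/column names.
#' @examples
#' m <- read_scoring_matrix(system.file("extdata", "BLOSUM62",
#'                                      package = "wavealign"))
#' m["A", "A"]
#' @export
read_scoring_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    abort(sprintf("'%s': not an NCBI matrix file (no header and data rows)", path))
  }
  header <- toupper(strsplit(trimws(lines[1]), "\\s+")[[1]])
  k <- length(header)
  body <- lines[-1]
  if (length(body) < k) {
    abort(sprintf("'%s': %d residues in header but only %d data rows",
                  path, k, length(body)))
  }
  if (length(body) > k) {
    abort(sprintf("'%s': %d residues in header but %d data rows",
                  path, k, length(body)))
  }
  labels <- character(k)
  scores <- matrix(NA_integer_, k, k)
  for (i in seq_len(k)) {
    fields <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(fields) != k + 1L) {
      abort(sprintf("'%s' row %d: expected residue label plus %d scores, found %d fields",
                    path, i, k, length(fields)))
    }
    labels[i] <- toupper(fields[1])
    vals <- suppressWarnings(as.integer(fields[-1]))
    if (anyNA(vals)) {
      abort(sprintf("'%s' row %d ('%s'): non-integer score", path, i, labels[i]))
    }
    scores[i, ] <- vals
  }
  if (!setequal(labels, header)) {
    abort(sprintf("'%s': row labels do not match header residues", path))
  }
  # accept row order differing from header order
  scores <- scores[match(header, labels), , drop = FALSE]
  dimnames(scores) <- list(header, header)
  if (!isSymmetric(unname(scores))) {
    warn(sprintf("'%s': substitution matrix is not symmetric", path))
  }
  scores
}

#' The packaged BLOSUM62 matrix
#'
#' Loads the standard NCBI-distribution BLOSUM62 substitution matrix shipped
#' with the package (24 residues: the 20 amino acids plus B, Z, X, *).
#'
#' @return 24 x 24 integer matrix.
#' @examples
#' blosum62()["A", "W"]
#' @export
blosum62 <- function() {
  read_scoring_matrix(system.file("extdata", "BLOSUM62",
                                  package = "wavealign", mustWork = TRUE))
}

#' Read sequences from FASTA or FASTQ
#'
#' Returns the sequences in file order as a tibble. Ids are the header up to
#' the first whitespace; residues are upper-cased; FASTQ qualities are
#' discarded. With `format = "auto"` the format is detected from the first
#' character of the file ('>' FASTA, '@' FASTQ). Windows line endings and a
#' missing final newline are tolerated. An empty file yields an empty
#' tibble.
#'
#' @param path path to the sequence file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  if (file.size(path) == 0L) {
    return(tibble(id = character(0), seq = character(0), length = integer(0)))
  }
  head_raw <- readBin(path, "raw", n = 4096L)
  if (format == "auto") {
    first <- rawToChar(head_raw[1])
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     abort(sprintf("'%s': cannot detect format from first character '%s'",
                                   path, first)))
  }
  # normalize CRLF for the Biostrings parser
  if (as.raw(13L) %in% readBin(path, "raw", n = file.size(path))) {
    txt <- readLines(path, warn = FALSE)
    path <- tempfile(fileext = paste0(".", format))
    on.exit(unlink(path), add = TRUE)
    writeLines(sub("\r$", "", txt), path)
  }
  set <- Biostrings::readBStringSet(path, format = format)
  tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = unname(toupper(as.character(set))),
    length = unname(Biostrings::width(set))
  )
}

#' Write sequences to FASTA
#'
#' @param seqs a data frame with columns `id` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(stats::setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

RESULT_COLUMNS <- c("pair_index", "query_id", "ref_id", "score",
                    "query_start", "query_end", "ref_start", "ref_end",
                    "aligned")

#' Write alignment results as TSV
#'
#' One header row, then one row per result with columns `pair_index`,
#' `query_id`, `ref_id`, `score`, `query_start`, `query_end`, `ref_start`,
#' `ref_end`, `aligned`. Coordinates are 0-based inclusive with -1
#' sentinels for unaligned pairs; `aligned` is written as `true`/`false`.
#' Byte output is deterministic for a fixed input.
#'
#' @param results an alignment result tibble (see [align_pairs()]).
#' @param path output path.
#' @return Number of data rows written.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  missing_cols <- setdiff(RESULT_COLUMNS, names(results))
  if (length(missing_cols) > 0L) {
    abort(paste0("results are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::select(as_tibble(results), dplyr::all_of(RESULT_COLUMNS))
  out$aligned <- ifelse(is.na(out$aligned), NA_character_,
                        ifelse(out$aligned, "true", "false"))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  nrow(out)
}

#' Read an alignment result TSV back into a tibble
#'
#' Inverse of [write_results()]; a write/read round trip reproduces the
#' in-memory records.
#'
#' @param path path to a TSV written by [write_results()].
#' @return A tibble with the result columns.
#' @export
read_results <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      pair_index = readr::col_integer(),
      query_id = readr::col_character(),
      ref_id = readr::col_character(),
      score = readr::col_integer(),
      query_start = readr::col_integer(),
      query_end = readr::col_integer(),
      ref_start = readr::col_integer(),
      ref_end = readr::col_integer(),
      aligned = readr::col_character()
    ),
    na = "NA", progress = FALSE
  )
  out$aligned <- c("true" = TRUE, "false" = FALSE)[out$aligned]
  names(out$aligned) <- NULL
  class(out) <- c("alignment_tbl", class(out))
  out
}
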