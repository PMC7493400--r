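# Scoring schemes: DNA match/mismatch scalars or a protein substitution
# matrix, plus affine gap penalties. Penalties are stored as non-negative
# magnitudes and subtracted during alignment. Opening a length-1 gap costs
# gap_open alone: gap_open replaces, not adds to, the first extension. Some
# libraries charge open + extend for the first gap residue; to reproduce
# their scores, pass gap_open' = gap_open + gap_extend there.

DNA_PLAIN <- c("A", "C", "G", "T")
DNA_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' DNA scoring scheme
#'
#' Match/mismatch scalar scoring with affine gap penalties. Defaults are the
#' conventional short-read settings: match 6, mismatch 4, gap open 4, gap
#' extend 1. All four values are non-negative magnitudes; mismatch and gap
#' penalties are subtracted during alignment. IUPAC ambiguity codes
#' (N, R, Y, S, W, K, M, B, D, H, V) are accepted in input and score as a
#' mismatch against every residue, including themselves.
#'
#' A length-1 gap costs `gap_open` alone (it replaces the first extension);
#' a length-k gap costs `gap_open + (k - 1) * gap_extend`.
#'
#' @param match non-negative integer added for identical plain bases.
#' @param mismatch non-negative integer subtracted for non-identical or
#'   ambiguous bases.
#' @param gap_open non-negative integer cost of opening a gap.
#' @param gap_extend non-negative integer cost of each further gap residue.
#' @return A `scoring_scheme` object.
#' @examples
#' dna_scheme()
#' dna_scheme(match = 1, mismatch = 1, gap_open = 2, gap_extend = 1)
#' @export
dna_scheme <- function(match = 6L, mismatch = 4L, gap_open = 4L,
                       gap_extend = 1L) {
  match <- check_nonneg_int(match, "match")
  mismatch <- check_nonneg_int(mismatch, "mismatch")
  gaps <- check_gaps(gap_open, gap_extend)
  alphabet <- c(DNA_PLAIN, DNA_AMBIG)
  new_scheme(
    mode = "dna", match = match, mismatch = mismatch,
    matrix = NULL, gap_open = gaps[1], gap_extend = gaps[2],
    alphabet = alphabet, lut = make_lut(alphabet), n_plain = 4L
  )
}

#' Protein scoring scheme
#'
#' Substitution-matrix scoring with affine gap penalties. The default matrix
#' is the packaged NCBI BLOSUM62 (see [blosum62()]), with gap open 6 and gap
#' extend 1. Residues absent from the matrix alphabet are rejected at
#' alignment time; ambiguity codes (B, Z, X, *) score by the matrix's own
#' rows.
#'
#' @param matrix square integer substitution matrix with residue dimnames,
#'   as returned by [read_scoring_matrix()] or [blosum62()].
#' @param gap_open,gap_extend non-negative integer gap penalties; see
#'   [dna_scheme()] for the first-gap-residue convention.
#' @return A `scoring_scheme` object.
#' @examples
#' protein_scheme()
#' @export
protein_scheme <- function(matrix = blosum62(), gap_open = 6L,
                           gap_extend = 1L) {
  matrix <- check_submatrix(matrix)
  gaps <- check_gaps(gap_open, gap_extend)
  alphabet <- rownames(matrix)
  new_scheme(
    mode = "protein", match = NA_integer_, mismatch = NA_integer_,
    matrix = matrix, gap_open = gaps[1], gap_extend = gaps[2],
    alphabet = alphabet, lut = make_lut(alphabet), n_plain = nrow(matrix)
  )
}

new_scheme <- function(mode, match, mismatch, matrix, gap_open, gap_extend,
                       alphabet, lut, n_plain) {
  structure(
    list(
      mode = mode, match = match, mismatch = mismatch, matrix = matrix,
      gap_open = gap_open, gap_extend = gap_extend, alphabet = alphabet,
      lut = lut, n_plain = n_plain
    ),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  if (x$mode == "dna") {
    cat(sprintf("<scoring_scheme: dna> match +%d, mismatch -%d, gap open %d, gap extend %d\n",
                x$match, x$mismatch, x$gap_open, x$gap_extend))
  } else {
    cat(sprintf("<scoring_scheme: protein> %dx%d matrix [%s...], gap open %d, gap extend %d\n",
                nrow(x$matrix), ncol(x$matrix),
                paste(utils::head(x$alphabet, 5), collapse = ""),
                x$gap_open, x$gap_extend))
  }
  invisible(x)
}

check_nonneg_int <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single non-negative integer", what))
  }
  as.integer(x)
}

check_gaps <- function(gap_open, gap_extend) {
  gap_open <- check_nonneg_int(gap_open, "gap_open")
  gap_extend <- check_nonneg_int(gap_extend, "gap_extend")
  if (gap_open < gap_extend) {
    warn(sprintf(
      "gap_open (%d) < gap_extend (%d): unusual affine penalties, proceeding anyway",
      gap_open, gap_extend
    ))
  }
  c(gap_open, gap_extend)
}

check_submatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m))) {
    abort("`matrix` must be a square matrix with residue dimnames")
  }
  storage.mode(m) <- "integer"
  if (anyNA(m)) abort("substitution matrix contains missing values")
  if (!identical(rownames(m), colnames(m))) {
    abort("substitution matrix row and column names differ")
  }
  if (anyDuplicated(rownames(m))) {
    abort("substitution matrix alphabet has duplicated residues")
  }
  if (!isSymmetric(unname(m))) {
    warn("substitution matrix is not symmetric")
  }
  m
}

# 256-entry character-code lookup; both cases map to the same 0-based code,
# -1 marks an invalid residue.
make_lut <- function(alphabet) {
  lut <- rep(-1L, 256L)
  up <- utf8ToInt(paste(alphabet, collapse = ""))
  lut[up + 1L] <- seq_along(alphabet) - 1L
  lo <- utf8ToInt(tolower(paste(alphabet, collapse = "")))
  keep <- lut[lo + 1L] == -1L  # don't clobber, e.g. '*' has no case
  lut[lo[keep] + 1L] <- (seq_along(alphabet) - 1L)[keep]
  lut
}

#' Encode a sequence as 0-based alphabet indices
#'
#' Maps each residue of `seq` to its index in the scheme's alphabet: for DNA,
#' the fixed ordering A, C, G, T then the ambiguity codes; for protein, the
#' substitution matrix header order. Case-insensitive.
#'
#' @param seq a single character string of residues.
#' @param scheme a [dna_scheme()] or [protein_scheme()].
#' @return Integer vector of 0-based indices, one per residue.
#' @examples
#' encode_sequence("ACGT", dna_scheme())
#' @export
encode_sequence <- function(seq, scheme) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  check_scheme(scheme)
  if (nchar(seq) == 0L) return(integer(0))
  codes <- scheme$lut[utf8ToInt(seq) + 1L]
  bad <- which(codes == -1L)
  if (length(bad) > 0L) {
    p <- bad[1]
    abort(sprintf("invalid residue '%s' at position %d",
                  substr(seq, p, p), p))
  }
  codes
}

#' Substitution score of two encoded residues
#'
#' DNA mode: `+match` when the codes are equal and neither is an ambiguity
#' code, else `-mismatch`. Protein mode: the matrix entry. Vectorized over
#' `a` and `b`.
#'
#' @param a,b integer vectors of 0-based encoded residues
#'   (see [encode_sequence()]).
#' @inheritParams encode_sequence
#' @return Integer vector of scores.
#' @examples
#' s <- dna_scheme(match = 6, mismatch = 4)
#' substitution_score(0L, 0L, s)  # A vs A: +6
#' substitution_score(0L, 3L, s)  # A vs T: -4
#' @export
substitution_score <- function(a, b, scheme) {
  check_scheme(scheme)
  k <- length(scheme$alphabet)
  if (any(a < 0L | a >= k) || any(b < 0L | b >= k)) {
    abort("encoded residues out of range for this scheme's alphabet")
  }
  if (scheme$mode == "dna") {
    ifelse(a == b & a < scheme$n_plain, scheme$match, -scheme$mismatch)
  } else {
    scheme$matrix[cbind(a + 1L, b + 1L)]
  }
}

#' Single Gotoh cell update
#'
#' The published affine-gap recurrence for one dynamic-programming cell:
#' \deqn{E = \max(E_{left} - g_{ext},\; H_{left} - g_{open})}
#' \deqn{F = \max(F_{up} - g_{ext},\; H_{up} - g_{open})}
#' \deqn{H = \max(E,\; F,\; H_{diag} + s,\; 0)}
#' `H` is floored at zero (local alignment); `E` and `F` are not.
#'
#' @param h_diag,h_up,h_left `H` values of the diagonal, upper and left
#'   neighbours.
#' @param e_left `E` of the left neighbour.
#' @param f_up `F` of the upper neighbour.
#' @param sub substitution score of the two residues at this cell.
#' @inheritParams encode_sequence
#' @return Named integer vector `c(h, e, f)`.
#' @examples
#' cell_update(0, 0, 0, 0, 0, 6, dna_scheme(gap_open = 4, gap_extend = 1))
#' @export
cell_update <- function(h_diag, h_up, h_left, e_left, f_up, sub, scheme) {
  check_scheme(scheme)
  e <- pmax(e_left - scheme$gap_extend, h_left - scheme$gap_open)
  f <- pmax(f_up - scheme$gap_extend, h_up - scheme$gap_open)
  h <- pmax(e, f, h_diag + sub, 0L)
  c(h = as.integer(h), e = as.integer(e), f = as.integer(f))
}

#' Express a DNA scheme as a substitution matrix
#'
#' Builds the substitution matrix equivalent to a DNA scheme's scalar
#' scoring: `+match` on the A/C/G/T diagonal, `-mismatch` everywhere else,
#' including every row and column of the ambiguity codes. Aligning in
#' protein (matrix) mode with this matrix reproduces DNA-mode results
#' exactly; it exists to bridge the two scoring paths for equivalence
#' testing.
#'
#' @param scheme a [dna_scheme()].
#' @return Square integer matrix with the DNA alphabet as dimnames.
#' @examples
#' dna_as_matrix(dna_scheme(match = 6, mismatch = 4))[1:4, 1:4]
#' @export
dna_as_matrix <- function(scheme) {
  check_scheme(scheme)
  if (scheme$mode != "dna") {
    abort("dna_as_matrix() requires a DNA scheme, got a protein scheme")
  }
  k <- length(scheme$alphabet)
  m <- matrix(-scheme$mismatch, k, k,
              dimnames = list(scheme$alphabet, scheme$alphabet))
  diag(m)[seq_len(scheme$n_plain)] <- scheme$match
  storage.mode(m) <- "integer"
  m
}

check_scheme <- function(scheme) {
  if (!inherits(scheme, "scoring_scheme")) {
    abort("`scheme` must be a scoring_scheme (see dna_scheme(), protein_scheme())")
  }
  invisible(scheme)
}

# arguments handed to the C++ kernels, in one place
scheme_cpp_args <- function(scheme) {
  dna <- scheme$mode == "dna"
  list(
    lut = scheme$lut,
    dna_mode = dna,
    match_score = if (dna) scheme$match else 0L,
    mismatch_penalty = if (dna) scheme$mismatch else 0L,
    n_plain = scheme$n_plain,
    submat = if (dna) matrix(0L, 1L, 1L) else scheme$matrix,
    gap_init = scheme$gap_open,
    gap_ext = scheme$gap_extend
  )
}
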