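# Scoring primitives: residue encoding, substitution lookup, the single-cell
# Gotoh update, and the DNA-as-matrix bridge.

test_that("encode_sequence maps residues to alphabet indices", {
  s <- default_dna()
  expect_identical(encode_sequence("ACGT", s), 0:3)
  expect_identical(encode_sequence("acgt", s), 0:3)  # case-insensitive
  expect_identical(encode_sequence("", s), integer(0))
  expect_identical(encode_sequence("N", s), 4L)  # first ambiguity code

  # protein indices follow the BLOSUM62 header order read from the file
  m <- blosum62()
  sp <- default_protein()
  expect_identical(encode_sequence("ARNDX", sp),
                   match(c("A", "R", "N", "D", "X"), rownames(m)) - 1L)

  expect_error(encode_sequence("ACGU", s), "invalid residue 'U' at position 4")
  expect_error(encode_sequence("AR1D", sp), "invalid residue '1' at position 3")
})

test_that("substitution_score follows mode semantics and paper defaults", {
  s <- dna_scheme(match = 6, mismatch = 4)
  A <- 0L; T_ <- 3L; N <- 4L
  expect_identical(substitution_score(A, A, s), 6L)
  expect_identical(substitution_score(A, T_, s), -4L)
  # ambiguity codes mismatch everything, including themselves
  expect_identical(substitution_score(N, N, s), -4L)
  expect_identical(substitution_score(N, A, s), -4L)

  m <- blosum62()
  sp <- default_protein()
  enc <- function(ch) encode_sequence(ch, sp)
  expect_identical(substitution_score(enc("A"), enc("A"), sp), m["A", "A"])
  expect_identical(substitution_score(enc("A"), enc("W"), sp), m["A", "W"])
})

test_that("substitution_score is symmetric for symmetric tables", {
  s <- default_dna()
  sp <- default_protein()
  k_dna <- length(s$alphabet)
  for (rep in 1:50) {
    a <- sample.int(k_dna, 1) - 1L; b <- sample.int(k_dna, 1) - 1L
    expect_identical(substitution_score(a, b, s), substitution_score(b, a, s))
    ap <- sample.int(24, 1) - 1L; bp <- sample.int(24, 1) - 1L
    expect_identical(substitution_score(ap, bp, sp),
                     substitution_score(bp, ap, sp))
  }
})

test_that("cell_update implements the affine-gap recurrence", {
  s <- dna_scheme(match = 6, mismatch = 4, gap_open = 4, gap_extend = 1)
  expect_identical(cell_update(0, 0, 0, 0, 0, 6, s), c(h = 6L, e = -1L, f = -1L))
  expect_identical(cell_update(0, 0, 0, 0, 0, -4, s), c(h = 0L, e = -1L, f = -1L))
  expect_identical(
    cell_update(h_diag = 6, h_up = 0, h_left = 6, e_left = -1, f_up = -1,
                sub = -4, s),
    c(h = 2L, e = 2L, f = -2L)
  )
})

test_that("cell_update floors H at zero but never E or F", {
  s <- dna_scheme(match = 2, mismatch = 5, gap_open = 6, gap_extend = 2)
  for (rep in 1:200) {
    v <- sample(-30:30, 6, replace = TRUE)
    out <- cell_update(v[1], v[2], v[3], v[4], v[5], v[6], s)
    expect_gte(out[["h"]], 0L)
    expect_identical(out[["e"]], max(v[4] - 2L, v[3] - 6L))
    expect_identical(out[["f"]], max(v[5] - 2L, v[2] - 6L))
  }
})

test_that("dna_as_matrix reproduces scalar DNA scoring", {
  s <- dna_scheme(match = 6, mismatch = 4)
  m <- dna_as_matrix(s)
  expect_identical(unname(diag(m)[1:4]), rep(6L, 4))
  expect_true(all(m[upper.tri(m)] == -4L))
  expect_identical(m["N", "N"], -4L)  # ambiguity rows mismatch themselves

  z <- dna_as_matrix(dna_scheme(match = 0, mismatch = 0, gap_open = 4))
  expect_true(all(z == 0L))

  expect_error(dna_as_matrix(default_protein()), "DNA scheme")
})

test_that("scheme validation warns on unusual gaps and rejects bad input", {
  expect_warning(dna_scheme(gap_open = 1, gap_extend = 3), "gap_open")
  expect_error(dna_scheme(match = -1), "non-negative")
  expect_error(protein_scheme(matrix = matrix(1, 2, 3)), "square")
  asym <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
                 dimnames = list(c("A", "C"), c("A", "C")))
  expect_warning(protein_scheme(matrix = asym), "not symmetric")
})
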