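# Forward scoring phase: active window geometry, engine contract, oracle
# equivalence, and the O(|Q|) working-state guarantee.

test_that("active_range traces the grow/constant/shrink window", {
  expect_identical(active_range(0, 6, 9), c(lo = 0L, hi = 0L))
  expect_identical(active_range(7, 6, 9), c(lo = 0L, hi = 5L))  # full width
  expect_identical(active_range(13, 6, 9), c(lo = 5L, hi = 5L))  # last diagonal

  # width profile over a full sweep: +1 per step below n, constant to m, -1 after
  n <- 5L; m <- 12L
  widths <- vapply(0:(n + m - 2), function(I) {
    r <- active_range(I, n, m); r[["hi"]] - r[["lo"]] + 1L
  }, integer(1))
  expect_identical(widths, c(1:5, rep(5L, m - n), 4:1))

  expect_error(active_range(14, 6, 9), "contract violation")
  expect_error(active_range(-1, 6, 9), "contract violation")
  expect_error(active_range(3, 9, 6), "contract violation")
})

test_that("forward_score matches hand-checked and oracle results", {
  s <- default_dna()
  e <- forward_score("ACGT", "ACGT", s)
  expect_identical(e$score, 24L)
  expect_identical(e$query_end, 3L)
  expect_identical(e$ref_end, 3L)
  expect_true(e$aligned)

  e0 <- forward_score("AAAA", "TTTT", s)
  expect_identical(e0$score, 0L)
  expect_identical(e0$query_end, -1L)
  expect_identical(e0$ref_end, -1L)
  expect_false(e0$aligned)

  g <- forward_score("GGTTGACTA", "TGTTACGGAT", s)
  o <- full_matrix_align("GGTTGACTA", "TGTTACGGAT", s)
  expect_identical(g$score, o$score)
  expect_identical(g$query_end, o$query_end)
  expect_identical(g$ref_end, o$ref_end)

  expect_error(forward_score("", "ACGT", s), "empty")
  expect_error(forward_score("ACGTA", "ACGT", s), "role-order contract violation")
})

test_that("engine equals the full-matrix oracle across a parameter grid", {
  set.seed(101)
  schemes <- list(default_dna(), ext_heavy_dna(),
                  dna_scheme(match = 1, mismatch = 1, gap_open = 2, gap_extend = 1))
  for (rep in 1:120) {
    sch <- schemes[[1 + rep %% length(schemes)]]
    n <- sample(1:60, 1); m <- sample(n:120, 1)
    q <- random_dna(n); r <- random_dna(m)
    e <- forward_score(q, r, sch)
    o <- full_matrix_align(q, r, sch)
    expect_identical(e$score, o$score)
    expect_identical(e$query_end, o$query_end)
    expect_identical(e$ref_end, o$ref_end)
  }
})

test_that("appending residues never decreases the score", {
  set.seed(102)
  s <- default_dna()
  for (rep in 1:40) {
    q <- random_dna(sample(5:30, 1))
    r <- random_dna(sample(40:80, 1))
    base <- forward_score(q, r, s)$score
    expect_gte(forward_score(paste0(q, random_dna(3)), r, s)$score, base)
    expect_gte(forward_score(q, paste0(random_dna(3), r), s)$score, base)
  }
})

test_that("score is bounded by |Q| times the maximum substitution score", {
  set.seed(103)
  s <- dna_scheme(match = 5, mismatch = 2, gap_open = 3, gap_extend = 1)
  for (rep in 1:40) {
    n <- sample(1:40, 1)
    q <- random_dna(n); r <- random_dna(sample(n:90, 1))
    sc <- forward_score(q, r, s)$score
    expect_gte(sc, 0L)
    expect_lte(sc, n * 5L)
  }
})

test_that("swapping query and reference preserves the score", {
  set.seed(104)
  s <- default_dna()
  for (rep in 1:40) {
    n <- sample(2:40, 1); m <- sample(n:80, 1)
    q <- random_dna(n); r <- random_dna(m)
    a <- align_pair(q, r, s)
    b <- align_pair(r, q, s)  # engine swaps internally, transposes back
    expect_identical(a$score, b$score)
    if (a$aligned) {
      o <- full_matrix_align(r, q, s)
      expect_identical(b$score, o$score)
    }
  }
})

test_that("working state is linear in query length, independent of reference", {
  s <- default_dna()
  set.seed(105)
  q <- random_dna(300)
  w_long <- attr(forward_score(q, random_dna(1200), s), "work_ints")
  w_short <- attr(forward_score(q, random_dna(600), s), "work_ints")
  expect_identical(w_long, w_short)      # no dependence on |R|
  expect_identical(w_long, 6 * 300)      # two H diagonals + E/F + column maxima
  w_half <- attr(forward_score(random_dna(150), random_dna(1200), s), "work_ints")
  expect_identical(w_half, 6 * 150)      # scales with |Q|
})

test_that("engine agrees with an established affine-gap aligner", {
  # Biostrings charges open+extend for a gap's first residue; this engine
  # charges gap_open alone, so gapOpening is lowered by one gap_extend.
  set.seed(106)
  s <- dna_scheme(match = 6, mismatch = 4, gap_open = 4, gap_extend = 1)
  mat <- dna_as_matrix(s)[1:4, 1:4]
  for (rep in 1:25) {
    q <- random_dna(sample(10:50, 1))
    r <- random_dna(sample(50:120, 1))
    ours <- forward_score(q, r, s)$score
    ref <- Biostrings::pairwiseAlignment(
      q, r, type = "local", substitutionMatrix = mat,
      gapOpening = 3, gapExtension = 1, scoreOnly = TRUE
    )
    expect_identical(ours, as.integer(ref))
  }
})

test_that("reduce_best applies the smallest-column tie-break", {
  no_hit <- tibble::tibble(column = 0:3, row = rep(-1L, 4), max = rep(0L, 4))
  z <- reduce_best(no_hit)
  expect_identical(z$score, 0L)
  expect_identical(z$query_end, -1L)
  expect_identical(z$ref_end, -1L)

  single <- tibble::tibble(column = 0:2, row = c(5L, 2L, 7L), max = c(3L, 9L, 4L))
  b <- reduce_best(single)
  expect_identical(b$query_end, 1L)
  expect_identical(b$ref_end, 2L)
  expect_identical(b$score, 9L)

  tied <- tibble::tibble(column = 0:2, row = c(5L, 2L, 7L), max = c(3L, 9L, 9L))
  expect_identical(reduce_best(tied)$query_end, 1L)  # smaller column wins
})
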