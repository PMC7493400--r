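# Batch driver: even work partitioning, order preservation, scheduling
# invisibility, role enforcement and error policy.

test_that("partition_work splits evenly, larger shares first", {
  p <- partition_work(10, 4)
  expect_identical(p$size, c(3L, 3L, 2L, 2L))
  expect_identical(p$lo, c(0L, 3L, 6L, 8L))
  expect_identical(p$hi, c(3L, 6L, 8L, 10L))

  p0 <- partition_work(0, 8)
  expect_identical(nrow(p0), 8L)
  expect_true(all(p0$size == 0L))

  big <- partition_work(1000003, 8)
  expect_identical(sum(big$size), 1000003L)
  expect_lte(max(big$size) - min(big$size), 1L)

  expect_error(partition_work(5, 0), "config error")
})

test_that("partition ranges are disjoint and cover [0, N) for random draws", {
  set.seed(301)
  for (rep in 1:200) {
    N <- sample(0:5000, 1); w <- sample(1:16, 1)
    p <- partition_work(N, w)
    expect_identical(sum(p$size), N)
    expect_lte(max(p$size) - min(p$size), 1L)
    covered <- unlist(Map(function(lo, hi) if (hi > lo) lo:(hi - 1L) else integer(0),
                          p$lo, p$hi))
    expect_identical(sort(covered), if (N > 0) 0:(N - 1L) else integer(0))
    expect_identical(anyDuplicated(covered), 0L)
  }
})

test_that("align_pairs equals elementwise align_pair, in input order", {
  s <- default_dna()
  pairs <- tibble::tibble(
    query = c("ACGT", "CGT", "AAAA"),
    ref = c("ACGT", "AACGTAA", "TTTT")
  )
  res <- align_pairs(pairs, s)
  expect_identical(res$pair_index, 0:2)
  for (i in 1:3) {
    one <- align_pair(pairs$query[i], pairs$ref[i], s)
    expect_identical(res$score[i], one$score)
    expect_identical(res$query_start[i], one$query_start)
    expect_identical(res$query_end[i], one$query_end)
    expect_identical(res$ref_start[i], one$ref_start)
    expect_identical(res$ref_end[i], one$ref_end)
  }
})

test_that("empty batches and length mismatches are handled up front", {
  s <- default_dna()
  empty <- tibble::tibble(query = character(0), ref = character(0))
  res <- align_pairs(empty, s)
  expect_identical(nrow(res), 0L)

  q <- tibble::tibble(id = c("a", "b"), seq = c("ACGT", "ACGT"))
  r <- tibble::tibble(id = "c", seq = "ACGT")
  expect_error(pair_sequences(q, r), "one-to-one")
})

test_that("workers and batch_size never change any output value", {
  pairs <- simulate_pairs(400, query_len = c(30, 60), ref_len = c(60, 150),
                          identity = 0.9, indel_rate = 0.02, seed = 41)
  s <- default_dna()
  a <- align_pairs(pairs, s, workers = 1, batch_size = 20000)
  b <- align_pairs(pairs, s, workers = 4, batch_size = 37)
  c_ <- align_pairs(pairs, s, workers = 7, batch_size = 1)
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "total_cells") <- NULL; attr(x, "elapsed_s") <- NULL
    attr(x, "with_start") <- NULL
    x
  }
  expect_identical(strip(a), strip(b))
  expect_identical(strip(a), strip(c_))
  expect_identical(attr(a, "total_cells"), attr(b, "total_cells"))
})

test_that("role enforcement swaps per pair; coordinates keep original roles", {
  s <- default_dna()
  # query longer than reference: must swap internally under the default
  res <- align_pairs(tibble::tibble(query = "AAACGTAAA", ref = "ACGT"), s)
  o <- full_matrix_align("AAACGTAAA", "ACGT", s)
  expect_identical(res$score[1], o$score)
  expect_true(res$query_end[1] <= 8L && res$ref_end[1] <= 3L)

  expect_error(
    align_pairs(tibble::tibble(query = "AAACGTAAA", ref = "ACGT"), s,
                enforce_query_shorter = FALSE),
    "pair 0"
  )
})

test_that("per-pair errors abort with the pair index, or sentinel in permissive mode", {
  s <- default_dna()
  pairs <- tibble::tibble(query = c("ACGT", "ACXT", "CGT"),
                          ref = c("ACGT", "ACGT", "ACGTT"))
  expect_error(align_pairs(pairs, s), "pair 1.*invalid residue 'X'")

  res <- align_pairs(pairs, s, on_error = "permissive")
  expect_identical(nrow(res), 3L)
  expect_true(is.na(res$score[2]) && is.na(res$aligned[2]))
  expect_false(anyNA(res$score[c(1, 3)]))

  empty_seq <- tibble::tibble(query = c("ACGT", ""), ref = c("ACGT", "ACGT"))
  expect_error(align_pairs(empty_seq, s), "pair 1.*empty")
})

test_that("gcups implements the throughput definition", {
  expect_identical(gcups(1e9, 1), 1.0)
  expect_identical(gcups(0, 5), 0.0)
  expect_error(gcups(100, 0), "measurement error")
  expect_error(gcups(100, -2), "measurement error")

  pairs <- simulate_pairs(20, query_len = c(10, 20), ref_len = c(20, 40), seed = 42)
  res <- align_pairs(pairs, default_dna())
  expect_identical(attr(res, "total_cells"),
                   as.numeric(sum(nchar(pairs$query) * nchar(pairs$ref))))
})

test_that("glance and autoplot summarise a result table", {
  pairs <- simulate_pairs(30, query_len = c(10, 20), ref_len = c(20, 40), seed = 43)
  res <- align_pairs(pairs, default_dna())
  g <- glance(res)
  expect_identical(g$n_pairs, 30L)
  expect_identical(g$n_aligned, sum(res$aligned))
  expect_true(g$total_cells > 0)

  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("long queries trigger the design-envelope warning", {
  s <- default_dna()
  set.seed(302)
  pairs <- tibble::tibble(query = random_dna(30), ref = random_dna(60))
  expect_warning(align_pairs(pairs, s, warn_query_len = 20), "design envelope")
})
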