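mk_compat <- function(reads) {
  # reads: list of character vectors of candidate transcripts
  rows <- do.call(rbind, lapply(seq_along(reads), function(r)
    data.frame(read_id = paste0("r", r), transcript_id = reads[[r]],
               pos = 0, stringsAsFactors = FALSE)))
  compat_matrix(rows)
}

test_that("compatibility matrix and alignment readers validate input", {
  expect_error(compat_matrix(data.frame(
    read_id = c("r", "r"), transcript_id = "A", pos = 0)), "duplicate")

  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:A\tLN:500",
               "r1\t0\tA\t11\t255\t100M\t*\t0\t0\t*\t*",
               "r1\t0\tB\t1\t255\t100M\t*\t0\t0\t*\t*",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  cm <- read_alignments(sam, "sam")
  expect_equal(cm$N, 1L)          # the unaligned read is depth only
  expect_equal(cm$depth, 2L)
  expect_equal(sort(cm$aln$pos), c(0L, 10L))  # POS is 1-based in SAM

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("read_id\ttranscript_id\tpos", "r1\tA\t5"), tsv)
  expect_equal(read_alignments(tsv, "tsv")$aln$pos, 5L)
})

test_that("EM reproduces symmetric and winner-takes-all optima", {
  # 3 unique A + 3 unique B + 4 shared, equal lengths -> theta (1/2, 1/2)
  reads <- c(replicate(3, "A", simplify = FALSE),
             replicate(3, "B", simplify = FALSE),
             replicate(4, c("A", "B"), simplify = FALSE))
  em <- em_quantify(mk_compat(reads), c(A = 100, B = 100))
  expect_equal(em$theta, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(em$expected_count), 10)       # ML counts sum to N
  expect_equal(sum(em$tpm), 1e6, tolerance = 1e-3)

  # 2 unique A + 2 shared: L ~ theta_A^2 -> all mass on A
  reads2 <- c(replicate(2, "A", simplify = FALSE),
              replicate(2, c("A", "B"), simplify = FALSE))
  em2 <- em_quantify(mk_compat(reads2), c(A = 100, B = 100))
  expect_equal(em2$theta[1L], 1, tolerance = 1e-3)

  # unequal lengths: maximising x - x^3 gives theta_A = 1/sqrt(3)
  reads3 <- list("A", "B", c("A", "B"))
  em3 <- em_quantify(mk_compat(reads3), c(A = 100, B = 200))
  expect_equal(em3$theta[1L], 1 / sqrt(3), tolerance = 1e-4)

  # log-likelihood trace is non-decreasing
  expect_true(all(diff(attr(em3, "log_likelihood")) > -1e-9))

  expect_error(em_quantify(mk_compat(list("Z")), c(A = 100)), "unknown")
})

test_that("EM matches exhaustive grid search on random 2-transcript data", {
  set.seed(11)
  for (rep in 1:10) {
    eff <- c(A = sample(50:300, 1), B = sample(50:300, 1))
    reads <- lapply(seq_len(sample(3:12, 1)), function(i)
      sample(list("A", "B", c("A", "B")), 1)[[1L]])
    if (!any(vapply(reads, function(x) "A" %in% x, TRUE)) ||
        !any(vapply(reads, function(x) "B" %in% x, TRUE))) next
    em <- em_quantify(mk_compat(reads), eff)
    cand <- lapply(reads, function(x) match(x, c("A", "B")))
    xhat <- grid_search_2tx(cand, unname(eff))
    expect_equal(em$theta[1L], xhat, tolerance = 2e-3)
  }
})

test_that("Gibbs posterior means obey Dirichlet conjugacy", {
  # all reads unique: posterior mean is exactly (n + alpha) / (N + A)
  reads <- c(replicate(3, "A", simplify = FALSE), list("B"))
  pr <- prior_spec(c(1, 1), c(A = 1L, B = 2L))
  g <- gibbs_quantify(mk_compat(reads), c(A = 100, B = 100), pr,
                      n_samples = 5, burn_in = 2, seed = 1)
  expect_equal(g$theta, c(4 / 6, 2 / 6))
  expect_equal(g$expected_count, c(3, 1))

  # no reads at all: the posterior mean is the prior mean alpha / sum
  empty <- structure(list(
    aln = data.frame(read = integer(), transcript_id = character(),
                     pos = integer()),
    read_ids = character(), N = 0L, depth = 0L), class = "compat_matrix")
  pr2 <- prior_spec(c(0.60, 0.04), c(A = 1L, B = 2L))
  g0 <- gibbs_quantify(empty, c(A = 100, B = 100), pr2, n_samples = 5,
                       burn_in = 0, seed = 1)
  expect_equal(g0$theta, c(0.9375, 0.0625))

  # one fully ambiguous read leaves the posterior mean at the prior mean
  amb <- mk_compat(list(c("A", "B")))
  g1 <- gibbs_quantify(amb, c(A = 100, B = 100), pr2, n_samples = 4000,
                       burn_in = 100, seed = 3)
  # exact enumeration oracle over the 2 assignment states
  want <- oracle_posterior_mean(list(1:2), c(100, 100), c(0.60, 0.04))
  expect_equal(want[1L], 0.9375, tolerance = 1e-12)  # equals prior mean
  se <- sqrt(0.9375 * 0.0625) * (1.60 / 1.64 - 0.60 / 1.64) / sqrt(4000)
  expect_lt(abs(g1$theta[1L] - want[1L]), 3 * se)

  # enumeration oracle on a 3-read mixed case
  reads3 <- list("A", c("A", "B"), c("A", "B"))
  g3 <- gibbs_quantify(mk_compat(reads3), c(A = 100, B = 150), pr2,
                       n_samples = 6000, burn_in = 200, seed = 4)
  want3 <- oracle_posterior_mean(list(1, 1:2, 1:2), c(100, 150),
                                 c(0.60, 0.04))
  expect_equal(g3$theta, want3, tolerance = 0.01)

  expect_error(gibbs_quantify(amb, c(A = 100, B = 100),
                              prior_spec(1, c(A = 1L)), seed = 1), "B")
})

test_that("Gibbs output is bit-identical under a fixed seed", {
  reads <- c(replicate(5, c("A", "B"), simplify = FALSE), list("A"))
  pr <- prior_spec(c(0.5, 0.5), c(A = 1L, B = 2L))
  g1 <- gibbs_quantify(mk_compat(reads), c(A = 80, B = 120), pr,
                       n_samples = 50, burn_in = 20, seed = 99)
  g2 <- gibbs_quantify(mk_compat(reads), c(A = 80, B = 120), pr,
                       n_samples = 50, burn_in = 20, seed = 99)
  expect_identical(g1, g2)
  expect_equal(sum(g1$tpm), 1e6, tolerance = 1e-3)
})

test_that("uniform prior variants behave as pseudocount limits", {
  reads <- c(replicate(3, "A", simplify = FALSE), list("B"))
  u <- uniform_prior_variant(mk_compat(reads), c(A = 100, B = 100),
                             pseudocount = 1, n_samples = 5, burn_in = 2,
                             seed = 1)
  expect_equal(u$theta, c(4 / 6, 2 / 6))
  # equivalent to gibbs_quantify with an explicitly uniform prior
  pr <- prior_spec(1, c(A = 1L, B = 1L))
  g <- gibbs_quantify(mk_compat(reads), c(A = 100, B = 100), pr,
                      n_samples = 5, burn_in = 2, seed = 1)
  expect_equal(u$theta, g$theta)
  # large pseudocount pulls theta to uniform
  big <- uniform_prior_variant(mk_compat(reads), c(A = 100, B = 100),
                               pseudocount = 1e6, n_samples = 5,
                               burn_in = 2, seed = 1)
  expect_equal(big$theta, c(0.5, 0.5), tolerance = 1e-4)
  expect_error(uniform_prior_variant(mk_compat(reads), c(A = 100, B = 100),
                                     pseudocount = 0), "positive")
})

test_that("gene aggregation and expressed calls", {
  est <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    expected_count = c(5, 5, 10),
                    tpm = c(6e5, 4e5, 0), stringsAsFactors = FALSE)
  g <- aggregate_genes(est, c(t1 = "g1", t2 = "g1", t3 = "g2"))
  expect_equal(g$tpm[g$gene_id == "g1"], 1e6)
  expect_equal(g$expected_count[g$gene_id == "g2"], 10)
  # permuting isoform order gives the identical table
  expect_equal(aggregate_genes(est[3:1, ],
                               c(t1 = "g1", t2 = "g1", t3 = "g2")), g)
  expect_error(aggregate_genes(est, c(t1 = "g1")), "not mapped")

  expect_true(call_expressed(c(u = 1.0))[["u"]])    # inclusive boundary
  expect_false(call_expressed(c(u = 0.99))[["u"]])
  expect_equal(unname(vapply(c(0.5, 1, 2), function(ct)
    call_expressed(c(u = 0.7), ct)[["u"]], TRUE)),
    c(TRUE, FALSE, FALSE))
  expect_error(call_expressed(c(u = 1), 0), "positive")
})
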