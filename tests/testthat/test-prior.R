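test_that("DM log-likelihood matches closed forms and normalises", {
  # with unit alpha the DM is uniform over the compositions of N
  expect_equal(dm_log_likelihood(c(1, 1), 1), log(1 / 3), tolerance = 1e-12)
  expect_equal(dm_log_likelihood(c(2, 0), 1), log(1 / 3), tolerance = 1e-12)
  expect_equal(exp(dm_log_likelihood(c(5, 0), c(0.60, 0.04),
                                     labels = c(1, 2))),
               0.88, tolerance = 5e-3)
  expect_error(dm_log_likelihood(c(1, 1), c(1, -1), labels = c(1, 2)),
               "positive")

  # sum over all compositions is 1 for several (N, K, alpha) settings
  for (cfg in list(list(N = 4, a = c(0.5, 2)),
                   list(N = 6, a = c(1, 1, 1)),
                   list(N = 5, a = c(0.60, 0.04, 3)))) {
    K <- length(cfg$a)
    comps <- expand.grid(rep(list(0:cfg$N), K))
    comps <- comps[rowSums(comps) == cfg$N, , drop = FALSE]
    tot <- sum(apply(comps, 1, function(n)
      exp(dm_log_likelihood(as.numeric(n), cfg$a, labels = seq_len(K)))))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("fit_prior finds boundary optima of monotone likelihoods", {
  # counts (1,1): DM probability a/(2a+1) increases in a -> upper bound
  f1 <- fit_prior(training_set(c("a", "b"), c(1, 1), c(1, 1)))
  expect_equal(f1$alpha, 1e4)
  # counts (5,0): likelihood -> 1/2 as a -> 0 -> lower bound
  f2 <- fit_prior(training_set(c("a", "b"), c(5, 0), c(1, 1)))
  expect_equal(f2$alpha, 1e-4)
  # two-partition fit is never worse than single-partition (nesting)
  cnt <- c(40, 55, 2, 0, 1, 60, 33, 0)
  lab <- c(1, 1, 2, 2, 2, 1, 1, 2)
  ll2 <- fit_prior(training_set(letters[1:8], cnt, lab))$log_likelihood
  ll1 <- fit_prior(training_set(letters[1:8], cnt,
                                rep(1, 8)))$log_likelihood
  expect_gte(ll2, ll1 - 1e-6)
})

test_that("fit_prior recovers simulated pseudocounts, improving with size", {
  truth <- c(0.60, 0.04)
  err_at <- function(n_units, seed) {
    a <- rep(truth, each = n_units / 2)
    cnt <- simulate_dm_counts(a, N = 50 * n_units, seed = seed)
    fit <- fit_prior(training_set(paste0("u", seq_len(n_units)), cnt,
                                  rep(1:2, each = n_units / 2)))
    max(abs(fit$alpha - truth) / truth)
  }
  errs <- vapply(c(50, 200, 1000), function(n)
    stats::median(vapply(1:5, function(s) err_at(n, 100 * n + s),
                         numeric(1L))), numeric(1L))
  expect_lt(errs[3], 0.2)
  expect_true(errs[3] <= errs[1])  # monotone improvement with training size
})

test_that("partition models assign labels as specified", {
  feats <- data.frame(unit_id = c("a", "b", "c"),
                      has_peak = c(TRUE, FALSE, TRUE),
                      signal = c(5, 0, 9))
  expect_equal(unname(partition_units(feats, partition_model())),
               c(1L, 2L, 1L))
  expect_equal(unname(partition_units(feats,
                                      partition_model("no_partition"))),
               rep(1L, 3))
  flat <- within(feats, signal <- 1)
  expect_error(partition_units(flat,
                               partition_model("signal_quantile", k = 2)),
               "distinct")
  q2 <- partition_units(data.frame(unit_id = letters[1:4],
                                   signal = c(1, 2, 10, 20)),
                        partition_model("signal_quantile", k = 2))
  expect_equal(unname(q2), c(1L, 1L, 2L, 2L))

  # perfectly separable logistic responses reproduce the threshold rule
  set.seed(1)
  sig <- c(runif(20, 0, 1), runif(20, 10, 20))
  resp <- sig > 5
  lab <- partition_units(data.frame(unit_id = paste0("u", 1:40),
                                    signal = sig),
                         partition_model("logistic_combined"),
                         response = resp)
  expect_true(all(lab[resp] == lab[resp][1L]))
  expect_true(all(lab[!resp] == lab[!resp][1L]))
  expect_true(lab[resp][1L] != lab[!resp][1L])
  expect_error(partition_units(feats,
                               partition_model("logistic_combined")),
               "responses")
})

test_that("training set eligibility excludes ambiguous peaks and genes", {
  mk_ts <- function() transcript_set(rbind(
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c",
               strand = "+", start = 0, end = 1000),
    data.frame(transcript_id = "t2", gene_id = "g2", chrom = "c",
               strand = "+", start = 20000, end = 21000)))
  ts <- mk_ts()
  memb <- cluster_tss_groups(ts)
  peaks <- data.frame(chrom = "c", start = 0, end = 100, signal = 5)
  counts <- c(t1 = 40, t2 = 2)
  tr <- build_training_set(ts, memb, peaks, counts)
  expect_setequal(tr$unit_ids, c("t1", "t2"))
  expect_equal(tr$counts[match("t1", tr$unit_ids)], 40)

  # overlapping genes are excluded entirely
  ov <- transcript_set(rbind(
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c",
               strand = "+", start = 0, end = 1000),
    data.frame(transcript_id = "t2", gene_id = "g2", chrom = "c",
               strand = "+", start = 500, end = 1500),
    data.frame(transcript_id = "t3", gene_id = "g3", chrom = "c",
               strand = "+", start = 30000, end = 31000)))
  tr2 <- build_training_set(ov, cluster_tss_groups(ov), peaks,
                            c(t1 = 1, t2 = 1, t3 = 5))
  expect_equal(tr2$unit_ids, "t3")

  # overlapping TSS-group windows exclude their members
  near <- transcript_set(rbind(
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c",
               strand = "+", start = 0, end = 5000),
    data.frame(transcript_id = "t2", gene_id = "g1", chrom = "c",
               strand = "+", start = 700, end = 5000),
    data.frame(transcript_id = "t3", gene_id = "g3", chrom = "c",
               strand = "+", start = 30000, end = 31000)))
  # t1/t2 TSSs 700 apart: two groups with windows [tss-500, tss+500]
  # that overlap each other -> excluded
  tr3 <- build_training_set(near, cluster_tss_groups(near), peaks,
                            c(t1 = 1, t2 = 1, t3 = 5))
  expect_equal(tr3$unit_ids, "t3")

  expect_error(build_training_set(ov, cluster_tss_groups(ov), peaks,
                                  c(t1 = 1, t2 = 1)),
               "quantified count")
})

test_that("prior source comparison ranks informative labels first", {
  set.seed(7)
  wins <- 0L
  for (s in 1:25) {
    a <- rep(c(0.60, 0.04), each = 60)
    cnt <- simulate_dm_counts(a, N = 6000, seed = 500 + s)
    lab <- rep(1:2, each = 60)
    set.seed(900 + s)
    cand <- list(informative = lab, permuted = sample(lab))
    res <- compare_prior_sources(cnt, cand)
    if (res$source[1L] == "informative") wins <- wins + 1L
  }
  expect_gte(wins / 25, 0.95)

  cnt <- c(10, 0, 7, 1)
  one <- compare_prior_sources(cnt, list(only = c(1, 2, 1, 2)))
  expect_equal(one$source, "only")
  twin <- compare_prior_sources(cnt, list(a = c(1, 2, 1, 2),
                                          b = c(1, 2, 1, 2)))
  expect_equal(twin$log_likelihood[1], twin$log_likelihood[2],
               tolerance = 1e-6)
  expect_equal(twin$source, c("a", "b"))  # ties break by name
})

test_that("informativeness statistic is non-negative and errors sensibly", {
  cnt <- c(50, 60, 0, 1, 2, 40)
  r <- informativeness_test(cnt, c(1, 1, 2, 2, 2, 1),
                            n_permutations = 99, seed = 1)
  expect_gte(r$statistic, 0)
  expect_true(all(r$null_statistics >= -1e-6))  # nesting holds under perms
  expect_error(informativeness_test(cnt, rep(1, 6)), "two")
  expect_error(informativeness_test(cnt, c(1, 1, 2, 2, 2, 1),
                                    n_permutations = 10), "99")
})

test_that("prior files round-trip", {
  pr <- prior_spec(c(0.60, 0.04),
                   c(t1 = 1L, t2 = 2L, t3 = 1L), model = "two_partition")
  path <- tempfile()
  write_prior(pr, path, n_training_units = c(10L, 20L))
  back <- read_prior(path)
  expect_equal(back$alpha, pr$alpha)
  expect_equal(back$assignment, pr$assignment)
  expect_error(prior_alphas(back, c("t1", "zz")), "zz")
  expect_equal(unname(prior_alphas(back, c("t2", "t1"))), c(0.04, 0.60))
})
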