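test_that("kld matches hand-computed values and Gibbs' inequality", {
  p <- c(a = 0.5, b = 0.5)
  q <- c(a = 0.25, b = 0.75)
  # oracle: hand summation of the two terms
  expect_equal(kld(p, q), 0.5 * log(0.5 / 0.25) + 0.5 * log(0.5 / 0.75),
               tolerance = 1e-15)
  expect_equal(kld(p, p), 0)
  set.seed(1)
  for (i in 1:50) {
    pp <- rand_shares(); qq <- rand_shares()
    expect_gte(kld(pp, qq), 0)
  }
  expect_error(kld(c(0.5, 0.5), c(1, 0, 0)), "support")
  expect_error(kld(c(x = 1, y = 0), c(y = 0.5, x = 0.5)), "support")
})

test_that("kld zero policy governs unsupported research causes", {
  p <- c(a = 0.6, b = 0.4)
  q <- c(a = 1, b = 0)
  expect_error(kld(p, q, "error"), "q\\(x\\) = 0")
  expect_identical(kld(p, q, "inf"), Inf)
  # p(x) = 0 terms contribute nothing regardless of q
  expect_equal(kld(c(a = 1, b = 0), c(a = 0.5, b = 0.5)), log(2))
})

test_that("alternative metrics hit their closed-form extremes", {
  p <- c(a = 0.3, b = 0.7)
  same <- alt_divergences(p, p)
  expect_equal(same$psi, 0)
  expect_equal(same$hellinger, 0)
  expect_equal(same$jsd, 0)
  disj <- alt_divergences(c(a = 1, b = 0), c(a = 0, b = 1),
                          zero_policy = "inf")
  expect_equal(disj$hellinger, 1)
  expect_equal(disj$jsd, log(2))
  expect_identical(disj$psi, Inf)
  # jsd symmetric, bounded by ln 2
  set.seed(2)
  for (i in 1:25) {
    pp <- rand_shares(); qq <- rand_shares()
    a <- alt_divergences(pp, qq); b <- alt_divergences(qq, pp)
    expect_equal(a$jsd, b$jsd, tolerance = 1e-12)
    expect_lte(a$jsd, log(2))
    expect_equal(a$hellinger, b$hellinger, tolerance = 1e-12)
  }
})

test_that("exclusion drops near-zero causes and renormalizes properly", {
  p <- c(a = 0.005, b = 0.495, c = 0.5)
  q <- c(a = 0.2, b = 0.3, c = 0.5)
  ex <- apply_exclusion(p, q, eps = 0.01)
  expect_setequal(ex$kept, c("b", "c"))
  expect_equal(sum(ex$p), 1, tolerance = 1e-12)
  expect_equal(sum(ex$q), 1, tolerance = 1e-12)
  expect_equal(unname(ex$p), c(0.495, 0.5) / 0.995)
  # identity when nothing is below eps
  ex2 <- apply_exclusion(q, q, eps = 0.01)
  expect_equal(ex2$p, q)
  # makes kld finite when raw q had a zero
  p3 <- c(a = 0.3, b = 0.7, c = 0)
  q3 <- c(a = 0.009, b = 0.991, c = 0)
  ex3 <- apply_exclusion(p3, q3)
  expect_true(is.finite(kld(ex3$p, ex3$q, "inf")))
  expect_error(apply_exclusion(c(a = 0.005, b = 0.995),
                               c(a = 0.995, b = 0.005), eps = 0.01), "every")
  expect_error(apply_exclusion(p, q, eps = 0.7), "eps")
})

test_that("Laplace smoothing follows the pseudo-count formula", {
  counts <- c(a = 0, b = 10)
  expect_equal(unname(apply_laplace(counts, 1)), c(1 / 12, 11 / 12))
  expect_equal(apply_laplace(counts, 0), counts / sum(counts))
  big <- apply_laplace(c(rep(0, 15), 100), 1e9)
  expect_equal(unname(big), rep(1 / 16, 16), tolerance = 1e-6)
  expect_error(apply_laplace(counts, -1), "nonnegative")
})

test_that("log-normal sampler honors its parameterization", {
  cfg <- sampler_config(n_draws = 1e5, seed = 33)
  # degenerate interval
  expect_equal(sample_dalys(100, 100, 100, cfg), rep(100, 1e5))
  draws <- sample_dalys(100, 80, 125, cfg)
  expect_equal(mean(draws), 100, tolerance = 0.01)
  qs <- unname(stats::quantile(draws, c(0.025, 0.975)))
  expect_equal(qs[1], 80, tolerance = 0.05)
  expect_equal(qs[2], 125, tolerance = 0.05)
  # determinism
  expect_identical(draws, sample_dalys(100, 80, 125, cfg))
  expect_warning(sample_dalys(5, 0, 10, sampler_config(10, 1)),
                 "degenerate")
})

test_that("divergence CI collapses for zero-width bounds and flags n=1", {
  cw <- constant_world()
  res <- divergence_with_ci(cw$publications, cw$burden, 2020,
                            cfg = sampler_config(50, seed = 5))
  expect_equal(res$ci_low, res$kld, tolerance = 1e-12)
  expect_equal(res$ci_high, res$kld, tolerance = 1e-12)
  one <- divergence_with_ci(cw$publications, cw$burden, 2020,
                            cfg = sampler_config(1, seed = 5))
  expect_true(is.na(one$ci_low) && is.na(one$ci_high))
  expect_equal(one$kld, res$kld, tolerance = 1e-12)
})

test_that("divergence series covers the sampled point estimate and flags gaps", {
  w <- get_world()
  cfg <- sampler_config(100, seed = 7)
  ds <- divergence_series(w$publications, w$burden, 1999:2003, cfg = cfg)
  expect_s3_class(ds, "divergence_series")
  expect_true(all(ds$ci_low <= ds$kld & ds$kld <= ds$ci_high))
  # point estimate near the analytic KLD of the ground-truth shares
  gt <- w$ground_truth
  for (i in 1:5) {
    truth <- kld(gt$expected_burden_shares[i, ],
                 gt$expected_research_shares[i, ], "inf")
    expect_lt(truth, ds$ci_high[i])
    expect_equal(ds$kld[i], truth, tolerance = 0.10)
  }
  # a year with no articles is flagged, not dropped
  pubs_gap <- w$publications[w$publications$year != 2001, ]
  ds_gap <- divergence_series(pubs_gap, w$burden, 1999:2003, cfg = cfg)
  expect_identical(attr(ds_gap, "gaps"), 2001L)
  expect_true(is.na(ds_gap$kld[ds_gap$year == 2001]))

  # stationary world: flat series (fitted slope ~ 0)
  cw <- constant_world()
  ds_flat <- divergence_series(cw$publications, cw$burden, 2015:2021,
                               cfg = sampler_config(20, seed = 1))
  expect_equal(unname(coef(lm(kld ~ year, ds_flat))[2]), 0,
               tolerance = 1e-10)
})

test_that("alternate burden metrics give parallel but distinct series", {
  w <- get_world()
  cfg <- sampler_config(50, seed = 3)
  yrs <- c(1999, 2009, 2019)
  daly <- divergence_series(w$publications, w$burden, yrs, cfg = cfg)
  dths <- divergence_series(w$publications, w$burden, yrs, metric = "deaths",
                            cfg = cfg)
  prev <- divergence_series(w$publications, w$burden, yrs,
                            metric = "prevalence", cfg = cfg)
  # all decline over the window
  expect_lt(dths$kld[3], dths$kld[1])
  expect_lt(prev$kld[3], prev$kld[1])
  expect_false(isTRUE(all.equal(daly$kld, dths$kld)))
})

test_that("stratum filters select the intended subsets", {
  w <- get_world()
  full <- sum(oracle_counts(w$publications, 2019))
  funded <- sum(oracle_counts(
    w$publications, 2019, filters = list(funded = "yes")))
  expect_lt(funded, full)
  expect_equal(funded / full, 0.4, tolerance = 0.05)
  ds <- divergence_series(w$publications, w$burden, 2019,
                          cfg = sampler_config(20, seed = 2),
                          filters = list(research_type = "basic"))
  expect_true(is.finite(ds$kld))
})
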