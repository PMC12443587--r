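test_that("counterfactual scenarios coincide with observed at the base year", {
  w <- get_world()
  cfg <- sampler_config(100, seed = 9)
  obs <- divergence_series(w$publications, w$burden, 1999, cfg = cfg)
  fr <- counterfactual_series(w$publications, w$burden, 1999,
                              "fixed_research", 1999, cfg = cfg)
  fb <- counterfactual_series(w$publications, w$burden, 1999,
                              "fixed_burden", 1999, cfg = cfg)
  expect_gt(obs$ci_high, fr$kld[1]); expect_lt(obs$ci_low, fr$kld[1])
  expect_gt(obs$ci_high, fb$kld[1]); expect_lt(obs$ci_low, fb$kld[1])
  expect_error(counterfactual_series(w$publications, w$burden, 1901,
                                     "fixed_burden", 1999), "base year")
})

test_that("with constant research, fixing research reproduces the observed trend", {
  # burden drifts toward the (constant) research mix; fixed-research tracks
  # the observed series, fixed-burden stays flat
  w <- get_world()
  cfg <- sampler_config(100, seed = 9)
  yrs <- seq(1999, 2019, by = 2)
  obs <- divergence_series(w$publications, w$burden, yrs, cfg = cfg)
  fr <- counterfactual_series(w$publications, w$burden, 1999,
                              "fixed_research", yrs, cfg = cfg)
  fb <- counterfactual_series(w$publications, w$burden, 1999,
                              "fixed_burden", yrs, cfg = cfg)
  expect_gt(summary(lm(obs$kld ~ fr$kld))$r.squared, 0.95)
  sl <- summary(lm(kld ~ year, fb))$coefficients[2, ]
  expect_lt(abs(sl[1]), 2 * sl[2] + 1e-4)  # slope CI straddles zero
  # the mirror image: drifting research against constant burden
  ids <- default_causes()$cause_id
  wm <- get_world(seed = 31L,
                  burden_trends = matrix(0, 16, 8,
                                         dimnames = list(ids, un_regions())),
                  research_drift = 0.002)
  obs_m <- divergence_series(wm$publications, wm$burden, yrs, cfg = cfg)
  fb_m <- counterfactual_series(wm$publications, wm$burden, 1999,
                                "fixed_burden", yrs, cfg = cfg)
  fr_m <- counterfactual_series(wm$publications, wm$burden, 1999,
                                "fixed_research", yrs, cfg = cfg)
  expect_gt(summary(lm(obs_m$kld ~ fb_m$kld))$r.squared, 0.95)
  sl_m <- summary(lm(kld ~ year, fr_m))$coefficients[2, ]
  expect_lt(abs(sl_m[1]), 2 * sl_m[2] + 1e-4)
})

test_that("contributions match direct summand arithmetic on a 2-cause toy", {
  pubs <- data.frame(year = rep(c(2000L, 2010L), each = 2),
                     cause_id = c("a", "b", "a", "b"),
                     country = "USA",
                     n_articles = c(30L, 70L, 30L, 70L),
                     funded = "no", us_public_funded = 0L,
                     industry_author = 0L, research_type = "basic",
                     industry_phase3 = 0L)
  burden <- data.frame(year = rep(c(2000L, 2010L), each = 2),
                       cause_id = c("a", "b", "a", "b"),
                       location = "USA", metric = "daly",
                       mean = c(60, 40, 50, 50), lower = c(60, 40, 50, 50),
                       upper = c(60, 40, 50, 50))
  causes <- data.frame(cause_id = c("a", "b"), name = c("A", "B"),
                       level = 2L, parent_id = "", communicable = FALSE)
  ct <- disease_contributions(pubs, burden, 2000, 2010, causes,
                              zero_policy = "raw")
  # oracle: direct summand arithmetic
  d0 <- c(0.6 * log(0.6 / 0.3), 0.4 * log(0.4 / 0.7))
  d1 <- c(0.5 * log(0.5 / 0.3), 0.5 * log(0.5 / 0.7))
  expect_equal(ct$contribution, (d1 - d0) / sum(d0), tolerance = 1e-12)
  expect_equal(attr(ct, "total"), (sum(d1) - sum(d0)) / sum(d0),
               tolerance = 1e-12)
  expect_equal(ct$contribution, c(-0.836, 0.290), tolerance = 0.001)
  # same years: all zero
  ct0 <- disease_contributions(pubs, burden, 2000, 2000, causes,
                               zero_policy = "raw")
  expect_equal(ct0$contribution, c(0, 0))
  # alternative normalization
  ct1 <- disease_contributions(pubs, burden, 2000, 2010, causes,
                               zero_policy = "raw",
                               normalize_by = "year1")
  expect_equal(attr(ct1, "total"), (sum(d1) - sum(d0)) / sum(d1),
               tolerance = 1e-12)
})

test_that("contributions sum exactly to the total relative change", {
  w <- get_world()
  set.seed(5)
  for (i in 1:5) {
    ys <- sort(sample(1999:2021, 2))
    ct <- disease_contributions(w$publications, w$burden, ys[1], ys[2])
    expect_equal(sum(ct$contribution), attr(ct, "total"), tolerance = 1e-12)
    expect_equal(attr(ct, "total"),
                 (attr(ct, "kld1") - attr(ct, "kld0")) / attr(ct, "kld0"),
                 tolerance = 1e-12)
  }
  # communicable causes reduce divergence in the default world
  ct <- disease_contributions(w$publications, w$burden, 1999, 2019)
  comm <- default_causes()$cause_id[default_causes()$communicable]
  expect_lt(sum(ct$contribution[ct$cause_id %in% comm]), 0)
})

test_that("lag zero reproduces the contemporaneous comparison", {
  w <- get_world()
  l0 <- lagged_divergence(w$publications, w$burden, 0, 1999:2005)
  direct <- vapply(1999:2005, function(y) {
    p <- burden_shares(w$burden, y)
    q <- apply_laplace(oracle_counts(w$publications, y))
    kld(p, q, "inf")
  }, numeric(1))
  expect_equal(l0$kld, direct, tolerance = 1e-12)
  expect_error(lagged_divergence(w$publications, w$burden, 50, 1999:2005),
               "feasible")
})

test_that("a lag scan recovers a built-in research delay", {
  wl <- get_world(seed = 5L, research_follows_burden_lag = 5L)
  scan <- lag_scan(wl$publications, wl$burden, 0:10, years = 1999:2011)
  expect_identical(scan$lag[which.min(scan$mean_kld)], 5L)
  # stationary world: lag barely matters
  cw <- constant_world(years = 2000:2021)
  scan_flat <- lag_scan(cw$publications, cw$burden, 0:5, years = 2000:2010)
  expect_lt(diff(range(scan_flat$mean_kld)), 1e-10)
})
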