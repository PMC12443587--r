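test_that("research trends are exact on noiseless linear counts", {
  causes <- default_causes()
  ids <- causes$cause_id
  years <- 2014:2021
  slopes <- stats::setNames(seq(-20, 130, by = 10), ids)
  pubs <- expand.grid(year = years, cause_id = ids, stringsAsFactors = FALSE)
  pubs$country <- "USA"
  pubs$n_articles <- 1000 + slopes[pubs$cause_id] * (pubs$year - 2014)
  pubs$funded <- "no"; pubs$us_public_funded <- 0L
  pubs$industry_author <- 0L; pubs$research_type <- "basic"
  pubs$industry_phase3 <- 0L
  tr <- fit_research_trends(pubs, window = 2016:2021)
  expect_equal(stats::setNames(tr$slope, tr$cause_id), slopes,
               tolerance = 1e-9)
  proj <- predict(tr, 2022:2025)
  expect_equal(proj["2025", "neoplasms"],
               1000 + slopes[["neoplasms"]] * (2025 - 2014),
               tolerance = 1e-9, ignore_attr = TRUE)
  # constant counts: zero slope, flat projection, floored below
  cw <- constant_world()
  tr0 <- fit_research_trends(cw$publications, window = 2018:2021)
  expect_equal(tr0$slope, rep(0, 16), tolerance = 1e-9)
  expect_error(fit_research_trends(cw$publications, window = 1990:1995),
               "outside")
})

test_that("pandemic adjustment relaxes only the shocked cause to its pre-shock line", {
  w <- get_world(seed = 13L, years = 2014:2021,
                 total_articles_per_year = 30000L)
  ws <- covid_shock(w, "resp_tb", years = c(2020L, 2021L),
                    research_share = c(0.12, 0.13))
  tr <- fit_research_trends(ws$publications, 2018:2021)
  tra <- covid_adjust(tr, ws$publications, "resp_tb", span = 2022:2024,
                      anchor_window = 2016:2019)
  raw <- predict(tr, 2022:2026)
  adj <- predict(tra, 2022:2026)
  # non-target causes bit-identical
  others <- setdiff(colnames(raw), "resp_tb")
  expect_identical(raw[, others], adj[, others])
  # by the end of the span the projection sits on the pre-shock line
  n_pre <- vapply(2016:2019, function(y) {
    sum(ws$publications$n_articles[ws$publications$year == y &
                                     ws$publications$cause_id == "resp_tb"])
  }, numeric(1))
  line <- coef(lm(n_pre ~ I(2016:2019)))
  pre_2025 <- unname(line[1] + line[2] * 2025)
  expect_equal(adj["2025", "resp_tb"], pre_2025, tolerance = 0.05,
               ignore_attr = TRUE)
  # the shocked trend would have projected far above it
  expect_gt(raw["2025", "resp_tb"] / pre_2025, 2)
})

test_that("withdrawal phases out the affected volume linearly", {
  pubs <- data.frame(year = rep(2022:2028, each = 2),
                     cause_id = "hiv_std",
                     country = rep(c("NGA", "USA"), 7),
                     n_articles = 100L,
                     funded = "yes", us_public_funded = 1L,
                     industry_author = 0L, research_type = "basic",
                     industry_phase3 = 0L)
  out <- apply_withdrawal(pubs, start_year = 2022L, phase_in_years = 5L)
  aff <- out[out$country == "NGA", ]
  # year k of the phase-in removes k/5 of the affected volume
  expect_equal(aff$n_articles, 100 * (1 - pmin(1, (2022:2028 - 2021) / 5)))
  expect_equal(aff$n_articles[aff$year == 2024], 40)  # year 3: 60 removed
  expect_true(all(aff$n_articles[aff$year >= 2026] == 0))
  # US rows untouched; unflagged tables unchanged
  expect_true(all(out$n_articles[out$country == "USA"] == 100))
  clean <- transform(pubs, us_public_funded = 0L)
  expect_equal(apply_withdrawal(clean, 2022L), clean)
  abrupt <- apply_withdrawal(pubs, 2024L, abrupt = TRUE)
  expect_true(all(abrupt$n_articles[abrupt$country == "NGA" &
                                      abrupt$year >= 2024] == 0))
  expect_error(apply_withdrawal(pubs[, -6], 2022L), "us_public_funded")
})

test_that("degenerate projections are flat and equal the last observed divergence", {
  cw <- constant_world()
  sp <- projection_spec(horizon_year = 2030L, trend_window = 2018:2021,
                        covid_adjust = FALSE, n_sims = 1L, seed = 4L,
                        burden_trend_window = 2015:2021)
  pr <- run_projection(cw$publications, cw$burden, sp)
  expect_equal(length(unique(round(pr$kld, 12))), 1L)
  # equals the divergence of the last observed year exactly
  p <- burden_shares(cw$burden, 2021)
  q_counts <- vapply(default_causes()$cause_id, function(cid) {
    sum(cw$publications$n_articles[cw$publications$year == 2021 &
                                     cw$publications$cause_id == cid])
  }, numeric(1))
  ref <- kld(p, apply_laplace(q_counts, 1), "inf")
  expect_equal(pr$kld, rep(ref, nrow(pr)), tolerance = 1e-9)
})

test_that("projection runs are seed-deterministic", {
  w <- get_world()
  sp <- projection_spec(horizon_year = 2030L, n_sims = 50L, seed = 99L,
                        withdrawal = list(phase_in_years = 5L))
  a <- run_projection(w$publications, w$burden, sp)
  b <- run_projection(w$publications, w$burden, sp)
  expect_identical(a, b)
  sp2 <- projection_spec(horizon_year = 2030L, n_sims = 50L, seed = 100L,
                         withdrawal = list(phase_in_years = 5L))
  c <- run_projection(w$publications, w$burden, sp2)
  expect_false(identical(a$kld, c$kld))
  # different seeds stay within each other's CIs
  expect_true(all(c$kld > a$ci_low & c$kld < a$ci_high))
})

test_that("withdrawal raises divergence when it hits only under-researched causes", {
  # provable construction: US funding flags only on causes with research
  # share below burden share throughout, narrow burden uncertainty
  ids <- default_causes()$cause_id
  comm <- default_causes()$communicable
  rs <- world_spec()$burden_shares
  rs[comm] <- rs[comm] * 0.5  # research at half the burden share
  rs <- rs / sum(rs)
  pus <- matrix(0, 8, 16, dimnames = list(un_regions(), ids))
  pus[, comm] <- 0.3
  pus["Northern America", ] <- 0
  w <- generate_world(world_spec(
    research_shares = rs,
    burden_trends = matrix(0, 16, 8, dimnames = list(ids, un_regions())),
    p_us_funding = pus, rel_lower = 0.05, rel_upper = 0.05,
    burden_noise_sd = 0, seed = 77L))
  sp <- projection_spec(horizon_year = 2035L, covid_adjust = FALSE,
                        n_sims = 100L, seed = 7L,
                        withdrawal = list(phase_in_years = 5L))
  pr <- run_projection(w$publications, w$burden, sp)
  base <- pr[pr$scenario == "baseline", ]
  wd <- pr[pr$scenario == "withdrawal", ]
  expect_true(all(wd$kld >= base$kld))
})

test_that("funding exposure shares recover the generator probabilities", {
  w <- get_world()
  ex <- exposure_shares(w$publications, years = 2015:2021,
                        regions = w$regions)
  expect_false("Northern America" %in% ex$region)
  gt <- w$ground_truth$p_us_funding
  hiv_ssa <- ex$share[ex$region == "Sub-Saharan Africa" &
                        ex$cause_id == "hiv_std"]
  n <- ex$n_articles[ex$region == "Sub-Saharan Africa" &
                       ex$cause_id == "hiv_std"]
  tol <- 3 * sqrt(0.41 * 0.59 / n)  # binomial tolerance
  expect_equal(hiv_ssa, gt["Sub-Saharan Africa", "hiv_std"],
               tolerance = tol / 0.41)
  # scale invariance: duplicating every article changes nothing
  p2 <- transform(w$publications, n_articles = n_articles * 2L)
  ex2 <- exposure_shares(p2, years = 2015:2021, regions = w$regions)
  expect_equal(ex2$share, ex$share, tolerance = 1e-12)
  # no funded articles: all shares zero
  p0 <- transform(w$publications, us_public_funded = 0L)
  ex0 <- exposure_shares(p0, years = 2015:2021, regions = w$regions)
  expect_true(all(ex0$share[!is.na(ex0$share)] == 0))
})

test_that("funder-country shares recover the acknowledgment distribution", {
  w <- get_world()
  fs <- funder_country_shares(w$funders, "resp_tb", top_k = 10L)
  expect_lte(sum(fs$share), 1)
  gt <- w$ground_truth$funder_dist
  expect_equal(fs$share[fs$funder_country == "CHN"], unname(gt["CHN"]),
               tolerance = 0.05)
  expect_equal(fs$share[fs$funder_country == "GBR"], unname(gt["GBR"]),
               tolerance = 0.05)
  expect_identical(fs$funder_country[1], "CHN")  # largest non-US funder
  single <- data.frame(year = 2020L, cause_id = "mental",
                       funder_country = "CHN", n_articles = 5L)
  expect_equal(funder_country_shares(single, "mental")$share, 1)
  expect_error(funder_country_shares(single, "neoplasms"), "no non-US")
})
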