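test_that("table round trips through CSV are lossless", {
  w <- get_world()
  dir <- withr_local_tempdir()
  write_tables(w, dir)
  back <- read_tables(file.path(dir, "publications.csv"),
                      file.path(dir, "burden.csv"),
                      file.path(dir, "causes.csv"),
                      file.path(dir, "regions.csv"))
  expect_equal(back$publications, w$publications)
  expect_equal(back$burden, w$burden)
  expect_equal(back$causes, w$causes)
  expect_equal(back$regions, w$regions)
})

test_that("validation rejects malformed tables with row diagnostics", {
  bur <- data.frame(year = 2000, cause_id = "neoplasms", location = "USA",
                    metric = "daly", mean = c(10, 5, 7),
                    lower = c(8, 6, 6), upper = c(12, 5.5, 6.5))
  expect_error(validate_burden(bur), "2, 3")
  pubs <- data.frame(year = 2000, cause_id = c("neoplasms", "nonexistent"),
                     country = "USA", n_articles = 1, funded = "yes",
                     us_public_funded = 0L, industry_author = 0L,
                     research_type = "basic", industry_phase3 = 0L)
  expect_error(validate_publications(pubs), "nonexistent")
  expect_error(validate_burden(bur[, -3]), "location")
  expect_error(
    validate_publications(transform(pubs[1, ], n_articles = -1)),
    "nonnegative integer")
})

test_that("cause hierarchy validation catches orphans and duplicates", {
  causes <- rbind(default_causes(),
                  data.frame(cause_id = "ihd", name = "Ischemic heart disease",
                             level = 3L, parent_id = "cardiovascular",
                             communicable = FALSE),
                  data.frame(cause_id = "mi", name = "Myocardial infarction",
                             level = 4L, parent_id = "ihd",
                             communicable = FALSE))
  expect_silent(validate_causes(causes))
  orphan <- rbind(causes, data.frame(cause_id = "lost", name = "x",
                                     level = 3L, parent_id = "",
                                     communicable = FALSE))
  expect_error(validate_causes(orphan), "lost")
  expect_error(validate_causes(rbind(causes, causes[1, ])), "duplicate")
})

test_that("rollup to level 2 sums through the hierarchy and conserves mass", {
  causes <- rbind(default_causes(),
                  data.frame(cause_id = "ihd", name = "IHD", level = 3L,
                             parent_id = "cardiovascular",
                             communicable = FALSE),
                  data.frame(cause_id = "mi", name = "MI", level = 4L,
                             parent_id = "ihd", communicable = FALSE),
                  data.frame(cause_id = "stroke", name = "Stroke", level = 3L,
                             parent_id = "cardiovascular",
                             communicable = FALSE))
  x <- data.frame(year = 2000L,
                  cause_id = c("ihd", "stroke"),
                  country = "USA", n_articles = c(3L, 4L))
  up <- rollup_to_level2(x, causes)
  expect_equal(up$cause_id, "cardiovascular")
  expect_equal(up$n_articles, 7L)

  # already at level 2: identity up to aggregation
  x2 <- data.frame(year = 2000L, cause_id = c("neoplasms", "mental"),
                   country = "USA", n_articles = c(5L, 6L))
  expect_equal(rollup_to_level2(x2, causes)$n_articles[order(
    rollup_to_level2(x2, causes)$cause_id)], c(6L, 5L))

  # mixed levels 3/4, random counts: grand total conserved exactly
  set.seed(9)
  x3 <- data.frame(year = sample(1999:2001, 30, TRUE),
                   cause_id = sample(c("mi", "ihd", "stroke", "neoplasms"),
                                     30, TRUE),
                   country = sample(c("USA", "DEU"), 30, TRUE),
                   n_articles = sample(0:20, 30, TRUE))
  up3 <- rollup_to_level2(x3, causes)
  expect_identical(sum(up3$n_articles), sum(x3$n_articles))
  expect_true(all(up3$cause_id %in% c("cardiovascular", "neoplasms")))
})

test_that("region aggregation conserves totals and reports empty regions", {
  regions <- default_regions()
  set.seed(4)
  x <- data.frame(year = 2000L,
                  cause_id = "neoplasms",
                  country = sample(regions$country[1:10], 40, TRUE),
                  n_articles = sample(1:50, 40, TRUE))
  agg <- aggregate_regions(x, regions)
  expect_equal(sum(agg$n_articles), sum(x$n_articles))
  # oracle: naive group-and-sum
  byreg <- tapply(x$n_articles, regions$region[match(x$country,
                                                     regions$country)], sum)
  got <- agg$n_articles[match(names(byreg), agg$region)]
  expect_equal(unname(got), unname(as.vector(byreg)))
  # regions with no data appear with zero
  expect_setequal(agg$region, un_regions())
  expect_true(all(agg$n_articles[!agg$region %in% names(byreg)] == 0))
  expect_error(
    aggregate_regions(transform(x[1, ], country = "XXX"), regions), "XXX")
})

test_that("share computation matches direct division and flags empty scopes", {
  causes <- default_causes()
  x <- data.frame(cause_id = c("neoplasms", "mental"), n_articles = c(10, 30))
  s <- compute_shares(x, causes)
  expect_equal(unname(s[c("neoplasms", "mental")]), c(0.25, 0.75))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(sum(s > 0), 2L)  # absent causes get share 0, stay in support

  set.seed(11)
  counts <- sample(0:100, 16)
  x2 <- data.frame(cause_id = causes$cause_id, n_articles = counts)
  s2 <- compute_shares(x2, causes)
  expect_equal(unname(s2), counts / sum(counts), tolerance = 1e-12)

  # permutation equivariance under cause reordering
  perm <- sample(16)
  causes_p <- causes[perm, ]
  s2p <- compute_shares(x2, causes_p)
  expect_equal(s2p, s2[causes_p$cause_id])

  expect_error(compute_shares(x2[0, ], causes), "empty scope")
})
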