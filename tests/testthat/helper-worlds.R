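# Shared fixtures, all generated in code.

# Memoized default synthetic world so test files do not regenerate it.
.world_cache <- new.env(parent = emptyenv())
get_world <- function(seed = 42L, ...) {
  key <- paste0("w", seed, paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(world_spec(seed = seed, ...))
  }
  .world_cache[[key]]
}

# Random share distribution over k causes (positive everywhere).
rand_shares <- function(k = 16L) {
  x <- stats::rgamma(k, shape = 1)
  x / sum(x)
}

# Brute-force definition-level divergence oracles, written as plain loops,
# independent of the package implementations.
brute_kld <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  }
  s
}
brute_psi <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0 && q[i] > 0) s <- s + (q[i] - p[i]) * log(q[i] / p[i])
  }
  s
}
brute_hellinger <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + (sqrt(p[i]) - sqrt(q[i]))^2
  sqrt(s / 2)
}
brute_jsd <- function(p, q) {
  m <- (p + q) / 2
  0.5 * brute_kld(p, m) + 0.5 * brute_kld(q, m)
}

# A tiny deterministic world with constant research counts and constant,
# zero-width burden: the degenerate construction used by projection tests.
constant_world <- function(years = 2015:2021, n_per_cause = NULL) {
  causes <- default_causes()
  ids <- causes$cause_id
  if (is.null(n_per_cause)) {
    n_per_cause <- stats::setNames(seq(100, 1600, by = 100), ids)
  }
  pubs <- expand.grid(year = years, cause_id = ids, stringsAsFactors = FALSE)
  pubs$country <- "USA"
  pubs$n_articles <- n_per_cause[pubs$cause_id]
  pubs$funded <- "no"
  pubs$us_public_funded <- 0L
  pubs$industry_author <- 0L
  pubs$research_type <- "basic"
  pubs$industry_phase3 <- 0L
  b_mean <- stats::setNames(seq(1600, 100, by = -100) * 1e4, ids)
  burden <- expand.grid(year = years, cause_id = ids,
                        stringsAsFactors = FALSE)
  burden$location <- "USA"
  burden$metric <- "daly"
  burden$mean <- b_mean[burden$cause_id]
  burden$lower <- burden$mean
  burden$upper <- burden$mean
  list(publications = pubs, burden = burden, causes = causes)
}

# Per-cause article counts for a scope, used as a test-side oracle.
oracle_counts <- function(pubs, years, filters = NULL) {
  sel <- pubs[pubs$year %in% years, ]
  if (!is.null(filters)) {
    for (col in names(filters)) sel <- sel[sel[[col]] %in% filters[[col]], ]
  }
  ids <- default_causes()$cause_id
  out <- stats::setNames(numeric(length(ids)), ids)
  got <- tapply(sel$n_articles, sel$cause_id, sum)
  out[names(got)] <- got
  out
}

# temp dir cleaned up when the calling test exits
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("ba")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
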