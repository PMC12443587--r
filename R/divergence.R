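#' Kullback-Leibler divergence of research from burden shares
#'
#' Computes \eqn{KLD(p||q) = \sum_x p(x) \ln(p(x)/q(x))} in nats, where
#' \code{p} is the reference distribution (burden shares) and \code{q} the
#' comparison distribution (research shares). Zero alignment, i.e. identical
#' distributions, gives 0; the divergence is otherwise positive. Terms with
#' \code{p(x) = 0} contribute 0. A cause with \code{q(x) = 0} but
#' \code{p(x) > 0} is handled per the zero policy: \code{"error"} stops,
#' \code{"inf"} returns \code{Inf}. Smoothing and exclusion are applied
#' upstream (see \code{\link{apply_laplace}} and \code{\link{apply_exclusion}}).
#'
#' @param p reference (burden) share vector.
#' @param q comparison (research) share vector on the same support; if both
#'   vectors are named the names must match.
#' @param zero_policy \code{"error"} or \code{"inf"}.
#' @return Nonnegative scalar divergence in nats.
#' @export
#' @examples
#' kld(c(0.5, 0.5), c(0.25, 0.75))  # 0.5*log(2) + 0.5*log(2/3)
kld <- function(p, q, zero_policy = c("error", "inf")) {
  zero_policy <- match.arg(zero_policy)
  check_pair(p, q)
  bad <- q == 0 & p > 0
  if (any(bad)) {
    if (zero_policy == "error") {
      stop("q(x) = 0 where p(x) > 0 for: ",
           paste(names(p)[bad], collapse = ", "),
           "; use Laplace smoothing or exclusion, or zero_policy = \"inf\"",
           call. = FALSE)
    }
    return(Inf)
  }
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

check_pair <- function(p, q) {
  if (length(p) != length(q)) {
    stop("p and q must share the same support (lengths differ)", call. = FALSE)
  }
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    stop("p and q must share the same support (names differ)", call. = FALSE)
  }
  if (any(p < 0) || any(q < 0)) stop("shares must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("shares must sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Alternative divergence metrics
#'
#' The sensitivity metrics reported alongside the KLD: the Population
#' Stability Index \eqn{\sum (q-p)\ln(q/p)}, the Hellinger distance
#' \eqn{\sqrt{\frac12\sum(\sqrt p - \sqrt q)^2}} (in [0, 1]) and the
#' Jensen-Shannon divergence
#' \eqn{\frac12 KLD(p||m) + \frac12 KLD(q||m)} with \eqn{m = (p+q)/2}
#' (in [0, ln 2]). Hellinger and JSD are finite for zeros; the PSI follows the
#' zero policy.
#'
#' @inheritParams kld
#' @return Named list with elements \code{psi}, \code{hellinger}, \code{jsd}.
#' @export
alt_divergences <- function(p, q, zero_policy = c("error", "inf")) {
  zero_policy <- match.arg(zero_policy)
  check_pair(p, q)
  one_zero <- xor(p == 0, q == 0)
  psi <- if (any(one_zero)) {
    if (zero_policy == "error") {
      stop("PSI undefined: exactly one of p(x), q(x) is zero for: ",
           paste(names(p)[one_zero], collapse = ", "), call. = FALSE)
    }
    Inf
  } else {
    both_pos <- p > 0 & q > 0
    sum((q[both_pos] - p[both_pos]) * log(q[both_pos] / p[both_pos]))
  }
  hellinger <- sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
  m <- (p + q) / 2
  jsd_term <- function(a) {
    pos <- a > 0
    sum(a[pos] * log(a[pos] / m[pos]))
  }
  jsd <- 0.5 * jsd_term(p) + 0.5 * jsd_term(q)
  list(psi = psi, hellinger = hellinger, jsd = jsd)
}

#' Exclude near-zero outliers and renormalize
#'
#' Drops causes where either distribution falls below \code{eps} (default
#' 0.01) and renormalizes both vectors over the surviving support: the
#' sensitivity rule that keeps the KLD finite when research on a cause is
#' (almost) absent.
#'
#' @inheritParams kld
#' @param eps exclusion threshold in [0, 0.5).
#' @return List with renormalized \code{p}, \code{q} and the surviving
#'   \code{kept} cause names.
#' @export
apply_exclusion <- function(p, q, eps = 0.01) {
  if (eps < 0 || eps >= 0.5) stop("eps must be in [0, 0.5)", call. = FALSE)
  check_pair(p, q)
  keep <- p >= eps & q >= eps
  if (!any(keep)) stop("exclusion removed every cause", call. = FALSE)
  p2 <- p[keep] / sum(p[keep])
  q2 <- q[keep] / sum(q[keep])
  list(p = p2, q = q2, kept = names(p2))
}

#' Laplace-smoothed shares from counts
#'
#' \eqn{share_x = (count_x + \alpha) / (total + \alpha K)} over the K causes.
#' With \code{alpha = 0} this is the raw share vector; as \code{alpha} grows
#' the shares shrink toward uniform.
#'
#' @param counts named nonnegative count vector over the cause set.
#' @param alpha smoothing pseudo-count, >= 0 (default 1: one pseudo-article
#'   per cause).
#' @return Named share vector summing to 1.
#' @export
apply_laplace <- function(counts, alpha = 1) {
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  (counts + alpha) / (sum(counts) + alpha * length(counts))
}

#' Sampler configuration for burden-uncertainty propagation
#'
#' @param n_draws number of Monte Carlo draws (default 1000).
#' @param seed integer seed; each scope derives its own substream from it.
#' @param z normal quantile matching the reported interval coverage
#'   (default 1.959964, the 97.5\% point, for 95\% intervals).
#' @return A list of class \code{sampler_config}.
#' @export
sampler_config <- function(n_draws = 1000L, seed = 1L, z = 1.959964) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 z = z),
            class = "sampler_config")
}

# Deterministic substream seed < 2^31 derived from a root seed and a counter,
# so adding scopes never perturbs earlier ones.
sub_seed <- function(seed, counter) {
  as.integer((as.double(seed %% 65011L) * 33013 + as.double(counter) * 7919
              + 17) %% 2147483629)
}

# Evaluate code under a seed, restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Log-normal parameters from a reported (mean, lower, upper) triple:
# sigma = ln(upper/lower) / (2 z), mu = ln(mean) - sigma^2 / 2, so the
# distribution mean equals the reported mean and the (2.5, 97.5)% quantile
# ratio matches the reported interval's.
lognormal_params <- function(mean, lower, upper, z = 1.959964) {
  sigma <- log(upper / lower) / (2 * z)
  mu <- log(mean) - sigma^2 / 2
  list(mu = mu, sigma = sigma)
}

#' Simulate burden values from reported asymmetric uncertainty intervals
#'
#' Draws from a log-normal distribution parameterized from the reported mean
#' and the asymmetric lower/upper bounds: \eqn{\sigma = \ln(u/l)/(2z)} and
#' \eqn{\mu = \ln(mean) - \sigma^2/2}, so that the distribution mean equals
#' the reported mean and the central 95\% interval spans a
#' \code{upper/lower} ratio. Degenerate intervals (lower = upper) return the
#' mean exactly; a nonpositive lower bound with positive mean falls back to
#' the degenerate-at-mean distribution with a warning.
#'
#' @param mean,lower,upper reported estimates, 0 < lower <= mean <= upper.
#' @param cfg a \code{\link{sampler_config}}; its seed is used directly.
#' @return Numeric vector of \code{cfg$n_draws} positive draws.
#' @export
sample_dalys <- function(mean, lower, upper, cfg = sampler_config()) {
  stopifnot(length(mean) == 1L)
  if (lower > mean || mean > upper) {
    stop("need lower <= mean <= upper", call. = FALSE)
  }
  if (lower <= 0 && mean > 0) {
    warning("nonpositive lower bound; falling back to degenerate at mean")
    return(rep(mean, cfg$n_draws))
  }
  if (mean == 0 || lower == upper) return(rep(mean, cfg$n_draws))
  par <- lognormal_params(mean, lower, upper, cfg$z)
  local_seed(cfg$seed,
             stats::rlnorm(cfg$n_draws, meanlog = par$mu, sdlog = par$sigma))
}

# Matrix of burden draws: n_draws x n_causes, sampled independently per cause
# (the reported bounds are per-cause marginals), under the current RNG state.
draw_burden_matrix <- function(rows, n_draws, z) {
  k <- nrow(rows)
  out <- matrix(0, n_draws, k, dimnames = list(NULL, rows$cause_id))
  for (i in seq_len(k)) {
    m <- rows$mean[i]; l <- rows$lower[i]; u <- rows$upper[i]
    if (m == 0 || l == u) {
      out[, i] <- m
    } else if (l <= 0) {
      out[, i] <- m
    } else {
      par <- lognormal_params(m, l, u, z)
      out[, i] <- stats::rlnorm(n_draws, par$mu, par$sigma)
    }
  }
  out
}

# Apply a zero policy to a (p, q) pair (q from counts) and compute all four
# metrics. Returns list(kld, psi, hellinger, jsd).
metrics_under_policy <- function(p, q_counts, zero_policy, alpha, eps) {
  q_raw <- q_counts / sum(q_counts)
  if (zero_policy == "laplace") {
    q <- apply_laplace(q_counts, alpha)
    k <- kld(p, q, "inf")
    alt <- alt_divergences(p, q, "inf")
  } else if (zero_policy == "exclude") {
    ex <- apply_exclusion(p, q_raw, eps)
    k <- kld(ex$p, ex$q, "inf")
    alt <- alt_divergences(ex$p, ex$q, "inf")
  } else if (zero_policy == "raw") {
    k <- kld(p, q_raw, "inf")
    alt <- alt_divergences(p, q_raw, "inf")
  } else {  # "error"
    k <- kld(p, q_raw, "error")
    alt <- alt_divergences(p, q_raw, "error")
  }
  list(kld = k, psi = alt$psi, hellinger = alt$hellinger, jsd = alt$jsd)
}

#' Divergence with burden-uncertainty confidence interval for one scope
#'
#' For each Monte Carlo draw, per-cause burden values are simulated from
#' their log-normal uncertainty distributions (\code{\link{sample_dalys}}
#' parameterization), renormalized to a share distribution and compared
#' against the fixed research shares; the reported divergence is the
#' across-draw mean and the 95\% CI is mean +/- z * SD.
#'
#' @param pubs publications table.
#' @param burden burden table.
#' @param year scope year.
#' @param causes cause table.
#' @param metric burden metric.
#' @param zero_policy \code{"laplace"} (default), \code{"exclude"},
#'   \code{"raw"} or \code{"error"}.
#' @param alpha Laplace pseudo-count (on article counts).
#' @param eps exclusion threshold.
#' @param cfg \code{\link{sampler_config}}.
#' @param filters optional stratum filters passed to
#'   \code{\link{research_shares}}.
#' @param seed_counter internal offset so that multi-year series give each
#'   year its own substream.
#' @return One-row data frame: year, kld, psi, hellinger, jsd, ci_low,
#'   ci_high, n_sims.
#' @export
divergence_with_ci <- function(pubs, burden, year, causes = default_causes(),
                               metric = "daly",
                               zero_policy = c("laplace", "exclude", "raw",
                                               "error"),
                               alpha = 1, eps = 0.01,
                               cfg = sampler_config(), filters = NULL,
                               seed_counter = 0L) {
  zero_policy <- match.arg(zero_policy)
  q_counts <- research_counts(pubs, year, causes, filters = filters)
  if (sum(q_counts) <= 0) {
    stop("empty scope: no articles in year ", year, call. = FALSE)
  }
  rows <- burden_rows(burden, year, causes, metric)
  mets <- matrix(NA_real_, cfg$n_draws, 4L,
                 dimnames = list(NULL, c("kld", "psi", "hellinger", "jsd")))
  local_seed(sub_seed(cfg$seed, seed_counter), {
    draws <- draw_burden_matrix(rows, cfg$n_draws, cfg$z)
    for (s in seq_len(cfg$n_draws)) {
      p <- draws[s, ] / sum(draws[s, ])
      m <- metrics_under_policy(p, q_counts, zero_policy, alpha, eps)
      mets[s, ] <- c(m$kld, m$psi, m$hellinger, m$jsd)
    }
  })
  est <- colMeans(mets)
  if (cfg$n_draws > 1L) {
    sd_kld <- stats::sd(mets[, "kld"])
    ci <- est[["kld"]] + c(-1, 1) * cfg$z * sd_kld
  } else {
    ci <- c(NA_real_, NA_real_)  # CI undefined at a single draw
  }
  data.frame(year = year, kld = est[["kld"]], psi = est[["psi"]],
             hellinger = est[["hellinger"]], jsd = est[["jsd"]],
             ci_low = ci[1], ci_high = ci[2], n_sims = cfg$n_draws)
}

#' Yearly research-burden divergence series
#'
#' One divergence result per year, comparing that year's global research
#' share distribution against its global burden share distribution, with
#' uncertainty propagated from the burden bounds. Supports the deaths and
#' prevalence burden metrics and stratum filters (funded-only, industry,
#' research type, industry phase-3 trials). Years whose scope selects no
#' articles are flagged in the \code{gaps} attribute rather than silently
#' dropped.
#'
#' @inheritParams divergence_with_ci
#' @param years integer vector of years.
#' @return A \code{divergence_series} object: a data frame with columns year,
#'   kld, psi, hellinger, jsd, ci_low, ci_high, n_sims.
#' @export
divergence_series <- function(pubs, burden, years, causes = default_causes(),
                              metric = "daly",
                              zero_policy = c("laplace", "exclude", "raw",
                                              "error"),
                              alpha = 1, eps = 0.01,
                              cfg = sampler_config(), filters = NULL) {
  zero_policy <- match.arg(zero_policy)
  if (!length(years)) stop("years must be nonempty", call. = FALSE)
  rows <- vector("list", length(years))
  gaps <- integer(0)
  for (i in seq_along(years)) {
    res <- tryCatch(
      divergence_with_ci(pubs, burden, years[i], causes, metric, zero_policy,
                         alpha, eps, cfg, filters, seed_counter = i),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      gaps <- c(gaps, years[i])
      rows[[i]] <- data.frame(year = years[i], kld = NA_real_, psi = NA_real_,
                              hellinger = NA_real_, jsd = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              n_sims = 0L)
    } else {
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows)
  structure(out,
            class = c("divergence_series", "data.frame"),
            metric = metric, zero_policy = zero_policy, gaps = gaps)
}

#' @export
print.divergence_series <- function(x, ...) {
  cat("Research-burden divergence series (", attr(x, "metric"), ", ",
      attr(x, "zero_policy"), " zero policy, ",
      min(x$year), "-", max(x$year), ")\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  gaps <- attr(x, "gaps")
  if (length(gaps)) cat("flagged empty-scope years:",
                        paste(gaps, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.divergence_series <- function(object, ...) {
  ok <- !is.na(object$kld)
  first <- object$kld[ok][1]
  last <- object$kld[ok][sum(ok)]
  fit <- stats::lm(kld ~ year, data = as.data.frame(object)[ok, ])
  out <- list(
    years = range(object$year),
    kld_first = first, kld_last = last,
    relative_change = (last - first) / first,
    slope = unname(stats::coef(fit)[2]),
    gaps = attr(object, "gaps")
  )
  class(out) <- "summary.divergence_series"
  out
}

#' @export
print.summary.divergence_series <- function(x, ...) {
  cat("Divergence series ", x$years[1], "-", x$years[2], "\n", sep = "")
  cat(sprintf("  KLD %.4f -> %.4f (relative change %+.1f%%)\n",
              x$kld_first, x$kld_last, 100 * x$relative_change))
  cat(sprintf("  fitted yearly slope %+.5f nats/yr\n", x$slope))
  if (length(x$gaps)) cat("  empty-scope years:",
                          paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.divergence_series <- function(x, ...) {
  df <- as.data.frame(x)
  ylim <- range(c(df$kld, df$ci_low, df$ci_high), na.rm = TRUE)
  graphics::plot(df$year, df$kld, type = "b", pch = 16,
                 xlab = "Year", ylab = "KLD (nats)", ylim = ylim, ...)
  ok <- !is.na(df$ci_low)
  graphics::arrows(df$year[ok], df$ci_low[ok], df$year[ok], df$ci_high[ok],
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  invisible(x)
}
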