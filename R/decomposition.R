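#' Counterfactual divergence series with one distribution frozen
#'
#' The two scenario experiments that decompose what drives divergence change:
#' \code{fixed_research} holds the research distribution at its base-year
#' value and computes \eqn{KLD(p_t || q_{base})} per year, asking how the
#' divergence would have evolved had the research mix not changed;
#' \code{fixed_burden} holds the burden distribution at its base-year value
#' and computes \eqn{KLD(p_{base} || q_t)}. Confidence intervals come from the
#' burden-uncertainty sampler applied to whichever burden year enters the
#' comparison (year t for fixed research, the base year for fixed burden); the
#' research side carries no uncertainty model. At the base year both scenarios
#' coincide with the observed divergence.
#'
#' @inheritParams divergence_series
#' @param base_year year whose distribution is frozen.
#' @param which \code{"fixed_research"} or \code{"fixed_burden"}.
#' @return A \code{scenario_series} object: data frame with columns year,
#'   kld, ci_low, ci_high, label.
#' @export
counterfactual_series <- function(pubs, burden, base_year, which =
                                    c("fixed_research", "fixed_burden"),
                                  years, causes = default_causes(),
                                  metric = "daly",
                                  zero_policy = c("laplace", "exclude", "raw",
                                                  "error"),
                                  alpha = 1, eps = 0.01,
                                  cfg = sampler_config(), filters = NULL) {
  which <- match.arg(which)
  zero_policy <- match.arg(zero_policy)
  if (!base_year %in% unique(burden$year) ||
      !base_year %in% unique(pubs$year)) {
    stop("base year ", base_year, " not present in the data", call. = FALSE)
  }
  q_base_counts <- research_counts(pubs, base_year, causes, filters = filters)
  rows_base <- burden_rows(burden, base_year, causes, metric)
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    if (which == "fixed_research") {
      q_counts <- q_base_counts
      rows <- burden_rows(burden, y, causes, metric)
    } else {
      q_counts <- research_counts(pubs, y, causes, filters = filters)
      rows <- rows_base
    }
    klds <- numeric(cfg$n_draws)
    local_seed(sub_seed(cfg$seed, i), {
      draws <- draw_burden_matrix(rows, cfg$n_draws, cfg$z)
      for (s in seq_len(cfg$n_draws)) {
        p <- draws[s, ] / sum(draws[s, ])
        klds[s] <- metrics_under_policy(p, q_counts, zero_policy, alpha,
                                        eps)$kld
      }
    })
    est <- mean(klds)
    ci <- if (cfg$n_draws > 1L) est + c(-1, 1) * cfg$z * stats::sd(klds)
          else c(NA_real_, NA_real_)
    out[[i]] <- data.frame(year = y, kld = est, ci_low = ci[1],
                           ci_high = ci[2], label = which)
  }
  structure(do.call(rbind, out),
            class = c("scenario_series", "data.frame"),
            base_year = base_year, metric = metric,
            zero_policy = zero_policy)
}

#' @export
print.scenario_series <- function(x, ...) {
  cat("Counterfactual divergence series (", x$label[1], ", base year ",
      attr(x, "base_year"), ")\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' Per-disease contributions to the relative change in divergence
#'
#' With per-cause divergence summand \eqn{d_x(t) = p_x(t)\ln(p_x(t)/q_x(t))},
#' each cause's contribution to the relative change between two years is
#' \eqn{(d_x(y_1) - d_x(y_0)) / KLD(y_0)}; contributions sum to the total
#' relative change \eqn{\Delta KLD / KLD(y_0)} by construction. Negative
#' contributions are divergence-reducing. Both distributions are adjusted by
#' the same zero policy as the headline divergence so the summands add up to
#' the reported totals.
#'
#' @inheritParams divergence_series
#' @param year0 baseline year (the denominator of the relative change).
#' @param year1 comparison year.
#' @param normalize_by which year's KLD normalizes the change
#'   (\code{"year0"}, the default, or \code{"year1"}).
#' @return A \code{contribution_table}: data frame with columns cause_id,
#'   contribution, plus attributes \code{total} (the total relative change)
#'   and \code{kld0}, \code{kld1}.
#' @export
disease_contributions <- function(pubs, burden, year0, year1,
                                  causes = default_causes(), metric = "daly",
                                  zero_policy = c("laplace", "exclude", "raw",
                                                  "error"),
                                  alpha = 1, eps = 0.01, filters = NULL,
                                  normalize_by = c("year0", "year1")) {
  zero_policy <- match.arg(zero_policy)
  normalize_by <- match.arg(normalize_by)
  summands <- function(year) {
    q_counts <- research_counts(pubs, year, causes, filters = filters)
    p <- burden_shares(burden, year, causes, metric)
    if (zero_policy == "laplace") {
      q <- apply_laplace(q_counts, alpha)
    } else if (zero_policy == "exclude") {
      ex <- apply_exclusion(p, q_counts / sum(q_counts), eps)
      full <- stats::setNames(rep(NA_real_, length(p)), names(p))
      d <- ifelse(ex$p > 0, ex$p * log(ex$p / ex$q), 0)
      full[ex$kept] <- d
      full[setdiff(names(p), ex$kept)] <- 0  # excluded causes carry no summand
      return(full)
    } else {
      q <- q_counts / sum(q_counts)
    }
    ifelse(p > 0, p * log(p / q), 0)
  }
  d0 <- summands(year0)
  d1 <- summands(year1)
  k0 <- sum(d0)
  k1 <- sum(d1)
  denom <- if (normalize_by == "year0") k0 else k1
  if (!is.finite(denom) || denom == 0) {
    stop("relative change undefined: KLD in the normalizing year is ",
         denom, call. = FALSE)
  }
  contrib <- (d1 - d0) / denom
  out <- data.frame(cause_id = names(contrib),
                    contribution = unname(contrib),
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("contribution_table", "data.frame"),
            total = sum(contrib), kld0 = k0, kld1 = k1,
            year0 = year0, year1 = year1, normalize_by = normalize_by)
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("Per-disease contributions to relative KLD change, ",
      attr(x, "year0"), " -> ", attr(x, "year1"),
      " (normalized by ", attr(x, "normalize_by"), ")\n", sep = "")
  df <- as.data.frame(x)
  df <- df[order(df$contribution), ]
  print.data.frame(format(df, digits = 3), row.names = FALSE)
  cat(sprintf("total relative change: %+.1f%% (KLD %.4f -> %.4f)\n",
              100 * attr(x, "total"), attr(x, "kld0"), attr(x, "kld1")))
  invisible(x)
}

#' Lagged divergence series
#'
#' Compares each year's burden distribution with the research distribution
#' \code{lag} years later, \eqn{KLD(p_t || q_{t+lag})}, to test whether
#' research adjusts to burden with a delay. Lag 0 reproduces the
#' contemporaneous series.
#'
#' @inheritParams divergence_series
#' @param lag nonnegative integer lag in years.
#' @return Data frame with columns burden_year, research_year, kld.
#' @export
lagged_divergence <- function(pubs, burden, lag, years,
                              causes = default_causes(), metric = "daly",
                              zero_policy = c("laplace", "exclude", "raw",
                                              "error"),
                              alpha = 1, eps = 0.01, filters = NULL) {
  zero_policy <- match.arg(zero_policy)
  if (lag < 0) stop("lag must be nonnegative", call. = FALSE)
  pub_years <- unique(pubs$year)
  feas <- years[(years + lag) %in% pub_years]
  if (!length(feas)) stop("no feasible years at lag ", lag, call. = FALSE)
  kl <- vapply(feas, function(y) {
    p <- burden_shares(burden, y, causes, metric)
    q_counts <- research_counts(pubs, y + lag, causes, filters = filters)
    metrics_under_policy(p, q_counts, zero_policy, alpha, eps)$kld
  }, numeric(1))
  data.frame(burden_year = feas, research_year = feas + lag, kld = kl)
}

#' Scan lags for the best research-burden alignment delay
#'
#' Mean lagged divergence for each lag in a scan window; a research enterprise
#' that copies burden with delay d attains its minimum at lag d.
#'
#' @inheritParams lagged_divergence
#' @param lags integer lags to scan (default 0:10).
#' @return Data frame with columns lag, mean_kld, n_years.
#' @export
lag_scan <- function(pubs, burden, lags = 0:10, years,
                     causes = default_causes(), metric = "daly",
                     zero_policy = c("laplace", "exclude", "raw", "error"),
                     alpha = 1, eps = 0.01, filters = NULL) {
  zero_policy <- match.arg(zero_policy)
  rows <- lapply(lags, function(l) {
    s <- lagged_divergence(pubs, burden, l, years, causes, metric,
                           zero_policy, alpha, eps, filters)
    data.frame(lag = l, mean_kld = mean(s$kld), n_years = nrow(s))
  })
  do.call(rbind, rows)
}
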