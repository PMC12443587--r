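#' Fit linear research trends per cause
#'
#' Ordinary least-squares trend of yearly global article counts per cause
#' over a fitting window (by default the last four observed years,
#' 2018-2021), used to extrapolate research output.
#'
#' @param pubs publications table.
#' @param window integer years of the fitting window (>= 2 years).
#' @param causes cause table.
#' @param filters optional stratum filters.
#' @return A \code{research_trends} object: data frame with columns cause_id,
#'   intercept, slope; the window and the last observed counts are attached
#'   as attributes. Use \code{predict(trends, years)} to extrapolate.
#' @export
fit_research_trends <- function(pubs, window = 2018:2021,
                                causes = default_causes(), filters = NULL) {
  if (length(window) < 2L) stop("window must span at least 2 years",
                                call. = FALSE)
  if (!all(window %in% unique(pubs$year))) {
    stop("window years outside the data: ",
         paste(setdiff(window, unique(pubs$year)), collapse = ", "),
         call. = FALSE)
  }
  ids <- level2_ids(causes)
  counts <- sapply(window, function(y) {
    research_counts(pubs, y, causes, filters = filters)
  })  # causes x years
  coefs <- t(apply(counts, 1, function(n) {
    stats::coef(stats::lm(n ~ window))
  }))
  out <- data.frame(cause_id = ids, intercept = coefs[, 1],
                    slope = coefs[, 2], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  last_year <- max(pubs$year)
  structure(out, class = c("research_trends", "data.frame"),
            window = window,
            last_year = last_year,
            last_counts = research_counts(pubs, last_year, causes,
                                          filters = filters),
            covid = NULL, pubs_years = sort(unique(pubs$year)))
}

#' Extrapolate fitted research trends
#'
#' @param object a \code{research_trends} fit.
#' @param years years to project.
#' @param floor minimum projected count per cause-year (default 1 article, so
#'   divergences stay finite).
#' @param ... unused.
#' @return Matrix years x causes of projected counts.
#' @export
predict.research_trends <- function(object, years, floor = 1, ...) {
  out <- outer(years, object$slope) +
    matrix(object$intercept, length(years), nrow(object), byrow = TRUE)
  dimnames(out) <- list(years, object$cause_id)
  cov <- attr(object, "covid")
  if (!is.null(cov)) {
    cid <- cov$cause
    y0 <- cov$last_year          # last observed (shocked) level
    yT <- max(cov$span) + 1L     # back on the pre-shock line here
    for (i in seq_along(years)) {
      y <- years[i]
      if (y <= y0) next
      trend_val <- cov$pre_intercept + cov$pre_slope * y
      if (y >= yT) {
        out[i, cid] <- trend_val
      } else {
        w <- (y - y0) / (yT - y0)
        end_val <- cov$pre_intercept + cov$pre_slope * yT
        out[i, cid] <- (1 - w) * cov$last_level + w * end_val
      }
    }
  }
  low <- out < floor
  if (any(low)) out[low] <- floor
  out
}

#' Adjust projected research for a pandemic shock
#'
#' Replaces the target cause's projection by a linear relaxation from its
#' last observed (shocked) level back to its pre-shock trend line (fitted on
#' an anchor window ending 2019) by the end of the adjustment span; other
#' causes are untouched.
#'
#' @param trends a \code{research_trends} fit.
#' @param pubs the publications table the trends were fitted on.
#' @param cause target cause id (the respiratory-infections category).
#' @param span adjustment years (default 2022-2024).
#' @param anchor_window pre-shock years used to fit the relaxation target
#'   line (default 2016-2019).
#' @param causes cause table.
#' @param filters optional stratum filters (must match the trend fit's).
#' @return The trends object with the adjustment attached.
#' @export
covid_adjust <- function(trends, pubs, cause = "resp_tb", span = 2022:2024,
                         anchor_window = 2016:2019,
                         causes = default_causes(), filters = NULL) {
  if (!cause %in% trends$cause_id) {
    stop("cause not present in trends: ", cause, call. = FALSE)
  }
  anchor_window <- intersect(anchor_window, unique(pubs$year))
  if (length(anchor_window) < 2L) {
    stop("anchor window must contain at least 2 observed years",
         call. = FALSE)
  }
  n <- vapply(anchor_window, function(y) {
    research_counts(pubs, y, causes, filters = filters)[[cause]]
  }, numeric(1))
  fit <- stats::coef(stats::lm(n ~ anchor_window))
  last_year <- attr(trends, "last_year")
  last_level <- attr(trends, "last_counts")[[cause]]
  attr(trends, "covid") <- list(cause = cause, span = span,
                                pre_intercept = unname(fit[1]),
                                pre_slope = unname(fit[2]),
                                last_year = last_year,
                                last_level = last_level)
  trends
}

#' Withdraw US public funding from non-US-led research
#'
#' Removes article volume that acknowledges US public funding and has a
#' non-US first author, phased in linearly: in year k of the phase-in,
#' k / phase_in_years of the affected volume is removed (all of it from the
#' full phase-in onward, or immediately in abrupt mode). US-first-author
#' rows are untouched.
#'
#' @param pubs publications table with the \code{us_public_funded} flag.
#' @param start_year first withdrawal year.
#' @param phase_in_years length of the linear phase-in (default 5).
#' @param abrupt if TRUE the full volume is removed from \code{start_year}.
#' @param us_country country code identifying US first authors.
#' @return The publications table with reduced (possibly fractional)
#'   \code{n_articles}.
#' @export
apply_withdrawal <- function(pubs, start_year, phase_in_years = 5L,
                             abrupt = FALSE, us_country = "USA") {
  if (!"us_public_funded" %in% names(pubs)) {
    stop("publications table lacks the us_public_funded flag", call. = FALSE)
  }
  affected <- pubs$us_public_funded == 1L & pubs$country != us_country
  frac <- pmin(1, pmax(0, (pubs$year - start_year + 1) / phase_in_years))
  if (abrupt) frac <- as.numeric(pubs$year >= start_year)
  pubs$n_articles <- pubs$n_articles * ifelse(affected, 1 - frac, 1)
  pubs
}

#' Projection scenario specification
#'
#' @param horizon_year final projected year (default 2050).
#' @param trend_window research trend-fitting years (default 2018-2021).
#' @param covid_adjust adjust the respiratory-infections projection for the
#'   pandemic shock over \code{covid_span}.
#' @param covid_cause,covid_span,covid_anchor shock-adjustment parameters.
#' @param n_sims Monte Carlo draws per year (default 1000).
#' @param seed root seed.
#' @param burden_forecast \code{"linear_continuation"} (per-cause OLS on the
#'   global burden means over \code{burden_trend_window}) or a data frame
#'   with columns year, cause_id, mean, lower, upper supplying an external
#'   forecast.
#' @param burden_trend_window years for the linear burden continuation.
#' @param withdrawal \code{NULL} (scenario 1 only) or a list with elements
#'   \code{phase_in_years} (default 5) and \code{abrupt} (default FALSE) to
#'   add the funding-withdrawal scenario.
#' @param floor minimum projected article count per cause-year.
#' @param metric burden metric.
#' @param zero_policy,alpha divergence zero-handling (as in
#'   \code{\link{divergence_series}}).
#' @param z normal quantile for the CIs.
#' @return A list of class \code{projection_spec}.
#' @export
projection_spec <- function(horizon_year = 2050L, trend_window = 2018:2021,
                            covid_adjust = TRUE, covid_cause = "resp_tb",
                            covid_span = 2022:2024,
                            covid_anchor = 2016:2019,
                            n_sims = 1000L, seed = 11L,
                            burden_forecast = "linear_continuation",
                            burden_trend_window = 2010:2021,
                            withdrawal = NULL, floor = 1,
                            metric = "daly", zero_policy = "laplace",
                            alpha = 1, z = 1.959964) {
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  structure(list(horizon_year = as.integer(horizon_year),
                 trend_window = trend_window, covid_adjust = covid_adjust,
                 covid_cause = covid_cause, covid_span = covid_span,
                 covid_anchor = covid_anchor,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 burden_forecast = burden_forecast,
                 burden_trend_window = burden_trend_window,
                 withdrawal = withdrawal, floor = floor, metric = metric,
                 zero_policy = zero_policy, alpha = alpha, z = z),
            class = "projection_spec")
}

# Per-cause global burden forecast (mean, lower, upper) for the projected
# years: linear continuation of the trend-window global means, with the last
# observed year's relative interval widths carried forward. Negative
# extrapolations are floored at a small positive fraction of the last level.
forecast_burden <- function(burden, spec, years, causes) {
  if (is.data.frame(spec$burden_forecast)) return(spec$burden_forecast)
  ids <- level2_ids(causes)
  window <- intersect(spec$burden_trend_window, unique(burden$year))
  if (length(window) < 2L) stop("burden trend window outside data",
                                call. = FALSE)
  hist <- sapply(window, function(y) {
    burden_rows(burden, y, causes, spec$metric)$mean
  })
  rownames(hist) <- ids
  last <- burden_rows(burden, max(unique(burden$year)), causes, spec$metric)
  rel_lo <- 1 - last$lower / last$mean
  rel_hi <- last$upper / last$mean - 1
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    fit <- stats::coef(stats::lm(hist[i, ] ~ window))
    pred <- fit[1] + fit[2] * years
    pred <- pmax(pred, 0.001 * last$mean[i])
    rows[[i]] <- data.frame(year = years, cause_id = ids[i], mean = pred,
                            lower = pred * (1 - rel_lo[i]),
                            upper = pred * (1 + rel_hi[i]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Project future research-burden divergence
#'
#' Scenario 1 (baseline): research counts follow their fitted linear trends
#' (optionally pandemic-adjusted); burden follows a pluggable forecast
#' (linear continuation by default). Scenario 2 (withdrawal): additionally,
#' the article volume acknowledging US public funding with non-US first
#' authors is removed, phased linearly. Per simulation draw, burden values
#' are sampled from log-normal uncertainty around the forecast means and the
#' yearly divergence is computed against the projected research shares;
#' reported are the across-simulation mean and 95\% CI per year per scenario.
#' Deterministic given the spec's seed.
#'
#' @param pubs publications table.
#' @param burden burden table.
#' @param spec a \code{\link{projection_spec}}.
#' @param causes cause table.
#' @return A \code{projection_series}: data frame with columns scenario,
#'   year, kld, ci_low, ci_high.
#' @export
run_projection <- function(pubs, burden, spec = projection_spec(),
                           causes = default_causes()) {
  stopifnot(inherits(spec, "projection_spec"))
  last_obs <- max(pubs$year)
  if (spec$horizon_year <= last_obs) {
    stop("horizon must exceed the last observed year", call. = FALSE)
  }
  years <- (last_obs + 1L):spec$horizon_year
  trends <- fit_research_trends(pubs, spec$trend_window, causes)
  if (isTRUE(spec$covid_adjust) && spec$covid_cause %in% trends$cause_id) {
    trends <- covid_adjust(trends, pubs, spec$covid_cause, spec$covid_span,
                           spec$covid_anchor, causes)
  }
  counts_base <- predict(trends, years, floor = spec$floor)
  fc <- forecast_burden(burden, spec, years, causes)
  ids <- level2_ids(causes)

  scenarios <- list(baseline = counts_base)
  if (!is.null(spec$withdrawal)) {
    w <- spec$withdrawal
    phase <- if (is.null(w$phase_in_years)) 5L else w$phase_in_years
    abrupt <- isTRUE(w$abrupt)
    # per-cause share of recent volume that is US-funded with non-US lead
    recent <- filter_pubs(pubs, spec$trend_window)
    aff <- recent[recent$us_public_funded == 1L & recent$country != "USA", ,
                  drop = FALSE]
    tot_c <- research_counts(recent, spec$trend_window, causes)
    aff_c <- research_counts(aff, spec$trend_window, causes)
    aff_share <- ifelse(tot_c > 0, aff_c / tot_c, 0)
    frac <- pmin(1, (years - years[1] + 1) / phase)
    if (abrupt) frac <- rep(1, length(years))
    counts_w <- counts_base * (1 - outer(frac, aff_share))
    counts_w[counts_w < spec$floor] <- spec$floor
    scenarios$withdrawal <- counts_w
  }

  cfg_z <- spec$z
  out <- vector("list", length(scenarios))
  for (si in seq_along(scenarios)) {
    counts <- scenarios[[si]]
    klds <- matrix(NA_real_, spec$n_sims, length(years))
    local_seed(sub_seed(spec$seed, si), {
      for (j in seq_along(years)) {
        rows <- fc[fc$year == years[j], , drop = FALSE]
        rows <- rows[match(ids, rows$cause_id), ]
        draws <- draw_burden_matrix(rows, spec$n_sims, cfg_z)
        P <- draws / rowSums(draws)
        q <- counts[j, ]
        if (spec$zero_policy %in% c("laplace", "raw")) {
          qq <- if (spec$zero_policy == "laplace") {
            apply_laplace(q, spec$alpha)
          } else q / sum(q)
          L <- P * log(sweep(P, 2, qq, "/"))
          L[P == 0] <- 0
          klds[, j] <- rowSums(L)
        } else {
          for (s in seq_len(spec$n_sims)) {
            klds[s, j] <- metrics_under_policy(P[s, ], q, spec$zero_policy,
                                               spec$alpha, 0.01)$kld
          }
        }
      }
    })
    est <- colMeans(klds)
    if (spec$n_sims > 1L) {
      sds <- apply(klds, 2, stats::sd)
      lo <- est - cfg_z * sds
      hi <- est + cfg_z * sds
    } else {
      lo <- hi <- rep(NA_real_, length(years))
    }
    out[[si]] <- data.frame(scenario = names(scenarios)[si], year = years,
                            kld = est, ci_low = lo, ci_high = hi,
                            stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out),
            class = c("projection_series", "data.frame"),
            spec = spec)
}

#' @export
print.projection_series <- function(x, ...) {
  sp <- attr(x, "spec")
  cat("Projected research-burden divergence to ", sp$horizon_year,
      " (", sp$n_sims, " simulations)\n", sep = "")
  for (sc in unique(x$scenario)) {
    sub <- x[x$scenario == sc, ]
    cat(sprintf("  %-10s KLD %.4f (%d) -> %.4f (%d)\n", sc,
                sub$kld[1], sub$year[1],
                sub$kld[nrow(sub)], sub$year[nrow(sub)]))
  }
  invisible(x)
}

#' @export
plot.projection_series <- function(x, ...) {
  df <- as.data.frame(x)
  scen <- unique(df$scenario)
  cols <- c(baseline = "steelblue", withdrawal = "firebrick")
  ylim <- range(c(df$kld, df$ci_low, df$ci_high), na.rm = TRUE)
  graphics::plot(NA, xlim = range(df$year), ylim = ylim,
                 xlab = "Year", ylab = "KLD (nats)", ...)
  for (sc in scen) {
    sub <- df[df$scenario == sc, ]
    graphics::lines(sub$year, sub$kld, lty = 2, lwd = 2,
                    col = cols[[sc]] %||% "black")
  }
  graphics::legend("topleft", legend = scen, lty = 2, lwd = 2,
                   col = unname(cols[scen]), bty = "n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exposure of region-led research to US public funding
#'
#' Per first-author region (excluding Northern America) and cause, the share
#' of publications acknowledging US public funding among all publications in
#' the cell. Empty cells are reported as NA, not 0.
#'
#' @param pubs publications table.
#' @param years years pooled (default 2015-2021).
#' @param regions region map.
#' @param causes cause table.
#' @param exclude_region region(s) left out of the table.
#' @return Data frame with columns region, cause_id, n_articles, share.
#' @export
exposure_shares <- function(pubs, years = 2015:2021,
                            regions = default_regions(),
                            causes = default_causes(),
                            exclude_region = "Northern America") {
  sel <- filter_pubs(pubs, years)
  sel$region <- regions$region[match(sel$country, regions$country)]
  if (anyNA(sel$region)) {
    stop("countries not present in region map: ",
         paste(unique(sel$country[is.na(sel$region)]), collapse = ", "),
         call. = FALSE)
  }
  sel <- sel[!sel$region %in% exclude_region, , drop = FALSE]
  regs <- setdiff(un_regions(), exclude_region)
  ids <- level2_ids(causes)
  grid <- expand.grid(region = regs, cause_id = ids, stringsAsFactors = FALSE)
  grid$n_articles <- 0
  grid$share <- NA_real_
  key <- paste(sel$region, sel$cause_id)
  tot <- tapply(sel$n_articles, key, sum)
  us <- tapply(sel$n_articles * (sel$us_public_funded == 1L), key, sum)
  gkey <- paste(grid$region, grid$cause_id)
  idx <- match(names(tot), gkey)
  grid$n_articles[idx] <- tot
  grid$share[idx] <- us[names(tot)] / tot
  grid
}

#' Shares of non-US funder countries for a cause
#'
#' Among articles on the cause acknowledging non-US funding, the share
#' attributable to each of the top-k funder countries by acknowledgment
#' volume.
#'
#' @param funders funder-acknowledgment table with columns cause_id,
#'   funder_country, n_articles (the synthetic generator returns one as its
#'   \code{funders} element).
#' @param cause cause id.
#' @param top_k number of countries to report (default 10).
#' @param years optional year subset (requires a year column).
#' @return Data frame with columns funder_country, n_articles, share, sorted
#'   by share.
#' @export
funder_country_shares <- function(funders, cause, top_k = 10L, years = NULL) {
  sel <- funders[funders$cause_id == cause &
                   funders$funder_country != "USA", , drop = FALSE]
  if (!is.null(years)) sel <- sel[sel$year %in% years, , drop = FALSE]
  if (!nrow(sel) || sum(sel$n_articles) == 0) {
    stop("no non-US funded articles for cause ", cause, call. = FALSE)
  }
  tot <- tapply(sel$n_articles, sel$funder_country, sum)
  tot <- sort(tot, decreasing = TRUE)
  top <- utils::head(tot, top_k)
  data.frame(funder_country = names(top), n_articles = as.vector(top),
             share = as.vector(top) / sum(tot), stringsAsFactors = FALSE)
}
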