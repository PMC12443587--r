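#' Specification of a synthetic research-and-burden world
#'
#' Describes a world with the statistical structure the alignment analysis
#' assumes: 16 level-2 causes, 8 UN regions, years 1999-2021, near-constant
#' research shares, declining and regionally concentrated communicable burden,
#' rising and globally spread noncommunicable burden, asymmetric burden
#' uncertainty intervals, and US-public-funding acknowledgment concentrated in
#' communicable-disease research led from sub-Saharan Africa. All defaults are
#' the generator's fixed study conditions; ground truth is returned alongside
#' the tables so recovery tests have an analytic oracle.
#'
#' @param years calendar years covered (default 1999-2021).
#' @param causes cause table (16 level-2 causes by default).
#' @param regions country-to-region map; the generator allocates volumes to
#'   the mapped countries with fixed within-region weights.
#' @param total_articles_per_year articles drawn per year (multinomially, so
#'   yearly totals are exact).
#' @param research_shares named baseline research share vector over the cause
#'   set (normalized internally).
#' @param research_drift per-cause additive annual drift of research shares
#'   (scalar or named vector; default 0, emulating a research mix that stays
#'   virtually unchanged).
#' @param research_follows_burden_lag if a nonnegative integer, research
#'   shares each year copy the expected burden shares of \code{lag} years
#'   earlier instead of the baseline (used for lag-recovery experiments).
#' @param burden_total global DALY volume in the first year.
#' @param burden_shares named first-year global DALY share vector.
#' @param region_weights 16 x 8 matrix of within-cause regional burden weights
#'   (rows causes, columns the UN regions, rows summing to 1).
#' @param burden_trends 16 x 8 matrix of annual multiplicative log-trends of
#'   regional burden.
#' @param burden_noise_sd standard deviation of multiplicative log-normal
#'   noise on generated burden means.
#' @param rel_lower,rel_upper relative half-widths of the asymmetric
#'   uncertainty interval: lower = mean (1 - rel_lower), upper =
#'   mean (1 + rel_upper).
#' @param p_us_funding 8 x 16 matrix (regions x causes) of the probability
#'   that an article acknowledges US public funding.
#' @param funded_target overall share of articles with known funding
#'   acknowledgment (default 0.4).
#' @param p_unknown share of articles with unknown funding status.
#' @param research_type_probs probabilities of basic/applied/clinical types.
#' @param p_industry probability of an industry-affiliated author.
#' @param p_phase3 probability that an industry clinical article is a
#'   phase-3 trial.
#' @param research_region_weights allocation of research volume over regions
#'   (research concentrated in Northern America, Europe and Eastern Asia).
#' @param funder_dist named distribution of non-US funder countries.
#' @param seed root seed; per-year substreams are derived from it so
#'   subsetting years is reproducible.
#' @return A list of class \code{world_spec}.
#' @export
world_spec <- function(years = 1999:2021,
                       causes = default_causes(),
                       regions = default_regions(),
                       total_articles_per_year = 50000L,
                       research_shares = NULL,
                       research_drift = 0,
                       research_follows_burden_lag = NULL,
                       burden_total = 2.5e9,
                       burden_shares = NULL,
                       region_weights = NULL,
                       burden_trends = NULL,
                       burden_noise_sd = 0.02,
                       rel_lower = 0.15,
                       rel_upper = 0.25,
                       p_us_funding = NULL,
                       funded_target = 0.4,
                       p_unknown = 0.2,
                       research_type_probs = c(basic = 0.45, applied = 0.30,
                                               clinical = 0.25),
                       p_industry = 0.15,
                       p_phase3 = 0.3,
                       research_region_weights = NULL,
                       funder_dist = NULL,
                       seed = 42L) {
  validate_causes(causes)
  validate_regions(regions)
  ids <- level2_ids(causes)
  k <- length(ids)
  regs <- un_regions()

  norm_named <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.null(names(x))) names(x) <- ids
    x <- x[ids]
    if (any(is.na(x) | x < 0)) stop("share vector must cover all causes and be nonnegative",
                                    call. = FALSE)
    x / sum(x)
  }

  default_research <- c(
    hiv_std = 0.035, resp_tb = 0.03, enteric = 0.02, ntd_malaria = 0.015,
    maternal_neonatal = 0.03, nutritional = 0.01,
    cardiovascular = 0.11, neoplasms = 0.22, chronic_resp = 0.04,
    digestive = 0.07, neurological = 0.09, mental = 0.07, substance = 0.03,
    diabetes_kidney = 0.05, musculoskeletal = 0.05, skin = 0.03
  )
  default_burden <- c(
    hiv_std = 0.05, resp_tb = 0.11, enteric = 0.07, ntd_malaria = 0.05,
    maternal_neonatal = 0.09, nutritional = 0.04,
    cardiovascular = 0.16, neoplasms = 0.10, chronic_resp = 0.04,
    digestive = 0.04, neurological = 0.05, mental = 0.045, substance = 0.025,
    diabetes_kidney = 0.04, musculoskeletal = 0.06, skin = 0.02
  )
  if (!setequal(ids, names(default_research))) {
    # non-default cause set: fall back to uniform-ish defaults
    default_research <- stats::setNames(rep(1 / k, k), ids)
    default_burden <- stats::setNames(rep(1 / k, k), ids)
  }
  research_shares <- norm_named(research_shares, default_research)
  burden_shares <- norm_named(burden_shares, default_burden)

  comm <- causes$communicable[match(ids, causes$cause_id)]
  if (is.null(region_weights)) {
    region_weights <- matrix(NA_real_, k, 8, dimnames = list(ids, regs))
    for (i in seq_len(k)) {
      region_weights[i, ] <- if (comm[i]) {
        c(0.25, 0.05, 0.02, 0.05, 0.05, 0.01, 0.02, 0.55)
      } else {
        c(0.20, 0.26, 0.14, 0.09, 0.10, 0.07, 0.02, 0.12)
      }
    }
  }
  region_weights <- region_weights / rowSums(region_weights)
  if (is.null(burden_trends)) {
    burden_trends <- matrix(0.015, k, 8, dimnames = list(ids, regs))
    for (i in seq_len(k)) {
      if (comm[i]) {
        burden_trends[i, ] <- -0.005
        burden_trends[i, c("Central and Southern Asia",
                           "Sub-Saharan Africa")] <- -0.025
      }
    }
    if ("cardiovascular" %in% ids) {
      burden_trends["cardiovascular", ] <-
        c(0.02, 0.018, -0.005, 0.012, 0.015, -0.005, -0.005, 0.012)
    }
    if ("neoplasms" %in% ids) burden_trends["neoplasms", ] <- 0.004
  } else {
    if (is.null(dimnames(burden_trends))) {
      dimnames(burden_trends) <- list(ids, regs)
    }
  }
  if (!all(is.finite(burden_trends))) stop("trends must be finite",
                                           call. = FALSE)

  if (is.null(research_region_weights)) {
    research_region_weights <- stats::setNames(
      c(0.05, 0.20, 0.30, 0.04, 0.04, 0.30, 0.04, 0.03), regs)
  }
  research_region_weights <- research_region_weights / sum(research_region_weights)

  if (is.null(p_us_funding)) {
    p_us_funding <- matrix(0.08, 8, k, dimnames = list(regs, ids))
    p_us_funding[, comm] <- 0.15
    if ("hiv_std" %in% ids) p_us_funding[, "hiv_std"] <- 0.35
    if ("resp_tb" %in% ids) p_us_funding[, "resp_tb"] <- 0.22
    if ("substance" %in% ids) p_us_funding[, "substance"] <- 0.18
    if ("neurological" %in% ids) p_us_funding[, "neurological"] <- 0.16
    p_us_funding["Sub-Saharan Africa", comm] <- 0.20
    if ("hiv_std" %in% ids) p_us_funding["Sub-Saharan Africa", "hiv_std"] <- 0.41
    if ("resp_tb" %in% ids) p_us_funding["Sub-Saharan Africa", "resp_tb"] <- 0.25
    p_us_funding["Northern America", ] <- 0.45
  }
  if (any(p_us_funding < 0 | p_us_funding > 1)) {
    stop("funding probabilities must be in [0, 1]", call. = FALSE)
  }

  if (is.null(funder_dist)) {
    funder_dist <- c(CHN = 0.20, GBR = 0.16, CAN = 0.12, AUS = 0.10,
                     DEU = 0.08, JPN = 0.07, FRA = 0.06, NLD = 0.05,
                     CHE = 0.04, SWE = 0.03, KOR = 0.03, ITA = 0.03,
                     ESP = 0.03)
  }
  funder_dist <- funder_dist / sum(funder_dist)

  if (length(research_drift) == 1L) {
    research_drift <- stats::setNames(rep(research_drift, k), ids)
  }
  research_drift <- research_drift[ids]

  if (total_articles_per_year <= 0) {
    stop("total_articles_per_year must be positive", call. = FALSE)
  }
  stopifnot(rel_lower >= 0, rel_lower < 1, rel_upper >= 0,
            funded_target >= 0, funded_target <= 1,
            p_unknown >= 0, p_industry >= 0, p_industry <= 1,
            p_phase3 >= 0, p_phase3 <= 1)

  structure(list(
    years = years, causes = causes, regions = regions,
    total_articles_per_year = as.integer(total_articles_per_year),
    research_shares = research_shares, research_drift = research_drift,
    research_follows_burden_lag = research_follows_burden_lag,
    burden_total = burden_total, burden_shares = burden_shares,
    region_weights = region_weights, burden_trends = burden_trends,
    burden_noise_sd = burden_noise_sd,
    rel_lower = rel_lower, rel_upper = rel_upper,
    p_us_funding = p_us_funding, funded_target = funded_target,
    p_unknown = p_unknown, research_type_probs = research_type_probs,
    p_industry = p_industry, p_phase3 = p_phase3,
    research_region_weights = research_region_weights,
    funder_dist = funder_dist, seed = as.integer(seed)
  ), class = "world_spec")
}

# Fixed within-region country weights: 0.7/0.3 for two countries,
# 0.5/0.3/0.2 for three, in map order.
country_weights <- function(regions) {
  w <- numeric(nrow(regions))
  for (r in unique(regions$region)) {
    idx <- which(regions$region == r)
    w[idx] <- if (length(idx) == 2L) c(0.7, 0.3)
              else if (length(idx) == 3L) c(0.5, 0.3, 0.2)
              else rep(1 / length(idx), length(idx))
  }
  stats::setNames(w, regions$country)
}

#' Expected cause-share trajectories implied by a world spec
#'
#' Analytic (noise-free) global burden and research share trajectories, the
#' oracle against which generated tables are tested.
#'
#' @param spec a \code{\link{world_spec}}.
#' @param years years to evaluate (may extend beyond the spec's range; the
#'   trend model extrapolates).
#' @return List with matrices \code{burden} and \code{research}
#'   (years x causes), each row summing to 1.
#' @export
expected_shares <- function(spec, years = spec$years) {
  ids <- names(spec$burden_shares)
  y0 <- min(spec$years)
  burden <- matrix(NA_real_, length(years), length(ids),
                   dimnames = list(years, ids))
  for (j in seq_along(years)) {
    lev <- spec$burden_shares *
      rowSums(spec$region_weights * exp(spec$burden_trends * (years[j] - y0)))
    burden[j, ] <- lev / sum(lev)
  }
  research <- matrix(NA_real_, length(years), length(ids),
                     dimnames = list(years, ids))
  lag <- spec$research_follows_burden_lag
  for (j in seq_along(years)) {
    if (!is.null(lag)) {
      src_year <- years[j] - lag
      lev <- spec$burden_shares *
        rowSums(spec$region_weights * exp(spec$burden_trends * (src_year - y0)))
      research[j, ] <- lev / sum(lev)
    } else {
      s <- spec$research_shares + spec$research_drift * (years[j] - y0)
      s[s < 0] <- 0
      research[j, ] <- s / sum(s)
    }
  }
  list(burden = burden, research = research)
}

# Strata cell grid for one (region, cause): 4 funding states x 3 research
# types x 3 industry states, with the joint probabilities implied by the spec.
strata_grid <- function() {
  expand.grid(
    fund_state = c("us", "yes0", "no", "unknown"),
    research_type = c("basic", "applied", "clinical"),
    ind_state = c("none", "ind", "ind_ph3"),
    stringsAsFactors = FALSE
  )
}

strata_probs <- function(spec, region, cause) {
  g <- strata_grid()
  pu <- spec$p_us_funding[region, cause]
  p_yes <- max(spec$funded_target, pu)
  p_unk <- min(spec$p_unknown, 1 - p_yes)
  p_no <- 1 - p_yes - p_unk
  pf <- c(us = pu, yes0 = p_yes - pu, no = p_no, unknown = p_unk)
  pt <- spec$research_type_probs
  p_ind <- function(rtype, state) {
    if (state == "none") return(1 - spec$p_industry)
    if (rtype == "clinical") {
      if (state == "ind") spec$p_industry * (1 - spec$p_phase3)
      else spec$p_industry * spec$p_phase3
    } else {
      if (state == "ind") spec$p_industry else 0
    }
  }
  probs <- pf[g$fund_state] * pt[g$research_type] *
    mapply(p_ind, g$research_type, g$ind_state)
  unname(probs)
}

#' Generate a synthetic world
#'
#' Draws publication counts multinomially per year from the (possibly
#' drifting) research-share vector, allocates them to countries and strata
#' per the spec's region and funding model, and builds burden tables whose
#' means follow the per-cause per-region trend model with asymmetric bounds
#' \code{mean (1 - a)} and \code{mean (1 + b)}. Deterministic given the
#' spec's seed; per-year random substreams are derived from the root seed.
#'
#' @param spec a \code{\link{world_spec}}.
#' @return A list of class \code{synthetic_world} with elements
#'   \code{publications}, \code{burden}, \code{funders} (per year x cause
#'   funder-country acknowledgment counts), \code{causes}, \code{regions}
#'   and \code{ground_truth}.
#' @export
generate_world <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  ids <- names(spec$burden_shares)
  regs <- un_regions()
  cw <- country_weights(spec$regions)
  countries <- spec$regions$country
  creg <- spec$regions$region
  exp_sh <- expected_shares(spec)

  # --- publications: one multinomial per year over cause x country x stratum
  g <- strata_grid()
  n_str <- nrow(g)
  cells <- expand.grid(stratum = seq_len(n_str),
                       country = countries, cause_id = ids,
                       stringsAsFactors = FALSE)
  cells$region <- creg[match(cells$country, countries)]
  # probability within a cause: country weight (research geography) x strata
  strat_rc <- array(NA_real_, c(8, length(ids), n_str),
                    dimnames = list(regs, ids, NULL))
  for (r in regs) for (cid in ids) {
    strat_rc[r, cid, ] <- strata_probs(spec, r, cid)
  }
  country_research_w <- spec$research_region_weights[creg] * cw /
    stats::ave(cw, creg, FUN = sum)  # weights within region scaled by region share
  names(country_research_w) <- countries
  base_prob <- country_research_w[cells$country] *
    strat_rc[cbind(match(cells$region, regs), match(cells$cause_id, ids),
                   cells$stratum)]

  pub_list <- vector("list", length(spec$years))
  funder_list <- vector("list", length(spec$years))
  for (j in seq_along(spec$years)) {
    y <- spec$years[j]
    probs <- base_prob * exp_sh$research[j, cells$cause_id]
    counts <- local_seed(sub_seed(spec$seed, j), {
      n <- as.vector(stats::rmultinom(1, spec$total_articles_per_year,
                                      probs))
      # funder countries for the non-US-funded acknowledgments
      yes0 <- g$fund_state[cells$stratum] == "yes0"
      per_cause_yes0 <- tapply(n[yes0], cells$cause_id[yes0], sum)
      fc <- lapply(ids, function(cid) {
        tot <- per_cause_yes0[[cid]]
        if (is.na(tot) || tot == 0) return(NULL)
        draw <- as.vector(stats::rmultinom(1, tot, spec$funder_dist))
        data.frame(year = y, cause_id = cid,
                   funder_country = names(spec$funder_dist),
                   n_articles = draw, stringsAsFactors = FALSE)
      })
      list(n = n, fc = do.call(rbind, fc))
    })
    n <- counts$n
    keep <- n > 0
    st <- g[cells$stratum[keep], ]
    pub_list[[j]] <- data.frame(
      year = y,
      cause_id = cells$cause_id[keep],
      country = cells$country[keep],
      n_articles = n[keep],
      funded = ifelse(st$fund_state %in% c("us", "yes0"), "yes",
                      st$fund_state),
      us_public_funded = as.integer(st$fund_state == "us"),
      industry_author = as.integer(st$ind_state != "none"),
      research_type = st$research_type,
      industry_phase3 = as.integer(st$ind_state == "ind_ph3"),
      stringsAsFactors = FALSE
    )
    us_rows <- pub_list[[j]][pub_list[[j]]$us_public_funded == 1L, ]
    us_fc <- NULL
    if (nrow(us_rows)) {
      per_cause_us <- tapply(us_rows$n_articles, us_rows$cause_id, sum)
      us_fc <- data.frame(year = y, cause_id = names(per_cause_us),
                          funder_country = "USA",
                          n_articles = as.vector(per_cause_us),
                          stringsAsFactors = FALSE)
    }
    funder_list[[j]] <- rbind(counts$fc, us_fc)
  }
  publications <- do.call(rbind, pub_list)
  rownames(publications) <- NULL
  funders <- do.call(rbind, funder_list)
  rownames(funders) <- NULL

  # --- burden: mean follows the trend model; bounds multiplicative
  y0 <- min(spec$years)
  metric_scale <- c(daly = 1, deaths = 0.022, prevalence = 2)
  # deterministic cause tilts so deaths / prevalence are distinct but parallel
  tilt <- list(
    daly = rep(1, length(ids)),
    deaths = 0.5 + seq(1.5, 0.5, length.out = length(ids)),
    prevalence = 0.5 + seq(0.5, 1.5, length.out = length(ids))
  )
  grid_b <- expand.grid(country = countries, cause_id = ids,
                        stringsAsFactors = FALSE)
  grid_b$region <- creg[match(grid_b$country, countries)]
  cw_in_region <- cw / stats::ave(cw, creg, FUN = sum)
  names(cw_in_region) <- countries
  bur_list <- vector("list", length(spec$years) * 3L)
  idx <- 0L
  for (j in seq_along(spec$years)) {
    y <- spec$years[j]
    base <- spec$burden_total * spec$burden_shares[grid_b$cause_id] *
      spec$region_weights[cbind(grid_b$cause_id, grid_b$region)] *
      cw_in_region[grid_b$country] *
      exp(spec$burden_trends[cbind(grid_b$cause_id, grid_b$region)] * (y - y0))
    noise <- local_seed(sub_seed(spec$seed, 1000L + j),
                        stats::rnorm(nrow(grid_b) * 3L, 0,
                                     spec$burden_noise_sd))
    for (mi in seq_along(names(metric_scale))) {
      met <- names(metric_scale)[mi]
      tl <- stats::setNames(tilt[[met]], ids)
      mean_v <- base * metric_scale[[met]] * tl[grid_b$cause_id] *
        exp(noise[(mi - 1L) * nrow(grid_b) + seq_len(nrow(grid_b))])
      idx <- idx + 1L
      bur_list[[idx]] <- data.frame(
        year = y, cause_id = grid_b$cause_id, location = grid_b$country,
        metric = met, mean = mean_v,
        lower = mean_v * (1 - spec$rel_lower),
        upper = mean_v * (1 + spec$rel_upper),
        stringsAsFactors = FALSE
      )
    }
  }
  burden <- do.call(rbind, bur_list)
  rownames(burden) <- NULL

  ground_truth <- list(
    expected_research_shares = exp_sh$research,
    expected_burden_shares = exp_sh$burden,
    region_weights = spec$region_weights,
    burden_trends = spec$burden_trends,
    p_us_funding = spec$p_us_funding,
    funder_dist = spec$funder_dist,
    research_region_weights = spec$research_region_weights,
    spec = spec
  )
  structure(list(publications = publications, burden = burden,
                 funders = funders, causes = spec$causes,
                 regions = spec$regions, ground_truth = ground_truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic research-burden world\n")
  cat("  years:", min(x$publications$year), "-", max(x$publications$year),
      "\n")
  cat("  article-cause links:", sum(x$publications$n_articles), "in",
      nrow(x$publications), "rows\n")
  cat("  burden rows:", nrow(x$burden), "(3 metrics,",
      length(unique(x$burden$location)), "countries)\n")
  invisible(x)
}

# Rescale integer counts to a new total, repairing the rounding residual on
# the largest cell so the total is hit exactly.
scale_to_total <- function(counts, new_total) {
  new_total <- round(new_total)
  out <- round(counts * new_total / sum(counts))
  resid <- new_total - sum(out)
  if (resid != 0) {
    i <- which.max(out)
    out[i] <- max(0, out[i] + resid)
  }
  out
}

#' Inject a pandemic-style shock into a synthetic world
#'
#' In the shock years the target cause's burden (DALY metric) and research
#' shares are raised to the configured levels, with all other causes scaled
#' down proportionally, mirroring the abrupt rise of respiratory-infection
#' burden and research in 2020-2021.
#'
#' @param world a \code{synthetic_world}.
#' @param cause target cause id.
#' @param years shock years.
#' @param burden_share,research_share target global shares per shock year
#'   (recycled to \code{length(years)}); each must be < 1.
#' @return The modified world.
#' @export
covid_shock <- function(world, cause = "resp_tb", years = c(2020L, 2021L),
                        burden_share = c(0.13, 0.16),
                        research_share = c(0.12, 0.14)) {
  if (!length(years)) return(world)
  if (!cause %in% world$causes$cause_id) {
    stop("unknown target cause: ", cause, call. = FALSE)
  }
  burden_share <- rep_len(burden_share, length(years))
  research_share <- rep_len(research_share, length(years))
  if (any(burden_share >= 1) || any(research_share >= 1)) {
    stop("shock shares must be < 1", call. = FALSE)
  }
  pubs <- world$publications
  bur <- world$burden
  for (i in seq_along(years)) {
    y <- years[i]
    # research: rescale target vs rest to hit the configured share
    sel_y <- pubs$year == y
    n_tot <- sum(pubs$n_articles[sel_y])
    sel_t <- sel_y & pubs$cause_id == cause
    n_t <- sum(pubs$n_articles[sel_t])
    target <- round(research_share[i] * n_tot)
    if (n_t == 0) {
      pubs <- rbind(pubs, data.frame(
        year = y, cause_id = cause, country = "USA",
        n_articles = target, funded = "no", us_public_funded = 0L,
        industry_author = 0L, research_type = "basic",
        industry_phase3 = 0L, stringsAsFactors = FALSE))
      sel_y <- pubs$year == y
      sel_t <- sel_y & pubs$cause_id == cause
    } else {
      pubs$n_articles[sel_t] <- scale_to_total(pubs$n_articles[sel_t],
                                               target)
    }
    other <- sel_y & pubs$cause_id != cause
    pubs$n_articles[other] <- scale_to_total(pubs$n_articles[other],
                                             n_tot - target)
    # burden (DALY metric): rescale means and bounds
    sel_by <- bur$year == y & bur$metric == "daly"
    b_tot <- sum(bur$mean[sel_by])
    sel_bt <- sel_by & bur$cause_id == cause
    b_t <- sum(bur$mean[sel_bt])
    f_t <- burden_share[i] * b_tot / b_t
    f_o <- (1 - burden_share[i]) * b_tot / (b_tot - b_t)
    for (col in c("mean", "lower", "upper")) {
      bur[[col]][sel_bt] <- bur[[col]][sel_bt] * f_t
      bur[[col]][sel_by & bur$cause_id != cause] <-
        bur[[col]][sel_by & bur$cause_id != cause] * f_o
    }
  }
  world$publications <- pubs[pubs$n_articles > 0, , drop = FALSE]
  world$burden <- bur
  world$ground_truth$shock <- list(cause = cause, years = years,
                                   burden_share = burden_share,
                                   research_share = research_share)
  world
}
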