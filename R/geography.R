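#' Herfindahl-Hirschman index of a regional share vector
#'
#' \eqn{\sum_r s_r^2} over the regional shares of one cause's burden; 1/8 for
#' a uniform spread over the eight regions, 1 when all burden sits in a single
#' region.
#'
#' @param shares nonnegative shares summing to 1.
#' @return Scalar in (0, 1].
#' @export
hhi <- function(shares) {
  if (any(shares < 0)) stop("shares must be nonnegative", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-6) {
    stop("shares must sum to 1 (got ", format(sum(shares)), ")",
         call. = FALSE)
  }
  sum(shares^2)
}

#' Classify causes as geographically local or global
#'
#' Computes each cause's regional burden-share vector (pooled over the given
#' years), its HHI, and classifies a cause as \emph{local} when its HHI
#' strictly exceeds the threshold — by default the mean HHI across the cause
#' set, so ties go to \emph{global}.
#'
#' @param burden burden table (country- or region-located).
#' @param regions country-to-region map (used when locations are countries).
#' @param years years pooled.
#' @param causes cause table.
#' @param metric burden metric.
#' @param threshold \code{"sample_mean"} or a fixed numeric threshold.
#' @return A \code{locality_table}: data frame with columns cause_id, hhi,
#'   class, and the 8 regional share columns; the threshold used is attached
#'   as an attribute.
#' @export
classify_locality <- function(burden, regions = default_regions(),
                              years, causes = default_causes(),
                              metric = "daly", threshold = "sample_mean") {
  ids <- level2_ids(causes)
  if (length(ids) < 2L) stop("need at least 2 causes", call. = FALSE)
  sel <- burden[burden$year %in% years & burden$metric == metric, ,
                drop = FALSE]
  if (!all(unique(sel$location) %in% un_regions())) {
    sel <- aggregate_regions(sel, regions, c("mean", "lower", "upper"))
  } else {
    names(sel)[names(sel) == "location"] <- "region"
  }
  regs <- un_regions()
  share_mat <- matrix(0, length(ids), length(regs),
                      dimnames = list(ids, regs))
  for (cid in ids) {
    rows <- sel[sel$cause_id == cid, , drop = FALSE]
    tot <- tapply(rows$mean, rows$region, sum)
    share_mat[cid, names(tot)] <- tot
    share_mat[cid, ] <- share_mat[cid, ] / sum(share_mat[cid, ])
  }
  h <- apply(share_mat, 1, hhi)
  thr <- if (identical(threshold, "sample_mean")) mean(h) else threshold
  # strict threshold with a float guard so exact ties classify as global
  out <- data.frame(cause_id = ids, hhi = unname(h),
                    class = ifelse(h > thr + 1e-12, "local", "global"),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(share_mat))
  rownames(out) <- NULL
  structure(out, class = c("locality_table", "data.frame"), threshold = thr)
}

#' @export
print.locality_table <- function(x, ...) {
  cat("Geographic concentration of burden (HHI threshold ",
      format(attr(x, "threshold"), digits = 4), ")\n", sep = "")
  print.data.frame(format(as.data.frame(x)[c("cause_id", "hhi", "class")],
                          digits = 4), row.names = FALSE)
  invisible(x)
}

#' Research-to-burden ratio per location
#'
#' For each country (or region), the location's share of global research
#' divided by its share of global burden, pooled over years. Locations with a
#' ratio above 1 are flagged as net producers of research relative to their
#' burden. Scale-invariant to total article volume.
#'
#' @param pubs publications table.
#' @param burden burden table with locations at the same level as requested.
#' @param regions region map, required for \code{level = "region"}.
#' @param years years pooled.
#' @param causes cause table.
#' @param metric burden metric.
#' @param level \code{"country"} or \code{"region"}.
#' @return Data frame with columns location, research_share, burden_share,
#'   ratio, net_producer.
#' @export
research_burden_ratio <- function(pubs, burden, regions = default_regions(),
                                  years, causes = default_causes(),
                                  metric = "daly",
                                  level = c("country", "region")) {
  level <- match.arg(level)
  psel <- filter_pubs(pubs, years)
  bsel <- burden[burden$year %in% years & burden$metric == metric, ,
                 drop = FALSE]
  if (level == "region") {
    psel <- aggregate_regions(psel, regions, "n_articles")
    if (!all(unique(bsel$location) %in% un_regions())) {
      bsel <- aggregate_regions(bsel, regions, c("mean", "lower", "upper"))
    } else {
      names(bsel)[names(bsel) == "location"] <- "region"
    }
    ploc <- psel$region; bloc <- bsel$region
  } else {
    if (!all(unique(bsel$location) %in% regions$country)) {
      stop("country-level ratios need country-located burden rows",
           call. = FALSE)
    }
    ploc <- psel$country; bloc <- bsel$location
  }
  r_tot <- tapply(psel$n_articles, ploc, sum)
  b_tot <- tapply(bsel$mean, bloc, sum)
  if (sum(r_tot) <= 0 || sum(b_tot) <= 0) {
    stop("pooled totals must be positive", call. = FALSE)
  }
  locs <- sort(union(names(r_tot), names(b_tot)))
  rs <- stats::setNames(rep(0, length(locs)), locs)
  bs <- rs
  rs[names(r_tot)] <- r_tot / sum(r_tot)
  bs[names(b_tot)] <- b_tot / sum(b_tot)
  ratio <- ifelse(bs > 0, rs / bs, NA_real_)  # zero burden share: undefined
  data.frame(location = locs, research_share = unname(rs),
             burden_share = unname(bs), ratio = unname(ratio),
             net_producer = unname(!is.na(ratio) & ratio > 1),
             stringsAsFactors = FALSE)
}

#' Correlation between burden locality and research-burden mismatch
#'
#' For each cause: x is the difference between the cause's DALY share within
#' net-producer countries and its DALY share within the remaining countries
#' (within-group normalized shares); y is the cause's global DALY share minus
#' its global research share. Returns the per-cause pairs and their Pearson
#' (headline) and Spearman correlations.
#'
#' @param pubs publications table.
#' @param burden burden table with country locations.
#' @param net_producers character vector of net-producer countries (for
#'   example from \code{\link{research_burden_ratio}}); must be a nonempty
#'   proper subset of the burden locations.
#' @param years years pooled.
#' @param causes cause table.
#' @param metric burden metric.
#' @return List with \code{pairs} (data frame cause_id, x, y),
#'   \code{pearson} and \code{spearman}.
#' @export
locality_correlation <- function(pubs, burden, net_producers, years,
                                 causes = default_causes(), metric = "daly") {
  locs <- unique(burden$location)
  if (!length(net_producers) || all(locs %in% net_producers)) {
    stop("net-producer set must be a nonempty proper subset of locations",
         call. = FALSE)
  }
  others <- setdiff(locs, net_producers)
  p_net <- burden_shares(burden, years, causes, metric,
                         locations = net_producers)
  p_oth <- burden_shares(burden, years, causes, metric, locations = others)
  p_glob <- burden_shares(burden, years, causes, metric)
  q_glob <- research_shares(pubs, years, causes)
  x <- p_net - p_oth
  y <- p_glob - q_glob
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degenerate variance; correlation undefined")
    pe <- NA_real_; sp <- NA_real_
  } else {
    pe <- stats::cor(x, y)
    sp <- stats::cor(x, y, method = "spearman")
  }
  list(pairs = data.frame(cause_id = names(x), x = unname(x), y = unname(y),
                          stringsAsFactors = FALSE),
       pearson = pe, spearman = sp)
}

#' Regional change in research and burden shares for a cause group
#'
#' Per region, the change in the cause group's share of the region's research
#' and of its burden between two years, in percentage points. Shares are
#' within-region (the cause group's share of that region's total), plus a
#' global row.
#'
#' @param pubs publications table.
#' @param burden burden table.
#' @param cause_group character vector of cause ids forming the group.
#' @param year0,year1 comparison years.
#' @param regions region map.
#' @param causes cause table.
#' @param metric burden metric.
#' @return Data frame with columns region, d_research_pp, d_burden_pp.
#' @export
regional_change <- function(pubs, burden, cause_group, year0, year1,
                            regions = default_regions(),
                            causes = default_causes(), metric = "daly") {
  group_share <- function(tab, year, value_col, loc) {
    sel <- tab[tab$year == year, , drop = FALSE]
    if (!is.null(loc)) sel <- sel[sel$region == loc, , drop = FALSE]
    tot <- sum(sel[[value_col]])
    if (tot <= 0) return(NA_real_)  # missing region-year: flagged as NA
    sum(sel[[value_col]][sel$cause_id %in% cause_group]) / tot
  }
  p_r <- aggregate_regions(filter_pubs(pubs, c(year0, year1)), regions,
                           "n_articles")
  bsel <- burden[burden$year %in% c(year0, year1) & burden$metric == metric, ,
                 drop = FALSE]
  if (!all(unique(bsel$location) %in% un_regions())) {
    b_r <- aggregate_regions(bsel, regions, c("mean", "lower", "upper"))
  } else {
    b_r <- bsel
    names(b_r)[names(b_r) == "location"] <- "region"
  }
  regs <- c(un_regions(), "Global")
  out <- data.frame(region = regs, d_research_pp = NA_real_,
                    d_burden_pp = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(regs)) {
    loc <- if (regs[i] == "Global") NULL else regs[i]
    out$d_research_pp[i] <- 100 * (group_share(p_r, year1, "n_articles", loc) -
                                     group_share(p_r, year0, "n_articles", loc))
    out$d_burden_pp[i] <- 100 * (group_share(b_r, year1, "mean", loc) -
                                   group_share(b_r, year0, "mean", loc))
  }
  out
}
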