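#' Roll a table keyed at cause level 3/4 up to level 2
#'
#' Each row's cause is replaced by its level-2 ancestor (for example a
#' level-4 myocardial-infarction code rolls up through ischemic heart disease
#' into cardiovascular diseases) and values are summed within each ancestor.
#' Total mass is conserved exactly.
#'
#' @param x data frame with a \code{cause_id} column.
#' @param causes cause hierarchy table.
#' @param value_cols names of the numeric columns to sum; defaults to
#'   \code{"n_articles"} if present, else \code{c("mean","lower","upper")}.
#' @return A data frame keyed at level 2, aggregated over all non-value
#'   columns.
#' @export
rollup_to_level2 <- function(x, causes = default_causes(),
                             value_cols = NULL) {
  if (is.null(value_cols)) {
    value_cols <- if ("n_articles" %in% names(x)) "n_articles"
                  else intersect(c("mean", "lower", "upper"), names(x))
  }
  anc <- vapply(unique(x$cause_id), l2_ancestor, character(1), causes = causes)
  x$cause_id <- unname(anc[x$cause_id])
  key_cols <- setdiff(names(x), value_cols)
  agg <- stats::aggregate(x[value_cols], by = x[key_cols], FUN = sum)
  agg[, names(x), drop = FALSE]
}

#' Aggregate a country-keyed table to the eight UN regions
#'
#' Values are summed within each region; the global total is conserved.
#' Regions present in the map but absent from the data are reported with
#' zero rows so region-level tables are always complete.
#'
#' @param x data frame with a \code{country} (or \code{location}) column.
#' @param regions country-to-region map.
#' @param value_cols numeric columns to sum (defaulting as in
#'   \code{\link{rollup_to_level2}}).
#' @return A data frame keyed by \code{region}.
#' @export
aggregate_regions <- function(x, regions = default_regions(),
                              value_cols = NULL) {
  loc_col <- if ("country" %in% names(x)) "country" else "location"
  if (is.null(value_cols)) {
    value_cols <- if ("n_articles" %in% names(x)) "n_articles"
                  else intersect(c("mean", "lower", "upper"), names(x))
  }
  unmapped <- setdiff(unique(x[[loc_col]]), regions$country)
  if (length(unmapped)) {
    stop("countries not present in region map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  x$region <- regions$region[match(x[[loc_col]], regions$country)]
  x[[loc_col]] <- NULL
  key_cols <- setdiff(names(x), value_cols)
  agg <- stats::aggregate(x[value_cols], by = x[key_cols], FUN = sum)
  # completeness: regions in the map with no data appear with zero values
  missing_regions <- setdiff(unique(regions$region), agg$region)
  if (length(missing_regions)) {
    other_keys <- setdiff(key_cols, "region")
    if (length(other_keys) == 0L) {
      zero <- data.frame(region = missing_regions, stringsAsFactors = FALSE)
      zero[value_cols] <- 0
      agg <- rbind(agg, zero[, names(agg), drop = FALSE])
    } else {
      base_keys <- unique(agg[other_keys])
      for (r in missing_regions) {
        zero <- base_keys
        zero$region <- r
        zero[value_cols] <- 0
        agg <- rbind(agg, zero[, names(agg), drop = FALSE])
      }
    }
  }
  agg
}

#' Compute a share distribution over the level-2 cause set
#'
#' Shares are per-cause totals divided by the grand total, always over the
#' full configured cause set: causes absent from the selection get share 0, so
#' distributions are comparable across scopes.
#'
#' @param x data frame with \code{cause_id} and one value column.
#' @param causes cause table; its level-2 ids fix the support and ordering.
#' @param value_col name of the value column (defaults as in
#'   \code{\link{rollup_to_level2}}).
#' @return Named numeric vector of shares summing to 1, ordered by the cause
#'   set.
#' @export
compute_shares <- function(x, causes = default_causes(), value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- if ("n_articles" %in% names(x)) "n_articles" else "mean"
  }
  ids <- level2_ids(causes)
  totals <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(x)) {
    got <- tapply(x[[value_col]], x$cause_id, sum)
    totals[names(got)] <- got
  }
  grand <- sum(totals)
  if (!is.finite(grand) || grand <= 0) {
    stop("empty scope: selection has zero total ", value_col, call. = FALSE)
  }
  totals / grand
}

# Filter a publications table by years and optional stratum filters.
# filters: named list over the stratum columns, e.g. list(funded = "yes",
# research_type = "basic"); values are kept-if-in sets.
filter_pubs <- function(pubs, years = NULL, countries = NULL, filters = NULL) {
  keep <- rep(TRUE, nrow(pubs))
  if (!is.null(years)) keep <- keep & pubs$year %in% years
  if (!is.null(countries)) keep <- keep & pubs$country %in% countries
  if (!is.null(filters)) {
    for (col in names(filters)) {
      if (!col %in% names(pubs)) {
        stop("unknown stratum filter column: ", col, call. = FALSE)
      }
      keep <- keep & pubs[[col]] %in% filters[[col]]
    }
  }
  pubs[keep, , drop = FALSE]
}

# Per-cause article-link counts for a scope.
research_counts <- function(pubs, years, causes = default_causes(),
                            countries = NULL, filters = NULL) {
  sel <- filter_pubs(pubs, years, countries, filters)
  ids <- level2_ids(causes)
  counts <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(sel)) {
    got <- tapply(sel$n_articles, sel$cause_id, sum)
    counts[names(got)] <- got
  }
  counts
}

#' Research share distribution for a scope
#'
#' @param pubs publications table.
#' @param years years to pool.
#' @param causes cause table.
#' @param countries optional country subset.
#' @param filters optional named list of stratum filters.
#' @return Named share vector over the level-2 causes.
#' @export
research_shares <- function(pubs, years, causes = default_causes(),
                            countries = NULL, filters = NULL) {
  counts <- research_counts(pubs, years, causes, countries, filters)
  total <- sum(counts)
  if (total <= 0) {
    stop("empty scope: no articles selected for years ",
         paste(range(years), collapse = "-"), call. = FALSE)
  }
  counts / total
}

#' Burden share distribution for a scope
#'
#' @param burden burden table.
#' @param years years to pool (summing means within cause).
#' @param causes cause table.
#' @param metric one of \code{"daly"}, \code{"deaths"}, \code{"prevalence"}.
#' @param locations optional location subset.
#' @param value_col which estimate column to use (\code{"mean"} by default).
#' @return Named share vector over the level-2 causes.
#' @export
burden_shares <- function(burden, years, causes = default_causes(),
                          metric = "daly", locations = NULL,
                          value_col = "mean") {
  sel <- burden[burden$year %in% years & burden$metric == metric, ,
                drop = FALSE]
  if (!is.null(locations)) sel <- sel[sel$location %in% locations, ,
                                      drop = FALSE]
  compute_shares(sel, causes, value_col)
}

# Burden mean/lower/upper summed over locations for one year x metric,
# as a 16 x 3 data frame keyed by cause (used by the uncertainty sampler).
burden_rows <- function(burden, year, causes = default_causes(),
                        metric = "daly", locations = NULL) {
  sel <- burden[burden$year == year & burden$metric == metric, , drop = FALSE]
  if (!is.null(locations)) sel <- sel[sel$location %in% locations, ,
                                      drop = FALSE]
  if (!nrow(sel)) {
    stop("no burden rows for year ", year, ", metric ", metric, call. = FALSE)
  }
  ids <- level2_ids(causes)
  out <- data.frame(cause_id = ids,
                    mean = 0, lower = 0, upper = 0,
                    stringsAsFactors = FALSE)
  for (col in c("mean", "lower", "upper")) {
    got <- tapply(sel[[col]], sel$cause_id, sum)
    out[[col]][match(names(got), ids)] <- got
  }
  out
}
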