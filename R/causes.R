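#' Default level-2 cause set
#'
#' The 16 mid-level Global Burden of Disease cause categories used as the
#' analysis support, with their communicable / noncommunicable status.
#' Residual "other" categories are not part of the set. The first six causes
#' belong to the communicable, maternal, neonatal and nutritional group.
#'
#' @return A data frame with columns \code{cause_id}, \code{name},
#'   \code{level}, \code{parent_id} and \code{communicable}.
#' @export
#' @examples
#' causes <- default_causes()
#' nrow(causes)  # 16
default_causes <- function() {
  data.frame(
    cause_id = c(
      "hiv_std", "resp_tb", "enteric", "ntd_malaria",
      "maternal_neonatal", "nutritional",
      "cardiovascular", "neoplasms", "chronic_resp", "digestive",
      "neurological", "mental", "substance", "diabetes_kidney",
      "musculoskeletal", "skin"
    ),
    name = c(
      "HIV/AIDS and sexually transmitted infections",
      "Respiratory infections and tuberculosis",
      "Enteric infections",
      "Neglected tropical diseases and malaria",
      "Maternal and neonatal disorders",
      "Nutritional deficiencies",
      "Cardiovascular diseases",
      "Neoplasms",
      "Chronic respiratory diseases",
      "Digestive diseases",
      "Neurological disorders",
      "Mental disorders",
      "Substance use disorders",
      "Diabetes and kidney diseases",
      "Musculoskeletal disorders",
      "Skin and subcutaneous diseases"
    ),
    level = 2L,
    parent_id = "",
    communicable = rep(c(TRUE, FALSE), c(6L, 10L)),
    stringsAsFactors = FALSE
  )
}

#' The eight United Nations geographical regions
#'
#' @return Character vector of the eight fixed region labels.
#' @export
un_regions <- function() {
  c(
    "Central and Southern Asia",
    "Eastern and South-Eastern Asia",
    "Europe",
    "Latin America and the Caribbean",
    "Northern Africa and Western Asia",
    "Northern America",
    "Oceania",
    "Sub-Saharan Africa"
  )
}

#' Default country-to-region map
#'
#' A compact ISO-3166 alpha-3 country to UN-region map covering the countries
#' emitted by the synthetic-world generator. Real analyses supply their own
#' complete map via \code{read_tables()}.
#'
#' @return A data frame with columns \code{country} and \code{region}.
#' @export
default_regions <- function() {
  data.frame(
    country = c(
      "IND", "PAK",
      "CHN", "JPN", "IDN",
      "DEU", "GBR", "FRA",
      "BRA", "MEX",
      "EGY", "TUR", "SAU",
      "USA", "CAN",
      "AUS", "NZL",
      "NGA", "ZAF", "KEN"
    ),
    region = rep(un_regions(), c(2L, 3L, 3L, 2L, 3L, 2L, 2L, 3L)),
    stringsAsFactors = FALSE
  )
}

level2_ids <- function(causes) causes$cause_id[causes$level == 2L]

#' Validate a cause hierarchy table
#'
#' Checks uniqueness of cause ids, that level-2 causes have empty parents and
#' that every level-3/4 cause's parent chain terminates at a level-2 cause.
#'
#' @param causes data frame with columns cause_id, name, level, parent_id,
#'   communicable.
#' @return The validated data frame, invisibly.
#' @export
validate_causes <- function(causes) {
  need <- c("cause_id", "name", "level", "parent_id", "communicable")
  miss <- setdiff(need, names(causes))
  if (length(miss)) {
    stop("causes table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(causes$cause_id)) {
    dup <- unique(causes$cause_id[duplicated(causes$cause_id)])
    stop("duplicate cause_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(causes$level %in% 2:4)) {
    stop("cause levels must be in {2, 3, 4}", call. = FALSE)
  }
  bad2 <- causes$level == 2L & !(is.na(causes$parent_id) | causes$parent_id == "")
  if (any(bad2)) {
    stop("level-2 causes must have empty parent_id: ",
         paste(causes$cause_id[bad2], collapse = ", "), call. = FALSE)
  }
  for (id in causes$cause_id[causes$level > 2L]) {
    l2_ancestor(id, causes)  # errors on orphans / cycles
  }
  invisible(causes)
}

# Resolve a cause id to its level-2 ancestor; errors if the chain does not
# terminate at level 2.
l2_ancestor <- function(cause_id, causes) {
  idx <- match(cause_id, causes$cause_id)
  if (is.na(idx)) {
    stop("unknown cause_id: ", cause_id, call. = FALSE)
  }
  seen <- character(0)
  while (causes$level[idx] != 2L) {
    if (cause_id %in% seen) {
      stop("cycle in cause hierarchy at: ", cause_id, call. = FALSE)
    }
    seen <- c(seen, cause_id)
    parent <- causes$parent_id[idx]
    if (is.na(parent) || parent == "") {
      stop("cause '", cause_id, "' has no level-2 ancestor", call. = FALSE)
    }
    cause_id <- parent
    idx <- match(cause_id, causes$cause_id)
    if (is.na(idx)) {
      stop("cause '", seen[length(seen)], "' has unknown parent '",
           cause_id, "'", call. = FALSE)
    }
  }
  causes$cause_id[idx]
}

#' Validate a country-to-region map
#' @param regions data frame with columns country, region.
#' @return The validated map, invisibly.
#' @export
validate_regions <- function(regions) {
  miss <- setdiff(c("country", "region"), names(regions))
  if (length(miss)) {
    stop("regions table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(regions$country)) {
    dup <- unique(regions$country[duplicated(regions$country)])
    stop("countries mapped to more than one region: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(regions$region), un_regions())
  if (length(unknown)) {
    stop("unknown region label(s): ", paste(unknown, collapse = ", "),
         "; the eight UN region labels are fixed", call. = FALSE)
  }
  invisible(regions)
}

#' Validate a publication-counts table
#'
#' One row per unique (year, cause, country, stratum) combination with a
#' nonnegative integer count of article-to-cause links.
#'
#' @param pubs data frame with columns year, cause_id, country, n_articles and
#'   the stratum flag columns funded, us_public_funded, industry_author,
#'   research_type, industry_phase3.
#' @param causes cause table used for referential-integrity checks.
#' @param regions optional region map; countries absent from it are rejected.
#' @return The validated table, invisibly.
#' @export
validate_publications <- function(pubs, causes = default_causes(),
                                  regions = NULL) {
  need <- c("year", "cause_id", "country", "n_articles",
            "funded", "us_public_funded", "industry_author",
            "research_type", "industry_phase3")
  miss <- setdiff(need, names(pubs))
  if (length(miss)) {
    stop("publications table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(pubs$n_articles) | pubs$n_articles < 0 |
                 pubs$n_articles != round(pubs$n_articles))
  if (length(bad)) {
    stop("n_articles must be a nonnegative integer; offending row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(pubs$cause_id), causes$cause_id)
  if (length(unknown)) {
    stop("unknown cause_id(s) in publications table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(pubs$funded %in% c("yes", "no", "unknown"))) {
    stop("funded must be one of yes|no|unknown", call. = FALSE)
  }
  if (!all(pubs$research_type %in% c("basic", "applied", "clinical"))) {
    stop("research_type must be one of basic|applied|clinical", call. = FALSE)
  }
  if (!is.null(regions)) {
    unmapped <- setdiff(unique(pubs$country), regions$country)
    if (length(unmapped)) {
      stop("countries not present in region map: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
  }
  invisible(pubs)
}

#' Validate a burden table
#'
#' One row per (year, cause, location, metric) with mean, lower and upper
#' estimates satisfying 0 <= lower <= mean <= upper.
#'
#' @param burden data frame with columns year, cause_id, location, metric,
#'   mean, lower, upper.
#' @param causes cause table used for referential-integrity checks.
#' @return The validated table, invisibly.
#' @export
validate_burden <- function(burden, causes = default_causes()) {
  need <- c("year", "cause_id", "location", "metric", "mean", "lower", "upper")
  miss <- setdiff(need, names(burden))
  if (length(miss)) {
    stop("burden table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(burden$metric %in% c("daly", "deaths", "prevalence"))) {
    stop("metric must be one of daly|deaths|prevalence", call. = FALSE)
  }
  bad <- which(burden$lower > burden$mean | burden$mean > burden$upper |
                 burden$lower < 0)
  if (length(bad)) {
    stop("rows violating 0 <= lower <= mean <= upper: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(burden$cause_id), causes$cause_id)
  if (length(unknown)) {
    stop("unknown cause_id(s) in burden table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(burden$year, burden$cause_id, burden$location, burden$metric)
  if (anyDuplicated(key)) {
    stop("duplicate (year, cause, location, metric) rows: ",
         paste(utils::head(which(duplicated(key)), 10L), collapse = ", "),
         call. = FALSE)
  }
  invisible(burden)
}
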