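#' Read the delimited-text input tables
#'
#' Reads and validates the four tables the pipeline consumes:
#' \code{publications.csv} (year, cause_id, country, n_articles, funded,
#' us_public_funded, industry_author, research_type, industry_phase3),
#' \code{burden.csv} (year, cause_id, location, metric, mean, lower, upper),
#' \code{causes.csv} (cause_id, name, level, parent_id, communicable) and
#' \code{regions.csv} (country, region). All files are UTF-8 CSV with a header
#' row. Rows violating table invariants are rejected with row-numbered
#' diagnostics.
#'
#' @param publications,burden,causes,regions file paths; \code{causes} and
#'   \code{regions} may be \code{NULL} to fall back on the package defaults.
#' @return A named list with elements \code{publications}, \code{burden},
#'   \code{causes}, \code{regions}.
#' @export
read_tables <- function(publications, burden, causes = NULL, regions = NULL) {
  causes_tab <- if (is.null(causes)) default_causes() else {
    x <- utils::read.csv(causes, stringsAsFactors = FALSE)
    x$communicable <- as.logical(x$communicable) | x$communicable == 1
    if (is.null(x$parent_id)) x$parent_id <- ""
    x$parent_id[is.na(x$parent_id)] <- ""
    x
  }
  validate_causes(causes_tab)
  regions_tab <- if (is.null(regions)) default_regions() else {
    utils::read.csv(regions, stringsAsFactors = FALSE)
  }
  validate_regions(regions_tab)
  pubs <- utils::read.csv(publications, stringsAsFactors = FALSE)
  if (!is.null(pubs$funded)) pubs$funded <- as.character(pubs$funded)
  validate_publications(pubs, causes_tab, regions_tab)
  bur <- utils::read.csv(burden, stringsAsFactors = FALSE)
  validate_burden(bur, causes_tab)
  list(publications = pubs, burden = bur,
       causes = causes_tab, regions = regions_tab)
}

#' Write the pipeline tables back to CSV
#'
#' The inverse of \code{\link{read_tables}}; round trips are lossless field by
#' field.
#'
#' @param tables named list as returned by \code{read_tables} or
#'   \code{\link{generate_world}} (the ground-truth element is ignored).
#' @param dir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    publications = file.path(dir, "publications.csv"),
    burden = file.path(dir, "burden.csv"),
    causes = file.path(dir, "causes.csv"),
    regions = file.path(dir, "regions.csv")
  )
  utils::write.csv(tables$publications, paths[["publications"]],
                   row.names = FALSE)
  utils::write.csv(tables$burden, paths[["burden"]], row.names = FALSE)
  utils::write.csv(tables$causes, paths[["causes"]], row.names = FALSE)
  utils::write.csv(tables$regions, paths[["regions"]], row.names = FALSE)
  invisible(paths)
}
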