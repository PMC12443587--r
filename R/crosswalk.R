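#' Term-level crosswalk evaluation
#'
#' Treats every (term, cause) pair of a closed universe as one binary
#' classification instance: a pair is positive in a mapping when the mapping
#' assigns that cause to that term. Accuracy is the fraction of pairs on
#' which the candidate map and the gold standard agree (true negatives
#' count); precision and recall are over positive pairs. The cause universe
#' defaults to the causes present in the gold standard.
#'
#' @param map candidate mapping: data frame with columns term, cause_id (one
#'   row per assigned pair; terms with no causes may appear with NA cause_id
#'   or be listed only in the gold standard's term universe).
#' @param gold gold-standard mapping in the same shape.
#' @param causes optional character vector fixing the cause universe.
#' @return Named list with accuracy, precision, recall, and the pair counts
#'   tp, fp, fn, tn.
#' @export
term_level_metrics <- function(map, gold, causes = NULL) {
  terms_map <- unique(map$term)
  terms_gold <- unique(gold$term)
  if (!setequal(terms_map, terms_gold)) {
    stop("term universes differ; symmetric difference: ",
         paste(c(setdiff(terms_map, terms_gold),
                 setdiff(terms_gold, terms_map)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(causes)) {
    causes <- sort(unique(gold$cause_id[!is.na(gold$cause_id)]))
  }
  pos_map <- pair_keys(map, causes)
  pos_gold <- pair_keys(gold, causes)
  n_pairs <- length(terms_gold) * length(causes)
  tp <- length(intersect(pos_map, pos_gold))
  fp <- length(setdiff(pos_map, pos_gold))
  fn <- length(setdiff(pos_gold, pos_map))
  tn <- n_pairs - tp - fp - fn
  list(
    accuracy = (tp + tn) / n_pairs,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

pair_keys <- function(mapping, causes) {
  ok <- !is.na(mapping$cause_id) & mapping$cause_id %in% causes
  unique(paste(mapping$term[ok], mapping$cause_id[ok], sep = "\r"))
}

#' Article-level crosswalk evaluation
#'
#' An article's predicted (resp. gold) causes are the union of its terms'
#' mapped causes; metrics are computed over article-cause pairs with articles
#' weighted equally. Articles with no terms are excluded, with the exclusion
#' count reported.
#'
#' @inheritParams term_level_metrics
#' @param articles data frame with columns article_id, term (one row per
#'   term occurrence; duplicated terms within an article are harmless).
#' @return As \code{\link{term_level_metrics}}, plus \code{n_articles} and
#'   \code{n_excluded}.
#' @export
article_level_metrics <- function(map, gold, articles, causes = NULL) {
  if (is.null(causes)) {
    causes <- sort(unique(gold$cause_id[!is.na(gold$cause_id)]))
  }
  art_ids <- unique(articles$article_id)
  has_terms <- art_ids[art_ids %in%
                         articles$article_id[!is.na(articles$term)]]
  n_excluded <- length(art_ids) - length(has_terms)
  article_causes <- function(mapping) {
    ok <- !is.na(mapping$cause_id) & mapping$cause_id %in% causes
    m <- merge(articles, mapping[ok, c("term", "cause_id")], by = "term")
    unique(paste(m$article_id, m$cause_id, sep = "\r"))
  }
  pos_map <- article_causes(map)
  pos_gold <- article_causes(gold)
  n_pairs <- length(has_terms) * length(causes)
  tp <- length(intersect(pos_map, pos_gold))
  fp <- length(setdiff(pos_map, pos_gold))
  fn <- length(setdiff(pos_gold, pos_map))
  tn <- n_pairs - tp - fp - fn
  list(
    accuracy = (tp + tn) / n_pairs,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    tp = tp, fp = fp, fn = fn, tn = tn,
    n_articles = length(has_terms), n_excluded = n_excluded
  )
}

#' Per-cause recall on disease-specific journal articles
#'
#' For each cause with labeled journal articles: the fraction of that
#' cause-journal's articles whose mapped causes (union over the article's
#' terms) include the journal's cause. Causes with no labeled articles are
#' reported as NA.
#'
#' @inheritParams article_level_metrics
#' @param journals data frame with columns article_id, journal_cause_id.
#' @return Data frame with columns cause_id, n_articles, recall.
#' @export
journal_recall <- function(map, articles, journals) {
  ok <- !is.na(map$cause_id)
  m <- merge(articles, map[ok, c("term", "cause_id")], by = "term")
  predicted <- unique(m[c("article_id", "cause_id")])
  causes <- sort(unique(journals$journal_cause_id))
  out <- data.frame(cause_id = causes, n_articles = 0L, recall = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(causes)) {
    arts <- journals$article_id[journals$journal_cause_id == causes[i]]
    out$n_articles[i] <- length(arts)
    if (!length(arts)) next
    hit <- vapply(arts, function(a) {
      causes[i] %in% predicted$cause_id[predicted$article_id == a]
    }, logical(1))
    out$recall[i] <- mean(hit)
  }
  out
}
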