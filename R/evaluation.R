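#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly
#' drawn positive outranks a uniformly drawn negative, with ties counting
#' one half.
#'
#' @param labels binary vector (0/1 or logical); both classes must be
#'   present.
#' @param scores numeric prediction scores, higher means more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(labels) == length(scores))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop_domain("AUC undefined: both classes must be present (pos=%d, neg=%d)", np, nn)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' Points of the empirical ROC curve, one per distinct score threshold
#' (tied scores are collapsed into a single step), starting at (0, 0) and
#' ending at (1, 1).  The trapezoidal area over these points equals the
#' rank-based [auc()].
#'
#' @inheritParams auc
#' @return data frame with columns `fpr`, `tpr`, `threshold` (the score
#'   at or above which a prediction counts positive; `Inf` for the
#'   (0, 0) point).
#' @export
roc_points <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop_domain("ROC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np),
             threshold = c(Inf, s[last]))
}

#' Normalized discounted cumulative gain at n
#'
#' `DCG = sum_{i=1..n} rel_i / log2(i + 1)` over the score-ranked list;
#' `IDCG` is the DCG of the same relevances sorted in decreasing order;
#' `NDCG = DCG / IDCG`, defined as 0 when no item is relevant.
#'
#' @param rel relevance vector (binary here) in score-rank order, best
#'   first.
#' @param n cutoff rank (positions beyond `length(rel)` contribute 0).
#' @return NDCG in `[0, 1]`.
#' @export
ndcg_at_n <- function(rel, n) {
  stopifnot(n >= 1, length(rel) >= 1)
  rel <- as.numeric(rel)
  top <- seq_len(min(n, length(rel)))
  disc <- 1 / log2(top + 1)
  dcg <- sum(rel[top] * disc)
  idcg <- sum(sort(rel, decreasing = TRUE)[top] * disc)
  if (idcg == 0) return(0)
  dcg / idcg
}

# Rank labels by decreasing score with stable tie order, then NDCG@n.
ndcg_from_scores <- function(labels, scores, n) {
  ndcg_at_n(labels[order(-scores)], n)
}

#' Evaluate ranking metrics on a scored test set
#'
#' Computes the global AUC over all test triples and NDCG@n either over
#' the global list or (default) averaged over sided entities with at
#' least one positive — each new drug (or disease) has its own candidate
#' list ranked and scored, matching the cold-start framing.
#'
#' @param labels binary labels of the test triples.
#' @param scores model scores for the test triples.
#' @param group optional vector identifying the sided entity of each
#'   triple; `NULL` for a single global ranking.
#' @param n_values NDCG cutoffs.
#' @return An object of class `ranking_metrics`: list with `auc`,
#'   `ndcg` (named vector over cutoffs), `roc` (data frame), and
#'   `n_entities` used for the NDCG average.
#' @export
ranking_metrics <- function(labels, scores, group = NULL, n_values = c(1, 3, 5, 10)) {
  labels <- as.integer(as.logical(labels))
  a <- auc(labels, scores)
  roc <- roc_points(labels, scores)
  if (is.null(group)) {
    nd <- vapply(n_values, function(n) ndcg_from_scores(labels, scores, n), numeric(1))
    ne <- 1L
  } else {
    idx <- split(seq_along(labels), group)
    idx <- Filter(function(ii) sum(labels[ii]) > 0, idx)
    if (length(idx) < length(unique(group)))
      tt_log("NDCG: skipped %d entities with no positive test triples",
             length(unique(group)) - length(idx))
    if (!length(idx)) stop_domain("no entity has a positive test triple")
    per <- vapply(idx, function(ii) {
      vapply(n_values, function(n) ndcg_from_scores(labels[ii], scores[ii], n), numeric(1))
    }, numeric(length(n_values)))
    nd <- if (length(n_values) == 1L) mean(per) else rowMeans(per)
    ne <- length(idx)
  }
  structure(list(auc = a, ndcg = stats::setNames(nd, paste0("ndcg@", n_values)),
                 roc = roc, n_entities = ne),
            class = "ranking_metrics")
}

#' @export
print.ranking_metrics <- function(x, ...) {
  cat(sprintf("<ranking_metrics> AUC=%.4f  %s  (%d ranked lists)\n", x$auc,
              paste(sprintf("%s=%.4f", names(x$ndcg), x$ndcg), collapse = "  "),
              x$n_entities))
  invisible(x)
}

#' Evaluate a trained model on a labeled test set
#'
#' Scores every test triple with the model and computes [ranking_metrics()].
#'
#' @param model a trained model (see [new_model()]).
#' @param test data frame with columns `i`, `j`, `k`, `label`.
#' @param grouping `"entity"` (default): NDCG per sided entity, averaged;
#'   `"global"`: single ranked list.
#' @param side which entity indexes the per-entity grouping, `"drug"`
#'   (column `i`) or `"disease"` (column `k`).
#' @param n_values NDCG cutoffs.
#' @export
evaluate_fold <- function(model, test, grouping = c("entity", "global"),
                          side = c("drug", "disease"), n_values = c(1, 3, 5, 10)) {
  grouping <- match.arg(grouping)
  side <- match.arg(side)
  stopifnot(nrow(test) > 0)
  scores <- predict_triples(model, test)
  group <- if (grouping == "entity") {
    if (side == "drug") test$i else test$k
  }
  ranking_metrics(test$label, scores, group = group, n_values = n_values)
}
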