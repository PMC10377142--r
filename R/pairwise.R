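# Pairwise association prediction from the latent vectors learned during
# triple-association training: drug-disease, drug-gene, disease-gene.

#' Pairwise score matrix from two sets of latent vectors
#'
#' Scores every (a, b) entity pair by the inner product of their latent
#' vectors.
#'
#' @param lat_a,lat_b latent matrices (entities-by-r), e.g. from
#'   [latent_vectors()].
#' @return |A|-by-|B| numeric score matrix.
#' @export
pairwise_scores <- function(lat_a, lat_b) {
  lat_a <- as_batch(lat_a)
  lat_b <- as_batch(lat_b)
  if (ncol(lat_a) != ncol(lat_b))
    stop_domain("latent dimensions disagree (%d vs %d)", ncol(lat_a), ncol(lat_b))
  tcrossprod(lat_a, lat_b)
}

#' Cold-start evaluation of pairwise predictions
#'
#' Reuses the triple-model fold assignment: for each sided entity in the
#' selected test folds, all counterpart entities are ranked by score;
#' known pairs are the positives and every other counterpart is a
#' negative (no subsampling — pairwise matrices are small).  AUC is
#' pooled over the test entities' scores; NDCG@n is averaged per entity.
#'
#' @param scores matrix from [pairwise_scores()]; rows are the sided
#'   entities.
#' @param known 2-column integer matrix of known (row-entity,
#'   col-entity) pairs.
#' @param folds optional [split_folds_by_entity()] result whose sided
#'   entities index the score rows.
#' @param test_folds folds whose entities are evaluated (default: all
#'   folds, i.e. every entity with a known pair is evaluated once as a
#'   cold-start case).
#' @param n_values NDCG cutoffs.
#' @return a [ranking_metrics()] object.
#' @export
evaluate_pairwise <- function(scores, known, folds = NULL, test_folds = NULL,
                              n_values = c(1, 3, 5, 10)) {
  known <- matrix(as.integer(as.matrix(known)), ncol = 2L)
  if (nrow(known) == 0L) stop_domain("no known pairs to evaluate against")
  if (any(known[, 1] < 1L | known[, 1] > nrow(scores) |
          known[, 2] < 1L | known[, 2] > ncol(scores)))
    stop_domain("known pairs reference entities outside the score matrix")

  if (!is.null(folds)) {
    ents <- as.integer(names(folds$entity_fold))
    if (!is.null(test_folds))
      ents <- ents[folds$entity_fold %in% test_folds]
    test_entities <- intersect(ents, unique(known[, 1]))
  } else {
    test_entities <- unique(known[, 1])
  }
  if (!length(test_entities))
    stop_domain("no test entity has a known pair")

  labels <- integer(0); svals <- numeric(0); group <- integer(0)
  for (e in test_entities) {
    y <- integer(ncol(scores))
    y[known[known[, 1] == e, 2]] <- 1L
    labels <- c(labels, y)
    svals <- c(svals, scores[e, ])
    group <- c(group, rep.int(e, ncol(scores)))
  }
  ranking_metrics(labels, svals, group = group, n_values = n_values)
}

#' Pairwise prediction for all three role pairs from a trained model
#'
#' Computes drug-disease, drug-gene and disease-gene score matrices as
#' inner products of the triple model's latent vectors.  With the
#' default `"marginal"` weighting, the learned output weights and the
#' mean latent vector of the absent role are folded into the first
#' role's latents before the inner product — the direct analogue of
#' deriving the pair matrix `A diag(lambda) B'` from a CP decomposition,
#' where `lambda` absorbs the third mode.  `"none"` uses the raw latent
#' vectors.
#'
#' @param model a trained model.
#' @param path which path's latents to use, see [latent_vectors()].
#' @param weighting `"marginal"` (default) or `"none"`.
#' @return named list of score matrices `drug_disease`, `drug_gene`,
#'   `disease_gene`.
#' @export
predict_pairwise <- function(model, path = "both",
                             weighting = c("marginal", "none")) {
  weighting <- match.arg(weighting)
  pair <- function(ra, rb, rc) {
    la <- latent_vectors(model, ra, path)
    lb <- latent_vectors(model, rb, path)
    if (weighting == "marginal")
      la <- sweep(la, 2, marginal_weights(model, rc, path), "*")
    pairwise_scores(la, lb)
  }
  list(drug_disease = pair("dr", "di", "ge"),
       drug_gene = pair("dr", "ge", "di"),
       disease_gene = pair("di", "ge", "dr"))
}

# Output-layer weights times the mean latent of the role absent from a
# pairwise prediction, restricted to the requested path's dimensions.
marginal_weights <- function(model, absent_role, path = "both") {
  h <- model$params$h
  r <- model$rank
  hsel <- switch(model$kind,
    gtd = h,
    mlp = h,
    ensemble = switch(path, gtd = h[seq_len(r)], mlp = h[-seq_len(r)], both = h))
  mean_lat <- colMeans(latent_vectors(model, absent_role, path))
  hsel * mean_lat
}

#' Write a pairwise score matrix as a long TSV
#'
#' @param scores score matrix.
#' @param path output TSV (entity-a, entity-b, score).
#' @param ids_a,ids_b identifier vectors for rows/columns (default:
#'   positions).
#' @export
write_pairwise_scores <- function(scores, path, ids_a = NULL, ids_b = NULL) {
  ids_a <- ids_a %||% seq_len(nrow(scores))
  ids_b <- ids_b %||% seq_len(ncol(scores))
  tab <- data.frame(entity_a = rep(ids_a, times = ncol(scores)),
                    entity_b = rep(ids_b, each = nrow(scores)),
                    score = as.vector(scores))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Top-n candidate counterparts per entity
#'
#' @param scores score matrix (rows = query entities).
#' @param n list length per query entity.
#' @param exclude optional 2-column matrix of (row, col) pairs to drop
#'   from the candidates (e.g. training-time known pairs).
#' @return data frame entity, candidate, score, rank.
#' @export
top_candidates <- function(scores, n = 10L, exclude = NULL) {
  s <- as.matrix(scores)
  if (!is.null(exclude)) {
    exclude <- matrix(as.integer(as.matrix(exclude)), ncol = 2L)
    s[exclude] <- -Inf
  }
  out <- lapply(seq_len(nrow(s)), function(e) {
    o <- order(-s[e, ])[seq_len(min(n, ncol(s)))]
    o <- o[is.finite(s[e, o])]
    if (!length(o)) return(NULL)
    data.frame(entity = e, candidate = o, score = s[e, o], rank = seq_along(o))
  })
  do.call(rbind, out)
}
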