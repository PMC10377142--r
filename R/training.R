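# Experiment protocol: negative sampling at a fixed ratio, entity-wise
# cold-start cross-validation folds, the optimization loop, and
# hyperparameter sweeps.

#' Training configuration
#'
#' @param neg_ratio negatives sampled per positive (alpha, default 10).
#' @param n_folds number of entity-wise folds (default 10).
#' @param side cold-start side: `"drug"` or `"disease"`.
#' @param rank latent dimension r.
#' @param lr learning rate for the adaptive-moment optimizer.
#' @param max_epochs epoch cap.
#' @param patience epochs without validation AUC improvement before
#'   early stopping.
#' @param min_epochs burn-in epochs before early stopping can trigger
#'   (the validation AUC of cold-start entities transiently dips while
#'   the fusion weights are still learning the similarity mapping, so
#'   stopping is suspended until the burn-in has passed).
#' @param seed master seed: negatives, folds and weight initialization
#'   all derive from it.
#' @export
training_config <- function(neg_ratio = 10L, n_folds = 10L,
                            side = c("drug", "disease"), rank = 8L,
                            lr = 1e-2, max_epochs = 200L, patience = 10L,
                            min_epochs = 100L, seed = 1L) {
  side <- match.arg(side)
  stopifnot(neg_ratio >= 1L, n_folds >= 2L, patience >= 1L, rank >= 1L,
            max_epochs >= 1L, lr > 0, min_epochs >= 0L)
  structure(list(neg_ratio = as.integer(neg_ratio), n_folds = as.integer(n_folds),
                 side = side, rank = as.integer(rank), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs), seed = as.integer(seed)),
            class = "training_config")
}

#' Sample negative triples for a sparse tensor
#'
#' Draws `alpha` unlinked cells per positive, uniformly without
#' replacement from the tensor cells that are not positives, and returns
#' the labeled union of positives (label 1) and sampled negatives
#' (label 0).
#'
#' @param tensor a [triple_tensor()].
#' @param alpha negatives per positive.
#' @param seed RNG seed; sampling is reproducible given the seed.
#' @return data frame with columns `i`, `j`, `k`, `label`.
#' @export
sample_negatives <- function(tensor, alpha = 10L, seed = 1L) {
  npos <- nrow(tensor$positives)
  stopifnot(npos > 0L)
  cells <- prod(as.numeric(tensor$shape))
  nneg <- alpha * npos
  if (cells - npos < nneg)
    stop_domain("tensor has %g free cells; cannot sample %d negatives",
                cells - npos, nneg)
  pos_ids <- cell_id(tensor$positives, tensor$shape)
  neg_ids <- with_seed(seed, {
    got <- numeric(0)
    while (length(got) < nneg) {
      draw <- floor(stats::runif(2L * (nneg - length(got))) * cells)
      draw <- draw[!(draw %in% pos_ids)]
      got <- unique(c(got, draw))
    }
    got[seq_len(nneg)]
  })
  neg <- cell_coords(neg_ids, tensor$shape)
  out <- data.frame(rbind(tensor$positives, neg))
  out$label <- rep(c(1L, 0L), c(npos, nneg))
  out
}

#' Entity-wise cold-start fold assignment
#'
#' Partitions the sided entities (drugs or diseases) into folds so that
#' known positives are spread evenly: entities are sorted by decreasing
#' positive count and each is assigned to the currently lightest fold.
#' All triples — positive and negative — follow their sided entity, so a
#' test fold's entities contribute no training triples (cold start).
#'
#' @param data labeled triple set from [sample_negatives()].
#' @param side `"drug"` (entities are column `i`) or `"disease"`
#'   (column `k`).
#' @param n_folds number of folds.
#' @param seed seed used to break ties among equally loaded entities.
#' @return object of class `fold_assignment`: `entity_fold` (named
#'   integer vector), `side`, `n_folds`, and the labeled `data` with a
#'   `fold` column appended.
#' @export
split_folds_by_entity <- function(data, side = c("drug", "disease"),
                                  n_folds = 10L, seed = 1L) {
  side <- match.arg(side)
  ecol <- if (side == "drug") "i" else "k"
  ents <- sort(unique(data[[ecol]]))
  pos_count <- vapply(split(data$label, data[[ecol]])[as.character(ents)],
                      sum, numeric(1))
  if (sum(pos_count > 0) < n_folds)
    stop_domain("need at least %d sided entities with a positive; have %d",
                n_folds, sum(pos_count > 0))
  ord <- with_seed(seed, order(-pos_count, stats::runif(length(ents))))
  fold_of <- integer(length(ents))
  load <- numeric(n_folds)
  for (pos in ord) {
    f <- which.min(load)
    fold_of[pos] <- f
    load[f] <- load[f] + pos_count[pos]
  }
  entity_fold <- stats::setNames(fold_of, ents)
  data$fold <- unname(entity_fold[as.character(data[[ecol]])])
  structure(list(entity_fold = entity_fold, side = side,
                 n_folds = as.integer(n_folds), data = data),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> side=%s n_folds=%d entities=%d\n",
              x$side, x$n_folds, length(x$entity_fold)))
  invisible(x)
}

#' Train/validation/test triple split for one fold
#'
#' Fold `t` is the test fold; fold `t + 1` (wrapping around) is held out
#' for validation-based early stopping; the remaining folds train.
#'
#' @param folds a [split_folds_by_entity()] result.
#' @param test_fold test fold number.
#' @return list of data frames `train`, `validation`, `test`.
#' @export
fold_split <- function(folds, test_fold) {
  stopifnot(test_fold >= 1L, test_fold <= folds$n_folds)
  val_fold <- test_fold %% folds$n_folds + 1L
  d <- folds$data
  list(train = d[!(d$fold %in% c(test_fold, val_fold)), , drop = FALSE],
       validation = d[d$fold == val_fold, , drop = FALSE],
       test = d[d$fold == test_fold, , drop = FALSE])
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) array(0, dim(x) %||% length(x))),
       v = lapply(params, function(x) array(0, dim(x) %||% length(x))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

#' Train a model on one cold-start fold split
#'
#' Full-batch binary cross-entropy minimization with an adaptive-moment
#' optimizer.  After every epoch the validation AUC is computed; training
#' stops when it has not improved for `patience` epochs, and the weights
#' of the best validation epoch are restored.
#'
#' @param model an untrained [new_model()].
#' @param split a [fold_split()] (train / validation / test data frames).
#' @param cfg a [training_config()].
#' @param verbose print per-epoch progress.
#' @return the trained model, with a `trace` field: data frame of epoch,
#'   training loss and validation AUC.
#' @export
train_fold <- function(model, split, cfg, verbose = FALSE) {
  train <- split$train
  val <- split$validation
  stopifnot(nrow(train) > 0, nrow(val) > 0)
  y <- train$label
  state <- adam_init(model$params)
  best <- list(auc = -Inf, params = model$params, epoch = 0L)
  trace <- data.frame(epoch = integer(), loss = numeric(), val_auc = numeric())

  for (epoch in seq_len(cfg$max_epochs)) {
    fwd <- forward_cache(model, train)
    loss <- bce_loss(fwd$p, y)
    if (!is.finite(loss))
      stop_domain("non-finite training loss at epoch %d; try a lower learning rate",
                  epoch)
    dout <- (fwd$p - y) / length(y)
    grads <- backward_cache(model, fwd, dout)
    upd <- adam_step(model$params, grads, state, cfg$lr)
    model$params <- upd$params
    state <- upd$state

    val_auc <- auc(val$label, predict_triples(model, val))
    trace <- rbind(trace, data.frame(epoch = epoch, loss = loss, val_auc = val_auc))
    if (verbose)
      tt_log("epoch %3d  loss %.5f  val AUC %.4f", epoch, loss, val_auc)
    if (val_auc > best$auc + 1e-9) {
      best <- list(auc = val_auc, params = model$params, epoch = epoch)
    } else if (epoch > (cfg$min_epochs %||% 0L) &&
               epoch - max(best$epoch, cfg$min_epochs %||% 0L) >= cfg$patience) {
      break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$trace <- trace
  model$best_epoch <- best$epoch
  model
}

#' Cross-validated training over all (or selected) folds
#'
#' Trains one model per test fold and evaluates it on the held-out
#' cold-start entities.  Metrics are reported per fold and pooled
#' (scores of all test folds concatenated into one ranking).
#'
#' @param kind model kind: `"gtd"`, `"mlp"` or `"ensemble"`.
#' @param folds a [split_folds_by_entity()] result.
#' @param cfg a [training_config()].
#' @param sims list of similarity matrices (`dr`, `ge`, `di`).
#' @param dims tensor dims `c(I, J, K)`.
#' @param test_folds folds to run (default: all).
#' @param n_values NDCG cutoffs.
#' @param ... passed to [new_model()].
#' @return list with `per_fold` (list of `ranking_metrics`), `pooled`
#'   (`ranking_metrics` over concatenated scores), `models`, `mean_auc`.
#' @export
train_model <- function(kind, folds, cfg, sims, dims,
                        test_folds = seq_len(folds$n_folds),
                        n_values = c(1, 3, 5, 10), ...) {
  per_fold <- list()
  models <- list()
  pooled <- data.frame()
  for (tf in test_folds) {
    sp <- fold_split(folds, tf)
    model <- new_model(kind, dims = dims, rank = cfg$rank, sims = sims,
                       init_seed = cfg$seed + tf, ...)
    model <- train_fold(model, sp, cfg)
    m <- evaluate_fold(model, sp$test, side = folds$side, n_values = n_values)
    per_fold[[as.character(tf)]] <- m
    models[[as.character(tf)]] <- model
    sc <- predict_triples(model, sp$test)
    pooled <- rbind(pooled, data.frame(
      label = sp$test$label, score = sc,
      entity = if (folds$side == "drug") sp$test$i else sp$test$k))
  }
  pooled_metrics <- ranking_metrics(pooled$label, pooled$score,
                                    group = pooled$entity, n_values = n_values)
  list(per_fold = per_fold, pooled = pooled_metrics, models = models,
       mean_auc = mean(vapply(per_fold, function(m) m$auc, numeric(1))))
}

#' Hyperparameter sweep over rank and negative ratio
#'
#' Re-runs the full protocol (negative sampling, folds, training,
#' evaluation) for every combination of model kind, rank and negative
#' ratio, under a fixed per-cell seed, and tabulates mean test AUC.
#'
#' @param tensor a [triple_tensor()].
#' @param kinds model kinds to sweep.
#' @param ranks ranks to sweep.
#' @param alphas negative ratios to sweep.
#' @param cfg base [training_config()] (rank and neg_ratio overridden per
#'   cell).
#' @param sims similarity matrices.
#' @param test_folds folds run per cell (fewer folds = faster sweep).
#' @return data frame: kind, rank, alpha, mean test AUC, mean NDCG@10.
#' @export
sweep_hyperparameters <- function(tensor, kinds, ranks, alphas, cfg, sims,
                                  test_folds = 1L) {
  stopifnot(length(kinds) > 0, length(ranks) > 0, length(alphas) > 0)
  grid <- expand.grid(kind = kinds, rank = ranks, alpha = alphas,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    kind <- grid$kind[g]; rank <- grid$rank[g]; alpha <- grid$alpha[g]
    cfg_g <- cfg
    cfg_g$rank <- as.integer(rank)
    cfg_g$neg_ratio <- as.integer(alpha)
    labeled <- sample_negatives(tensor, alpha = alpha, seed = cfg$seed)
    folds <- split_folds_by_entity(labeled, side = cfg$side,
                                   n_folds = cfg$n_folds, seed = cfg$seed)
    fit <- train_model(kind, folds, cfg_g, sims, tensor$shape,
                       test_folds = test_folds)
    data.frame(kind = kind, rank = rank, alpha = alpha,
               auc = fit$mean_auc,
               ndcg10 = mean(vapply(fit$per_fold,
                                    function(m) m$ndcg[["ndcg@10"]], numeric(1))))
  })
  do.call(rbind, res)
}
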