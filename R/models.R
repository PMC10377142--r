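# Scoring models: generalized tensor decomposition (GTD), per-role MLP
# towers, and their ensemble.  The standalone operations below are pure
# functions over explicit weights; new_model()/predict_triples() wrap them
# into a trainable model with learned ID embeddings and similarity fusion.

as_batch <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

#' Generalized tensor decomposition score
#'
#' CP decomposition scores a tensor cell as the sum over latent
#' dimensions of the product of the drug, gene and disease factors.  GTD
#' generalizes this with a learned output weight vector `h` and an
#' activation: `score = act(h' (a * b * c))` with `*` the element-wise
#' product.  With `activation = "identity"` and `h = 1` this is exactly
#' the CP model.
#'
#' @param a,b,c latent vectors of equal length r, or B-by-r matrices for
#'   a batch of triples.
#' @param h output weight vector of length r.
#' @param activation output activation: `"sigmoid"` (default),
#'   `"identity"`, `"relu"`, or a function.
#' @return numeric vector of scores (length B).
#' @export
gtd_score <- function(a, b, c, h, activation = "sigmoid") {
  a <- as_batch(a); b <- as_batch(b); c <- as_batch(c)
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(c)))
    stop_domain("latent vectors must have equal dimensions")
  if (length(h) != ncol(a))
    stop_domain("output weights h (length %d) must match rank %d", length(h), ncol(a))
  act <- resolve_activation(activation)
  drop(act((a * b * c) %*% h))
}

#' Construct an MLP tower
#'
#' A per-role stack of fully connected layers following a tower pattern:
#' layer widths non-increasing after the first (bottom) layer, which is
#' the widest.
#'
#' @param input_width width of the input latent vector (the rank r).
#' @param widths integer vector of layer output widths.
#' @param activations activation per layer (recycled), by name or
#'   function.
#' @param init_seed RNG seed for Glorot-uniform weight initialization.
#' @return object of class `mlp_tower`: list of layers, each with `W`
#'   (in-by-out), `b` and `activation`.
#' @export
mlp_tower <- function(input_width, widths, activations = "relu", init_seed = 1L) {
  stopifnot(length(widths) >= 1L, all(widths >= 1L))
  activations <- rep(as.list(activations), length.out = length(widths))
  fan_in <- c(input_width, widths[-length(widths)])
  layers <- with_seed(init_seed, {
    lapply(seq_along(widths), function(l) {
      list(W = glorot(fan_in[l], widths[l]),
           b = numeric(widths[l]),
           activation = activations[[l]])
    })
  })
  structure(layers, class = "mlp_tower", input_width = input_width)
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Forward pass through an MLP tower
#'
#' Applies `z_l = act_l(W_l' z_{l-1} + b_l)` from the input latent up to
#' the top layer.
#'
#' @param tower an [mlp_tower()].
#' @param z0 input latent vector (length = tower input width) or B-by-r
#'   batch matrix.
#' @return the top-layer output (vector, or B-by-width matrix for batch
#'   input).
#' @export
mlp_forward <- function(tower, z0) {
  vec_in <- !is.matrix(z0)
  z <- as_batch(z0)
  if (ncol(z) != attr(tower, "input_width"))
    stop_domain("tower input width %d, got %d", attr(tower, "input_width"), ncol(z))
  for (layer in tower) {
    act <- resolve_activation(layer$activation)
    z <- act(addbias(z %*% layer$W, layer$b))
  }
  if (vec_in) drop(z) else z
}

addbias <- function(m, b) m + rep(b, each = nrow(m))

#' MLP path score
#'
#' Each role's latent vector is transformed by its own tower; the
#' element-wise product of the three tower outputs is projected through
#' the output weights and activation, as in [gtd_score()].
#'
#' @param towers list of three [mlp_tower()]s (drug, gene, disease).
#' @param a,b,c input latent vectors (or batch matrices).
#' @param h output weights, length = top tower width.
#' @inheritParams gtd_score
#' @export
mlp_score <- function(towers, a, b, c, h, activation = "sigmoid") {
  stopifnot(length(towers) == 3L)
  gtd_score(mlp_forward(towers[[1]], a), mlp_forward(towers[[2]], b),
            mlp_forward(towers[[3]], c), h, activation)
}

#' Ensemble score
#'
#' Concatenates the GTD path's interaction vector `a_G * b_G * c_G` with
#' the MLP path's interaction vector (element-wise product of tower
#' outputs) and projects the concatenation through a single shared output
#' layer `h` of length r + top tower width.
#'
#' @param gtd list with latents `a`, `b`, `c` for the GTD path.
#' @param mlp list with `towers` (three [mlp_tower()]s) and latents `a`,
#'   `b`, `c` for the MLP path.
#' @param h fused output weights.
#' @inheritParams gtd_score
#' @export
ensemble_score <- function(gtd, mlp, h, activation = "sigmoid") {
  vg <- as_batch(gtd$a) * as_batch(gtd$b) * as_batch(gtd$c)
  vm <- as_batch(mlp_forward(mlp$towers[[1]], mlp$a)) *
        as_batch(mlp_forward(mlp$towers[[2]], mlp$b)) *
        as_batch(mlp_forward(mlp$towers[[3]], mlp$c))
  if (nrow(vg) != nrow(vm)) stop_domain("path batch sizes disagree")
  v <- cbind(vg, vm)
  if (length(h) != ncol(v))
    stop_domain("fused output weights must have length %d (r + top tower width)", ncol(v))
  act <- resolve_activation(activation)
  drop(act(v %*% h))
}

#' Per-role feature bundle
#'
#' Holds one role's learnable ID-embedding table, its fixed similarity
#' matrix (side information), and the affine fusion map that converts
#' the concatenated (embedding, similarity-row) feature to the shared
#' latent size r.
#'
#' @param emb n-by-d embedding matrix (one row per entity).
#' @param sim n-by-n similarity matrix for the role.
#' @param W fusion weights, (d + n)-by-r.
#' @param b fusion bias, length r.
#' @param activation fusion activation (default `"relu"`).
#' @export
feature_bundle <- function(emb, sim, W, b, activation = "relu") {
  sim <- unclass(sim)
  stopifnot(nrow(emb) == nrow(sim), nrow(W) == ncol(emb) + ncol(sim),
            length(b) == ncol(W))
  structure(list(emb = emb, sim = sim, W = W, b = b, activation = activation),
            class = "feature_bundle")
}

#' Fuse ID embedding and similarity features into a latent vector
#'
#' Concatenates an entity's ID embedding with its similarity row and
#' applies the bundle's affine map: `act(W' [emb; sim] + b)`.  Novel
#' (cold-start) entities with zero similarity rows are valid inputs.
#'
#' @param bundle a [feature_bundle()].
#' @param entities integer entity positions (vectorized).
#' @return length(entities)-by-r latent matrix (a vector for a single
#'   entity).
#' @export
fuse_features <- function(bundle, entities) {
  n <- nrow(bundle$emb)
  if (any(entities < 1L | entities > n))
    stop_domain("entity index out of range 1..%d", n)
  x <- cbind(bundle$emb[entities, , drop = FALSE],
             bundle$sim[entities, , drop = FALSE])
  act <- resolve_activation(bundle$activation)
  out <- act(addbias(x %*% bundle$W, bundle$b))
  if (length(entities) == 1L) drop(out) else out
}

# ---------------------------------------------------------------------------
# Trainable model container

default_tower_widths <- function(rank) c(2L * rank, rank, max(1L, rank %/% 2L))

#' Construct a trainable triple-association model
#'
#' Builds the parameter set for one of the three scoring models over a
#' drug-gene-disease tensor: `"gtd"`, `"mlp"`, or their `"ensemble"`
#' (which keeps separate embedding/fusion parameters per path and a
#' single fused output layer).  Weights use seeded Glorot-uniform
#' initialization; ID embeddings are uniform in (-0.05, 0.05).
#'
#' @param kind `"gtd"`, `"mlp"` or `"ensemble"`.
#' @param dims integer `c(I, J, K)`: entity counts per role.
#' @param rank latent dimension r shared by all roles.
#' @param sims list of three similarity matrices (`dr`, `ge`, `di`) used
#'   as fixed side information; `NULL` entries become zero matrices
#'   (no side information).
#' @param d_id ID-embedding dimension (default = rank).
#' @param tower_widths MLP tower layer widths (default
#'   `c(2r, r, floor(r/2))`, the widest layer at the bottom).
#' @param fusion_activation,tower_activation activations for the fusion
#'   map and tower hidden layers.  The default is `"leaky_relu"`
#'   (slope 0.01): with plain ReLU and small ranks, whole latent
#'   columns can die at initialization and the optimizer is left at an
#'   exact zero-gradient saddle.
#' @param init_seed seed for weight initialization.
#' @return object of class `tritensor_model`.
#' @export
new_model <- function(kind = c("gtd", "mlp", "ensemble"), dims, rank,
                      sims = NULL, d_id = rank,
                      tower_widths = default_tower_widths(rank),
                      fusion_activation = "leaky_relu",
                      tower_activation = "leaky_relu",
                      init_seed = 1L) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, rank >= 1L)
  roles <- c("dr", "ge", "di")
  sims <- lapply(stats::setNames(seq_along(roles), roles), function(s) {
    m <- sims[[s]] %||% matrix(0, dims[s], dims[s])
    m <- unclass(m)
    stopifnot(nrow(m) == dims[s], ncol(m) == dims[s])
    unname(m)
  })

  paths <- switch(kind, gtd = "G", mlp = "M", ensemble = c("G", "M"))
  params <- list()
  with_seed(init_seed, {
    for (p in paths) {
      for (s in seq_along(roles)) {
        rl <- roles[s]
        params[[pn("emb", p, rl)]] <- matrix(
          stats::runif(dims[s] * d_id, -0.05, 0.05), dims[s], d_id)
        params[[pn("fuseW", p, rl)]] <- glorot(d_id + dims[s], rank)
        # small positive bias keeps rectified units initially active
        params[[pn("fuseb", p, rl)]] <- rep(
          if (fusion_activation %in% c("relu", "leaky_relu")) 0.1 else 0, rank)
      }
    }
    if ("M" %in% paths) {
      fan_in <- c(rank, tower_widths[-length(tower_widths)])
      for (rl in roles) {
        for (l in seq_along(tower_widths)) {
          params[[pn("towerW", "M", rl, l)]] <- glorot(fan_in[l], tower_widths[l])
          params[[pn("towerb", "M", rl, l)]] <- rep(
            if (tower_activation %in% c("relu", "leaky_relu")) 0.1 else 0,
            tower_widths[l])
        }
      }
    }
    top <- tower_widths[length(tower_widths)]
    h_len <- switch(kind, gtd = rank, mlp = top, ensemble = rank + top)
    params[["h"]] <- drop(glorot(h_len, 1L))
  })

  structure(
    list(kind = kind, dims = dims, rank = rank, d_id = d_id,
         tower_widths = as.integer(tower_widths), sims = sims,
         fusion_activation = fusion_activation,
         tower_activation = tower_activation,
         init_seed = init_seed, params = params, trained = FALSE),
    class = "tritensor_model"
  )
}

pn <- function(...) paste(..., sep = ".")

#' @export
print.tritensor_model <- function(x, ...) {
  cat(sprintf("<tritensor_model> kind=%s dims=%s rank=%d %s\n", x$kind,
              paste(x$dims, collapse = "x"), x$rank,
              if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

#' Extract a role's feature bundle from a model
#'
#' @param model a [new_model()].
#' @param role `"dr"`, `"ge"` or `"di"`.
#' @param path `"G"` (GTD) or `"M"` (MLP); ignored for single-path
#'   models.
#' @export
model_bundle <- function(model, role = c("dr", "ge", "di"), path = NULL) {
  role <- match.arg(role)
  path <- path %||% switch(model$kind, gtd = "G", mlp = "M", ensemble = "G")
  pr <- model$params
  feature_bundle(pr[[pn("emb", path, role)]], model$sims[[role]],
                 pr[[pn("fuseW", path, role)]], pr[[pn("fuseb", path, role)]],
                 model$fusion_activation)
}

#' Extract a role's MLP tower from a model
#'
#' @inheritParams model_bundle
#' @export
model_tower <- function(model, role = c("dr", "ge", "di")) {
  role <- match.arg(role)
  stopifnot(model$kind %in% c("mlp", "ensemble"))
  L <- length(model$tower_widths)
  layers <- lapply(seq_len(L), function(l) {
    list(W = model$params[[pn("towerW", "M", role, l)]],
         b = model$params[[pn("towerb", "M", role, l)]],
         activation = model$tower_activation)
  })
  structure(layers, class = "mlp_tower", input_width = model$rank)
}

#' Score drug-gene-disease triples with a model
#'
#' Runs the model's full forward pass — feature fusion per role, then the
#' GTD head, the MLP towers, or the ensemble of both — on a batch of
#' tensor coordinates.
#'
#' @param model a [new_model()].
#' @param triples data frame or matrix with columns `i` (drug), `j`
#'   (gene), `k` (disease).
#' @return numeric vector of scores in (0, 1).
#' @export
predict_triples <- function(model, triples) {
  fwd <- forward_cache(model, triples)
  fwd$p
}

# Full forward pass keeping intermediates for backpropagation.
forward_cache <- function(model, triples) {
  triples <- as.data.frame(triples)
  nm <- names(triples)
  cols <- if (all(c("i", "j", "k") %in% nm)) c("i", "j", "k") else 1:3
  ii <- as.integer(triples[[cols[1]]])
  jj <- as.integer(triples[[cols[2]]])
  kk <- as.integer(triples[[cols[3]]])
  ents <- list(dr = ii, ge = jj, di = kk)
  pr <- model$params
  fuse_act <- resolve_activation(model$fusion_activation)
  tow_act <- resolve_activation(model$tower_activation)
  paths <- switch(model$kind, gtd = "G", mlp = "M", ensemble = c("G", "M"))

  cache <- list(ents = ents, fusion = list(), tower = list())
  A <- list()
  for (p in paths) {
    for (rl in names(ents)) {
      e <- ents[[rl]]
      x <- cbind(pr[[pn("emb", p, rl)]][e, , drop = FALSE],
                 model$sims[[rl]][e, , drop = FALSE])
      pre <- addbias(x %*% pr[[pn("fuseW", p, rl)]], pr[[pn("fuseb", p, rl)]])
      a <- fuse_act(pre)
      cache$fusion[[pn(p, rl)]] <- list(x = x, pre = pre, a = a)
      A[[pn(p, rl)]] <- a
    }
  }
  if ("M" %in% paths) {
    L <- length(model$tower_widths)
    for (rl in names(ents)) {
      z <- A[[pn("M", rl)]]
      zs <- vector("list", L + 1L); zs[[1]] <- z
      pres <- vector("list", L)
      for (l in seq_len(L)) {
        pres[[l]] <- addbias(zs[[l]] %*% pr[[pn("towerW", "M", rl, l)]],
                             pr[[pn("towerb", "M", rl, l)]])
        zs[[l + 1L]] <- tow_act(pres[[l]])
      }
      cache$tower[[rl]] <- list(zs = zs, pres = pres)
    }
  }

  v <- NULL
  if ("G" %in% paths)
    v <- A[[pn("G", "dr")]] * A[[pn("G", "ge")]] * A[[pn("G", "di")]]
  if ("M" %in% paths) {
    L1 <- length(model$tower_widths) + 1L
    vm <- cache$tower$dr$zs[[L1]] * cache$tower$ge$zs[[L1]] * cache$tower$di$zs[[L1]]
    v <- if (is.null(v)) vm else cbind(v, vm)
  }
  out_pre <- drop(v %*% pr$h)
  cache$v <- v
  cache$p <- sigmoid(out_pre)
  cache
}

act_grad <- function(name, pre, post) {
  switch(name,
    relu = (pre > 0) + 0,
    leaky_relu = ifelse(pre > 0, 1, 0.01),
    identity = array(1, dim(pre)),
    sigmoid = post * (1 - post),
    stop_domain("no analytic gradient for activation '%s'", name))
}

# Backpropagation: returns gradients for every parameter given
# dL/d(out_pre) for the batch.  Structure mirrors forward_cache().
backward_cache <- function(model, cache, dout) {
  pr <- model$params
  g <- lapply(pr, function(x) array(0, dim(x) %||% length(x)))
  paths <- switch(model$kind, gtd = "G", mlp = "M", ensemble = c("G", "M"))
  ents <- cache$ents

  g$h <- drop(crossprod(cache$v, dout))
  dv <- outer(dout, pr$h)

  dA <- list()
  col0 <- 0L
  if ("G" %in% paths) {
    dvg <- dv[, seq_len(model$rank), drop = FALSE]
    col0 <- model$rank
    a <- lapply(c("dr", "ge", "di"), function(rl) cache$fusion[[pn("G", rl)]]$a)
    dA[[pn("G", "dr")]] <- dvg * a[[2]] * a[[3]]
    dA[[pn("G", "ge")]] <- dvg * a[[1]] * a[[3]]
    dA[[pn("G", "di")]] <- dvg * a[[1]] * a[[2]]
  }
  if ("M" %in% paths) {
    L <- length(model$tower_widths)
    top <- model$tower_widths[L]
    dvm <- dv[, col0 + seq_len(top), drop = FALSE]
    zt <- lapply(c("dr", "ge", "di"), function(rl) cache$tower[[rl]]$zs[[L + 1L]])
    dZ <- list(dr = dvm * zt[[2]] * zt[[3]],
               ge = dvm * zt[[1]] * zt[[3]],
               di = dvm * zt[[1]] * zt[[2]])
    for (rl in c("dr", "ge", "di")) {
      d <- dZ[[rl]]
      tc <- cache$tower[[rl]]
      for (l in rev(seq_len(L))) {
        dpre <- d * act_grad(model$tower_activation, tc$pres[[l]], tc$zs[[l + 1L]])
        g[[pn("towerW", "M", rl, l)]] <- crossprod(tc$zs[[l]], dpre)
        g[[pn("towerb", "M", rl, l)]] <- colSums(dpre)
        d <- dpre %*% t(pr[[pn("towerW", "M", rl, l)]])
      }
      dA[[pn("M", rl)]] <- d
    }
  }

  for (p in paths) {
    for (rl in c("dr", "ge", "di")) {
      fc <- cache$fusion[[pn(p, rl)]]
      dpre <- dA[[pn(p, rl)]] * act_grad(model$fusion_activation, fc$pre, fc$a)
      g[[pn("fuseW", p, rl)]] <- crossprod(fc$x, dpre)
      g[[pn("fuseb", p, rl)]] <- colSums(dpre)
      dx <- dpre %*% t(pr[[pn("fuseW", p, rl)]])
      dE <- dx[, seq_len(model$d_id), drop = FALSE]
      rs <- rowsum(dE, ents[[rl]])
      rows <- as.integer(rownames(rs))
      gm <- g[[pn("emb", p, rl)]]
      gm[rows, ] <- gm[rows, , drop = FALSE] + rs
      g[[pn("emb", p, rl)]] <- gm
    }
  }
  g
}

#' Entity latent vectors from a trained model
#'
#' The latent representation used for pairwise association prediction:
#' the fusion-layer output for the GTD path, the top tower output for the
#' MLP path, or (default for the ensemble) the concatenation of both.
#'
#' @param model a [new_model()].
#' @param role `"dr"`, `"ge"` or `"di"`.
#' @param path `"gtd"`, `"mlp"`, or `"both"` (concatenate; default).
#' @param entities integer positions (default: all entities of the role).
#' @return entities-by-dim latent matrix.
#' @export
latent_vectors <- function(model, role = c("dr", "ge", "di"),
                           path = c("both", "gtd", "mlp"), entities = NULL) {
  role <- match.arg(role)
  path <- match.arg(path)
  s <- match(role, c("dr", "ge", "di"))
  entities <- entities %||% seq_len(model$dims[s])
  want_g <- path %in% c("both", "gtd")
  want_m <- path %in% c("both", "mlp")
  out <- NULL
  if (want_g && model$kind %in% c("gtd", "ensemble")) {
    out <- as_batch(fuse_features(model_bundle(model, role, "G"), entities))
  }
  if (want_m && model$kind %in% c("mlp", "ensemble")) {
    a <- as_batch(fuse_features(model_bundle(model, role, "M"), entities))
    zm <- as_batch(mlp_forward(model_tower(model, role), a))
    out <- if (is.null(out)) zm else cbind(out, zm)
  }
  if (is.null(out))
    stop_domain("model kind '%s' has no '%s' path", model$kind, path)
  out
}
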