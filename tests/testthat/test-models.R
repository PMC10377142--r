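test_that("GTD head degenerate cases behave as the algebra dictates", {
  h <- c(0.3, -0.2, 0.5)
  expect_equal(gtd_score(numeric(3), runif(3), runif(3), h), 0.5)
  expect_equal(gtd_score(runif(3), runif(3), runif(3), numeric(3)), 0.5)
  expect_error(gtd_score(runif(3), runif(2), runif(3), h), "equal dimensions")
  expect_error(gtd_score(runif(3), runif(3), runif(3), runif(2)), "match rank")
})

test_that("identity GTD with unit weights is exactly the CP model", {
  for (r in c(2, 5, 8)) {
    set.seed(r)
    A <- matrix(rnorm(6 * r), 6, r)
    B <- matrix(rnorm(7 * r), 7, r)
    C <- matrix(rnorm(4 * r), 4, r)
    tri <- random_triples(c(6, 7, 4), 25, seed = r + 1)
    got <- gtd_score(A[tri$i, , drop = FALSE], B[tri$j, , drop = FALSE],
                     C[tri$k, , drop = FALSE], rep(1, r), activation = "identity")
    want <- mapply(function(i, j, k) oracle_cp_cell(A, B, C, i, j, k),
                   tri$i, tri$j, tri$k)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("GTD score is invariant under simultaneous latent permutation", {
  set.seed(42)
  r <- 6
  a <- rnorm(r); b <- rnorm(r); c <- rnorm(r); h <- rnorm(r)
  p <- sample(r)
  expect_equal(gtd_score(a, b, c, h), gtd_score(a[p], b[p], c[p], h[p]))
})

test_that("MLP towers forward as the layer recursion dictates", {
  id_tower <- structure(list(list(W = diag(4), b = numeric(4),
                                  activation = "identity")),
                        class = "mlp_tower", input_width = 4L)
  z <- rnorm(4)
  expect_equal(mlp_forward(id_tower, z), z)

  # all-negative pre-activations die under ReLU
  neg_tower <- structure(list(list(W = -diag(3), b = numeric(3),
                                   activation = "relu")),
                         class = "mlp_tower", input_width = 3L)
  expect_equal(mlp_forward(neg_tower, c(1, 2, 3)), numeric(3))

  expect_error(mlp_forward(id_tower, rnorm(3)), "width")
})

test_that("tower forward matches a naive per-layer loop on random stacks", {
  set.seed(7)
  tower <- mlp_tower(5, c(8, 4, 2), activations = "relu", init_seed = 7)
  z0 <- matrix(rnorm(15), 3, 5)
  naive <- z0
  for (layer in tower) {
    out <- matrix(0, nrow(naive), ncol(layer$W))
    for (b in seq_len(nrow(naive))) {
      v <- drop(t(layer$W) %*% naive[b, ]) + layer$b
      out[b, ] <- pmax(v, 0)
    }
    naive <- out
  }
  expect_equal(mlp_forward(tower, z0), naive, tolerance = 1e-12)
})

test_that("identity towers reduce the MLP score to the GTD score", {
  id_tower <- structure(list(list(W = diag(3), b = numeric(3),
                                  activation = "identity")),
                        class = "mlp_tower", input_width = 3L)
  towers <- list(id_tower, id_tower, id_tower)
  set.seed(1)
  a <- runif(3); b <- runif(3); c <- runif(3); h <- rnorm(3)
  expect_equal(mlp_score(towers, a, b, c, h), gtd_score(a, b, c, h))

  # a zeroed tower output forces sigma(0) = 0.5
  zero_tower <- structure(list(list(W = 0 * diag(3), b = numeric(3),
                                    activation = "identity")),
                          class = "mlp_tower", input_width = 3L)
  expect_equal(mlp_score(list(zero_tower, id_tower, id_tower), a, b, c, h), 0.5)

  # compositional: equals hand-chained forward + head calls
  t2 <- mlp_tower(3, c(4, 2), init_seed = 3)
  towers2 <- list(t2, mlp_tower(3, c(4, 2), init_seed = 4),
                  mlp_tower(3, c(4, 2), init_seed = 5))
  h2 <- rnorm(2)
  expect_equal(mlp_score(towers2, a, b, c, h2),
               gtd_score(mlp_forward(towers2[[1]], a),
                         mlp_forward(towers2[[2]], b),
                         mlp_forward(towers2[[3]], c), h2))
})

test_that("the ensemble concatenates both interaction vectors before one head", {
  set.seed(11)
  r <- 4
  towers <- lapply(5:7, function(s) mlp_tower(r, c(2 * r, r, 2), init_seed = s))
  g <- list(a = runif(r), b = runif(r), c = runif(r))
  m <- list(towers = towers, a = runif(r), b = runif(r), c = runif(r))
  h <- rnorm(r + 2)

  expect_equal(ensemble_score(g, m, numeric(r + 2)), 0.5)

  # masking the MLP half recovers the GTD path
  h_gtd_only <- c(h[1:r], numeric(2))
  expect_equal(ensemble_score(g, m, h_gtd_only),
               gtd_score(g$a, g$b, g$c, h[1:r]))

  # equals independent recomputation from the two interaction vectors
  vg <- g$a * g$b * g$c
  vm <- mlp_forward(towers[[1]], m$a) * mlp_forward(towers[[2]], m$b) *
        mlp_forward(towers[[3]], m$c)
  expect_equal(ensemble_score(g, m, h),
               1 / (1 + exp(-sum(c(vg, vm) * h))))

  expect_error(ensemble_score(g, m, numeric(3)), "length")
})

test_that("feature fusion maps concatenated features to rank dimensions", {
  n <- 5; d <- 3
  sim <- random_sims(c(n, n, n), seed = 2)$dr
  emb <- matrix(rnorm(n * d), n, d)
  for (r in c(8, 16, 32)) {
    bund <- feature_bundle(emb, sim, matrix(rnorm((d + n) * r), d + n, r),
                           rnorm(r))
    expect_length(fuse_features(bund, 2L), r)
    expect_equal(dim(fuse_features(bund, c(1L, 3L))), c(2L, r))
  }
  # identity-configured map passes the concatenated input through
  bund_id <- feature_bundle(emb, sim, diag(d + n), numeric(d + n),
                            activation = "identity")
  expect_equal(fuse_features(bund_id, 4L), c(emb[4, ], sim[4, ]))
  # zero inputs with a zero map leave only the bias
  bund0 <- feature_bundle(matrix(0, n, d), matrix(0, n, n),
                          matrix(0, d + n, 2), c(0.7, -0.1),
                          activation = "identity")
  expect_equal(fuse_features(bund0, 1L), c(0.7, -0.1))
  expect_error(fuse_features(bund_id, 99L), "out of range")
})

test_that("the model forward pass equals the composition of the exported ops", {
  dims <- c(6, 7, 5)
  sims <- random_sims(dims, seed = 3)
  tri <- random_triples(dims, 20, seed = 4)
  for (kind in c("gtd", "mlp", "ensemble")) {
    model <- new_model(kind, dims, rank = 4, sims = sims, init_seed = 5)
    got <- predict_triples(model, tri)
    lat <- function(path) list(
      a = as.matrix(fuse_features(model_bundle(model, "dr", path), tri$i)),
      b = as.matrix(fuse_features(model_bundle(model, "ge", path), tri$j)),
      c = as.matrix(fuse_features(model_bundle(model, "di", path), tri$k)))
    want <- switch(kind,
      gtd = { l <- lat("G"); gtd_score(l$a, l$b, l$c, model$params$h) },
      mlp = { l <- lat("M")
              towers <- lapply(c("dr", "ge", "di"), function(rl) model_tower(model, rl))
              mlp_score(towers, l$a, l$b, l$c, model$params$h) },
      ensemble = { lg <- lat("G"); lm <- lat("M")
                   towers <- lapply(c("dr", "ge", "di"), function(rl) model_tower(model, rl))
                   ensemble_score(list(a = lg$a, b = lg$b, c = lg$c),
                                  list(towers = towers, a = lm$a, b = lm$b, c = lm$c),
                                  model$params$h) })
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("frozen exact CP factors reconstruct a synthetic tensor perfectly", {
  set.seed(9)
  R <- 3; dims <- c(8, 6, 5)
  A <- matrix(runif(dims[1] * R), dims[1], R)
  B <- matrix(runif(dims[2] * R), dims[2], R)
  C <- matrix(runif(dims[3] * R), dims[3], R)
  grid <- expand.grid(i = 1:dims[1], j = 1:dims[2], k = 1:dims[3])
  truth <- mapply(function(i, j, k) oracle_cp_cell(A, B, C, i, j, k),
                  grid$i, grid$j, grid$k)
  recon <- gtd_score(A[grid$i, ], B[grid$j, ], C[grid$k, ], rep(1, R),
                     activation = "identity")
  expect_lt(max(abs(recon - truth)), 1e-6)
})

test_that("latent vectors expose the paths used for pairwise prediction", {
  dims <- c(4, 5, 3)
  sims <- random_sims(dims, seed = 8)
  model <- new_model("ensemble", dims, rank = 3, sims = sims, init_seed = 2)
  lg <- latent_vectors(model, "dr", "gtd")
  lm <- latent_vectors(model, "dr", "mlp")
  lb <- latent_vectors(model, "dr", "both")
  expect_equal(ncol(lg), 3)
  expect_equal(ncol(lm), tail(model$tower_widths, 1))
  expect_equal(lb, cbind(lg, lm))
  gtd_only <- new_model("gtd", dims, rank = 3, sims = sims, init_seed = 2)
  expect_error(latent_vectors(gtd_only, "dr", "mlp"), "path")
})
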