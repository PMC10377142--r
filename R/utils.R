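# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

leaky_relu <- function(x, slope = 0.01) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

identity_act <- function(x) x

#' @noRd
resolve_activation <- function(act) {
  if (is.function(act)) return(act)
  switch(match.arg(act, c("sigmoid", "relu", "leaky_relu", "identity")),
    sigmoid = sigmoid,
    relu = relu,
    leaky_relu = leaky_relu,
    identity = identity_act
  )
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Lightweight logging; suppressible via suppressMessages().
tt_log <- function(...) message("tritensor: ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)
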