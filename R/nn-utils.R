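## Minimal neural-network primitives: parameter containers, Adam updates and
## dropout. Parameters are flat named lists of numeric matrices/vectors.

nn_linear_init <- function(n_in, n_out) {
  k <- 1 / sqrt(max(n_in, 1))
  list(W = matrix(stats::runif(n_out * n_in, -k, k), n_out, n_in),
       b = stats::runif(n_out, -k, k))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

## one Adam step with decoupled-from-loss L2 (gradient += wd * param, the
## classical Adam weight-decay used by the torch optimizer default)
adam_step <- function(params, grads, state, lr = 1e-3, wd = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]] + wd * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

dropout_mask <- function(n, p) {
  if (p <= 0) return(rep(1, n))
  (stats::runif(n) >= p) / (1 - p)
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(a, b) {
  for (k in names(b)) a[[k]] <- a[[k]] + b[[k]]
  a
}
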