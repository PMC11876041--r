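#' Discrete-time interval grid for the neural survival head
#'
#' Builds right-closed interval boundaries `0 = tau_0 < tau_1 < ... < tau_B`
#' covering the observed time range in steps of `width`, plus one overflow
#' interval; an observed time `T` falls in interval `b` when
#' `tau_{b-1} < T <= tau_b`.
#'
#' @param times observed times.
#' @param width interval width (default 0.5, the visit spacing of both the
#'   simulated and cohort-style grids).
#' @return numeric vector of boundaries (class `dt_intervals`).
#' @export
make_intervals <- function(times, width = 0.5) {
  hi <- max(times)
  bounds <- seq(0, ceiling(hi / width + 1e-9) * width, by = width)
  if (max(bounds) <= hi) bounds <- c(bounds, max(bounds) + width)
  bounds <- c(bounds, max(bounds) + width)   # overflow interval
  structure(bounds, class = "dt_intervals")
}

interval_index <- function(bounds, times) {
  b <- findInterval(times, bounds, left.open = TRUE)
  b[times <= bounds[1]] <- 1L
  pmin(pmax(b, 1L), length(bounds) - 1L)
}

## landmark interval: number of whole intervals fully elapsed at time l
## (l = 0 -> 0; conditioning is on T > tau_{l_idx})
landmark_index <- function(bounds, l) {
  i <- findInterval(l + 1e-12, bounds) - 1L
  pmin(pmax(i, 0L), length(bounds) - 2L)
}

#' Conditional failure/survival functions from interval probabilities
#'
#' Given a probability vector over discrete time intervals, returns the
#' failure function `F(tau_b) = sum_{l < t <= b} P(T = t) / P(T > l)` and the
#' survival function `S = 1 - F` on the interval boundaries, conditioning on
#' survival past interval `l`.
#'
#' @param p probability vector over `B` intervals (sums to 1).
#' @param l landmark interval index in `0..B-1` (0 = no conditioning).
#' @return list with `F` and `S`, numeric vectors of length `B + 1` aligned
#'   with the boundaries `tau_0..tau_B`.
#' @export
failure_from_probs <- function(p, l = 0L) {
  stopifnot(abs(sum(p) - 1) < 1e-8, l >= 0, l < length(p))
  Pl <- if (l == 0L) 1 else 1 - sum(p[seq_len(l)])
  if (Pl <= 0) stop("conditioning on zero survival mass (P(T > l) = 0)")
  cum <- cumsum(p)
  Fb <- c(0, (cum - if (l == 0L) 0 else cum[l]) / Pl)
  Fb[seq_len(l + 1)] <- 0
  Fb <- pmin(pmax(Fb, 0), 1)
  list(F = Fb, S = 1 - Fb)
}

## ---- network internals -----------------------------------------------

dtnn_init <- function(n_in, n_hidden, n_out) {
  l1 <- nn_linear_init(n_in, n_hidden)
  l2 <- nn_linear_init(n_hidden, n_out)
  list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b)
}

## forward pass: Z (n x d) -> list(logits, probs, cache)
dtnn_forward <- function(params, Z, dropout = 0, train = FALSE) {
  A1 <- Z %*% t(params$W1)
  A1 <- sweep(A1, 2, params$b1, "+")
  H1 <- relu(A1)
  mask <- NULL
  if (train && dropout > 0) {
    mask <- matrix(dropout_mask(length(H1), dropout), nrow(H1), ncol(H1))
    H1 <- H1 * mask
  }
  A2 <- H1 %*% t(params$W2)
  A2 <- sweep(A2, 2, params$b2, "+")
  P <- softmax_rows(A2)
  list(probs = P, cache = list(Z = Z, A1 = A1, H1 = H1, mask = mask))
}

## negative log-likelihood (sum over samples) and d loss / d logits
## event:     -log P(T = b_i)
## censored:  -log [ P(T > b_i) / P(T > l_i) ]
dtnn_nll <- function(P, b, event, l_idx) {
  n <- nrow(P); B <- ncol(P)
  cum <- t(apply(P, 1, cumsum))
  PA <- 1 - cum[cbind(seq_len(n), b)]                            # P(T > b)
  PL <- 1 - ifelse(l_idx == 0L, 0, cum[cbind(seq_len(n), pmax(l_idx, 1L))])  # P(T > l)
  pb <- P[cbind(seq_len(n), b)]
  eps <- 1e-12
  ## degenerate samples (no probability mass where the likelihood needs it)
  ## contribute neither loss nor gradient: the clipped likelihood is flat there
  ev <- event == 1 & pb > eps
  cz <- event == 0 & PL > eps & PA > eps
  ll <- numeric(n)
  ll[ev] <- -log(pb[ev])
  ll[cz] <- -(log(PA[cz]) - log(PL[cz]))
  ## gradient wrt logits
  G <- matrix(0, n, B)
  iev <- which(ev)
  if (length(iev)) {
    G[iev, ] <- P[iev, , drop = FALSE]
    G[cbind(iev, b[iev])] <- G[cbind(iev, b[iev])] - 1
  }
  cs <- which(cz)
  if (length(cs)) {
    onesA <- outer(b[cs], seq_len(B), `<`) * 1          # 1(t > b_i)
    onesL <- outer(l_idx[cs], seq_len(B), `<`) * 1      # 1(t > l_i)
    G[cs, ] <- P[cs, , drop = FALSE] *
      (onesL / PL[cs] - onesA / PA[cs])
  }
  list(loss = sum(ll), dlogits = G, skipped = sum(!(ev | cz)))
}

## backward through the 2-layer net given d loss / d logits
dtnn_backward <- function(params, cache, dlogits) {
  dW2 <- t(dlogits) %*% cache$H1
  db2 <- colSums(dlogits)
  dH1 <- dlogits %*% params$W2
  if (!is.null(cache$mask)) dH1 <- dH1 * cache$mask
  dA1 <- dH1 * (cache$A1 > 0)
  dW1 <- t(dA1) %*% cache$Z
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Fit the discrete-time neural survival head
#'
#' A two-layer fully connected network (32 hidden units, ReLU and dropout
#' after the first layer, softmax output over time intervals) trained with
#' the discrete-time negative log-likelihood: events contribute
#' `-log P(T = T_i | Z_i)` and censored subjects
#' `-log S(T_i | Z_i, T > l_i)`, where `l_i` is the training sample's
#' landmark (0 when the sample was not landmarked).
#'
#' @param Z encoding matrix (one row per subject).
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param l per-sample landmark times (scalar or vector; default 0).
#' @param intervals boundaries from [make_intervals()]; computed from the
#'   training times when `NULL`.
#' @param hidden hidden-layer width.
#' @param epochs,batch_size,lr,weight_decay,dropout training hyperparameters.
#' @param seed RNG seed (initialization, batch order, dropout).
#' @return an object of class `dtnn_head`.
#' @export
fit_discrete_nn <- function(Z, time, event, l = 0, intervals = NULL,
                            hidden = 32, epochs = 100, batch_size = 32,
                            lr = 1e-3, weight_decay = 1e-5, dropout = 0.3,
                            seed = 1) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(length(time) == n, length(event) == n)
  if (length(l) == 1) l <- rep(l, n)
  if (is.null(intervals)) intervals <- make_intervals(time)
  B <- length(intervals) - 1L
  b <- interval_index(intervals, time)
  l_idx <- landmark_index(intervals, l)
  deg <- event == 0 & b <= l_idx
  if (any(deg & l_idx > 0))
    warning(sum(deg & l_idx > 0),
            " censored sample(s) with no mass beyond their landmark interval; skipped")

  ## standardize inputs for stable optimization
  ctr <- colMeans(Z)
  scl <- apply(Z, 2, stats::sd); scl[scl < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, ctr), 2, scl, "/")

  set.seed(seed)
  params <- dtnn_init(ncol(Z), hidden, B)
  state <- adam_init(params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1, n)]
      fw <- dtnn_forward(params, Zs[rows, , drop = FALSE], dropout, train = TRUE)
      nl <- dtnn_nll(fw$probs, b[rows], event[rows], l_idx[rows])
      gr <- dtnn_backward(params, fw$cache, nl$dlogits / length(rows))
      upd <- adam_step(params, gr, state, lr, weight_decay)
      params <- upd$params; state <- upd$state
    }
  }
  structure(list(params = params, intervals = intervals, hidden = hidden,
                 center = ctr, scale = scl, feature_names = colnames(Z)),
            class = "dtnn_head")
}

#' Predicted interval probabilities from a fitted discrete-time head
#' @param object a `dtnn_head`.
#' @param Z encoding matrix.
#' @return matrix of interval probabilities (rows sum to 1).
#' @export
predict_interval_probs <- function(object, Z) {
  Z <- as.matrix(Z)
  if (!is.null(object$feature_names) && !is.null(colnames(Z)) &&
      !identical(colnames(Z), object$feature_names))
    stop("encoding features do not match the fitted head")
  Zs <- sweep(sweep(Z, 2, object$center), 2, object$scale, "/")
  dtnn_forward(object$params, Zs)$probs
}

#' Predicted survival curves from a fitted discrete-time head
#'
#' Softmax interval probabilities are turned into a right-continuous step
#' survival function on the interval boundaries (`S(tau_b) = P(T > b)`) and
#' evaluated on `grid`; times beyond the last boundary are extended flat.
#' Conditioning on a landmark is applied downstream through
#' [conditional_risk()], which for this model coincides with the
#' interval-probability form of the conditional failure function.
#'
#' @param object a `dtnn_head`.
#' @param Z encoding matrix.
#' @param grid evaluation times.
#' @return a [survival_curves] object.
#' @export
predict_discrete_nn <- function(object, Z, grid) {
  P <- predict_interval_probs(object, Z)
  Sb <- t(apply(P, 1, function(p) 1 - cumsum(p)))
  bounds <- object$intervals
  S <- t(apply(Sb, 1, function(s) step_eval(bounds[-1], s, grid, before = 1)))
  if (length(grid) == 1) S <- matrix(S, ncol = 1)
  survival_curves(curve_ids(Z), grid, S)
}
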