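#' Recurrent neural network encoder
#'
#' Stage-one Elman recurrent network. Each layer computes
#' `h_{n,j} = tanh(W_{n0} x_{n,j} + b_{n0} + W_{n1} h_{n,j-1} + b_{n1})`
#' over a subject's visit sequence; the input at step `j` is the vector of
#' longitudinal values at that visit (optionally with the visit time
#' appended so irregular spacing is visible to the recurrence). The subject
#' encoding is `Z = [B, h_{J}]`: baseline covariates plus the final hidden
#' state.
#'
#' Two training modes:
#' * `"long_only"`: minimizes the next-visit mean squared error (a
#'   feed-forward head predicts the next visit's longitudinal values from the
#'   hidden state and baseline covariates).
#' * `"combined"`: first trains on the sum of the longitudinal loss and the
#'   discrete-time survival negative log-likelihood (through a survival head
#'   on `Z`), then fine-tunes the whole encoder and survival head on the
#'   survival loss alone.
#'
#' @param mode `"combined"` or `"long_only"`.
#' @param layers number of recurrent layers.
#' @param width hidden width; defaults to 5 + the number of longitudinal
#'   covariates.
#' @param head_hidden hidden width of the feed-forward heads.
#' @param include_time append the visit time to the input at each step.
#' @param epochs,batch_size,lr,weight_decay,dropout training hyperparameters
#'   (dropout is applied between recurrent layers and after head hidden
#'   layers, training only).
#' @param seed RNG seed.
#' @return an encoder specification; fit with [fit_encoder()].
#' @export
encoder_rnn <- function(mode = c("combined", "long_only"), layers = 2,
                        width = NULL, head_hidden = 32, include_time = TRUE,
                        epochs = 100, batch_size = 32, lr = 1e-3,
                        weight_decay = 1e-5, dropout = 0.3, seed = 1) {
  structure(list(type = "rnn", mode = match.arg(mode), layers = layers,
                 width = width, head_hidden = head_hidden,
                 include_time = include_time, epochs = epochs,
                 batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, dropout = dropout, seed = seed),
            class = c("encoder_rnn", "encoder_spec"))
}

## ---- parameter construction ------------------------------------------

rnn_init_params <- function(d_in, H, L, d_base, d_head_hidden, Q, B_int) {
  p <- list()
  for (n in seq_len(L)) {
    i0 <- nn_linear_init(if (n == 1) d_in else H, H)
    i1 <- nn_linear_init(H, H)
    p[[paste0("W0_", n)]] <- i0$W; p[[paste0("b0_", n)]] <- i0$b
    p[[paste0("W1_", n)]] <- i1$W; p[[paste0("b1_", n)]] <- i1$b
  }
  lh1 <- nn_linear_init(H + d_base, d_head_hidden)
  lh2 <- nn_linear_init(d_head_hidden, Q)
  p$Wl1 <- lh1$W; p$bl1 <- lh1$b; p$Wl2 <- lh2$W; p$bl2 <- lh2$b
  if (B_int > 0) {
    sh1 <- nn_linear_init(H + d_base, d_head_hidden)
    sh2 <- nn_linear_init(d_head_hidden, B_int)
    p$Ws1 <- sh1$W; p$bs1 <- sh1$b; p$Ws2 <- sh2$W; p$bs2 <- sh2$b
  }
  p
}

## ---- data preparation ------------------------------------------------

## standardized per-subject sequences + baselines for a view
rnn_prepare <- function(data, stats_, include_time) {
  idx <- visit_index(data)
  Q <- length(data$long_vars)
  Ym <- as.matrix(data$visits[, data$long_vars, drop = FALSE])
  storage.mode(Ym) <- "double"
  for (q in seq_len(Q)) {                 # mean-fill then standardize
    col <- Ym[, q]
    col[is.na(col)] <- stats_$means[q]
    Ym[, q] <- (col - stats_$y_ctr[q]) / stats_$y_scl[q]
  }
  tt <- (data$visits$visit_time - stats_$t_ctr) / stats_$t_scl
  Bm <- baseline_matrix(data)
  Bm <- sweep(sweep(Bm, 2, stats_$b_ctr), 2, stats_$b_scl, "/")
  seqs <- lapply(idx, function(rows) {
    x <- Ym[rows, , drop = FALSE]
    if (include_time) x <- cbind(x, tt[rows])
    x
  })
  list(seqs = seqs, B = Bm, Y = Ym, idx = idx)
}

rnn_stats <- function(data) {
  means <- pooled_means(data)
  Ym <- as.matrix(data$visits[, data$long_vars, drop = FALSE])
  y_ctr <- colMeans(Ym, na.rm = TRUE)
  y_scl <- apply(Ym, 2, stats::sd, na.rm = TRUE); y_scl[!is.finite(y_scl) | y_scl < 1e-12] <- 1
  Bm <- as.matrix(data$subjects[, data$base_vars, drop = FALSE])
  b_ctr <- colMeans(Bm)
  b_scl <- apply(Bm, 2, stats::sd); b_scl[!is.finite(b_scl) | b_scl < 1e-12] <- 1
  t_ctr <- mean(data$visits$visit_time)
  t_scl <- stats::sd(data$visits$visit_time)
  if (!is.finite(t_scl) || t_scl < 1e-12) t_scl <- 1
  list(means = means, y_ctr = y_ctr, y_scl = y_scl,
       b_ctr = b_ctr, b_scl = b_scl, t_ctr = t_ctr, t_scl = t_scl)
}

## ---- forward / backward over one batch -------------------------------

## batch: list(seqs = list of J_i x d_in, B = m x d_base, targets = list of
## (J_i-1) x Q standardized next-visit values or NULL, surv = list(b, event,
## l_idx) or NULL). Subjects must be sorted by decreasing J.
## Returns loss components, gradients, and per-subject final hidden states.
rnn_batch_pass <- function(params, batch, L, H, dropout, train,
                           use_long, use_surv, grad = TRUE) {
  seqs <- batch$seqs
  m <- length(seqs)
  J <- vapply(seqs, nrow, integer(1))
  Jmax <- max(J)
  d_base <- ncol(batch$B)
  Q <- nrow(params$Wl2)

  h <- lapply(seq_len(L), function(n) matrix(0, m, H))
  cache <- vector("list", Jmax)
  Hfin <- matrix(0, m, H)
  long_loss <- 0; long_n <- 0
  long_caches <- vector("list", Jmax)

  for (j in seq_len(Jmax)) {
    act <- which(J >= j)
    x <- do.call(rbind, lapply(act, function(i) seqs[[i]][j, ]))
    st <- list(act = act, xs = vector("list", L), hs = vector("list", L),
               hprev = vector("list", L), masks = vector("list", L))
    inp <- x
    for (n in seq_len(L)) {
      hp <- h[[n]][act, , drop = FALSE]
      a <- inp %*% t(params[[paste0("W0_", n)]]) + h[[n]][act, , drop = FALSE] %*%
        t(params[[paste0("W1_", n)]])
      a <- sweep(a, 2, params[[paste0("b0_", n)]] + params[[paste0("b1_", n)]], "+")
      hn <- tanh(a)
      st$xs[[n]] <- inp; st$hs[[n]] <- hn; st$hprev[[n]] <- hp
      h[[n]][act, ] <- hn
      if (n < L) {
        if (train && dropout > 0) {
          msk <- matrix(dropout_mask(length(hn), dropout), nrow(hn), ncol(hn))
          st$masks[[n]] <- msk
          inp <- hn * msk
        } else inp <- hn
      }
    }
    cache[[j]] <- st
    done <- act[J[act] == j]
    if (length(done)) Hfin[done, ] <- h[[L]][done, , drop = FALSE]

    if (use_long) {
      tgt_rows <- act[J[act] > j]     # subjects with a next visit to predict
      if (length(tgt_rows)) {
        U <- cbind(h[[L]][tgt_rows, , drop = FALSE], batch$B[tgt_rows, , drop = FALSE])
        A1 <- sweep(U %*% t(params$Wl1), 2, params$bl1, "+")
        H1 <- relu(A1)
        mskl <- NULL
        if (train && dropout > 0) {
          mskl <- matrix(dropout_mask(length(H1), dropout), nrow(H1), ncol(H1))
          H1 <- H1 * mskl
        }
        pred <- sweep(H1 %*% t(params$Wl2), 2, params$bl2, "+")
        tgt <- do.call(rbind, lapply(tgt_rows, function(i) batch$targets[[i]][j, ]))
        wgt <- 1 / (m * Q * J[tgt_rows])          # per-subject 1/J_i weighting
        err <- pred - tgt
        long_loss <- long_loss + sum(wgt * rowSums(err^2))
        long_caches[[j]] <- list(rows = tgt_rows, U = U, A1 = A1, H1 = H1,
                                 mask = mskl, err = err, wgt = wgt)
      }
    }
  }

  surv_loss <- 0; surv_cache <- NULL
  if (use_surv) {
    Zs <- cbind(Hfin, batch$B)
    A1 <- sweep(Zs %*% t(params$Ws1), 2, params$bs1, "+")
    H1 <- relu(A1)
    msks <- NULL
    if (train && dropout > 0) {
      msks <- matrix(dropout_mask(length(H1), dropout), nrow(H1), ncol(H1))
      H1 <- H1 * msks
    }
    logits <- sweep(H1 %*% t(params$Ws2), 2, params$bs2, "+")
    P <- softmax_rows(logits)
    nl <- dtnn_nll(P, batch$surv$b, batch$surv$event, batch$surv$l_idx)
    surv_loss <- nl$loss / m
    surv_cache <- list(Zs = Zs, A1 = A1, H1 = H1, mask = msks,
                       dlogits = nl$dlogits / m)
  }

  out <- list(long_loss = long_loss, surv_loss = surv_loss, Hfin = Hfin)
  if (!grad) return(out)

  g <- zero_like(params)
  dHfin <- matrix(0, m, H)

  if (use_surv) {
    sc <- surv_cache
    g$Ws2 <- t(sc$dlogits) %*% sc$H1
    g$bs2 <- colSums(sc$dlogits)
    dH1 <- sc$dlogits %*% params$Ws2
    if (!is.null(sc$mask)) dH1 <- dH1 * sc$mask
    dA1 <- dH1 * (sc$A1 > 0)
    g$Ws1 <- t(dA1) %*% sc$Zs
    g$bs1 <- colSums(dA1)
    dZ <- dA1 %*% params$Ws1
    dHfin <- dHfin + dZ[, seq_len(H), drop = FALSE]
  }

  ## backward through time
  dh_next <- lapply(seq_len(L), function(n) matrix(0, m, H))
  for (j in rev(seq_len(Jmax))) {
    st <- cache[[j]]
    act <- st$act
    dh_here <- lapply(seq_len(L), function(n) dh_next[[n]][act, , drop = FALSE])
    ## survival head gradient enters at each subject's final step
    done <- which(J[act] == j)
    if (length(done) && use_surv)
      dh_here[[L]][done, ] <- dh_here[[L]][done, , drop = FALSE] +
        dHfin[act[done], , drop = FALSE]
    ## longitudinal head gradient at this step
    lc <- long_caches[[j]]
    if (!is.null(lc)) {
      dpred <- 2 * lc$err * lc$wgt
      g$Wl2 <- g$Wl2 + t(dpred) %*% lc$H1
      g$bl2 <- g$bl2 + colSums(dpred)
      dH1 <- dpred %*% params$Wl2
      if (!is.null(lc$mask)) dH1 <- dH1 * lc$mask
      dA1 <- dH1 * (lc$A1 > 0)
      g$Wl1 <- g$Wl1 + t(dA1) %*% lc$U
      g$bl1 <- g$bl1 + colSums(dA1)
      dU <- dA1 %*% params$Wl1
      pos <- match(lc$rows, act)
      dh_here[[L]][pos, ] <- dh_here[[L]][pos, , drop = FALSE] +
        dU[, seq_len(H), drop = FALSE]
    }
    for (n in rev(seq_len(L))) {
      da <- dh_here[[n]] * (1 - st$hs[[n]]^2)
      g[[paste0("W0_", n)]] <- g[[paste0("W0_", n)]] + t(da) %*% st$xs[[n]]
      g[[paste0("W1_", n)]] <- g[[paste0("W1_", n)]] + t(da) %*% st$hprev[[n]]
      g[[paste0("b0_", n)]] <- g[[paste0("b0_", n)]] + colSums(da)
      dh_prev <- da %*% params[[paste0("W1_", n)]]
      dh_next[[n]][, ] <- 0
      dh_next[[n]][act, ] <- dh_prev
      if (n > 1) {
        dx <- da %*% params[[paste0("W0_", n)]]
        if (!is.null(st$masks[[n - 1]])) dx <- dx * st$masks[[n - 1]]
        dh_here[[n - 1]] <- dh_here[[n - 1]] + dx
      }
    }
  }
  out$grads <- g
  out
}

## b1 gradients equal b0 gradients (shared pre-activation); mirror them
mirror_bias_grads <- function(g, L) {
  for (n in seq_len(L)) g[[paste0("b1_", n)]] <- g[[paste0("b0_", n)]]
  g
}

## ---- fitting ----------------------------------------------------------

#' @param spec an `encoder_rnn` specification.
#' @param data training view.
#' @param random_epochs when `TRUE`, the training view is re-truncated with
#'   [random_truncate()] at every epoch (the random landmarking strategy).
#' @param intervals survival-head interval boundaries (combined mode).
#' @param ... unused.
#' @rdname encoder_rnn
#' @export
fit_encoder.encoder_rnn <- function(spec, data, random_epochs = FALSE,
                                    intervals = NULL, ...) {
  Q <- length(data$long_vars)
  H <- if (is.null(spec$width)) 5L + Q else spec$width
  L <- spec$layers
  d_in <- Q + as.integer(spec$include_time)
  stats_ <- rnn_stats(data)
  use_surv <- spec$mode == "combined"
  if (use_surv && is.null(intervals)) intervals <- make_intervals(data$subjects$time)
  B_int <- if (use_surv) length(intervals) - 1L else 0L

  set.seed(spec$seed)
  params <- rnn_init_params(d_in, H, L, length(data$base_vars),
                            spec$head_hidden, Q, B_int)
  state <- adam_init(params)

  lmk <- training_landmarks(data)
  run_epochs <- function(params, state, n_epochs, use_long, use_surv_loss) {
    for (ep in seq_len(n_epochs)) {
      epoch_data <- if (random_epochs) random_truncate(data) else data
      prep <- rnn_prepare(epoch_data, stats_, spec$include_time)
      n <- n_subjects(epoch_data)
      if (use_long && all(vapply(prep$seqs, nrow, integer(1)) < 2))
        stop("longitudinal loss requires at least one subject with >= 2 visits")
      ord <- sample.int(n)
      for (start in seq(1, n, by = spec$batch_size)) {
        rows <- ord[start:min(start + spec$batch_size - 1, n)]
        Ji <- vapply(prep$seqs[rows], nrow, integer(1))
        rows <- rows[order(-Ji)]
        batch <- list(
          seqs = prep$seqs[rows],
          B = prep$B[rows, , drop = FALSE],
          targets = lapply(prep$seqs[rows], function(s)
            if (nrow(s) > 1) s[-1, seq_len(Q), drop = FALSE] else NULL))
        if (use_surv_loss) {
          tm <- epoch_data$subjects$time[rows]
          batch$surv <- list(b = interval_index(intervals, tm),
                             event = epoch_data$subjects$event[rows],
                             l_idx = landmark_index(intervals, lmk[rows]))
        }
        bp <- rnn_batch_pass(params, batch, L, H, spec$dropout, train = TRUE,
                             use_long = use_long, use_surv = use_surv_loss)
        gr <- mirror_bias_grads(bp$grads, L)
        upd <- adam_step(params, gr, state, spec$lr, spec$weight_decay)
        params <- upd$params; state <- upd$state
      }
    }
    list(params = params, state = state)
  }

  if (spec$mode == "long_only") {
    r <- run_epochs(params, state, spec$epochs, use_long = TRUE,
                    use_surv_loss = FALSE)
  } else {
    r <- run_epochs(params, state, spec$epochs, use_long = TRUE,
                    use_surv_loss = TRUE)
    r <- run_epochs(r$params, r$state, spec$epochs, use_long = FALSE,
                    use_surv_loss = TRUE)
  }

  structure(list(spec = spec, params = r$params, stats = stats_,
                 layers = L, width = H, d_in = d_in,
                 base_vars = data$base_vars, long_vars = data$long_vars,
                 means = stats_$means, intervals = intervals),
            class = c("fitted_rnn", "fitted_encoder"))
}

## per-sample training landmark times: strict views carry ds$landmark, super
## stacks carry entry_landmark, otherwise 0
training_landmarks <- function(data) {
  if (!is.null(data$subjects$entry_landmark)) return(data$subjects$entry_landmark)
  if (!is.na(data$landmark)) return(rep(data$landmark, n_subjects(data)))
  rep(0, n_subjects(data))
}

#' @export
encode.fitted_rnn <- function(object, data, ...) {
  if (!identical(data$long_vars, object$long_vars))
    stop("longitudinal variables do not match the fitted encoder")
  prep <- rnn_prepare(data, object$stats, object$spec$include_time)
  n <- n_subjects(data)
  Ji <- vapply(prep$seqs, nrow, integer(1))
  ord <- order(-Ji)
  batch <- list(seqs = prep$seqs[ord], B = prep$B[ord, , drop = FALSE],
                targets = NULL)
  bp <- rnn_batch_pass(object$params, batch, object$layers, object$width,
                       dropout = 0, train = FALSE,
                       use_long = FALSE, use_surv = FALSE, grad = FALSE)
  Hfin <- matrix(0, n, object$width)
  Hfin[ord, ] <- bp$Hfin
  colnames(Hfin) <- paste0("h", seq_len(object$width))
  Z <- cbind(baseline_matrix(data), Hfin)
  Z
}

#' Survival head jointly trained with a combined-mode RNN encoder
#'
#' After combined-mode training the survival head's parameters live inside
#' the encoder; this extracts them as a standalone `dtnn_head` operating on
#' the encoder's `Z = [B, h_J]` encodings.
#'
#' @param object a `fitted_rnn` encoder trained with `mode = "combined"`.
#' @return a `dtnn_head`.
#' @export
rnn_surv_head <- function(object) {
  stopifnot(inherits(object, "fitted_rnn"))
  if (object$spec$mode != "combined")
    stop("the encoder was not trained with a survival loss")
  p <- object$params
  d_base <- length(object$base_vars)
  H <- object$width
  ## head consumed [h, standardized B] during training; encode() emits the
  ## raw [B, h]: reorder the weight columns and standardize the B block
  ## through the head's own center/scale
  W1 <- cbind(p$Ws1[, H + seq_len(d_base), drop = FALSE],
              p$Ws1[, seq_len(H), drop = FALSE])
  structure(list(params = list(W1 = W1, b1 = p$bs1, W2 = p$Ws2, b2 = p$bs2),
                 intervals = object$intervals, hidden = object$spec$head_hidden,
                 center = c(object$stats$b_ctr, rep(0, H)),
                 scale = c(object$stats$b_scl, rep(1, H)),
                 feature_names = c(object$base_vars, paste0("h", seq_len(H)))),
            class = "dtnn_head")
}
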