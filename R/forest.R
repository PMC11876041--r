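#' Random survival forest head
#'
#' Survival trees grown on bootstrap resamples with the log-rank splitting
#' rule; leaves hold Kaplan-Meier curves of their in-bag samples and the
#' ensemble prediction is the average of the tree curves. Backed by the
#' `ranger` implementation.
#'
#' @param Z encoding matrix.
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param n_trees number of trees (default 1000).
#' @param min_split minimum node size to attempt a split (default 32).
#' @param min_leaf minimum terminal node size (default 16).
#' @param mtry size of the random feature subset per split; defaults to
#'   `ceiling(sqrt(D))`.
#' @param seed RNG seed.
#' @return an object of class `rsf_head`.
#' @export
fit_forest <- function(Z, time, event, n_trees = 1000, min_split = 32,
                       min_leaf = 16, mtry = NULL, seed = 1) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(Z)))
  df <- data.frame(Z, check.names = FALSE)
  df$.time <- time; df$.event <- event
  fit <- ranger::ranger(
    formula = survival::Surv(.time, .event) ~ .,
    data = df, num.trees = n_trees, mtry = min(mtry, ncol(Z)),
    min.node.size = min_split, min.bucket = min_leaf,
    splitrule = "logrank", seed = seed, num.threads = 1)
  structure(list(fit = fit, features = colnames(Z)), class = "rsf_head")
}

#' Predicted survival curves from a fitted forest head
#'
#' @param object an `rsf_head`.
#' @param Z encoding matrix with the training features.
#' @param grid evaluation times.
#' @return a [survival_curves] object.
#' @export
predict_forest <- function(object, Z, grid) {
  Z <- as.matrix(Z)
  if (!all(object$features %in% colnames(Z)))
    stop("encoding features do not match the fitted model")
  df <- data.frame(Z[, object$features, drop = FALSE], check.names = FALSE)
  pr <- stats::predict(object$fit, data = df, num.threads = 1)
  ut <- pr$unique.death.times
  S <- t(apply(pr$survival, 1, function(s)
    step_eval(ut, s, grid, before = 1)))
  if (length(grid) == 1) S <- matrix(S, ncol = 1)
  survival_curves(curve_ids(Z), grid, S)
}
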