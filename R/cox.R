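#' Cox proportional hazards survival head
#'
#' Fits `lambda_i(t) = lambda_0(t) exp(Z_i . beta)` by maximizing the partial
#' likelihood (Breslow tie handling) and estimates the baseline survival
#' `S_0(t) = exp(-Lambda_0(t))` with the Breslow estimator. Constant
#' (zero-variance) encoding columns are dropped with a warning.
#'
#' @param Z encoding matrix (one row per subject, named columns).
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param ridge optional ridge penalty (default 0 = plain partial
#'   likelihood, which reproduces the method's documented behaviour,
#'   including possible non-convergence on small landmarked subsets).
#' @return an object of class `cox_head` with elements `beta` (named
#'   coefficients), `basehaz` (step function data: `time`, `cumhaz`) and
#'   `features`.
#' @export
fit_cox <- function(Z, time, event, ridge = 0) {
  Z <- as.matrix(Z)
  if (sum(event) < 1) stop("at least one event is required")
  keep <- apply(Z, 2, function(col) stats::sd(col) > 1e-12)
  if (!all(keep)) {
    warning("dropping constant encoding column(s): ",
            paste(colnames(Z)[!keep], collapse = ", "))
    Z <- Z[, keep, drop = FALSE]
  }
  df <- data.frame(Z, check.names = FALSE)
  df$.time <- time; df$.event <- event
  rhs <- if (ncol(Z)) paste0("`", colnames(Z), "`", collapse = " + ") else "1"
  if (ridge > 0 && ncol(Z))
    rhs <- sprintf("ridge(%s, theta = %g, scale = TRUE)",
                   paste0("`", colnames(Z), "`", collapse = ", "), ridge)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::coxph(fml, data = df, ties = "breslow", x = FALSE, y = TRUE)
  if (ncol(Z) && !ridge) {
    conv <- tryCatch(fit$info$convergence, error = function(e) NULL)
    if (any(!is.finite(stats::coef(fit))))
      stop("Cox partial likelihood did not converge (non-finite coefficients)")
  }
  beta <- if (ncol(Z)) stats::coef(fit) else numeric(0)
  names(beta) <- colnames(Z)
  ## Breslow baseline cumulative hazard at covariates = 0
  lp <- if (ncol(Z)) drop(Z %*% beta) else rep(0, length(time))
  bh <- breslow_basehaz(time, event, lp)
  structure(list(beta = beta, basehaz = bh, features = colnames(Z),
                 fit = fit),
            class = "cox_head")
}

## Breslow estimator of the baseline cumulative hazard
breslow_basehaz <- function(time, event, lp) {
  elp <- exp(lp)
  et <- sort(unique(time[event == 1]))
  dN <- vapply(et, function(s) sum(event == 1 & time == s), numeric(1))
  risk <- vapply(et, function(s) sum(elp[time >= s]), numeric(1))
  data.frame(time = et, cumhaz = cumsum(dN / risk))
}

#' Predicted survival curves from a fitted Cox head
#'
#' Evaluates `S(t | Z) = S_0(t)^(exp(Z . beta))` on a time grid
#' (right-continuous step function; 1 before the first event time).
#'
#' @param object a `cox_head`.
#' @param Z encoding matrix with the training features.
#' @param grid evaluation times.
#' @return a [survival_curves] object.
#' @export
predict_cox <- function(object, Z, grid) {
  Z <- as.matrix(Z)
  if (length(object$features)) {
    if (!all(object$features %in% colnames(Z)))
      stop("encoding features do not match the fitted model")
    Z <- Z[, object$features, drop = FALSE]
    lp <- drop(Z %*% object$beta)
  } else lp <- rep(0, nrow(Z))
  H0 <- step_eval(object$basehaz$time, object$basehaz$cumhaz, grid, before = 0)
  S <- exp(-outer(exp(lp), H0))
  survival_curves(curve_ids(Z), grid, S)
}

## right-continuous step evaluation: value after the last step time <= t
step_eval <- function(times, values, t, before) {
  idx <- findInterval(t, times)
  out <- c(before, values)[idx + 1]
  out
}
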