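#' Per-subject predicted survival curves
#'
#' Container for predicted survival functions on a common time grid. Values
#' are clipped to `[0, 1]` and must be non-increasing in time (up to a small
#' numerical tolerance, which is then enforced).
#'
#' @param ids subject identifiers.
#' @param time_grid sorted evaluation times.
#' @param surv matrix of survival probabilities, one row per subject.
#' @return object of class `survival_curves`.
#' @export
survival_curves <- function(ids, time_grid, surv) {
  surv <- as.matrix(surv)
  stopifnot(nrow(surv) == length(ids), ncol(surv) == length(time_grid),
            !is.unsorted(time_grid))
  if (any(diff(t(surv)) > 1e-6))
    stop("survival curves must be non-increasing in time")
  surv <- pmin(pmax(surv, 0), 1)
  for (j in seq_len(ncol(surv))[-1])
    surv[, j] <- pmin(surv[, j], surv[, j - 1])
  rownames(surv) <- as.character(ids)
  structure(list(ids = as.character(ids), time_grid = time_grid, surv = surv),
            class = "survival_curves")
}

#' @export
print.survival_curves <- function(x, ...) {
  cat("<survival_curves> ", length(x$ids), " subjects on ",
      length(x$time_grid), " times [", min(x$time_grid), ", ",
      max(x$time_grid), "]\n", sep = "")
  invisible(x)
}

#' Conditional risk from predicted curves
#'
#' `R(t | l) = 1 - S(t) / S(l)`: the predicted probability of an event in
#' `(l, t]` given survival to the landmark `l`. Subjects with `S(l) = 0` are
#' returned as `NA` with a warning (they cannot be conditioned on).
#'
#' @param curves a [survival_curves] object whose grid contains `l` and `t`.
#' @param l landmark time.
#' @param t horizon time (`t >= l`).
#' @return named numeric vector of risks.
#' @export
conditional_risk <- function(curves, l, t) {
  stopifnot(t >= l)
  jl <- match(l, curves$time_grid); jt <- match(t, curves$time_grid)
  if (is.na(jl) || is.na(jt)) stop("l and t must be on the curve grid")
  Sl <- curves$surv[, jl]; St <- curves$surv[, jt]
  bad <- Sl <= 0
  if (any(bad)) warning(sum(bad), " subject(s) with S(l) = 0 set to NA")
  r <- ifelse(bad, NA_real_, 1 - St / Sl)
  stats::setNames(r, curves$ids)
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Estimates `G(t) = P(C > t)` by the Kaplan-Meier product over the training
#' observations with censoring (`1 - event`) as the endpoint; used for
#' inverse probability of censoring weighting. Must be computed on training
#' data only.
#'
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @return object of class `censoring_km` with fields `time` and `surv`;
#'   evaluate with [eval_censoring()].
#' @export
censoring_km <- function(time, event) {
  stopifnot(length(time) >= 1)
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv), class = "censoring_km")
}

#' Evaluate a censoring distribution
#'
#' @param G a `censoring_km` object.
#' @param t times at which to evaluate.
#' @param left when `TRUE` returns the left limit `G(t-)` (used when
#'   weighting events observed at `t`).
#' @return numeric vector of censoring survival probabilities.
#' @export
eval_censoring <- function(G, t, left = FALSE) {
  tt <- if (left) t - 1e-9 else t
  step_eval(G$time, G$surv, tt, before = 1)
}

#' IPCW time-dependent AUC
#'
#' Probability-weighted proportion of correctly ordered (case, control)
#' pairs at horizon `t`: cases are subjects with an observed event at or
#' before `t` (weighted by `1 / G(T_i-)`), controls are subjects still
#' event-free at `t`. Tied predicted risks count 1/2 by default;
#' `strict_ties = TRUE` reproduces the strict inequality variant, under
#' which ties score zero.
#'
#' @param risk predicted risks at horizon `t`.
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param G a `censoring_km` fitted on training data.
#' @param t horizon time.
#' @param strict_ties if `TRUE`, tied risks contribute 0 instead of 1/2.
#' @return the tdAUC value, or `NA` (with attribute `"reason"`) when there
#'   are no cases or no controls.
#' @export
tdauc_ipcw <- function(risk, time, event, G, t, strict_ties = FALSE) {
  ok <- !is.na(risk)
  risk <- risk[ok]; time <- time[ok]; event <- event[ok]
  case <- event == 1 & time <= t
  ctrl <- time > t
  if (!any(case) || !any(ctrl)) {
    out <- NA_real_
    attr(out, "reason") <- if (!any(case)) "no cases" else "no controls"
    return(out)
  }
  w <- 1 / eval_censoring(G, time[case], left = TRUE)
  drop_w <- !is.finite(w)
  if (any(drop_w)) {
    warning(sum(drop_w), " case(s) with zero censoring weight excluded")
    w <- w[!drop_w]
    case[which(case)[drop_w]] <- FALSE
  }
  rc <- risk[case]; rk <- risk[ctrl]
  ord <- sort(rk)
  n_lt <- findInterval(rc, ord, left.open = TRUE)        # controls with risk < case
  n_le <- findInterval(rc, ord)                          # controls with risk <= case
  ties <- n_le - n_lt
  pairs <- if (strict_ties) n_lt else n_lt + 0.5 * ties
  sum(w * pairs) / (length(rk) * sum(w))
}

#' IPCW Brier score
#'
#' Mean of the censoring-weighted squared differences between the predicted
#' risk and the observed status at horizon `t`: subjects with an event by
#' `t` contribute `(1 - risk)^2 / G(T_i-)`, subjects still at risk at `t`
#' contribute `risk^2 / G(t)`, subjects censored before `t` contribute 0.
#'
#' @inheritParams tdauc_ipcw
#' @return the Brier score.
#' @export
brier_ipcw <- function(risk, time, event, G, t) {
  ok <- !is.na(risk)
  risk <- risk[ok]; time <- time[ok]; event <- event[ok]
  n <- length(risk)
  ev <- event == 1 & time <= t
  atrisk <- time > t
  w_ev <- 1 / eval_censoring(G, time[ev], left = TRUE)
  w_ar <- 1 / eval_censoring(G, t)
  bad <- sum(!is.finite(w_ev)) + (any(atrisk) && !is.finite(w_ar))
  if (bad > 0) warning(bad, " contribution(s) with zero censoring weight excluded")
  w_ev[!is.finite(w_ev)] <- 0
  if (!is.finite(w_ar)) w_ar <- 0
  (sum((1 - risk[ev])^2 * w_ev) + sum(risk[atrisk]^2) * w_ar) / n
}

#' Mean squared error against the simulation truth
#'
#' @param risk predicted conditional risks.
#' @param true_risk ground-truth conditional risks (see
#'   [true_conditional_risk()]).
#' @return mean of squared differences over non-missing pairs.
#' @export
mse_vs_truth <- function(risk, true_risk) {
  if (length(risk) != length(true_risk)) stop("length mismatch")
  ok <- !is.na(risk) & !is.na(true_risk)
  mean((true_risk[ok] - risk[ok])^2)
}

#' Evaluation-metric ceiling from the simulation truth
#'
#' Computes tdAUC and Brier score with the predicted risk replaced by the
#' true conditional risk, giving the per-scenario performance ceiling
#' (its MSE is identically zero). `G` is estimated from the supplied
#' outcomes, which should be a training split when one exists.
#'
#' @param truth a `sim_truth` object.
#' @param data the evaluated `longitudinal_data` (typically the evaluation
#'   set the truth belongs to).
#' @param landmarks landmark times.
#' @param horizons horizon offsets added to each landmark.
#' @param G optional `censoring_km`; defaults to one fitted on `data`.
#' @return data.frame with columns `landmark`, `horizon`, `metric`, `value`.
#' @export
oracle_reference_metrics <- function(truth, data, landmarks, horizons,
                                     G = NULL) {
  if (is.null(G)) G <- censoring_km(data$subjects$time, data$subjects$event)
  rows <- list()
  for (l in landmarks) {
    lv <- suppressMessages(landmark(data, l))
    if (!n_subjects(lv)) next
    tm <- lv$subjects$time; ev <- lv$subjects$event
    for (h in horizons) {
      t <- l + h
      if (!t %in% truth$grid) next
      r <- true_conditional_risk(truth, lv$subjects$subject_id, l, t)
      rows[[length(rows) + 1]] <- data.frame(
        landmark = l, horizon = t,
        metric = c("tdAUC", "Brier", "MSE"),
        value = c(tdauc_ipcw(r, tm, ev, G, t),
                  brier_ipcw(r, tm, ev, G, t),
                  0))
    }
  }
  do.call(rbind, rows)
}

## subject ids for prediction output: row names or positional fallback
curve_ids <- function(Z) {
  if (!is.null(rownames(Z))) rownames(Z) else as.character(seq_len(nrow(Z)))
}
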