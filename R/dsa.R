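#' Fit a two-stage dynamic survival model
#'
#' The central fitting function: combines a longitudinal encoder (stage one),
#' a survival head (stage two) and a landmarking strategy for the training
#' data, returning a fitted model that predicts conditional survival curves
#' for new subjects at any landmark.
#'
#' Training strategies:
#' * `"none"`: one pipeline fitted on the complete histories. Evaluation
#'   still landmarks the test data, so this strategy deliberately exposes
#'   the train/evaluation mismatch it is known for.
#' * `"strict"`: one pipeline per landmark, fitted on data landmarked at
#'   that landmark (subjects with `T <= l` removed, visits after `l`
#'   removed).
#' * `"super"`: one pipeline fitted on the stacked landmarked copies of the
#'   training data.
#' * `"random"`: one pipeline whose training view is re-truncated to a
#'   random per-subject visit count at every epoch; only meaningful for
#'   iteratively trained encoders, so it requires an RNN encoder.
#'
#' @param data a [longitudinal_data] training set.
#' @param encoder an encoder specification ([encoder_baseline()],
#'   [encoder_last_visit()], [encoder_mfpca()], [encoder_rnn()]).
#' @param head survival head: `"cox"`, `"rsf"` or `"nn"`.
#' @param strategy landmarking strategy used during training.
#' @param landmarks landmark grid (used by `"strict"`/`"super"` training and
#'   as the default evaluation grid).
#' @param locf apply last-observation-carried-forward imputation before
#'   fitting (and, symmetrically, before encoding new data).
#' @param head_args list of extra arguments for the head fitter
#'   ([fit_cox()], [fit_forest()], [fit_discrete_nn()]).
#' @param intervals discrete-time interval boundaries for `"nn"` heads and
#'   combined-mode RNN encoders; defaults to half-unit bins over the
#'   training time range.
#' @param seed seed for the stochastic components (forest, networks).
#' @return an object of class `dsa`.
#' @export
dsa <- function(data, encoder = encoder_last_visit(), head = c("cox", "rsf", "nn"),
                strategy = c("strict", "none", "super", "random"),
                landmarks = c(1, 2, 3, 4), locf = TRUE,
                head_args = list(), intervals = NULL, seed = 1) {
  head <- match.arg(head)
  strategy <- match.arg(strategy)
  stopifnot(inherits(data, "longitudinal_data"))
  is_rnn <- inherits(encoder, "encoder_rnn")
  if (strategy == "random" && !is_rnn)
    stop("strategy 'random' requires an iteratively trained (RNN) encoder")
  combined_rnn <- is_rnn && encoder$mode == "combined"
  if (locf) data <- locf_impute(data)
  if (is.null(intervals) && (head == "nn" || combined_rnn))
    intervals <- make_intervals(data$subjects$time)
  if (is_rnn) encoder$seed <- seed

  fit_pipeline <- function(view, random_epochs = FALSE) {
    enc <- fit_encoder(encoder, view, random_epochs = random_epochs,
                       intervals = intervals)
    Z <- encode(enc, view)
    lmk <- training_landmarks(view)
    hd <- switch(head,
      cox = do.call(fit_cox, c(list(Z = Z, time = view$subjects$time,
                                    event = view$subjects$event), head_args)),
      rsf = do.call(fit_forest, c(list(Z = Z, time = view$subjects$time,
                                       event = view$subjects$event,
                                       seed = seed), head_args)),
      nn = if (combined_rnn) rnn_surv_head(enc) else
        do.call(fit_discrete_nn,
                c(list(Z = Z, time = view$subjects$time,
                       event = view$subjects$event, l = lmk,
                       intervals = intervals, seed = seed), head_args)))
    list(encoder = enc, head = hd)
  }

  pipelines <- if (strategy == "strict") {
    lapply(landmarks, function(l) {
      c(fit_pipeline(suppressMessages(landmark(data, l))), list(landmark = l))
    })
  } else if (strategy == "super") {
    list(fit_pipeline(super_landmark(data, landmarks)))
  } else if (strategy == "random") {
    list(fit_pipeline(data, random_epochs = TRUE))
  } else {
    list(fit_pipeline(data))
  }

  structure(list(pipelines = pipelines, encoder_spec = encoder, head = head,
                 strategy = strategy, landmarks = landmarks, locf = locf,
                 intervals = intervals, seed = seed,
                 base_vars = data$base_vars, long_vars = data$long_vars,
                 train_time = data$subjects$time,
                 train_event = data$subjects$event),
            class = "dsa")
}

select_pipeline <- function(object, l) {
  if (object$strategy != "strict") return(object$pipelines[[1]])
  hit <- which(vapply(object$pipelines, function(p) isTRUE(all.equal(p$landmark, l)),
                      logical(1)))
  if (!length(hit))
    stop("no pipeline fitted at landmark ", l,
         " (strict strategy fits only its training landmarks)")
  object$pipelines[[hit[1]]]
}

#' Predict conditional survival curves from a fitted two-stage model
#'
#' Landmarks `newdata` at `landmark` (removing subjects no longer at risk
#' and visits after the landmark), encodes the truncated histories and
#' returns survival curves on `times`.
#'
#' @param object a fitted [dsa] model.
#' @param newdata a [longitudinal_data] set.
#' @param landmark landmark time.
#' @param times evaluation times (defaults to the landmark plus half-unit
#'   steps up to 5 time units ahead).
#' @param ... unused.
#' @return a [survival_curves] object (the landmark time is always on the
#'   grid, so [conditional_risk()] applies directly).
#' @export
predict.dsa <- function(object, newdata, landmark, times = NULL, ...) {
  if (is.null(times)) times <- landmark + seq(0, 5, by = 0.5)
  times <- sort(unique(c(landmark, times)))
  lv <- suppressMessages(landmark(newdata, landmark))
  if (!n_subjects(lv)) stop("no subjects at risk at landmark ", landmark)
  if (object$locf) lv <- locf_impute(lv)
  p <- select_pipeline(object, landmark)
  Z <- encode(p$encoder, lv)
  switch(object$head,
         cox = predict_cox(p$head, Z, times),
         rsf = predict_forest(p$head, Z, times),
         nn = predict_discrete_nn(p$head, Z, times))
}

#' @export
print.dsa <- function(x, ...) {
  enc <- class(x$encoder_spec)[1]
  cat("<dsa> two-stage dynamic survival model\n")
  cat("  encoder:  ", sub("^encoder_", "", enc), "\n", sep = "")
  cat("  head:     ", x$head, "\n", sep = "")
  cat("  strategy: ", x$strategy, " (landmarks ",
      paste(x$landmarks, collapse = ", "), ")\n", sep = "")
  cat("  pipelines:", length(x$pipelines), "\n")
  invisible(x)
}

#' @export
summary.dsa <- function(object, ...) {
  print(object)
  if (object$head == "cox") {
    for (p in object$pipelines) {
      if (!is.null(p$landmark)) cat("\nlandmark", p$landmark, "coefficients:\n")
      else cat("\ncoefficients:\n")
      print(round(p$head$beta, 4))
    }
  }
  invisible(object)
}

#' @export
coef.dsa <- function(object, ...) {
  if (object$head != "cox") stop("coefficients are defined for the Cox head only")
  if (object$strategy == "strict")
    lapply(stats::setNames(object$pipelines,
                           paste0("l=", vapply(object$pipelines, `[[`, numeric(1),
                                               "landmark"))),
           function(p) p$head$beta)
  else object$pipelines[[1]]$head$beta
}

#' @export
plot.dsa <- function(x, newdata, landmark, times = NULL, max_subjects = 20, ...) {
  cv <- predict(x, newdata, landmark, times)
  n <- min(length(cv$ids), max_subjects)
  graphics::matplot(cv$time_grid, t(cv$surv[seq_len(n), , drop = FALSE]),
                    type = "s", lty = 1, col = grDevices::grey(0.2, 0.4),
                    xlab = "time", ylab = "predicted survival",
                    ylim = c(0, 1), ...)
  graphics::abline(v = landmark, lty = 2)
  invisible(cv)
}

#' Evaluate a fitted two-stage model on held-out data
#'
#' For each landmark `l`, the test set is landmarked at `l`, conditional
#' risks `1 - S(t)/S(l)` are computed at each horizon, and IPCW tdAUC and
#' Brier score (weighted by a censoring distribution fitted on the training
#' data) are reported; when the simulation truth is supplied the mean
#' squared error against the true conditional risk is added.
#'
#' @param object a fitted [dsa] model.
#' @param test a [longitudinal_data] evaluation set (disjoint subjects).
#' @param landmarks landmark times (default: the model's grid).
#' @param horizons horizon offsets ahead of each landmark.
#' @param G censoring distribution from [censoring_km()]; defaults to one
#'   fitted on the model's training outcomes.
#' @param truth optional `sim_truth` for MSE against the true risk.
#' @return data.frame with columns `landmark`, `horizon`, `metric`, `value`.
#' @export
evaluate_dsa <- function(object, test, landmarks = NULL,
                         horizons = seq(0.5, 5, by = 0.5), G = NULL,
                         truth = NULL) {
  if (is.null(landmarks)) landmarks <- object$landmarks
  if (is.null(G)) G <- censoring_km(object$train_time, object$train_event)
  rows <- list()
  for (l in landmarks) {
    lv <- suppressMessages(landmark(test, l))
    if (!n_subjects(lv)) next
    grid <- l + c(0, horizons)
    cv <- tryCatch(predict(object, test, l, grid), error = function(e) e)
    if (inherits(cv, "error")) {
      rows[[length(rows) + 1]] <- data.frame(landmark = l, horizon = NA_real_,
                                             metric = "error",
                                             value = NA_real_)
      next
    }
    tm <- lv$subjects$time; ev <- lv$subjects$event
    for (h in horizons) {
      t <- l + h
      r <- conditional_risk(cv, l, t)
      vals <- c(tdAUC = as.numeric(tdauc_ipcw(r, tm, ev, G, t)),
                Brier = brier_ipcw(r, tm, ev, G, t))
      if (!is.null(truth)) {
        rt <- tryCatch(true_conditional_risk(truth, lv$subjects$subject_id, l, t),
                       error = function(e) NULL)
        if (!is.null(rt)) vals <- c(vals, MSE = mse_vs_truth(r, rt))
      }
      rows[[length(rows) + 1]] <- data.frame(landmark = l, horizon = t,
                                             metric = names(vals),
                                             value = unname(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
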