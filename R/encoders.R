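#' Longitudinal encoders
#'
#' Stage-one models that summarize each subject's covariate history up to the
#' landmark into a fixed-length encoding `Z`. Constructors return an encoder
#' specification; [fit_encoder()] fits it to a (landmarked) training view and
#' [encode()] produces the per-subject encoding matrix.
#'
#' * `encoder_baseline()`: `Z = [B, Y(t0)]`, the baseline covariates and the
#'   first-visit longitudinal values; independent of the landmark.
#' * `encoder_last_visit()`: `Z = [B, Y(max t <= l)]`, the most recent
#'   available longitudinal values (the traditional landmarking covariate).
#'
#' Fitting records the training feature names and per-variable training means
#' used to fill values still missing after last-observation-carried-forward
#' (e.g. variables never observed for a subject), so encoding never leaks
#' evaluation data.
#'
#' @return an encoder specification of class `encoder_spec`.
#' @name encoders
NULL

#' @rdname encoders
#' @export
encoder_baseline <- function() {
  structure(list(type = "baseline"), class = c("encoder_baseline", "encoder_spec"))
}

#' @rdname encoders
#' @export
encoder_last_visit <- function() {
  structure(list(type = "last_visit"), class = c("encoder_last_visit", "encoder_spec"))
}

#' Fit an encoder to a training view
#'
#' @param spec an encoder specification (see [encoders], [encoder_mfpca()],
#'   [encoder_rnn()]).
#' @param data a `longitudinal_data` training view (landmarked, stacked or
#'   full, per the training strategy).
#' @param ... encoder-specific arguments.
#' @return a fitted encoder.
#' @export
fit_encoder <- function(spec, data, ...) UseMethod("fit_encoder")

#' Encode subjects with a fitted encoder
#'
#' @param object a fitted encoder returned by [fit_encoder()].
#' @param data a `longitudinal_data` view to encode.
#' @param ... unused.
#' @return numeric matrix with one row per subject (rownames are subject
#'   identifiers) and one named column per encoding feature.
#' @export
encode <- function(object, data, ...) UseMethod("encode")

## pooled training means per longitudinal variable (NA fallback imputation)
pooled_means <- function(data) {
  vapply(data$long_vars,
         function(q) mean(data$visits[[q]], na.rm = TRUE), numeric(1))
}

## baseline covariate matrix in subjects order
baseline_matrix <- function(data) {
  B <- as.matrix(data$subjects[, data$base_vars, drop = FALSE])
  rownames(B) <- data$subjects$subject_id
  storage.mode(B) <- "double"
  B
}

## longitudinal values at one visit per subject: pick = "first" | "last"
visit_values <- function(data, pick) {
  idx <- visit_index(data)
  rows <- vapply(idx, function(r) if (pick == "first") r[1] else r[length(r)],
                 integer(1))
  Y <- as.matrix(data$visits[rows, data$long_vars, drop = FALSE])
  rownames(Y) <- data$subjects$subject_id
  storage.mode(Y) <- "double"
  Y
}

fill_means <- function(Y, means) {
  for (j in seq_len(ncol(Y))) {
    nas <- is.na(Y[, j])
    if (any(nas)) Y[nas, j] <- means[colnames(Y)[j]]
  }
  Y
}

#' @export
fit_encoder.encoder_baseline <- function(spec, data, ...) {
  structure(list(spec = spec, base_vars = data$base_vars,
                 long_vars = data$long_vars, means = pooled_means(data)),
            class = c("fitted_baseline", "fitted_encoder"))
}

#' @export
fit_encoder.encoder_last_visit <- function(spec, data, ...) {
  structure(list(spec = spec, base_vars = data$base_vars,
                 long_vars = data$long_vars, means = pooled_means(data)),
            class = c("fitted_last_visit", "fitted_encoder"))
}

#' @export
encode.fitted_baseline <- function(object, data, ...) {
  Y <- fill_means(visit_values(data, "first"), object$means)
  colnames(Y) <- paste0(colnames(Y), "_t0")
  cbind(baseline_matrix(data), Y)
}

#' @export
encode.fitted_last_visit <- function(object, data, ...) {
  Y <- fill_means(visit_values(data, "last"), object$means)
  colnames(Y) <- paste0(colnames(Y), "_last")
  cbind(baseline_matrix(data), Y)
}

#' @export
print.fitted_encoder <- function(x, ...) {
  cat("<fitted ", class(x)[1], "> features from ",
      length(x$base_vars), " baseline + ", length(x$long_vars),
      " longitudinal variables\n", sep = "")
  invisible(x)
}
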