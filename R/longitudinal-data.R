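#' Longitudinal survival dataset
#'
#' Canonical in-memory container for longitudinal survival data: one row per
#' subject in `subjects` (identifier, observed time, event indicator and
#' baseline covariates) and one row per subject-visit in `visits` (identifier,
#' visit time and longitudinal covariate values, possibly missing).
#'
#' Invariants enforced: observed times are positive; visit times are strictly
#' increasing within subject; no visit falls after the subject's observed
#' time; every subject has at least one visit; the event indicator is 0/1.
#'
#' @param subjects data.frame with columns `subject_id`, `time`, `event` and
#'   one column per baseline covariate (numeric).
#' @param visits data.frame with columns `subject_id`, `visit_time` and one
#'   column per longitudinal covariate (numeric, `NA` allowed).
#' @param base_vars character vector naming the baseline covariate columns of
#'   `subjects`. Defaults to all columns other than `subject_id`, `time`,
#'   `event`.
#' @param long_vars character vector naming the longitudinal covariate columns
#'   of `visits`. Defaults to all columns other than `subject_id`,
#'   `visit_time`.
#' @param landmark landmark time associated with this view (`NA` for a full
#'   dataset).
#' @param strategy provenance tag, one of `"none"`, `"strict"`, `"super"`,
#'   `"random"`.
#' @return an object of class `longitudinal_data`.
#' @export
longitudinal_data <- function(subjects, visits,
                              base_vars = NULL, long_vars = NULL,
                              landmark = NA_real_, strategy = "none") {
  stopifnot(is.data.frame(subjects), is.data.frame(visits))
  req_s <- c("subject_id", "time", "event")
  req_v <- c("subject_id", "visit_time")
  miss <- setdiff(req_s, names(subjects))
  if (length(miss)) stop("subjects is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(req_v, names(visits))
  if (length(miss)) stop("visits is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(base_vars)) base_vars <- setdiff(names(subjects), req_s)
  if (is.null(long_vars)) long_vars <- setdiff(names(visits), req_v)
  subjects$subject_id <- as.character(subjects$subject_id)
  visits$subject_id <- as.character(visits$subject_id)

  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject_id in subjects table")
  if (nrow(subjects) && any(!is.finite(subjects$time) | subjects$time <= 0))
    stop("observed times must be positive and finite")
  if (nrow(subjects) && !all(subjects$event %in% c(0, 1)))
    stop("event indicator must be 0 or 1")
  if (!all(visits$subject_id %in% subjects$subject_id))
    stop("visits refer to unknown subject_id")

  ## sort visits by (subject in subjects order, time)
  ord <- order(match(visits$subject_id, subjects$subject_id), visits$visit_time)
  visits <- visits[ord, , drop = FALSE]
  rownames(visits) <- NULL
  rownames(subjects) <- NULL

  if (nrow(subjects)) {
    idx <- split(seq_len(nrow(visits)), factor(visits$subject_id, levels = subjects$subject_id))
    nv <- lengths(idx)
    if (any(nv == 0))
      stop("subject(s) without visits: ",
           paste(subjects$subject_id[nv == 0], collapse = ", "))
    for (i in seq_along(idx)) {
      tt <- visits$visit_time[idx[[i]]]
      if (anyDuplicated(tt) || is.unsorted(tt, strictly = TRUE))
        stop("visit times not strictly increasing for subject ", subjects$subject_id[i])
      if (tt[length(tt)] > subjects$time[i])
        stop("visit after observed time for subject ", subjects$subject_id[i])
    }
  }

  structure(list(subjects = subjects, visits = visits,
                 base_vars = base_vars, long_vars = long_vars,
                 landmark = landmark, strategy = strategy),
            class = "longitudinal_data")
}

#' @export
print.longitudinal_data <- function(x, ...) {
  cat("<longitudinal_data> ", nrow(x$subjects), " subjects, ",
      nrow(x$visits), " visits\n", sep = "")
  cat("  baseline covariates:    ", paste(x$base_vars, collapse = ", "), "\n", sep = "")
  cat("  longitudinal covariates:", paste(x$long_vars, collapse = ", "), "\n")
  cat("  events: ", sum(x$subjects$event), " (",
      round(100 * mean(x$subjects$event), 1), "%)\n", sep = "")
  if (!is.na(x$landmark))
    cat("  landmarked at ", x$landmark, " (strategy: ", x$strategy, ")\n", sep = "")
  invisible(x)
}

#' Number of subjects / visits per subject
#' @param ds a `longitudinal_data` object.
#' @return `n_subjects`: integer count. `n_visits`: named integer vector.
#' @export
n_subjects <- function(ds) nrow(ds$subjects)

#' @rdname n_subjects
#' @export
n_visits <- function(ds) {
  tab <- table(factor(ds$visits$subject_id, levels = ds$subjects$subject_id))
  stats::setNames(as.integer(tab), ds$subjects$subject_id)
}

## internal: split visit row indices by subject, in subjects order
visit_index <- function(ds) {
  split(seq_len(nrow(ds$visits)),
        factor(ds$visits$subject_id, levels = ds$subjects$subject_id))
}

#' Last observation carried forward
#'
#' Replaces each missing longitudinal value by the most recent non-missing
#' value of the same variable for the same subject. Values missing at all
#' visits up to a given visit remain missing (they are imputed with training
#' means at encoding time).
#'
#' @param ds a `longitudinal_data` object.
#' @return a `longitudinal_data` object with gaps filled forward.
#' @export
locf_impute <- function(ds) {
  v <- ds$visits
  idx <- visit_index(ds)
  for (q in ds$long_vars) {
    col <- v[[q]]
    if (!anyNA(col)) next
    for (rows in idx) {
      y <- col[rows]
      if (!anyNA(y)) next
      ok <- !is.na(y)
      if (!any(ok)) next
      ## index of last non-missing value at or before each position
      last <- cummax(ifelse(ok, seq_along(y), 0L))
      fill <- last > 0L
      y[fill] <- y[ok][cumsum(ok)[fill]]
      col[rows] <- y
    }
    v[[q]] <- col
  }
  ds$visits <- v
  ds
}

#' Subject-level k-fold split
#'
#' Partitions subjects into `k` disjoint folds, deterministically under
#' `seed`, and returns train/test dataset pairs.
#'
#' @param ds a `longitudinal_data` object.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the permutation.
#' @return list of `k` lists with elements `train` and `test`.
#' @export
kfold_split <- function(ds, k, seed) {
  n <- n_subjects(ds)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of subjects")
  ids <- ds$subjects$subject_id
  set.seed(seed)
  shuffled <- sample(ids)
  fold <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    test_ids <- shuffled[fold == f]
    list(train = subset_subjects(ds, setdiff(ids, test_ids)),
         test = subset_subjects(ds, intersect(ids, test_ids)))
  })
}

#' Restrict a dataset to a set of subjects
#' @param ds a `longitudinal_data` object.
#' @param ids subject identifiers to keep (order preserved as given).
#' @return a `longitudinal_data` object.
#' @export
subset_subjects <- function(ds, ids) {
  ids <- as.character(ids)
  keep_s <- ds$subjects[match(ids, ds$subjects$subject_id), , drop = FALSE]
  if (anyNA(keep_s$subject_id)) stop("unknown subject_id in ids")
  keep_v <- ds$visits[ds$visits$subject_id %in% ids, , drop = FALSE]
  longitudinal_data(keep_s, keep_v, ds$base_vars, ds$long_vars,
                    landmark = ds$landmark, strategy = ds$strategy)
}
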