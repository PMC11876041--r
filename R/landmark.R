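#' Landmark a dataset at time l
#'
#' Restricts the data to subjects still at risk at the landmark: subjects
#' with observed time `T_i <= l` are removed, visits after `l` are removed
#' (visits at exactly `l` are kept), and subjects whose first visit falls
#' after `l` are dropped (with a message reporting the count).
#'
#' @param ds a `longitudinal_data` object.
#' @param l landmark time (>= 0).
#' @return a `longitudinal_data` object tagged with the landmark.
#' @export
landmark <- function(ds, l) {
  stopifnot(is.numeric(l), length(l) == 1, l >= 0)
  at_risk <- ds$subjects$time > l
  if (!any(at_risk)) {
    warning("no subjects at risk at landmark ", l)
  }
  keep_ids <- ds$subjects$subject_id[at_risk]
  v <- ds$visits[ds$visits$subject_id %in% keep_ids & ds$visits$visit_time <= l, ,
                 drop = FALSE]
  has_visit <- keep_ids %in% v$subject_id
  if (any(!has_visit)) {
    message(sum(!has_visit), " subject(s) without pre-landmark visits dropped at l = ", l)
    keep_ids <- keep_ids[has_visit]
  }
  s <- ds$subjects[ds$subjects$subject_id %in% keep_ids, , drop = FALSE]
  longitudinal_data(s, v[v$subject_id %in% keep_ids, , drop = FALSE],
                    ds$base_vars, ds$long_vars,
                    landmark = l, strategy = "strict")
}

#' Stacked (super) landmark dataset
#'
#' Concatenates `landmark(ds, l)` over a grid of landmarks: a subject appears
#' once per landmark at which it is still at risk, with its history truncated
#' at that landmark. Replicates carry identifiers `"<id>@<l>"`; the original
#' identifier and the per-replicate landmark are stored in the `source_id`
#' and `entry_landmark` columns of `subjects`.
#'
#' @param ds a `longitudinal_data` object.
#' @param landmarks sorted vector of distinct landmark times.
#' @return a `longitudinal_data` object with `strategy = "super"`.
#' @export
super_landmark <- function(ds, landmarks) {
  if (!length(landmarks)) stop("landmarks must be non-empty")
  if (anyDuplicated(landmarks)) stop("duplicate landmark values")
  landmarks <- sort(landmarks)
  parts <- lapply(landmarks, function(l) {
    lv <- suppressMessages(landmark(ds, l))
    s <- lv$subjects
    if (!nrow(s)) return(NULL)
    v <- lv$visits
    s$source_id <- s$subject_id
    s$entry_landmark <- l
    new_id <- paste0(s$subject_id, "@", l)
    v$subject_id <- paste0(v$subject_id, "@", l)
    s$subject_id <- new_id
    list(s = s, v = v)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stop("no subjects at risk at any landmark")
  subjects <- do.call(rbind, lapply(parts, `[[`, "s"))
  visits <- do.call(rbind, lapply(parts, `[[`, "v"))
  out <- longitudinal_data(subjects, visits, ds$base_vars, ds$long_vars,
                           landmark = NA_real_, strategy = "super")
  out
}

#' Random truncation of visit histories
#'
#' For each subject independently draws a visit count `l ~ Uniform{1, ...,
#' J_i}` and truncates the subject's history to its first `l` visits. Event
#' times, indicators and baseline covariates are unchanged. Uses the current
#' RNG state, so repeated calls give fresh truncations (intended to be called
#' once per training epoch); seed the RNG for reproducibility.
#'
#' @param ds a `longitudinal_data` object.
#' @return a `longitudinal_data` object with `strategy = "random"`. The
#'   per-subject truncation landmark (time of the last retained visit) is
#'   stored in the `entry_landmark` column of `subjects`.
#' @export
random_truncate <- function(ds) {
  idx <- visit_index(ds)
  nv <- lengths(idx)
  l <- 1L + as.integer(floor(stats::runif(length(nv)) * nv))
  l <- pmin(l, nv)  # guard against runif returning exactly 1
  keep <- unlist(mapply(function(rows, k) rows[seq_len(k)], idx, l,
                        SIMPLIFY = FALSE), use.names = FALSE)
  v <- ds$visits[sort(keep), , drop = FALSE]
  s <- ds$subjects
  last_t <- vapply(split(v$visit_time, factor(v$subject_id, levels = s$subject_id)),
                   max, numeric(1))
  s$entry_landmark <- unname(last_t)
  longitudinal_data(s, v, ds$base_vars, ds$long_vars,
                    landmark = NA_real_, strategy = "random")
}
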