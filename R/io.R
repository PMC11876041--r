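#' Read a long-format longitudinal survival table
#'
#' Reads a delimited text file with one row per subject-visit and assembles a
#' [longitudinal_data] object. Baseline covariates must be constant within
#' subject; character/factor baseline columns are one-hot encoded with the
#' first (alphabetically sorted) level dropped, which keeps the design
#' deterministic and identifiable for proportional-hazards fitting.
#'
#' @param path file path of a comma-separated, UTF-8 text file with a header
#'   row; missing values are empty fields.
#' @param schema named list mapping roles to column names: `id`, `time`
#'   (visit time), `event_time`, `event`, and character vectors `baseline`
#'   and `longitudinal`. When `NULL`, columns named `subject_id`,
#'   `visit_time`, `event_time`, `event` are used, columns prefixed
#'   `base_` are baseline and columns prefixed `long_` are longitudinal.
#' @return a `longitudinal_data` object.
#' @export
read_long_table <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  strip_prefix <- FALSE
  if (is.null(schema)) {
    schema <- list(id = "subject_id", time = "visit_time",
                   event_time = "event_time", event = "event",
                   baseline = grep("^base_", names(df), value = TRUE),
                   longitudinal = grep("^long_", names(df), value = TRUE))
    strip_prefix <- TRUE
  }
  need <- c(schema$id, schema$time, schema$event_time, schema$event,
            schema$baseline, schema$longitudinal)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))

  id <- as.character(df[[schema$id]])
  if (anyDuplicated(paste(id, df[[schema$time]])))
    stop("duplicated (id, time) rows in ", path)

  first <- !duplicated(id)
  subjects <- data.frame(subject_id = id[first],
                         time = df[[schema$event_time]][first],
                         event = df[[schema$event]][first],
                         stringsAsFactors = FALSE)
  out_name <- function(x, prefix) if (strip_prefix) sub(prefix, "", x) else x
  for (b in schema$baseline) {
    col <- df[[b]][first]
    nm <- out_name(b, "^base_")
    if (is.character(col) || is.factor(col)) {
      col <- as.character(col)
      lev <- sort(unique(col))
      for (lv in lev[-1])
        subjects[[paste0(nm, "_", lv)]] <- as.numeric(col == lv)
    } else {
      subjects[[nm]] <- col
    }
  }
  visits <- data.frame(subject_id = id, visit_time = df[[schema$time]],
                       stringsAsFactors = FALSE)
  for (q in schema$longitudinal) visits[[out_name(q, "^long_")]] <- df[[q]]
  longitudinal_data(subjects, visits)
}

#' Write a longitudinal survival dataset as a long-format table
#'
#' Inverse of [read_long_table()]: one row per subject-visit, baseline values
#' repeated on every row. Numeric fields are written with 17 significant
#' digits so that a read/write round trip is exact.
#'
#' @param ds a `longitudinal_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(ds, path) {
  m <- match(ds$visits$subject_id, ds$subjects$subject_id)
  df <- data.frame(subject_id = ds$visits$subject_id,
                   visit_time = ds$visits$visit_time,
                   event_time = ds$subjects$time[m],
                   event = ds$subjects$event[m],
                   stringsAsFactors = FALSE)
  for (b in ds$base_vars) df[[paste0("base_", b)]] <- ds$subjects[[b]][m]
  for (q in ds$long_vars) df[[paste0("long_", q)]] <- ds$visits[[q]]
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    s <- sprintf("%.17g", df[[j]])
    s[is.na(df[[j]])] <- NA
    df[[j]] <- s
  }
  utils::write.table(df, path, sep = ",", qmethod = "double",
                     row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
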