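#' Fit and evaluate one two-stage pipeline
#'
#' Thin wrapper tying [dsa()] and [evaluate_dsa()] together: fits the
#' encoder/head/strategy cell on `train`, builds the censoring distribution
#' from the training outcomes, and evaluates on `test` at every landmark and
#' horizon.
#'
#' @param train,test disjoint [longitudinal_data] sets.
#' @param encoder encoder specification.
#' @param head `"cox"`, `"rsf"` or `"nn"`.
#' @param strategy training landmarking strategy.
#' @param landmarks landmark grid.
#' @param horizons horizon offsets.
#' @param truth optional `sim_truth` for the evaluation set.
#' @param seed seed for stochastic components.
#' @param ... passed to [dsa()].
#' @return data.frame of metrics with identification columns prepended.
#' @export
run_two_stage <- function(train, test, encoder, head, strategy,
                          landmarks = c(1, 2, 3, 4),
                          horizons = seq(0.5, 5, by = 0.5),
                          truth = NULL, seed = 1, ...) {
  if (length(intersect(train$subjects$subject_id, test$subjects$subject_id)))
    stop("train and test share subjects")
  fit <- dsa(train, encoder = encoder, head = head, strategy = strategy,
             landmarks = landmarks, seed = seed, ...)
  res <- evaluate_dsa(fit, test, landmarks, horizons, truth = truth)
  cbind(data.frame(encoder = class(encoder)[1], head = head,
                   strategy = strategy, stringsAsFactors = FALSE), res)
}

#' Replicated simulation study
#'
#' For each scenario: draws one shared evaluation set and `replicates`
#' independent training sets, fits every (encoder, head, strategy) cell on
#' each training set and evaluates it on the shared evaluation set. Failed
#' cells are recorded (metric `"error"`) and the study continues.
#'
#' @param scenarios integer vector of scenario ids (1..4).
#' @param cells list of cells; each cell is a list with elements `encoder`
#'   (a specification), `head` and `strategy`.
#' @param n_train training-set size per replicate.
#' @param replicates number of training replicates.
#' @param n_eval evaluation-set size (shared across replicates).
#' @param landmarks,horizons evaluation grid.
#' @param seed master seed; replicate and cell seeds are derived from it.
#' @param ... passed to [dsa()].
#' @return data.frame with columns `scenario`, `replicate`, cell ids,
#'   `landmark`, `horizon`, `metric`, `value`.
#' @export
run_simulation_study <- function(scenarios, cells, n_train = 1000,
                                 replicates = 10, n_eval = 3000,
                                 landmarks = c(1, 2, 3, 4),
                                 horizons = seq(0.5, 5, by = 0.5),
                                 seed = 1, ...) {
  out <- list()
  for (sc in scenarios) {
    eval_sim <- simulate_scenario(sc, n_subjects = n_eval,
                                  seed = seed * 101 + sc)
    eval_data <- relabel_subjects(eval_sim$data, prefix = "e")
    eval_truth <- relabel_truth(eval_sim$truth, prefix = "e")
    for (rep in seq_len(replicates)) {
      train <- simulate_scenario(sc, n_subjects = n_train,
                                 seed = seed * 7919 + sc * 613 + rep)$data
      for (ci in seq_along(cells)) {
        cell <- cells[[ci]]
        cell_seed <- seed + 31L * rep + ci
        res <- tryCatch(
          run_two_stage(train, eval_data, cell$encoder, cell$head,
                        cell$strategy, landmarks, horizons,
                        truth = eval_truth, seed = cell_seed, ...),
          error = function(e) data.frame(
            encoder = class(cell$encoder)[1], head = cell$head,
            strategy = cell$strategy, landmark = NA_real_,
            horizon = NA_real_, metric = "error", value = NA_real_))
        out[[length(out) + 1]] <- cbind(
          data.frame(scenario = sc, replicate = rep), res)
      }
    }
  }
  do.call(rbind, out)
}

relabel_subjects <- function(data, prefix) {
  data$subjects$subject_id <- paste0(prefix, data$subjects$subject_id)
  data$visits$subject_id <- paste0(prefix, data$visits$subject_id)
  data
}

relabel_truth <- function(truth, prefix) {
  truth$subject_id <- paste0(prefix, truth$subject_id)
  truth
}

#' Aggregate study metrics across replicates or folds
#'
#' @param results output of [run_simulation_study()] or
#'   [run_crossval_study()].
#' @return data.frame with mean and SD per cell, landmark, horizon and
#'   metric (the error-bar convention of the study figures).
#' @export
aggregate_metrics <- function(results) {
  res <- results[results$metric != "error" & !is.na(results$value), ]
  key <- c(intersect(c("scenario", "encoder", "head", "strategy"), names(res)),
           "landmark", "horizon", "metric")
  agg_m <- stats::aggregate(res$value, res[key], mean)
  agg_s <- stats::aggregate(res$value, res[key], stats::sd)
  names(agg_m)[ncol(agg_m)] <- "mean"
  agg_m$sd <- agg_s$x
  agg_m
}

#' Cross-validated cohort study
#'
#' Subject-level k-fold cross validation: every cell is fitted on k-1 folds
#' and evaluated on the held-out fold; the censoring distribution is always
#' estimated on the training folds only.
#'
#' @param data a [longitudinal_data] cohort.
#' @param k number of folds.
#' @param cells list of (encoder, head, strategy) cells.
#' @param landmarks,horizons evaluation grid.
#' @param seed seed (fold assignment and stochastic cells).
#' @param ... passed to [dsa()].
#' @return data.frame with a `fold` column.
#' @export
run_crossval_study <- function(data, k = 10, cells,
                               landmarks = c(1, 2, 3, 4),
                               horizons = seq(0.5, 5, by = 0.5),
                               seed = 1, ...) {
  folds <- kfold_split(data, k, seed)
  out <- list()
  for (f in seq_len(k)) {
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      res <- tryCatch(
        run_two_stage(folds[[f]]$train, folds[[f]]$test, cell$encoder,
                      cell$head, cell$strategy, landmarks, horizons,
                      seed = seed + 31L * f + ci, ...),
        error = function(e) data.frame(
          encoder = class(cell$encoder)[1], head = cell$head,
          strategy = cell$strategy, landmark = NA_real_,
          horizon = NA_real_, metric = "error", value = NA_real_))
      out[[length(out) + 1]] <- cbind(data.frame(fold = f), res)
    }
  }
  do.call(rbind, out)
}

#' Random hyperparameter search
#'
#' Draws `n_draws` hyperparameter sets from the given sampling space, trains
#' each on 80% of the training subjects, scores it by mean tdAUC on the
#' remaining 20%, and returns the best configuration. Test data must be kept
#' outside this function entirely; only the winning configuration should be
#' refitted and evaluated once.
#'
#' @param data training [longitudinal_data].
#' @param space named list; each element is either a vector of candidate
#'   values or a function `function(n)` returning `n` sampled values. Names
#'   are matched against arguments of the encoder specification first, then
#'   the head arguments.
#' @param build function `function(params)` returning the list
#'   `list(encoder = , head = , strategy = , head_args = )` for one sampled
#'   parameter set.
#' @param n_draws number of sampled configurations.
#' @param landmarks,horizons validation evaluation grid.
#' @param seed seed (sampling, split, training).
#' @param ... passed to [dsa()].
#' @return list with `best` (the winning parameter set), `score`, and
#'   `trace` (a data.frame of all draws and their validation scores).
#' @export
random_hyperparameter_search <- function(data, space, build, n_draws = 100,
                                         landmarks = c(1, 2, 3, 4),
                                         horizons = seq(0.5, 5, by = 0.5),
                                         seed = 1, ...) {
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i)
    lapply(space, function(s) if (is.function(s)) s(1) else
      s[[sample.int(length(s), 1)]]))
  if (all(vapply(space, function(s) !is.function(s) && length(s) == 1, logical(1))))
    warning("degenerate search space: a single configuration")
  ids <- data$subjects$subject_id
  n_val <- max(1L, round(0.2 * length(ids)))
  val_ids <- sample(ids, n_val)
  train <- subset_subjects(data, setdiff(ids, val_ids))
  valid <- subset_subjects(data, val_ids)
  scores <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    cfg <- build(draws[[i]])
    res <- tryCatch(
      run_two_stage(train, valid, cfg$encoder, cfg$head, cfg$strategy,
                    landmarks, horizons, seed = seed + i,
                    head_args = if (is.null(cfg$head_args)) list() else cfg$head_args,
                    ...),
      error = function(e) NULL)
    scores[i] <- if (is.null(res)) NA_real_ else
      mean(res$value[res$metric == "tdAUC"], na.rm = TRUE)
  }
  best <- which.max(scores)
  trace <- data.frame(draw = seq_len(n_draws), score = scores)
  list(best = draws[[best]], score = scores[best], trace = trace)
}
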