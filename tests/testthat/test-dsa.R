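test_that("super landmarking with one landmark reduces to strict", {
  sp <- sim_pair(1, 150, 200, seed = 81)
  m1 <- run_two_stage(sp$train, sp$eval, encoder_baseline(), "cox", "strict",
                      landmarks = 2, horizons = c(1, 2), truth = sp$truth)
  m2 <- run_two_stage(sp$train, sp$eval, encoder_baseline(), "cox", "super",
                      landmarks = 2, horizons = c(1, 2), truth = sp$truth)
  expect_equal(m1$value, m2$value, tolerance = 1e-10)
})

test_that("pipelines are reproducible under a seed", {
  sp <- sim_pair(1, 120, 150, seed = 82)
  for (cell in list(list(enc = encoder_last_visit(), head = "rsf"),
                    list(enc = encoder_rnn(mode = "long_only", epochs = 3),
                         head = "nn"))) {
    a <- run_two_stage(sp$train, sp$eval, cell$enc, cell$head, "none",
                       landmarks = 2, horizons = 2, seed = 9,
                       head_args = if (cell$head == "rsf") list(n_trees = 30)
                                   else list(epochs = 5))
    b <- run_two_stage(sp$train, sp$eval, cell$enc, cell$head, "none",
                       landmarks = 2, horizons = 2, seed = 9,
                       head_args = if (cell$head == "rsf") list(n_trees = 30)
                                   else list(epochs = 5))
    expect_equal(a$value, b$value, tolerance = 1e-12)
  }
})

test_that("train/test overlap and invalid strategy pairings are rejected", {
  sp <- sim_pair(1, 60, 60, seed = 83)
  expect_error(run_two_stage(sp$train, sp$train, encoder_baseline(), "cox",
                             "none", landmarks = 1, horizons = 1),
               "share subjects")
  expect_error(dsa(sp$train, encoder_baseline(), head = "cox",
                   strategy = "random"), "requires an iteratively trained")
})

test_that("strict prediction is only available at fitted landmarks", {
  sp <- sim_pair(1, 100, 100, seed = 84)
  fit <- dsa(sp$train, encoder_baseline(), head = "cox", strategy = "strict",
             landmarks = c(1, 2))
  expect_s3_class(predict(fit, sp$eval, 1), "survival_curves")
  expect_error(predict(fit, sp$eval, 3), "no pipeline fitted at landmark 3")
})

test_that("model object methods work", {
  sp <- sim_pair(1, 100, 100, seed = 85)
  fit <- dsa(sp$train, encoder_baseline(), head = "cox", strategy = "strict",
             landmarks = c(1, 2))
  expect_output(print(fit), "two-stage")
  expect_output(summary(fit), "coefficients")
  cf <- coef(fit)
  expect_named(cf, c("l=1", "l=2"))
  expect_true(all(is.finite(cf[["l=1"]])))
  pdf(NULL)
  cv <- plot(fit, sp$eval, landmark = 1)
  dev.off()
  expect_s3_class(cv, "survival_curves")
})

test_that("a reduced simulation study runs end to end with shared evaluation", {
  cells <- list(list(encoder = encoder_baseline(), head = "cox",
                     strategy = "strict"),
                list(encoder = encoder_last_visit(), head = "cox",
                     strategy = "super"))
  res <- run_simulation_study(1, cells, n_train = 120, replicates = 2,
                              n_eval = 200, landmarks = c(1, 2),
                              horizons = c(1, 2), seed = 5)
  expect_setequal(unique(res$replicate), 1:2)
  expect_true(all(c("tdAUC", "Brier", "MSE") %in% res$metric))
  ## 2 replicates -> 2 rows per realized (cell, landmark, horizon, metric)
  cnt <- with(res[res$metric == "MSE", ],
              table(encoder, landmark, horizon))
  expect_true(all(cnt[cnt > 0] == 2))
  ## every cell evaluated at both horizons past each landmark
  mse <- res[res$metric == "MSE", ]
  for (l in c(1, 2)) expect_setequal(mse$horizon[mse$landmark == l], l + c(1, 2))
  agg <- aggregate_metrics(res)
  expect_true(all(c("mean", "sd") %in% names(agg)))
})

test_that("cross-validation keeps folds disjoint and labels rows", {
  ds <- simulate_scenario(1, n_subjects = 80, seed = 86)$data
  cells <- list(list(encoder = encoder_baseline(), head = "cox",
                     strategy = "strict"))
  res <- run_crossval_study(ds, k = 2, cells, landmarks = 1, horizons = c(1, 2),
                            seed = 3)
  expect_setequal(unique(res$fold), 1:2)
  expect_true(all(res$metric %in% c("tdAUC", "Brier", "error")))
})

test_that("a degenerate search space returns the defaults with a warning", {
  ds <- simulate_scenario(1, n_subjects = 100, seed = 87)$data
  space <- list(n_trees = 40)
  build <- function(p) list(encoder = encoder_last_visit(), head = "rsf",
                            strategy = "strict",
                            head_args = list(n_trees = p$n_trees))
  expect_warning(
    out <- random_hyperparameter_search(ds, space, build, n_draws = 2,
                                        landmarks = 2, horizons = c(1, 2),
                                        seed = 4),
    "degenerate")
  expect_equal(out$best$n_trees, 40)
  expect_equal(nrow(out$trace), 2)
  expect_true(is.finite(out$score))
})

test_that("hyperparameter draws are reproducible under a seed", {
  ds <- simulate_scenario(1, n_subjects = 80, seed = 88)$data
  space <- list(n_trees = c(10, 20, 40, 80))
  build <- function(p) list(encoder = encoder_last_visit(), head = "rsf",
                            strategy = "strict",
                            head_args = list(n_trees = p$n_trees))
  a <- random_hyperparameter_search(ds, space, build, n_draws = 3,
                                    landmarks = 2, horizons = 2, seed = 6)
  b <- random_hyperparameter_search(ds, space, build, n_draws = 3,
                                    landmarks = 2, horizons = 2, seed = 6)
  expect_identical(a$best, b$best)
  expect_equal(a$trace$score, b$trace$score, tolerance = 1e-12)
})
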