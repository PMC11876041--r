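test_that("censoring KM matches the hand computation", {
  G <- censoring_km(c(1, 2, 3), c(1, 0, 1))
  ## censoring event at t = 2 with risk set {2, 3}: G = 1 on [0,2), 0.5 after
  expect_equal(eval_censoring(G, c(0.5, 1.5, 1.99)), c(1, 1, 1))
  expect_equal(eval_censoring(G, c(2, 2.5, 10)), c(0.5, 0.5, 0.5))
  expect_equal(eval_censoring(G, 2, left = TRUE), 1)
  ## no censored subjects: G == 1 everywhere before the last time
  G1 <- censoring_km(c(1, 2, 3), c(1, 1, 1))
  expect_equal(eval_censoring(G1, c(0.5, 1, 2.5)), c(1, 1, 1))
})

test_that("conditional risk follows the definition", {
  cv <- survival_curves(c("i", "j"), c(1, 3), rbind(c(0.8, 0.6), c(0.5, 0.5)))
  r <- conditional_risk(cv, 1, 3)
  expect_equal(unname(r), c(1 - 0.6 / 0.8, 0))
  expect_equal(unname(conditional_risk(cv, 1, 1)), c(0, 0))
  cv0 <- survival_curves("k", c(1, 3), rbind(c(0, 0)))
  expect_warning(r0 <- conditional_risk(cv0, 1, 3), "S\\(l\\) = 0")
  expect_true(is.na(r0))
})

test_that("IPCW metrics equal brute-force evaluation on a censored toy", {
  time <- c(0.5, 1.2, 2.5, 3.0, 1.8, 4.0)
  event <- c(1, 1, 0, 1, 1, 0)
  risk <- c(0.9, 0.7, 0.3, 0.6, 0.7, 0.1)
  G <- censoring_km(time, event)
  Gfun <- function(s) eval_censoring(G, s, left = TRUE)
  t <- 2
  expect_equal(tdauc_ipcw(risk, time, event, G, t),
               brute_tdauc(risk, time, event, Gfun, t), tolerance = 1e-12)
  expect_equal(tdauc_ipcw(risk, time, event, G, t, strict_ties = TRUE),
               brute_tdauc(risk, time, event, Gfun, t, strict = TRUE),
               tolerance = 1e-12)
  expect_equal(brier_ipcw(risk, time, event, G, t),
               brute_brier(risk, time, event, Gfun, eval_censoring(G, t), t),
               tolerance = 1e-12)
})

test_that("with zero censoring the IPCW metrics reduce to the classics", {
  set.seed(71)
  n <- 60
  time <- rexp(n, 0.4); event <- rep(1L, n)
  risk <- runif(n)
  G <- censoring_km(time, event)
  t <- stats::median(time)
  y <- as.integer(time <= t)
  ## naive AUC with half-credit ties
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  auc <- mean(ifelse(risk[pairs$i] > risk[pairs$j], 1,
                     ifelse(risk[pairs$i] == risk[pairs$j], 0.5, 0)))
  expect_equal(tdauc_ipcw(risk, time, event, G, t), auc, tolerance = 1e-12)
  expect_equal(brier_ipcw(risk, time, event, G, t), mean((y - risk)^2),
               tolerance = 1e-12)
  ## perfect and reversed ranking
  r2 <- ifelse(y == 1, 0.9, 0.1)
  expect_equal(tdauc_ipcw(r2, time, event, G, t), 1)
  expect_equal(tdauc_ipcw(1 - r2, time, event, G, t), 0)
  expect_equal(brier_ipcw(y, time, event, G, t), 0)
  expect_equal(brier_ipcw(rep(0.5, n), time, event, G, t), 0.25)
})

test_that("degenerate horizons return NA with a reason", {
  G <- censoring_km(c(1, 2), c(1, 1))
  out <- tdauc_ipcw(c(0.2, 0.4), c(1, 2), c(1, 1), G, t = 5)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "no controls")
})

test_that("duplicating subjects leaves both IPCW metrics unchanged", {
  time <- c(0.5, 1.2, 2.5, 3.0, 1.8, 4.0)
  event <- c(1, 1, 0, 1, 1, 0)
  risk <- c(0.9, 0.7, 0.3, 0.6, 0.7, 0.1)
  G <- censoring_km(time, event)
  d <- rep(seq_along(time), 2)
  G2 <- censoring_km(time[d], event[d])
  expect_equal(tdauc_ipcw(risk[d], time[d], event[d], G2, 2),
               tdauc_ipcw(risk, time, event, G, 2), tolerance = 1e-12)
  expect_equal(brier_ipcw(risk[d], time[d], event[d], G2, 2),
               brier_ipcw(risk, time, event, G, 2), tolerance = 1e-12)
})

test_that("MSE against the truth follows the definition", {
  r <- c(0.2, 0.4, 0.6, 0.8, 0.5)
  expect_equal(mse_vs_truth(r, r), 0)
  expect_equal(mse_vs_truth(r + 0.1, r), 0.01, tolerance = 1e-12)
  true <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(mse_vs_truth(r, true), mean((true - r)^2))
  expect_error(mse_vs_truth(r, true[-1]), "length")
})

test_that("oracle risks dominate fitted models and have zero MSE", {
  sp <- sim_pair(1, 300, 600, seed = 72)
  fit <- dsa(sp$train, encoder_baseline(), head = "cox", strategy = "strict",
             landmarks = c(1, 2))
  G <- censoring_km(sp$train$subjects$time, sp$train$subjects$event)
  orc <- oracle_reference_metrics(sp$truth, sp$eval, landmarks = c(1, 2),
                                  horizons = c(1, 2), G = G)
  expect_true(all(orc$value[orc$metric == "MSE"] == 0))
  expect_true(all(orc$value[orc$metric == "Brier"] > 0))
  mod <- evaluate_dsa(fit, sp$eval, landmarks = c(1, 2), horizons = c(1, 2),
                      G = G, truth = sp$truth)
  for (l in c(1, 2)) for (h in c(1, 2)) {
    a_o <- orc$value[orc$metric == "tdAUC" & orc$landmark == l &
                     orc$horizon == l + h]
    a_m <- mod$value[mod$metric == "tdAUC" & mod$landmark == l &
                     mod$horizon == l + h]
    expect_gte(a_o, a_m - 0.03)       # ceiling up to Monte-Carlo noise
  }
})

test_that("conditional risk from true curves equals the simulator truth", {
  r <- simulate_scenario(1, n_subjects = 30, seed = 73)
  tru <- r$truth
  cv <- survival_curves(tru$subject_id, tru$grid, tru$survival)
  expect_equal(conditional_risk(cv, 2, 4),
               true_conditional_risk(tru, l = 2, t = 4), tolerance = 1e-12)
})
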