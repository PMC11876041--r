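## dense rank-1 functional data with a known eigenstructure
rank1_data <- function(n = 150, noise = 0, seed = 21) {
  set.seed(seed)
  grid <- seq(0, 10, by = 0.5)
  phi <- sin(pi * grid / 10)
  w <- c(0.25, rep(0.5, 19), 0.25)                # trapezoid weights
  phi <- phi / sqrt(sum(phi^2 * w))               # unit L2 norm
  xi <- rnorm(n)
  xi <- (xi - mean(xi)) / sd(xi) * 2              # exact score variance 4
  Y <- 5 + outer(xi, phi) + matrix(rnorm(n * length(grid), 0, noise),
                                   n, length(grid))
  subjects <- data.frame(subject_id = sprintf("r%03d", 1:n),
                         time = 11, event = 0, z1 = 0)
  visits <- data.frame(subject_id = rep(subjects$subject_id, each = length(grid)),
                       visit_time = rep(grid, n),
                       y1 = as.vector(t(Y)))
  list(data = longitudinal_data(subjects, visits), phi = phi, xi = xi,
       grid = grid, w = w, mu = rep(5, length(grid)))
}

test_that("rank-1 data recovers the leading eigenvalue and eigenfunction", {
  rd <- rank1_data(noise = 0.05)
  fit <- dynland:::pace_fit(rd$data$visits$subject_id,
                            rd$data$visits$visit_time,
                            rd$data$visits$y1, grid_size = 51,
                            pve_uni = 0.99)
  expect_equal(fit$lambda[1], 4, tolerance = 0.05)
  expect_gt(abs(cor(fit$phi[, 1], rd$phi)), 0.99)
  expect_gt(fit$lambda[1] / sum(fit$lambda), 0.95)
})

test_that("conditional-expectation scores match quadrature scores on dense data", {
  rd <- rank1_data(noise = 0.05)
  fit <- dynland:::pace_fit(rd$data$visits$subject_id,
                            rd$data$visits$visit_time,
                            rd$data$visits$y1, 51, 0.99)
  idx <- split(seq_len(nrow(rd$data$visits)),
               factor(rd$data$visits$subject_id,
                      levels = rd$data$subjects$subject_id))
  pace <- vapply(idx, function(rows)
    dynland:::pace_scores(fit, rd$data$visits$visit_time[rows],
                          rd$data$visits$y1[rows])[1], numeric(1))
  quad <- vapply(idx, function(rows) {
    y <- rd$data$visits$y1[rows]
    sum((y - fit$mu) * fit$phi[, 1] * rd$w)
  }, numeric(1))
  expect_gt(cor(pace, quad), 0.99)
  expect_gt(abs(cor(pace, rd$xi)), 0.99)          # recovers generating scores
})

test_that("truncation shrinks conditional scores toward zero", {
  ## explicit Gaussian conditioning on a 2-point grid: one observation gives
  ## xi_hat = lambda phi1 (lambda phi1^2 + s2)^{-1} (y - mu), strictly smaller
  ## in magnitude than the 2-observation estimate for the same trajectory
  model <- list(grid = c(0, 1), mu = c(0, 0),
                phi = matrix(c(1, 1), 2, 1) / sqrt(1),
                lambda = 4, sigma2 = 0.5)
  y <- c(2, 2.2)
  full <- dynland:::pace_scores(model, c(0, 1), y)
  one <- dynland:::pace_scores(model, 0, y[1])
  ## oracle: hand-computed Gaussian conditional expectations
  Phi <- model$phi
  Sig2 <- Phi %*% (4 * t(Phi)) + diag(0.5, 2)
  expect_equal(full, drop(4 * t(Phi) %*% solve(Sig2, y)), tolerance = 1e-12)
  expect_equal(one, 4 * 1 / (4 + 0.5) * y[1], tolerance = 1e-12)
  expect_lt(abs(one) / abs(full), 1)
})

test_that("reconstruction error is non-increasing in the component count", {
  sim <- simulate_scenario(3, n_subjects = 80, seed = 22)$data
  enc <- fit_encoder(encoder_mfpca(pve_univariate = 0.999), sim)
  m <- enc$univariate[["y1"]]
  errs <- vapply(0:length(m$lambda), function(k) {
    fit <- mfpca_reconstruct(enc, sim, "y1", k)
    mean((fit - sim$visits$y1)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("constant variables contribute zero components with a warning", {
  ds <- toy_dataset()
  ds$visits$y2 <- 1
  expect_warning(enc <- fit_encoder(encoder_mfpca(), ds), "zero variance")
  expect_length(enc$univariate[["y2"]]$lambda, 0)
})

test_that("encoding has the contracted dimension and retains 95% variance", {
  sim <- simulate_scenario(1, n_subjects = 120, seed = 23)$data
  lv <- landmark(sim, 3)
  enc <- fit_encoder(encoder_mfpca(), lv)
  Z <- encode(enc, lv)
  K <- length(sim$base_vars); Q <- length(sim$long_vars)
  expect_equal(ncol(Z), K + Q + enc$n_scores)
  expect_true(all(is.finite(Z)))
  ev <- enc$eigenvalues
  expect_gte(sum(ev[seq_len(enc$n_scores)]) / sum(ev), 0.95)
})
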