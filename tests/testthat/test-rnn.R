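test_that("the recurrence matches a hand-computed scalar Elman step", {
  ## 1 layer, width 1, inputs = y only: h_j = tanh(w0 y + b0 + w1 h + b1)
  spec <- encoder_rnn(mode = "long_only", layers = 1, width = 1,
                      include_time = FALSE, epochs = 1, seed = 1)
  ds <- single_subject(c(0.5, -0.2, 0.8), T = 4)
  fit <- suppressWarnings(fit_encoder(spec, ds))
  ## overwrite with fixed weights and neutral normalization
  fit$params$W0_1 <- matrix(0.7); fit$params$b0_1 <- 0.1
  fit$params$W1_1 <- matrix(-0.4); fit$params$b1_1 <- 0.05
  fit$stats$y_ctr[] <- 0; fit$stats$y_scl[] <- 1; fit$stats$means[] <- 0
  fit$stats$b_ctr[] <- 0; fit$stats$b_scl[] <- 1
  Z <- encode(fit, ds)
  h <- 0
  for (y in c(0.5, -0.2, 0.8)) h <- tanh(0.7 * y + 0.1 - 0.4 * h + 0.05)
  expect_equal(unname(Z[1, "h1"]), h, tolerance = 1e-12)
  ## single-visit subject: one recurrence step from a zero initial state
  ds1 <- single_subject(0.5, times = 0, T = 1)
  Z1 <- encode(fit, ds1)
  expect_equal(unname(Z1[1, "h1"]), tanh(0.7 * 0.5 + 0.15), tolerance = 1e-12)
})

test_that("encoding dimension is baseline + hidden width and defaults to 5 + Q", {
  sim <- simulate_scenario(1, n_subjects = 25, seed = 31)$data
  spec <- encoder_rnn(mode = "long_only", epochs = 2, seed = 1)
  fit <- fit_encoder(spec, sim)
  Z <- encode(fit, sim)
  expect_equal(ncol(Z), 2 + (5 + 3))
  expect_equal(fit$width, 8)
  expect_equal(fit$layers, 2)
})

test_that("training is deterministic under a seed", {
  sim <- simulate_scenario(1, n_subjects = 20, seed = 32)$data
  f1 <- fit_encoder(encoder_rnn(mode = "long_only", epochs = 3, seed = 5), sim)
  f2 <- fit_encoder(encoder_rnn(mode = "long_only", epochs = 3, seed = 5), sim)
  expect_identical(f1$params, f2$params)
  f3 <- fit_encoder(encoder_rnn(mode = "long_only", epochs = 3, seed = 6), sim)
  expect_false(identical(f1$params, f3$params))
})

test_that("BPTT gradients match finite differences", {
  ns <- getNamespace("dynland")
  set.seed(42)
  L <- 2; H <- 3; Q <- 2; d_in <- 3; d_base <- 2; Bint <- 4
  params <- ns$rnn_init_params(d_in, H, L, d_base, 5, Q, Bint)
  seqs <- lapply(c(4, 2, 1), function(J) matrix(rnorm(J * d_in), J, d_in))
  batch <- list(seqs = seqs, B = matrix(rnorm(3 * d_base), 3, d_base),
                targets = lapply(seqs, function(s)
                  if (nrow(s) > 1) matrix(rnorm((nrow(s) - 1) * Q),
                                          nrow(s) - 1, Q) else NULL),
                surv = list(b = c(2L, 4L, 1L), event = c(1L, 0L, 1L),
                            l_idx = c(0L, 1L, 0L)))
  loss <- function(p) {
    r <- ns$rnn_batch_pass(p, batch, L, H, 0, FALSE, TRUE, TRUE, grad = FALSE)
    r$long_loss + r$surv_loss
  }
  g <- ns$mirror_bias_grads(
    ns$rnn_batch_pass(params, batch, L, H, 0, FALSE, TRUE, TRUE)$grads, L)
  eps <- 1e-6
  for (k in names(params)) {
    for (ii in seq_len(min(length(params[[k]]), 4))) {
      p2 <- params; p2[[k]][ii] <- p2[[k]][ii] + eps
      p3 <- params; p3[[k]][ii] <- p3[[k]][ii] - eps
      num <- (loss(p2) - loss(p3)) / (2 * eps)
      expect_equal(g[[k]][ii], num, tolerance = 1e-4,
                   label = paste("grad", k, ii))
    }
  }
})

test_that("training reduces the next-visit loss on noise-free linear data", {
  ## deterministic linear trajectories: the next visit is exactly predictable
  sim <- simulate_scenario(1, n_subjects = 60, seed = 33, noise_sd = 0)$data
  ns <- getNamespace("dynland")
  spec0 <- encoder_rnn(mode = "long_only", epochs = 0, dropout = 0, seed = 2)
  spec <- encoder_rnn(mode = "long_only", epochs = 300, lr = 1e-2, dropout = 0, seed = 2)
  long_loss <- function(fit) {
    prep <- ns$rnn_prepare(sim, fit$stats, TRUE)
    Ji <- vapply(prep$seqs, nrow, integer(1))
    ord <- order(-Ji)
    batch <- list(seqs = prep$seqs[ord], B = prep$B[ord, , drop = FALSE],
                  targets = lapply(prep$seqs[ord], function(s)
                    if (nrow(s) > 1) s[-1, 1:3, drop = FALSE] else NULL))
    ns$rnn_batch_pass(fit$params, batch, fit$layers, fit$width, 0, FALSE,
                      use_long = TRUE, use_surv = FALSE, grad = FALSE)$long_loss
  }
  f0 <- fit_encoder(spec0, sim)
  f1 <- fit_encoder(spec, sim)
  expect_lt(long_loss(f1), long_loss(f0) / 10)
})

test_that("long-only mode requires a subject with at least two visits", {
  ds <- single_subject(1, times = 0, T = 1)
  expect_error(fit_encoder(encoder_rnn(mode = "long_only", epochs = 1), ds),
               "2 visits")
})

test_that("combined mode exposes its survival head and the composition is consistent", {
  sim <- simulate_scenario(1, n_subjects = 40, seed = 34)$data
  spec <- encoder_rnn(mode = "combined", epochs = 4, seed = 3)
  fit <- fit_encoder(spec, sim, intervals = make_intervals(sim$subjects$time))
  head <- rnn_surv_head(fit)
  Z <- encode(fit, sim)
  P <- predict_interval_probs(head, Z)
  expect_equal(unname(rowSums(P)), rep(1, 40), tolerance = 1e-8)
  cv <- predict_discrete_nn(head, Z, grid = c(0, 1, 2, 5))
  expect_true(all(cv$surv >= 0 & cv$surv <= 1))
  expect_true(all(diff(t(cv$surv)) <= 1e-12))
})
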