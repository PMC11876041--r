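test_that("failure_from_probs matches the closed-form conditioning", {
  p <- c(0.5, 0.3, 0.2)
  r <- failure_from_probs(p, l = 0)
  expect_equal(r$F, c(0, 0.5, 0.8, 1))
  expect_equal(r$S[length(r$S)], 0)
  r1 <- failure_from_probs(p, l = 1)              # condition on T > interval 1
  expect_equal(r1$F[3], 0.3 / 0.5)
  expect_equal(r1$F, c(0, 0, 0.6, 1))
  expect_error(failure_from_probs(c(1, 0, 0), l = 2), "zero survival mass")
})

test_that("failure function is non-decreasing for random probability vectors", {
  set.seed(41)
  for (i in 1:1000) {
    B <- sample(2:8, 1)
    p <- rgamma(B, 1); p <- p / sum(p)
    l <- sample(0:(B - 1), 1)
    if (l > 0 && sum(p[seq_len(l)]) >= 1 - 1e-9) next
    r <- failure_from_probs(p, l)
    expect_true(all(diff(r$F) >= -1e-12))
    expect_true(all(r$F >= 0 & r$F <= 1))
  }
})

test_that("the likelihood matches a hand-computed value on frozen weights", {
  ## 3 samples, 3 intervals; identity-ish tiny network evaluated by hand
  ns <- getNamespace("dynland")
  params <- list(W1 = diag(2), b1 = c(0, 0),
                 W2 = matrix(c(1, 0, 0, 1, 0.5, -0.5), 3, 2, byrow = TRUE),
                 b2 = c(0, 0, 0))
  Z <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  fw <- ns$dtnn_forward(params, Z)
  H1 <- pmax(Z, 0)
  P_hand <- t(apply(H1 %*% t(params$W2), 1, function(a) exp(a) / sum(exp(a))))
  expect_equal(fw$probs, P_hand, tolerance = 1e-12)
  ## event in interval 2; censored in interval 1 with l = 0; censored with l = 1
  nl <- ns$dtnn_nll(fw$probs, b = c(2L, 1L, 2L), event = c(1L, 0L, 0L),
                    l_idx = c(0L, 0L, 1L))
  hand <- -log(P_hand[1, 2]) -
    log(1 - P_hand[2, 1]) -
    log((1 - sum(P_hand[3, 1:2])) / (1 - P_hand[3, 1]))
  expect_equal(nl$loss, hand, tolerance = 1e-12)
})

test_that("network gradients match finite differences", {
  ns <- getNamespace("dynland")
  set.seed(43)
  params <- ns$dtnn_init(3, 4, 5)
  Z <- matrix(rnorm(12), 4, 3)
  b <- c(1L, 3L, 5L, 2L); event <- c(1L, 0L, 1L, 0L); l_idx <- c(0L, 1L, 0L, 0L)
  loss <- function(p) {
    fw <- ns$dtnn_forward(p, Z)
    ns$dtnn_nll(fw$probs, b, event, l_idx)$loss
  }
  fw <- ns$dtnn_forward(params, Z)
  nl <- ns$dtnn_nll(fw$probs, b, event, l_idx)
  g <- ns$dtnn_backward(params, fw$cache, nl$dlogits)
  eps <- 1e-6
  for (k in names(params)) {
    for (ii in seq_len(min(length(params[[k]]), 5))) {
      p2 <- params; p2[[k]][ii] <- p2[[k]][ii] + eps
      p3 <- params; p3[[k]][ii] <- p3[[k]][ii] - eps
      expect_equal(g[[k]][ii], (loss(p2) - loss(p3)) / (2 * eps),
                   tolerance = 1e-4, label = paste("grad", k, ii))
    }
  }
})

test_that("a separable problem saturates towards indicator probabilities", {
  ## two Z values with disjoint event intervals, no censoring
  Z <- matrix(rep(c(-1, 1), each = 30), ncol = 1)
  time <- rep(c(0.3, 2.3), each = 30)
  event <- rep(1L, 60)
  fit <- fit_discrete_nn(Z, time, event, intervals = make_intervals(time, 1),
                         epochs = 400, dropout = 0, weight_decay = 0,
                         lr = 1e-2, seed = 2)
  P <- predict_interval_probs(fit, matrix(c(-1, 1), ncol = 1))
  expect_gt(P[1, 1], 0.95)                        # mass on interval (0, 1]
  expect_gt(P[2, 3], 0.95)                        # mass on interval (2, 3]
})

test_that("all-censored data pushes mass beyond the observed range", {
  Z <- matrix(rnorm(40), ncol = 1)
  fit <- fit_discrete_nn(Z, time = rep(2, 40), event = rep(0L, 40),
                         intervals = make_intervals(rep(2, 40), 1),
                         epochs = 300, dropout = 0, weight_decay = 0,
                         lr = 1e-2, seed = 3)
  cv <- predict_discrete_nn(fit, Z, grid = c(0, 1, 2))
  expect_true(all(cv$surv > 0.9))
})

test_that("curve prediction composes the softmax with the failure function", {
  set.seed(44)
  Z <- matrix(rnorm(10), 5, 2)
  fit <- fit_discrete_nn(Z, time = runif(5, 0.2, 2.8), event = c(1, 0, 1, 1, 0),
                         intervals = make_intervals(c(3), 1), epochs = 5, seed = 4)
  P <- predict_interval_probs(fit, Z)
  cv <- predict_discrete_nn(fit, Z, grid = c(0, 1, 2, 3, 10))
  for (i in 1:5) {
    r <- failure_from_probs(P[i, ], l = 0)
    expect_equal(unname(cv$surv[i, 2:4]), r$S[2:4], tolerance = 1e-10)
    expect_equal(unname(cv$surv[i, 1]), 1)                 # S before the first boundary
    expect_equal(unname(cv$surv[i, 5]), r$S[length(r$S)])  # flat beyond the last one
  }
})
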