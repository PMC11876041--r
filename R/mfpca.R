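#' Multivariate functional PCA encoder (PACE scores)
#'
#' Stage-one encoder that represents each longitudinal variable by a
#' Karhunen-Loeve expansion `Y_q(t) = mu_q(t) + sum_m xi_qm phi_qm(t)`,
#' estimated per variable with the PACE approach (mean by penalized spline
#' smoothing of the pooled points, covariance surface by smoothing raw
#' residual cross-products with the diagonal excluded, measurement-noise
#' variance from the diagonal gap, scores by Gaussian conditional
#' expectation). The univariate scores of all variables are then combined
#' by a second principal component decomposition (the two-step multivariate
#' construction), retaining the smallest number of multivariate scores whose
#' cumulative variance reaches `pve`.
#'
#' Each longitudinal variable is standardized to unit pooled variance before
#' fitting so that variables on different scales contribute comparably to the
#' multivariate step.
#'
#' @param pve fraction of variance the retained multivariate scores must
#'   explain (default 0.95).
#' @param pve_univariate fraction of variance retained per variable before
#'   the multivariate step (default 0.99).
#' @param include_baseline_long include the first-visit longitudinal values
#'   in the encoding next to the baseline covariates (default `TRUE`).
#' @param grid_size maximum size of the working grid for the mean and
#'   covariance functions.
#' @return an encoder specification; fit with [fit_encoder()].
#' @export
encoder_mfpca <- function(pve = 0.95, pve_univariate = 0.99,
                          include_baseline_long = TRUE, grid_size = 51) {
  structure(list(type = "mfpca", pve = pve, pve_univariate = pve_univariate,
                 include_baseline_long = include_baseline_long,
                 grid_size = grid_size),
            class = c("encoder_mfpca", "encoder_spec"))
}

## linear interpolation of each column of M (defined on grid) at times t
interp_cols <- function(grid, M, t) {
  if (length(grid) == 1L) return(matrix(M, nrow = length(t), ncol = ncol(M),
                                        byrow = TRUE))
  apply(M, 2, function(col) stats::approx(grid, col, t, rule = 2)$y,
        simplify = FALSE) |>
    (\(l) do.call(cbind, l))()
}

## univariate PACE fit for one variable: points (id, t, y), already scaled
pace_fit <- function(id, t, y, grid_size, pve_uni) {
  ut <- sort(unique(t))
  grid <- if (length(ut) <= grid_size) ut else
    seq(min(ut), max(ut), length.out = grid_size)
  G <- length(grid)

  ## mean function
  if (length(ut) >= 4) {
    ss <- stats::smooth.spline(t, y)
    mu <- stats::predict(ss, grid)$y
  } else {
    mu <- vapply(ut, function(a) mean(y[t == a]), numeric(1))
    mu <- stats::approx(ut, mu, grid, rule = 2)$y
  }
  if (G == 1L) {
    return(list(grid = grid, mu = mu, phi = matrix(0, 1, 0), lambda = numeric(0),
                sigma2 = max(stats::var(y), 1e-8)))
  }

  ## residuals snapped to grid
  gi <- vapply(t, function(a) which.min(abs(grid - a)), integer(1))
  res <- y - mu[gi]

  ## raw covariance accumulation over within-subject pairs
  Csum <- matrix(0, G, G); Cnt <- matrix(0, G, G)
  for (rows in split(seq_along(res), id)) {
    if (length(rows) < 1) next
    g <- gi[rows]; r <- res[rows]
    Csum[g, g] <- Csum[g, g] + tcrossprod(r)
    Cnt[g, g] <- Cnt[g, g] + 1
  }
  offd <- Cnt > 0 & row(Cnt) != col(Cnt)
  diag_ok <- diag(Cnt) > 0
  var_raw <- ifelse(diag_ok, diag(Csum) / pmax(diag(Cnt), 1), NA)

  if (sum(offd) >= 8 && length(unique(grid[row(Cnt)[offd]])) >= 3) {
    df <- data.frame(cc = (Csum / pmax(Cnt, 1))[offd],
                     t1 = grid[row(Cnt)[offd]], t2 = grid[col(Cnt)[offd]],
                     w = Cnt[offd])
    k <- min(8, length(unique(df$t1)))
    fit <- try(mgcv::gam(cc ~ te(t1, t2, k = k), weights = w, data = df),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      Craw <- Csum / pmax(Cnt, 1); Craw[Cnt == 0] <- 0
      Csm <- (Craw + t(Craw)) / 2
    } else {
      pg <- expand.grid(t1 = grid, t2 = grid)
      Csm <- matrix(stats::predict(fit, pg), G, G)
      Csm <- (Csm + t(Csm)) / 2
    }
  } else {
    ## few off-diagonal cells: raw symmetrized covariance; the diagonal is
    ## replaced by each row's largest off-diagonal value so that the raw
    ## diagonal's measurement-noise inflation stays out of the surface
    Craw <- Csum / pmax(Cnt, 1); Craw[Cnt == 0] <- 0
    Csm <- (Craw + t(Craw)) / 2
    if (sum(offd) > 0)
      diag(Csm) <- vapply(seq_len(G), function(j)
        max(Csm[j, -j]), numeric(1))
  }

  ## noise variance from the diagonal gap
  gap <- var_raw - diag(Csm)
  sigma2 <- max(mean(gap, na.rm = TRUE), 1e-8)
  if (!is.finite(sigma2)) sigma2 <- 1e-8

  ## eigendecomposition with trapezoid quadrature weights
  w <- diff(grid)
  w <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
  sw <- sqrt(w)
  E <- eigen(t(Csm * sw) * sw, symmetric = TRUE)
  lambda <- pmax(E$values, 0)
  phi <- E$vectors / sw
  ## sign convention: positive integral (fall back to positive max magnitude)
  for (m in seq_len(ncol(phi))) {
    s <- sum(phi[, m] * w)
    if (abs(s) < 1e-10) s <- phi[which.max(abs(phi[, m])), m]
    if (s < 0) phi[, m] <- -phi[, m]
  }
  tot <- sum(lambda)
  if (tot <= 1e-10) {
    M <- 0L
  } else {
    M <- which(cumsum(lambda) / tot >= pve_uni)[1]
    M <- min(M, sum(lambda > 1e-10 * tot))
    M <- max(M, 1L)
  }
  list(grid = grid, mu = mu, phi = phi[, seq_len(M), drop = FALSE],
       lambda = lambda[seq_len(M)], sigma2 = sigma2)
}

## conditional-expectation scores for one subject under one univariate model
pace_scores <- function(model, t, y) {
  M <- length(model$lambda)
  if (M == 0L) return(numeric(0))
  ok <- !is.na(y)
  if (!any(ok)) return(numeric(M))          # no data: conditional mean is 0
  t <- t[ok]; y <- y[ok]
  mu_i <- stats::approx(model$grid, model$mu, t, rule = 2)$y
  Phi_i <- interp_cols(model$grid, model$phi, t)
  Lam <- model$lambda
  SigY <- Phi_i %*% (Lam * t(Phi_i)) + diag(model$sigma2, length(t))
  drop(Lam * t(Phi_i) %*% solve(SigY, y - mu_i))
}

#' @export
fit_encoder.encoder_mfpca <- function(spec, data, ...) {
  means <- pooled_means(data)
  uni <- list(); sds <- numeric(0)
  score_list <- list()
  for (q in data$long_vars) {
    y <- data$visits[[q]]
    ok <- !is.na(y)
    sdq <- stats::sd(y[ok])
    if (!is.finite(sdq) || sdq < 1e-12) {
      warning("longitudinal variable ", q,
              " has (near) zero variance; it contributes no components")
      sds[q] <- 1
      uni[[q]] <- list(grid = NA_real_, mu = NA_real_,
                       phi = matrix(0, 1, 0), lambda = numeric(0), sigma2 = 1e-8)
      next
    }
    sds[q] <- sdq
    uni[[q]] <- pace_fit(data$visits$subject_id[ok], data$visits$visit_time[ok],
                         y[ok] / sdq, spec$grid_size, spec$pve_univariate)
  }

  ## training scores, stacked across variables
  idx <- visit_index(data)
  ids <- data$subjects$subject_id
  Xi <- NULL; cols <- character(0)
  for (q in data$long_vars) {
    m <- uni[[q]]
    Mq <- length(m$lambda)
    if (Mq == 0L) next
    Sq <- t(vapply(idx, function(rows) {
      pace_scores(m, data$visits$visit_time[rows], data$visits[[q]][rows] / sds[q])
    }, numeric(Mq)))
    if (Mq == 1L) Sq <- matrix(Sq, ncol = 1)
    Xi <- cbind(Xi, Sq)
    cols <- c(cols, paste0(q, "_xi", seq_len(Mq)))
  }

  if (is.null(Xi) || ncol(Xi) == 0L) {
    rot <- matrix(0, 0, 0); M <- 0L; evals <- numeric(0)
  } else {
    colnames(Xi) <- cols
    Cxi <- crossprod(Xi) / nrow(Xi)
    E <- eigen(Cxi, symmetric = TRUE)
    evals <- pmax(E$values, 0)
    tot <- sum(evals)
    M <- if (tot <= 1e-12) 0L else max(which(cumsum(evals) / tot >= spec$pve)[1], 1L)
    rot <- E$vectors[, seq_len(M), drop = FALSE]
    for (m in seq_len(M)) if (sum(rot[, m]) < 0) rot[, m] <- -rot[, m]
  }

  structure(list(spec = spec, base_vars = data$base_vars,
                 long_vars = data$long_vars, means = means, sds = sds,
                 univariate = uni, rotation = rot, n_scores = M,
                 score_names = cols, eigenvalues = evals),
            class = c("fitted_mfpca", "fitted_encoder"))
}

#' @export
encode.fitted_mfpca <- function(object, data, ...) {
  if (!identical(data$long_vars, object$long_vars))
    stop("longitudinal variables do not match the fitted model")
  idx <- visit_index(data)
  Xi <- NULL
  for (q in object$long_vars) {
    m <- object$univariate[[q]]
    Mq <- length(m$lambda)
    if (Mq == 0L) next
    Sq <- t(vapply(idx, function(rows) {
      pace_scores(m, data$visits$visit_time[rows],
                  data$visits[[q]][rows] / object$sds[q])
    }, numeric(Mq)))
    if (Mq == 1L) Sq <- matrix(Sq, ncol = 1)
    Xi <- cbind(Xi, Sq)
  }
  Z <- baseline_matrix(data)
  if (object$spec$include_baseline_long) {
    Y0 <- fill_means(visit_values(data, "first"), object$means)
    colnames(Y0) <- paste0(colnames(Y0), "_t0")
    Z <- cbind(Z, Y0)
  }
  if (object$n_scores > 0L) {
    rho <- Xi %*% object$rotation
    colnames(rho) <- paste0("rho", seq_len(object$n_scores))
    Z <- cbind(Z, rho)
  }
  Z
}

#' Reconstruct training-view trajectories from a fitted univariate expansion
#'
#' Utility mainly used to check that reconstruction error is non-increasing
#' in the number of retained components.
#'
#' @param object a `fitted_mfpca` encoder.
#' @param data a `longitudinal_data` view.
#' @param variable which longitudinal variable to reconstruct.
#' @param n_components how many univariate components to use.
#' @return numeric vector of fitted values aligned with
#'   `data$visits[[variable]]`.
#' @export
mfpca_reconstruct <- function(object, data, variable, n_components) {
  m <- object$univariate[[variable]]
  stopifnot(n_components <= length(m$lambda))
  sdq <- object$sds[variable]
  idx <- visit_index(data)
  out <- rep(NA_real_, nrow(data$visits))
  for (rows in idx) {
    t <- data$visits$visit_time[rows]
    xi <- pace_scores(m, t, data$visits[[variable]][rows] / sdq)
    mu_i <- stats::approx(m$grid, m$mu, t, rule = 2)$y
    Phi_i <- interp_cols(m$grid, m$phi, t)
    fit <- mu_i
    if (n_components > 0)
      fit <- fit + drop(Phi_i[, seq_len(n_components), drop = FALSE] %*%
                          xi[seq_len(n_components)])
    out[rows] <- fit * sdq
  }
  out
}
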