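logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

count_parameters <- function(K, P, M, R, N) {
  K * P * (1 + R) + K * P * M + N * (K - 1) + 1
}

#' Information criteria for a fitted model
#'
#' Computes AIC, BIC and DIC from the stored chain, using the marginal
#' (score-integrated) likelihood. With `Lhat` the maximum marginal
#' log-likelihood over draws and `p` the parameter count
#' `K P (1 + R) + K P M + N (K - 1) + 1` (mean and covariate-effect
#' coefficients, loadings, free allocation coordinates, noise variance):
#' `AIC = 2 p - 2 Lhat` (smallest best), `BIC = 2 Lhat - p log(n_tot)`
#' reported on the largest-is-best scale (the conventional-scale value
#' `-BIC` is also returned as `BIC_conventional`), and
#' `DIC = 2 * mean(D) - D(theta_hat)` with deviance `D = -2 loglik` and the
#' plug-in at the maximum-likelihood draw (smallest best).
#'
#' @param fit An `fmm_fit`.
#' @return A one-row tibble: `K`, `p`, `n_tot`, `loglik_hat`, `AIC`, `BIC`,
#'   `BIC_conventional`, `DIC`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "fmm_fit"))
  if (n_draws(fit) == 0L) abort("Empty chain.")
  n_tot <- sum(fit$data$n_i)
  R <- dim(fit$draws$eta)[3]
  N <- dim(fit$draws$Z)[2]
  p <- count_parameters(fit$K, fit$P, fit$M, R, N)
  Lhat <- max(fit$loglik)
  D <- -2 * fit$loglik
  tibble(K = fit$K, p = p, n_tot = n_tot, loglik_hat = Lhat,
         AIC = 2 * p - 2 * Lhat,
         BIC = 2 * Lhat - p * log(n_tot),
         BIC_conventional = -(2 * Lhat - p * log(n_tot)),
         DIC = 2 * mean(D) - (-2 * Lhat))
}

#' Elbow table over candidate numbers of features
#'
#' Collects the maximum marginal log-likelihood per fitted K, sorted by K,
#' with successive differences to aid reading off the elbow. On nested fits
#' of the same data the log-likelihood should be non-decreasing in K; since
#' MCMC maximization is approximate, a decrease is flagged in the `flag`
#' column rather than treated as an error.
#'
#' @param fits A list of `fmm_fit` objects (or a data frame with columns
#'   `K` and `loglik_hat`).
#' @return A tibble with columns `K`, `loglik_hat`, `diff`, `flag`.
#' @export
elbow_table <- function(fits) {
  tb <- if (is.data.frame(fits)) {
    tibble(K = fits$K, loglik_hat = fits$loglik_hat)
  } else {
    dplyr::bind_rows(lapply(fits, function(f) {
      tibble(K = f$K, loglik_hat = max(f$loglik))
    }))
  }
  tb <- dplyr::arrange(tb, .data$K)
  tb$diff <- c(NA_real_, diff(tb$loglik_hat))
  tb$flag <- !is.na(tb$diff) & tb$diff < 0
  tb
}

#' Conditional predictive ordinates and pseudo-marginal likelihood
#'
#' For each curve, the conditional predictive ordinate is the harmonic mean
#' over stored draws of the curve's marginal likelihood,
#' `CPO_i = [ mean_s 1 / p(Y_i | theta_s) ]^{-1}`, a leave-one-out
#' cross-validated predictive density. The pseudo-marginal likelihood is
#' `PsML = sum_i log CPO_i`; larger values indicate better predictive fit.
#' All computation is done in log space.
#'
#' @param fit An `fmm_fit`.
#' @return A list with `log_cpo` (length-N vector), `cpo`, and `psml`.
#' @export
cpo_psml <- function(fit) {
  stopifnot(inherits(fit, "fmm_fit"))
  S <- n_draws(fit)
  packed <- pack_data(fit$data, fit$basis)
  ll <- matrix(0, S, fit$data$N)
  for (s in seq_len(S)) {
    ll[s, ] <- cpp_curve_marginal_loglik(packed, state_to_cpp(state_from_draw(fit, s)))
  }
  if (any(!is.finite(ll))) abort("Non-finite per-curve likelihood encountered in CPO computation.")
  log_cpo <- -(apply(-ll, 2, logsumexp) - log(S))
  list(log_cpo = log_cpo, cpo = exp(log_cpo), psml = sum(log_cpo))
}

#' Relative mean integrated squared error (percent)
#'
#' `R-MISE = 100 * integral (f - fhat)^2 / integral f^2`, with trapezoid
#' quadrature on the supplied grids. For covariate-adjusted surfaces
#' `f(x, t)` supply `x_grid`; the integral then runs over both the time and
#' covariate grids.
#'
#' @param true_fn Function of `t` (or of `x, t` when `x_grid` is given).
#' @param est_fn Estimated function with the same signature.
#' @param t_grid Time grid (default 100 points on `[0, 1]`).
#' @param x_grid Optional covariate grid. For R > 1 covariates, a matrix or
#'   data frame with one covariate per column (integrated on the product
#'   grid row by row) or a vector shared across covariates.
#' @return Percent R-MISE (scalar).
#' @export
rmise <- function(true_fn, est_fn, t_grid = seq(0, 1, length.out = 100),
                  x_grid = NULL) {
  wt <- trapezoid_weights(t_grid)
  if (is.null(x_grid)) {
    f <- true_fn(t_grid)
    fh <- est_fn(t_grid)
    num <- sum(wt * (f - fh)^2)
    den <- sum(wt * f^2)
  } else {
    xg <- as.numeric(x_grid)
    wx <- trapezoid_weights(xg)
    num <- 0; den <- 0
    for (j in seq_along(xg)) {
      f <- true_fn(xg[j], t_grid)
      fh <- est_fn(xg[j], t_grid)
      num <- num + wx[j] * sum(wt * (f - fh)^2)
      den <- den + wx[j] * sum(wt * f^2)
    }
  }
  if (den <= 0) abort("The true function has zero norm on the grid; R-MISE is undefined.")
  100 * num / den
}

#' Root-mean-square error of the allocation estimate
#'
#' RMSE between a true allocation matrix and the pointwise posterior median
#' of the fitted allocations, minimized over feature-label permutations
#' (labels are only identified up to permutation).
#'
#' @param Z_true N x K matrix of true allocations.
#' @param fit An `fmm_fit` (the posterior median of `Z` is used), or an
#'   N x K matrix already summarizing the estimate.
#' @return Scalar RMSE.
#' @export
rmse_alloc <- function(Z_true, fit) {
  Z_true <- as.matrix(Z_true)
  Z_est <- if (inherits(fit, "fmm_fit")) {
    S <- n_draws(fit); N <- dim(fit$draws$Z)[2]; K <- dim(fit$draws$Z)[3]
    apply(array(fit$draws$Z, dim = c(S, N, K)), c(2, 3), median)
  } else {
    as.matrix(fit)
  }
  if (!all(dim(Z_true) == dim(Z_est))) abort("Dimension mismatch between true and estimated allocations.")
  K <- ncol(Z_true)
  best <- Inf
  for (p in all_permutations(K)) {
    err <- sqrt(mean((Z_true - Z_est[, p, drop = FALSE])^2))
    if (err < best) best <- err
  }
  best
}

#' Recovery metrics against a known simulation truth
#'
#' Summarizes how well a fitted model recovers a generating truth: percent
#' R-MISE of each feature's mean (marginal, at covariates zero, and - when
#' the fitted and generating models share the covariate dimension - of the
#' covariate-adjusted mean surface), and the allocation RMSE. Feature labels
#' are aligned by the permutation minimizing the summed marginal-mean L2
#' distance.
#'
#' @param fit An `fmm_fit`.
#' @param truth The `truth` element returned by [simulate_fmm_data()] (or a
#'   list with `state` and `basis`).
#' @param t_grid Time grid (default 100 points over the truth domain).
#' @param x_grid Covariate grid for surface R-MISE (default 20 points on
#'   `[-2, 2]`, the bulk of the standardized covariate scale).
#' @return A one-row tibble: `rmise_mean_marginal` (average over features),
#'   per-feature `rmise_marginal_k`, `rmise_mean_surface` (NA when covariate
#'   dimensions differ), and `rmse_alloc`.
#' @export
recovery_metrics <- function(fit, truth, t_grid = NULL, x_grid = NULL) {
  stopifnot(inherits(fit, "fmm_fit"))
  st <- truth$state
  tb <- truth$basis
  if (is.null(t_grid)) t_grid <- seq(tb$domain[1], tb$domain[2], length.out = 100)
  if (is.null(x_grid)) x_grid <- seq(-2, 2, length.out = 20)
  K <- fit$K
  S <- n_draws(fit)
  B <- eval_basis(fit$basis, t_grid)
  v_med <- apply(array(fit$draws$v, dim = c(S, K, fit$P)), c(2, 3), median)
  est_marg <- v_med %*% B                            # K x G
  true_marg <- t(vapply(seq_len(st$K), function(k) {
    mean_function(st, k, rep(0, st$R), t_grid, tb)
  }, numeric(length(t_grid))))
  wt <- trapezoid_weights(t_grid)
  perm <- all_permutations(K)[[which.min(vapply(all_permutations(K), function(p) {
    sum(vapply(seq_len(min(K, st$K)), function(k) {
      sum(wt * (est_marg[p[k], ] - true_marg[k, ])^2)
    }, numeric(1)))
  }, numeric(1)))]]

  rm_marg <- vapply(seq_len(min(K, st$K)), function(k) {
    tf <- function(t) mean_function(st, k, rep(0, st$R), t, tb)
    ef <- function(t) as.numeric(v_med[perm[k], ] %*% eval_basis(fit$basis, t))
    rmise(tf, ef, t_grid)
  }, numeric(1))

  R_fit <- dim(fit$draws$eta)[3]
  rm_surf_k <- if (R_fit == st$R && st$R > 0) {
    eta_med <- apply(array(fit$draws$eta, dim = c(S, fit$P, R_fit, K)),
                     c(2, 3, 4), median)
    vapply(seq_len(min(K, st$K)), function(k) {
      tf <- function(x, t) mean_function(st, k, rep(x, st$R), t, tb)
      ef <- function(x, t) {
        coefs <- v_med[perm[k], ] + matrix(eta_med[, , perm[k]], fit$P, R_fit) %*% rep(x, R_fit)
        as.numeric(crossprod(eval_basis(fit$basis, t), coefs))
      }
      rmise(tf, ef, t_grid, x_grid)
    }, numeric(1))
  } else rep(NA_real_, min(K, st$K))
  rm_surf <- mean(rm_surf_k)
  Z_true <- st$Z
  ra <- if (ncol(Z_true) == K) rmse_alloc(Z_true, fit) else NA_real_
  out <- tibble(rmise_mean_marginal = mean(rm_marg),
                rmise_mean_surface = rm_surf,
                rmse_alloc = ra)
  for (k in seq_along(rm_marg)) out[[paste0("rmise_marginal_", k)]] <- rm_marg[k]
  for (k in seq_along(rm_surf_k)) out[[paste0("rmise_surface_", k)]] <- rm_surf_k[k]
  out
}
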