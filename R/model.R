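#' Covariate-conditional mean of one latent feature
#'
#' Evaluates `mu_k(x, t) = (v_k + eta_k x)' B(t)`: the mean of feature `k`
#' at covariate value `x` (on the standardized scale used at fit time). With
#' no covariates (R = 0) this is `v_k' B(t)`.
#'
#' @param state An [fmm_state()].
#' @param k Feature index in `1:K`.
#' @param x Length-R numeric vector (ignored when R = 0).
#' @param times Evaluation times.
#' @param basis An [fmm_basis()].
#' @return Numeric vector, one value per time.
#' @export
mean_function <- function(state, k, x = numeric(0), times, basis) {
  stopifnot(inherits(state, "fmm_state"), k >= 1, k <= state$K)
  x <- as.numeric(x)
  if (length(x) != state$R) {
    abort(sprintf("`x` has length %d but the state has R = %d covariates.",
                  length(x), state$R))
  }
  coef <- state$v[k, ]
  if (state$R > 0) coef <- coef + as.numeric(matrix(state$eta[, , k], state$P, state$R) %*% x)
  S <- eval_basis(basis, times)
  as.numeric(crossprod(S, coef))
}

#' Covariance (or cross-covariance) surface between two features
#'
#' Evaluates the truncated Karhunen-Loeve covariance
#' `C_{k,k'}(s, t) = B(s)' (sum_m phi_km phi_k'm') B(t)` on the grid
#' `s_times x t_times`.
#'
#' @param state An [fmm_state()].
#' @param k,k2 Feature indices (equal for a covariance, different for a
#'   cross-covariance).
#' @param s_times,t_times Evaluation grids.
#' @param basis An [fmm_basis()].
#' @return Matrix of dimension `length(s_times) x length(t_times)`.
#' @export
covariance_surface <- function(state, k, k2, s_times, t_times, basis) {
  stopifnot(inherits(state, "fmm_state"))
  A <- matrix(0, state$P, state$P)
  for (m in seq_len(state$M)) {
    A <- A + tcrossprod(state$phi[, m, k], state$phi[, m, k2])
  }
  Ss <- eval_basis(basis, s_times)
  St <- eval_basis(basis, t_times)
  t(Ss) %*% A %*% St
}

curve_design <- function(data, basis) {
  lapply(data$times, function(t) t(eval_basis(basis, t)))  # n_i x P
}

curve_mean_vectors <- function(state, data, basis, S_list = NULL) {
  if (is.null(S_list)) S_list <- curve_design(data, basis)
  lapply(seq_len(data$N), function(i) {
    S <- S_list[[i]]
    x <- if (data$R > 0) data$X[i, ] else numeric(0)
    a <- numeric(state$P)
    Phi_bar <- matrix(0, state$P, state$M)
    for (k in seq_len(state$K)) {
      ck <- state$v[k, ]
      if (state$R > 0) ck <- ck + as.numeric(matrix(state$eta[, , k], state$P, state$R) %*% x)
      a <- a + state$Z[i, k] * ck
      Phi_bar <- Phi_bar + state$Z[i, k] * matrix(state$phi[, , k], state$P, state$M)
    }
    Phi_bar <- matrix(Phi_bar, state$P, state$M)
    as.numeric(S %*% a + S %*% (Phi_bar %*% state$chi[i, ]))
  })
}

#' Conditional log-likelihood (given the factor scores)
#'
#' Sum over curves of the Gaussian log-density of `Y_i(t_i)` under the
#' sampling model in which each curve is a convex combination of the feature
#' means plus the score-weighted pseudo-eigenfunctions, with iid noise
#' `sigma2`.
#'
#' @param state An [fmm_state()].
#' @param data An [fmm_data()] (N must match the state).
#' @param basis An [fmm_basis()].
#' @return Scalar log-likelihood.
#' @export
conditional_loglik <- function(state, data, basis) {
  stopifnot(inherits(data, "fmm_data"))
  if (state$sigma2 <= 0) abort("`sigma2` must be positive.")
  mu <- curve_mean_vectors(state, data, basis)
  ll <- 0
  for (i in seq_len(data$N)) {
    r <- data$values[[i]] - mu[[i]]
    n <- length(r)
    ll <- ll - 0.5 * n * log(2 * base::pi * state$sigma2) -
      0.5 * sum(r^2) / state$sigma2
  }
  ll
}

#' Marginal log-likelihood (factor scores integrated out)
#'
#' Sum over curves of the Gaussian log-density with mean
#' `sum_k Z_ik S_i (v_k + eta_k x_i)` and covariance
#' `V(t_i, z_i) + sigma2 I`, where `V` is the allocation-weighted sum of the
#' feature covariance and cross-covariance surfaces. The dense covariance is
#' factorized by Cholesky; if that fails a jitter of `1e-10 * trace / n` is
#' added once before erroring.
#'
#' @inheritParams conditional_loglik
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(state, data, basis) {
  stopifnot(inherits(data, "fmm_data"))
  if (state$sigma2 <= 0) abort("`sigma2` must be positive.")
  S_list <- curve_design(data, basis)
  ll <- 0
  for (i in seq_len(data$N)) {
    ll <- ll + marginal_loglik_curve(state, data, basis, i, S_list[[i]])
  }
  ll
}

marginal_loglik_curve <- function(state, data, basis, i, S = NULL) {
  if (is.null(S)) S <- t(eval_basis(basis, data$times[[i]]))
  x <- if (data$R > 0) data$X[i, ] else numeric(0)
  a <- numeric(state$P)
  Phi_bar <- matrix(0, state$P, state$M)
  for (k in seq_len(state$K)) {
    ck <- state$v[k, ]
    if (state$R > 0) ck <- ck + as.numeric(matrix(state$eta[, , k], state$P, state$R) %*% x)
    a <- a + state$Z[i, k] * ck
    Phi_bar <- Phi_bar + state$Z[i, k] *
      matrix(state$phi[, , k], state$P, state$M)
  }
  r <- data$values[[i]] - as.numeric(S %*% a)
  Psi <- S %*% Phi_bar                       # n x M
  n <- length(r)
  V <- tcrossprod(Psi) + state$sigma2 * diag(n)
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) {
    jit <- 1e-10 * sum(diag(V)) / n
    U <- tryCatch(chol(V + jit * diag(n)), error = function(e) NULL)
    if (is.null(U)) {
      abort(sprintf(
        "Marginal covariance for curve %s is not positive definite even after jitter (min diag %.3g, sigma2 %.3g).",
        data$ids[i], min(diag(V)), state$sigma2))
    }
  }
  w <- backsolve(U, r, transpose = TRUE)
  -0.5 * n * log(2 * base::pi) - sum(log(diag(U))) - 0.5 * sum(w^2)
}

ldgamma <- function(x, shape, rate) {
  ifelse(x > 0, shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x, -Inf)
}

lddirichlet <- function(z, alpha) {
  if (any(z <= 0) || abs(sum(z) - 1) > 1e-8) return(-Inf)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(z))
}

#' Log prior density of a parameter state
#'
#' Sums the log densities of the full prior stack: the MGP shrinkage prior on
#' the pseudo-eigenfunction coefficients and its gamma hierarchy, the RW1
#' smoothing priors on the mean coefficients (improper: computed up to the
#' constant normalization, but including the `tau^{rank/2}` factor so the
#' smoothing precisions are correctly weighted), the hierarchical Dirichlet
#' prior on allocations and mixing proportions, the exponential prior on the
#' allocation concentration and the inverse-gamma prior on the noise
#' variance. Out-of-support values return `-Inf`.
#'
#' @param state An [fmm_state()].
#' @param hyper An [fmm_hyper()].
#' @param basis An [fmm_basis()] or integer P (used only for the penalty).
#' @return Scalar log prior density (up to the RW1 improper constant).
#' @export
log_prior <- function(state, hyper, basis = state$P) {
  s <- state; h <- hyper
  D <- difference_penalty(if (inherits(basis, "fmm_basis")) basis else s$P)
  Q0 <- crossprod(D)
  rank_q <- s$P - 1L
  if (h$mean_ridge > 0) {
    Q0 <- Q0 + h$mean_ridge * diag(s$P)
    rank_q <- s$P
  }
  bad <- any(c(s$gamma, s$delta, s$a1, s$a2, s$tau_v, s$tau_eta) <= 0) ||
    s$sigma2 <= 0 || s$alpha3 <= 0 || any(s$Z <= 0) || any(s$pi <= 0)
  if (bad) return(-Inf)
  lp <- 0
  for (k in seq_len(s$K)) {
    tau_tilde <- cumprod(s$delta[, k])
    for (m in seq_len(s$M)) {
      prec <- s$gamma[, m, k] * tau_tilde[m]
      lp <- lp + sum(dnorm(s$phi[, m, k], 0, sqrt(1 / prec), log = TRUE))
    }
    lp <- lp + sum(ldgamma(s$gamma[, , k], h$nu_gamma / 2, h$nu_gamma / 2))
    lp <- lp + ldgamma(s$delta[1, k], s$a1[k], 1)
    if (s$M > 1) lp <- lp + sum(ldgamma(s$delta[-1, k], s$a2[k], 1))
    lp <- lp + ldgamma(s$a1[k], h$alpha1, h$beta1) +
      ldgamma(s$a2[k], h$alpha2, h$beta2)
    lp <- lp + 0.5 * rank_q * log(s$tau_v[k]) -
      0.5 * s$tau_v[k] * as.numeric(crossprod(s$v[k, ], Q0 %*% s$v[k, ]))
    lp <- lp + ldgamma(s$tau_v[k], h$alpha_v, h$beta_v)
    for (r in seq_len(s$R)) {
      e <- s$eta[, r, k]
      lp <- lp + 0.5 * rank_q * log(s$tau_eta[r, k]) -
        0.5 * s$tau_eta[r, k] * as.numeric(crossprod(e, Q0 %*% e))
      lp <- lp + ldgamma(s$tau_eta[r, k], h$alpha_eta, h$beta_eta)
    }
  }
  for (i in seq_len(s$N)) {
    lp <- lp + lddirichlet(s$Z[i, ], s$alpha3 * s$pi)
  }
  c_pi <- rep_len(h$c_pi, s$K)
  lp <- lp + lddirichlet(s$pi, c_pi)
  lp <- lp + ifelse(s$alpha3 > 0, log(h$b) - h$b * s$alpha3, -Inf)
  lp <- lp + h$alpha0 * log(h$beta0) - lgamma(h$alpha0) -
    (h$alpha0 + 1) * log(s$sigma2) - h$beta0 / s$sigma2
  lp
}

#' Allocation design matrix and its rank
#'
#' Builds the N x (K(K+1)/2) matrix whose i-th row is
#' `(Z_i1^2, ..., Z_iK^2, 2 Z_i1 Z_i2, ..., 2 Z_i(K-1) Z_iK)`. Full column
#' rank of this matrix (which requires `N >= K(K+1)/2`) is one of the
#' identifiability conditions on the allocation structure: it fails when the
#' allocations concentrate on a lower-dimensional subset of the simplex.
#'
#' @param Z N x K allocation matrix, rows on the simplex.
#' @return A list with `C` (the matrix), `rank`, and `full_rank` (logical).
#' @export
allocation_design <- function(Z) {
  Z <- as.matrix(Z)
  N <- nrow(Z); K <- ncol(Z)
  ncolC <- K * (K + 1) / 2
  C <- matrix(0, N, ncolC)
  C[, seq_len(K)] <- Z^2
  j <- K
  for (k in seq_len(K - 1)) {
    for (k2 in seq(k + 1, K)) {
      j <- j + 1L
      C[, j] <- 2 * Z[, k] * Z[, k2]
    }
  }
  r <- rank_svd(C)
  list(C = C, rank = r, full_rank = (r == ncolC) && (N >= ncolC))
}
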