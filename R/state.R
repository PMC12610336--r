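#' Prior hyperparameters
#'
#' Collects the hyperparameters of the prior stack: the multiplicative gamma
#' process (MGP) shrinkage prior on the pseudo-eigenfunction coefficients, the
#' first-order random walk (RW1) smoothing priors on the mean coefficients,
#' the hierarchical Dirichlet prior on the allocations, and the inverse-gamma
#' prior on the observation noise.
#'
#' The constraint `alpha2 > beta2` makes the expected cumulative MGP
#' precisions increase with the eigen-index, so higher-index loadings are
#' shrunk progressively harder towards zero.
#'
#' @param nu_gamma MGP local-precision degrees of freedom (Gamma(nu/2, nu/2)).
#' @param alpha1,beta1 Gamma prior on the first MGP column shape `a1`.
#' @param alpha2,beta2 Gamma prior on the later MGP column shapes `a2`;
#'   must satisfy `alpha2 > beta2`.
#' @param alpha_v,beta_v Gamma prior on the RW1 smoothing precision of the
#'   population mean coefficients.
#' @param alpha_eta,beta_eta Gamma prior on the RW1 smoothing precision of
#'   the covariate-effect coefficients.
#' @param c_pi Dirichlet concentration for the population mixing proportions;
#'   a scalar is recycled to length K at fit time.
#' @param b Rate of the exponential prior on the allocation concentration.
#' @param alpha0,beta0 Inverse-gamma prior on the noise variance.
#' @param mean_ridge Nonnegative ridge added to the RW1 precision operator,
#'   `tau * (D'D + mean_ridge * I)`. Zero (the default) is the improper RW1
#'   prior; a positive value gives a proper Gaussian prior, used e.g. by the
#'   prior-sampling utilities and simulation-based sampler checks.
#' @return An object of class `fmm_hyper`.
#' @export
fmm_hyper <- function(nu_gamma = 3, alpha1 = 2, beta1 = 1,
                      alpha2 = 3, beta2 = 1,
                      alpha_v = 1, beta_v = 1,
                      alpha_eta = 1, beta_eta = 1,
                      c_pi = 10, b = 1,
                      alpha0 = 1, beta0 = 1,
                      mean_ridge = 0) {
  vals <- c(nu_gamma = nu_gamma, alpha1 = alpha1, beta1 = beta1,
            alpha2 = alpha2, beta2 = beta2, alpha_v = alpha_v,
            beta_v = beta_v, alpha_eta = alpha_eta, beta_eta = beta_eta,
            b = b, alpha0 = alpha0, beta0 = beta0)
  if (any(vals <= 0)) {
    abort(paste0("Hyperparameters must be strictly positive; offending: ",
                 paste(names(vals)[vals <= 0], collapse = ", ")))
  }
  if (any(c_pi <= 0)) abort("`c_pi` must be strictly positive.")
  if (mean_ridge < 0) abort("`mean_ridge` must be nonnegative.")
  if (!(alpha2 > beta2)) {
    abort("Need alpha2 > beta2 so the MGP prior shrinks harder with increasing eigen-index.")
  }
  structure(as.list(environment()), class = "fmm_hyper")
}

#' MCMC settings
#'
#' @param n_iter Total number of sweeps.
#' @param burnin Number of initial sweeps discarded (also the adaptation
#'   window for Metropolis-Hastings proposal scales).
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param ladder Inverse-temperature ladder for tempered allocation sweeps:
#'   a decreasing vector in (0, 1), or `numeric(0)` (default) for plain
#'   Metropolis-Hastings allocation updates. See [fmm_ladder()].
#' @param temper_every Apply a tempered sweep every this many sweeps (plain
#'   sweeps in between); ignored when the ladder is empty.
#' @param kappa Initial Dirichlet proposal concentration for allocation
#'   updates (adapted during burn-in towards 20-40% acceptance).
#' @param step_a,step_pi,step_alpha3 Initial random-walk scales for the MGP
#'   shape, mixing-proportion and concentration updates (adapted in burn-in).
#' @param adapt Adapt proposal scales during burn-in?
#' @param verbose Print progress every `report_every` sweeps (0 = silent).
#' @param report_every Progress interval in sweeps.
#' @return An object of class `fmm_control`.
#' @export
fmm_control <- function(n_iter = 2000L, burnin = 500L, thin = 1L,
                        ladder = numeric(0), temper_every = 5L,
                        kappa = 50, step_a = 0.5, step_pi = 0.3,
                        step_alpha3 = 0.5, adapt = TRUE,
                        verbose = FALSE, report_every = 100L) {
  n_iter <- as.integer(n_iter); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (burnin >= n_iter) abort("`burnin` must be smaller than `n_iter`.")
  if ((n_iter - burnin) %% thin != 0L) {
    abort("`n_iter - burnin` must be divisible by `thin`.")
  }
  if (length(ladder) > 0) {
    if (any(ladder <= 0) || any(ladder >= 1) || is.unsorted(rev(ladder))) {
      abort("`ladder` must be a decreasing vector of inverse temperatures in (0, 1).")
    }
  }
  structure(as.list(environment()), class = "fmm_control")
}

#' Geometric inverse-temperature ladder
#'
#' Builds the default ladder for tempered allocation sweeps: `L` geometrically
#' spaced inverse temperatures from just below 1 down to `beta_min`.
#'
#' @param L Ladder length (number of rungs below the cold level).
#' @param beta_min Hottest (smallest) inverse temperature.
#' @return Decreasing numeric vector of length `L`.
#' @export
fmm_ladder <- function(L = 10L, beta_min = 0.1) {
  L <- as.integer(L)
  if (L == 0L) return(numeric(0))
  exp(seq(log(1), log(beta_min), length.out = L + 1L))[-1L]
}

#' Construct and validate one model parameter state
#'
#' A single draw of the full parameter vector: feature mean coefficients `v`
#' (K x P) and covariate effects `eta` (P x R x K), pseudo-eigenfunction
#' coefficients `phi` (P x M x K), factor scores `chi` (N x M), simplex
#' allocations `Z` (N x K), noise variance `sigma2`, MGP shrinkage parameters
#' (`gamma`, `delta`, `a1`, `a2`), RW1 smoothing precisions (`tau_v`,
#' `tau_eta`) and mixing parameters (`pi`, `alpha3`).
#'
#' @param v K x P matrix.
#' @param eta P x R x K array (R may be 0).
#' @param phi P x M x K array.
#' @param chi N x M matrix.
#' @param Z N x K matrix with rows on the unit simplex.
#' @param sigma2 Positive scalar.
#' @param gamma,delta,a1,a2,tau_v,tau_eta,pi,alpha3 Remaining blocks; any
#'   that are omitted are filled with neutral defaults (all ones, uniform
#'   mixing, `alpha3 = 1`).
#' @return An object of class `fmm_state`.
#' @export
fmm_state <- function(v, eta = NULL, phi, chi, Z, sigma2,
                      gamma = NULL, delta = NULL, a1 = NULL, a2 = NULL,
                      tau_v = NULL, tau_eta = NULL, pi = NULL, alpha3 = 1) {
  v <- as.matrix(v)
  K <- nrow(v); P <- ncol(v)
  if (is.null(eta)) eta <- array(0, dim = c(P, 0, K))
  if (length(dim(eta)) != 3L) abort("`eta` must be a P x R x K array.")
  R <- dim(eta)[2]
  phi <- if (length(dim(phi)) == 3L) phi else array(phi, dim = c(dim(phi), 1L))
  M <- dim(phi)[2]
  chi <- as.matrix(chi); Z <- as.matrix(Z)
  N <- nrow(Z)
  if (is.null(gamma)) gamma <- array(1, dim = c(P, M, K))
  if (is.null(delta)) delta <- matrix(1, M, K)
  if (is.null(a1)) a1 <- rep(2, K)
  if (is.null(a2)) a2 <- rep(3, K)
  if (is.null(tau_v)) tau_v <- rep(1, K)
  if (is.null(tau_eta)) tau_eta <- matrix(1, R, K)
  if (is.null(pi)) pi <- rep(1 / K, K)
  tau_eta <- matrix(tau_eta, R, K)
  state <- structure(
    list(v = v, eta = eta, phi = phi, chi = chi, Z = Z, sigma2 = sigma2,
         gamma = gamma, delta = delta, a1 = a1, a2 = a2,
         tau_v = tau_v, tau_eta = matrix(tau_eta, R, K),
         pi = as.numeric(pi), alpha3 = alpha3,
         K = K, P = P, R = R, M = M, N = N),
    class = "fmm_state")
  check_state(state)
  state
}

check_state <- function(s) {
  with(s, {
    stopifnot(
      dim(eta)[1] == P, dim(eta)[3] == K,
      dim(phi)[1] == P, dim(phi)[3] == K,
      ncol(chi) == M, nrow(chi) == N, ncol(Z) == K,
      length(pi) == K, length(a1) == K, length(a2) == K,
      length(tau_v) == K, nrow(tau_eta) == R || R == 0,
      dim(gamma)[1] == P, dim(gamma)[2] == M, dim(gamma)[3] == K,
      nrow(delta) == M, ncol(delta) == K
    )
    if (sigma2 <= 0) abort("`sigma2` must be positive.")
    if (any(Z < -1e-12) || any(Z > 1 + 1e-12) ||
        any(abs(rowSums(Z) - 1) > 1e-12)) {
      abort("Rows of `Z` must lie on the unit simplex (tolerance 1e-12).")
    }
    if (any(abs(sum(pi) - 1) > 1e-8) || any(pi < 0)) {
      abort("`pi` must lie on the unit simplex.")
    }
    if (any(c(gamma, delta, a1, a2, tau_v, tau_eta, alpha3) <= 0)) {
      abort("Variance-type parameters (gamma, delta, a1, a2, tau, alpha3) must be positive.")
    }
  })
  invisible(s)
}

#' @export
print.fmm_state <- function(x, ...) {
  cat(sprintf("<fmm_state> K = %d, P = %d, M = %d, R = %d, N = %d, sigma2 = %.4g\n",
              x$K, x$P, x$M, x$R, x$N, x$sigma2))
  invisible(x)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- g + 1e-300
  g / sum(g)
}

#' Draw a parameter state from the prior
#'
#' Samples every model parameter from the prior stack. The RW1 prior on the
#' mean coefficients is improper, so a proper draw requires a positive
#' `mean_ridge` in the hyperparameters; this is primarily a building block
#' for prior-predictive simulation and simulation-based sampler validation.
#'
#' @param K,P,M,R,N Model dimensions.
#' @param hyper An [fmm_hyper()] object with `mean_ridge > 0`.
#' @return An `fmm_state`.
#' @export
sample_prior_state <- function(K, P, M, R, N, hyper = fmm_hyper(mean_ridge = 1)) {
  if (hyper$mean_ridge <= 0) {
    abort("Sampling the mean coefficients from the prior requires `mean_ridge > 0` (the pure RW1 prior is improper).")
  }
  D <- difference_penalty(P)
  Q0 <- crossprod(D) + hyper$mean_ridge * diag(P)
  rmvn_prec <- function(tau) {
    U <- chol(tau * Q0)
    backsolve(U, rnorm(P))
  }
  tau_v <- rgamma(K, hyper$alpha_v, hyper$beta_v)
  v <- t(vapply(tau_v, rmvn_prec, numeric(P)))
  tau_eta <- matrix(rgamma(R * K, hyper$alpha_eta, hyper$beta_eta), R, K)
  eta <- array(0, dim = c(P, R, K))
  for (k in seq_len(K)) for (r in seq_len(R)) {
    eta[, r, k] <- rmvn_prec(tau_eta[r, k])
  }
  a1 <- rgamma(K, hyper$alpha1, hyper$beta1)
  a2 <- rgamma(K, hyper$alpha2, hyper$beta2)
  delta <- matrix(0, M, K)
  for (k in seq_len(K)) {
    delta[1, k] <- rgamma(1, a1[k], 1)
    if (M > 1) delta[2:M, k] <- rgamma(M - 1, a2[k], 1)
  }
  gamma <- array(rgamma(P * M * K, hyper$nu_gamma / 2, hyper$nu_gamma / 2),
                 dim = c(P, M, K))
  phi <- array(0, dim = c(P, M, K))
  for (k in seq_len(K)) {
    tau_tilde <- cumprod(delta[, k])
    for (m in seq_len(M)) {
      phi[, m, k] <- rnorm(P, 0, sqrt(1 / (gamma[, m, k] * tau_tilde[m])))
    }
  }
  chi <- matrix(rnorm(N * M), N, M)
  c_pi <- rep_len(hyper$c_pi, K)
  pi <- rdirichlet1(c_pi)
  alpha3 <- rexp(1, hyper$b)
  Z <- t(vapply(seq_len(N), function(i) rdirichlet1(alpha3 * pi), numeric(K)))
  sigma2 <- 1 / rgamma(1, hyper$alpha0, hyper$beta0)
  fmm_state(v = v, eta = eta, phi = phi, chi = chi, Z = Z, sigma2 = sigma2,
            gamma = gamma, delta = delta, a1 = a1, a2 = a2,
            tau_v = tau_v, tau_eta = tau_eta, pi = pi, alpha3 = alpha3)
}
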