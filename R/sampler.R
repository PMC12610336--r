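pack_data <- function(data, basis) {
  S <- do.call(rbind, lapply(data$times, function(t) t(eval_basis(basis, t))))
  off <- c(0L, cumsum(data$n_i))
  list(y = unlist(data$values, use.names = FALSE), S = S,
       off = as.integer(off), N = data$N,
       X = if (data$R > 0) unname(data$X) else matrix(0, data$N, 0))
}

control_to_cpp <- function(control) {
  control[c("n_iter", "burnin", "thin", "kappa", "step_a", "step_pi",
            "step_alpha3", "adapt", "verbose", "report_every", "ladder",
            "temper_every")]
}

state_to_cpp <- function(state) {
  unclass(state)[c("v", "eta", "phi", "chi", "Z", "sigma2", "gamma", "delta",
                   "a1", "a2", "tau_v", "tau_eta", "pi", "alpha3")]
}

state_from_cpp <- function(lst) {
  do.call(fmm_state, lst)
}

hyper_to_cpp <- function(hyper, K) {
  h <- unclass(hyper)
  h$c_pi <- rep_len(h$c_pi, K)
  h
}

# project v onto the unit simplex (Euclidean projection)
simplex_project <- function(v) {
  K <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(K) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

# least squares on the simplex: min ||c - t(V) z||, z on the simplex,
# by projected gradient (V is K x P, c length P)
simplex_ls <- function(c_vec, V, n_iter = 200) {
  K <- nrow(V)
  z <- rep(1 / K, K)
  G <- V %*% t(V)
  b <- as.numeric(V %*% c_vec)
  step <- 1 / max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-8)
  for (it in seq_len(n_iter)) {
    z <- simplex_project(z - step * as.numeric(G %*% z - b))
  }
  z
}

#' Initial parameter state for the sampler
#'
#' Builds a starting state from the data in three steps. Per-curve basis
#' coefficients are estimated by ridge-stabilized least squares and clustered
#' by k-means into K groups; allocations start at the simplex-constrained
#' least squares fit of each curve's coefficients on the cluster centers,
#' softened towards the barycenter (weight 0.8 on the fit, 0.2 uniform);
#' feature means start at the cluster centers; and the leading loadings and
#' scores start at the principal components of the coefficient residuals, so
#' the factor structure does not have to be discovered from a cold start
#' (with strong feature-specific covariance and low noise that discovery is
#' the sampler's slowest step). Deterministic given the R random seed.
#'
#' @param data An [fmm_data()].
#' @param basis An [fmm_basis()].
#' @param K,M Model dimensions.
#' @return An `fmm_state`.
#' @export
initial_state <- function(data, basis, K, M) {
  P <- basis$P
  coefs <- t(vapply(seq_len(data$N), function(i) {
    S <- t(eval_basis(basis, data$times[[i]]))
    as.numeric(solve(crossprod(S) + 1e-6 * diag(P), crossprod(S, data$values[[i]])))
  }, numeric(P)))
  if (K > 1) {
    km <- suppressWarnings(kmeans(coefs, centers = min(K, nrow(unique(coefs))),
                                  nstart = 5, iter.max = 50))
    centers <- km$centers
    if (nrow(centers) < K) {
      centers <- centers[rep_len(seq_len(nrow(centers)), K), , drop = FALSE]
    }
    Z <- t(vapply(seq_len(data$N), function(i) {
      simplex_ls(coefs[i, ], centers)
    }, numeric(K)))
    Z <- 0.8 * Z + 0.2 / K
    v <- centers
  } else {
    Z <- matrix(1, data$N, 1L)
    v <- matrix(colMeans(coefs), 1L, P)
  }
  # factor structure from principal components of the coefficient residuals
  E <- coefs - Z %*% v
  phi <- array(0, dim = c(P, M, K))
  chi <- matrix(rnorm(data$N * M, 0, 0.1), data$N, M)
  sv <- tryCatch(svd(E), error = function(e) NULL)
  if (!is.null(sv)) {
    m_use <- min(M, sum(sv$d > 1e-8))
    for (m in seq_len(m_use)) {
      dirn <- sv$v[, m] * sv$d[m] / sqrt(max(data$N - 1, 1))
      scores <- sv$u[, m] * sqrt(max(data$N - 1, 1))
      for (k in seq_len(K)) phi[, m, k] <- dirn
      chi[, m] <- scores
    }
  }
  resid_var <- mean(vapply(seq_len(data$N), function(i) {
    S <- t(eval_basis(basis, data$times[[i]]))
    mean((data$values[[i]] - S %*% coefs[i, ])^2)
  }, numeric(1)))
  fmm_state(
    v = v,
    eta = array(rnorm(P * data$R * K, 0, 0.05), dim = c(P, data$R, K)),
    phi = phi,
    chi = chi,
    Z = Z,
    sigma2 = max(resid_var, 1e-4),
    alpha3 = 1
  )
}

#' Fit the covariate-adjusted functional mixed membership model
#'
#' Runs the Markov chain Monte Carlo sampler: conjugate Gibbs draws for the
#' factor scores, pseudo-eigenfunction coefficients, feature mean and
#' covariate-effect coefficients, noise variance, shrinkage and smoothing
#' blocks, and Metropolis-Hastings moves for the simplex allocations
#' (optionally wrapped in Neal-style tempered transitions) and the mixing
#' parameters. The sweep order is fixed (scores, loadings, means, covariate
#' effects, variance, shrinkage, smoothing, allocations, mixing) so runs are
#' reproducible from the seed alone.
#'
#' Covariates are standardized internally (see [standardize_covariates()]);
#' fitted covariate effects are on the standardized scale and the applied
#' centers/scales are stored in the returned object.
#'
#' @param data An [fmm_data()].
#' @param K Number of latent functional features.
#' @param P Basis dimension (default 8).
#' @param M Number of pseudo-eigenfunctions (default `min(K * P, 3)`).
#' @param basis Optional [fmm_basis()]; default cubic splines on the observed
#'   time range.
#' @param hyper An [fmm_hyper()].
#' @param control An [fmm_control()].
#' @param init Optional starting `fmm_state`; default [initial_state()].
#' @param seed Optional integer seed applied via `set.seed()` before
#'   initialization and sampling.
#' @param validate Abort when [validate_fmm_data()] reports a failure?
#'
#' @return An object of class `fmm_fit` with elements `draws` (named list of
#'   draw-major arrays: `v`, `eta`, `phi`, `chi`, `Z`, `sigma2`, `gamma`,
#'   `delta`, `a1`, `a2`, `tau_v`, `tau_eta`, `pi`, `alpha3`), `loglik`
#'   (marginal log-likelihood trace of the stored draws), `accept`
#'   (acceptance rates), `data`, `basis`, `hyper`, `control`, `design`
#'   (standardization record) and `seed`.
#' @export
fmm_fit <- function(data, K, P = 8L, M = NULL, basis = NULL,
                    hyper = fmm_hyper(), control = fmm_control(),
                    init = NULL, seed = NULL, validate = TRUE) {
  stopifnot(inherits(data, "fmm_data"))
  K <- as.integer(K); P <- as.integer(P)
  if (is.null(M)) M <- min(K * P, 3L)
  M <- as.integer(M)
  if (M < 1L || M > K * P) abort("Need 1 <= M <= K * P.")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(basis)) {
    rng <- range(unlist(data$times, use.names = FALSE))
    basis <- fmm_basis(rng, P = P)
  } else {
    P <- basis$P
  }
  design <- if (data$R > 0) standardize_covariates(data$X) else NULL
  data_std <- data
  if (data$R > 0) data_std$X <- design$X_std
  rep_val <- validate_fmm_data(data_std, design, P)
  if (validate && !attr(rep_val, "ok")) {
    bad <- rep_val$check[rep_val$status == "fail"]
    abort(paste0("Input validation failed: ", paste(bad, collapse = "; "),
                 ". Run validate_fmm_data() for details or use validate = FALSE."))
  }
  if (is.null(init)) init <- initial_state(data_std, basis, K, M)
  packed <- pack_data(data_std, basis)
  res <- cpp_run_mcmc(packed, state_to_cpp(init), hyper_to_cpp(hyper, K),
                      control_to_cpp(control))
  structure(
    list(draws = res$draws, loglik = as.numeric(res$loglik),
         accept = res$accept, tuned = res$tuned,
         final_state = state_from_cpp(res$final_state),
         data = data_std, basis = basis, hyper = hyper, control = control,
         design = design, K = K, P = P, M = M, seed = seed,
         validation = rep_val),
    class = "fmm_fit")
}

#' @export
print.fmm_fit <- function(x, ...) {
  cat(sprintf(
    "<fmm_fit> K = %d features, P = %d, M = %d, N = %d curves, %d stored draws\n",
    x$K, x$P, x$M, x$data$N, n_draws(x)))
  cat(sprintf("  max marginal log-likelihood: %.2f | allocation acceptance: %.2f\n",
              max(x$loglik), x$accept$allocations))
  invisible(x)
}

#' Number of stored posterior draws
#' @param fit An `fmm_fit`.
#' @return Integer count.
#' @export
n_draws <- function(fit) length(fit$draws$sigma2)

#' Extract one stored draw as a parameter state
#'
#' @param fit An `fmm_fit`.
#' @param s Draw index.
#' @return An `fmm_state`.
#' @export
state_from_draw <- function(fit, s) {
  d <- fit$draws
  K <- fit$K; P <- fit$P; M <- fit$M
  R <- dim(d$eta)[3]
  N <- dim(d$Z)[2]
  fmm_state(
    v = matrix(d$v[s, , ], K, P),
    eta = array(d$eta[s, , , ], dim = c(P, R, K)),
    phi = array(d$phi[s, , , ], dim = c(P, M, K)),
    chi = matrix(d$chi[s, , ], N, M),
    Z = matrix(d$Z[s, , ], N, K),
    sigma2 = d$sigma2[s],
    gamma = array(d$gamma[s, , , ], dim = c(P, M, K)),
    delta = matrix(d$delta[s, , ], M, K),
    a1 = d$a1[s, ], a2 = d$a2[s, ],
    tau_v = d$tau_v[s, ],
    tau_eta = matrix(d$tau_eta[s, , ], R, K),
    pi = d$pi[s, ], alpha3 = d$alpha3[s])
}

#' Apply selected sampler update blocks to a state
#'
#' Runs one pass of the named update kernels (the same compiled kernels used
#' by [fmm_fit()]) on a parameter state and returns the updated state. Blocks:
#' `"scores"` (factor scores), `"loadings"` (pseudo-eigenfunction
#' coefficients), `"means"`, `"covariate_effects"`, `"variance"`,
#' `"shrinkage"` (gamma, delta and the MGP shapes), `"smoothing"` (RW1
#' precisions), `"allocations"` (plain Metropolis-Hastings sweep),
#' `"tempered"` (tempered allocation sweep; with an empty ladder this is
#' exactly one plain allocation sweep) and `"mixing"`.
#'
#' @param state An [fmm_state()].
#' @param data An [fmm_data()] with covariates already on the fitted scale.
#' @param basis An [fmm_basis()].
#' @param blocks Character vector of block names, applied in order.
#' @param hyper An [fmm_hyper()].
#' @param control An [fmm_control()] (supplies proposal scales and ladder).
#' @return An `fmm_state`; attribute `"accept"` carries acceptance counts.
#' @export
fmm_update <- function(state, data, basis,
                       blocks = c("scores", "loadings", "means",
                                  "covariate_effects", "variance",
                                  "shrinkage", "smoothing", "allocations",
                                  "mixing"),
                       hyper = fmm_hyper(), control = fmm_control()) {
  stopifnot(inherits(state, "fmm_state"), inherits(data, "fmm_data"))
  packed <- pack_data(data, basis)
  res <- cpp_update_blocks(blocks, packed, state_to_cpp(state),
                           hyper_to_cpp(hyper, state$K),
                           control_to_cpp(control))
  out <- state_from_cpp(res$state)
  attr(out, "accept") <- res$accept
  out
}

#' One full Gibbs sweep
#'
#' Applies every update block once, in the fixed sweep order used by
#' [fmm_fit()].
#'
#' @inheritParams fmm_update
#' @param tempered Use the tempered allocation kernel (with the control's
#'   ladder) instead of the plain one?
#' @return An `fmm_state`.
#' @export
fmm_sweep <- function(state, data, basis, hyper = fmm_hyper(),
                      control = fmm_control(), tempered = FALSE) {
  blocks <- c("scores", "loadings", "means", "covariate_effects", "variance",
              "shrinkage", "smoothing",
              if (tempered) "tempered" else "allocations",
              "scores",   # refresh scores after the marginal allocation move
              "mixing")
  fmm_update(state, data, basis, blocks, hyper, control)
}

#' Simulate observations from a parameter state
#'
#' Draws `y_i ~ N(mean_i, sigma2 I)` at the dataset's time points under the
#' conditional sampling model, returning a copy of the dataset with new
#' values. Used for posterior-predictive checks and simulation-based sampler
#' validation.
#'
#' @param state An [fmm_state()].
#' @param data An [fmm_data()] providing ids, time grids and covariates.
#' @param basis An [fmm_basis()].
#' @return An `fmm_data` with resampled `y`.
#' @export
simulate_observations <- function(state, data, basis) {
  mu <- curve_mean_vectors(state, data, basis)
  values <- lapply(mu, function(m) m + rnorm(length(m), 0, sqrt(state$sigma2)))
  curves <- tibble(
    id = rep(data$ids, data$n_i),
    t = unlist(data$times, use.names = FALSE),
    y = unlist(values, use.names = FALSE))
  covs <- if (data$R > 0) {
    dplyr::bind_cols(tibble(id = data$ids),
                     tibble::as_tibble(as.data.frame(data$X)))
  }
  fmm_data(curves, covs)
}
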