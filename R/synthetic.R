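# Shape library for planted feature structure. The first two shapes echo the
# motivating EEG setting qualitatively (a decaying aperiodic trend and a
# peaked component); the rest are generic smooth curves.
shape_mu <- list(
  function(t) 6 * exp(-2 * t) - 2,
  function(t) 4 * sin(2 * base::pi * t),
  function(t) 4 - 6 * t,
  function(t) 4 * cos(2 * base::pi * t),
  function(t) 8 * (t - 0.5)^2 - 2
)
shape_eta <- list(
  function(t) 2 * sin(base::pi * t),
  function(t) 2 * t - 1,
  function(t) cos(base::pi * t),
  function(t) 1.6 * exp(-t),
  function(t) 1 - 2 * t^2
)

project_to_basis <- function(f, basis, n_grid = 201) {
  g <- seq(basis$domain[1], basis$domain[2], length.out = n_grid)
  B <- t(eval_basis(basis, g))              # n x P
  as.numeric(solve(crossprod(B), crossprod(B, f(g))))
}

#' Construct the frozen ground-truth parameters for simulation studies
#'
#' Builds a deterministic, well-separated truth for a K-feature model:
#' feature means and covariate effects are basis projections of a fixed
#' library of smooth shapes, and the pseudo-eigenfunction coefficients are
#' scaled projections of shifted sinusoids with geometrically decaying
#' magnitudes, so the planted covariance has a small number of dominant
#' directions.
#'
#' @param K,R,M Model dimensions of the truth.
#' @param basis An [fmm_basis()].
#' @param phi_scale Magnitude of the leading pseudo-eigenfunction (later ones
#'   decay geometrically by halves). The default 2 plants strong
#'   feature-specific covariance, the regime in which distinguishing feature
#'   counts is informative; the structure-recovery study uses a gentler 0.5.
#' @param mu_scale Multiplier on the feature mean and covariate-effect
#'   shapes.
#' @return A list with `v` (K x P), `eta` (P x R x K), `phi` (P x M x K).
#' @export
make_truth_parameters <- function(K, R, M, basis, phi_scale = 2, mu_scale = 1) {
  P <- basis$P
  v <- mu_scale * t(vapply(seq_len(K), function(k) {
    project_to_basis(shape_mu[[(k - 1) %% length(shape_mu) + 1]], basis)
  }, numeric(P)))
  eta <- array(0, dim = c(P, R, K))
  idx <- 0
  for (k in seq_len(K)) for (r in seq_len(R)) {
    idx <- idx + 1
    eta[, r, k] <- mu_scale *
      project_to_basis(shape_eta[[(idx - 1) %% length(shape_eta) + 1]], basis)
  }
  phi <- array(0, dim = c(P, M, K))
  scales <- phi_scale * 0.5^(seq_len(M) - 1)
  for (k in seq_len(K)) for (m in seq_len(M)) {
    f <- local({
      kk <- k; mm <- m
      function(t) sin((mm + 0.5 * (kk - 1)) * base::pi * t + 0.3 * kk)
    })
    phi[, m, k] <- scales[m] * project_to_basis(f, basis)
  }
  list(v = v, eta = eta, phi = phi)
}

#' Simulate a dataset from the generative model
#'
#' Draws a dataset from the model's own sampling process: standardized
#' Gaussian covariates, Dirichlet allocations (optionally anchored so the
#' separability condition holds by construction), standard-normal factor
#' scores, and observations equal to the allocation-weighted feature means
#' plus score-weighted pseudo-eigenfunctions plus iid Gaussian noise, on a
#' regular time grid per curve.
#'
#' @param n_curves Number of curves N.
#' @param K,R,M Truth dimensions.
#' @param P Basis dimension of the truth (default 8).
#' @param n_points Observed time points per curve (regular grid, default 25).
#' @param order Spline order of the truth basis (default `min(4, P)`).
#' @param domain Time domain (default `c(0, 1)`).
#' @param sigma2 Observation noise variance (default 0.0025, i.e. noise
#'   standard deviation 0.05 against feature curves of amplitude 4-6: the
#'   high signal-to-noise regime of smoothed spectral curves).
#' @param alpha_z Symmetric Dirichlet concentration of the allocations
#'   (default 1.5 per component).
#' @param anchor Plant one pure observation per feature (curves 1..K set to
#'   the simplex vertices) so the separability condition holds by
#'   construction? Default `TRUE`.
#' @param truth Optional truth parameters from [make_truth_parameters()]
#'   (reused across replicate datasets in the studies).
#' @param seed Integer seed; the same seed reproduces the dataset bitwise.
#' @return A list with `data` (an [fmm_data()]), `truth` (generating
#'   `fmm_state` plus `basis` and `seed`), and `basis`.
#' @export
simulate_fmm_data <- function(n_curves, K = 2L, R = 0L, M = 2L, P = 8L,
                              n_points = 25L, order = NULL, domain = c(0, 1),
                              sigma2 = 0.0025, alpha_z = 1.5, anchor = TRUE,
                              truth = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(order)) order <- min(4L, P)
  basis <- fmm_basis(domain, P = P, order = order)
  if (is.null(truth)) truth <- make_truth_parameters(K, R, M, basis)
  N <- as.integer(n_curves)
  X <- if (R > 0) {
    Xr <- matrix(rnorm(N * R), N, R)
    standardize_covariates(Xr)$X_std
  } else matrix(0, N, 0)
  Z <- t(vapply(seq_len(N), function(i) rdirichlet1(rep(alpha_z, K)), numeric(K)))
  if (anchor && N >= K) {
    for (k in seq_len(K)) {
      Z[k, ] <- 0
      Z[k, k] <- 1
    }
  }
  chi <- matrix(rnorm(N * M), N, M)
  tgrid <- seq(domain[1], domain[2], length.out = n_points)
  S <- t(eval_basis(basis, tgrid))          # n x P
  values <- vector("list", N)
  for (i in seq_len(N)) {
    a <- numeric(P)
    Phib <- matrix(0, P, M)
    for (k in seq_len(K)) {
      ck <- truth$v[k, ]
      if (R > 0) ck <- ck + as.numeric(matrix(truth$eta[, , k], P, R) %*% X[i, ])
      a <- a + Z[i, k] * ck
      Phib <- Phib + Z[i, k] * matrix(truth$phi[, , k], P, M)
    }
    mu <- as.numeric(S %*% (a + Phib %*% chi[i, ]))
    values[[i]] <- mu + rnorm(n_points, 0, sqrt(sigma2))
  }
  ids <- sprintf("c%03d", seq_len(N))
  curves <- tibble(id = rep(ids, each = n_points), t = rep(tgrid, N),
                   y = unlist(values, use.names = FALSE))
  covs <- if (R > 0) {
    colnames(X) <- paste0("x", seq_len(R))
    dplyr::bind_cols(tibble(id = ids), tibble::as_tibble(as.data.frame(X)))
  }
  data <- fmm_data(curves, covs)
  truth_state <- fmm_state(v = truth$v, eta = truth$eta, phi = truth$phi,
                           chi = chi, Z = Z, sigma2 = sigma2)
  list(data = data, truth = list(state = truth_state, basis = basis, seed = seed),
       basis = basis)
}

#' Scenario grid for the structure-recovery study
#'
#' Lays out the nine-scenario recovery study: data generated from a
#' two-feature model with R in {0, 1, 2} covariates, crossed with three
#' sample sizes, each with per-replicate seeds. Each scenario carries its fit
#' specifications: the correctly specified fit, plus two misspecified
#' fits (data with one covariate fit without covariates; data with no
#' covariates fit with one randomly generated covariate).
#'
#' @param sample_sizes Three sample sizes (default 40, 80, 160).
#' @param n_reps Replicate datasets per scenario.
#' @param n_points Points per curve (regular grid, default 25).
#' @param sigma2,phi_scale Truth conditions for this study: moderate noise
#'   (0.04) and gentle feature-specific covariance (leading loading 0.5), so
#'   estimation error is dominated by sample size rather than posterior
#'   multimodality.
#' @param seed Master seed from which per-replicate seeds are derived.
#' @return A tibble with one row per (scenario, replicate, fit spec):
#'   columns `scenario`, `R_gen`, `N`, `rep`, `data_seed`, `fit`,
#'   `R_fit`, `random_covariate`, plus the truth conditions.
#' @export
study1_scenarios <- function(sample_sizes = c(40L, 80L, 160L), n_reps = 50L,
                             n_points = 25L, sigma2 = 0.04, phi_scale = 0.5,
                             seed = 1L) {
  stopifnot(length(sample_sizes) == 3L)
  grid <- tidyr::expand_grid(R_gen = c(0L, 1L, 2L),
                             N = as.integer(sample_sizes),
                             rep = seq_len(n_reps))
  grid$scenario <- paste0("R", grid$R_gen, "_N", grid$N)
  grid$data_seed <- seed + 1000L * grid$R_gen + 10L * grid$N + grid$rep
  grid$n_points <- as.integer(n_points)
  grid$sigma2 <- sigma2
  grid$phi_scale <- phi_scale
  fits <- dplyr::bind_rows(
    dplyr::mutate(grid, fit = "correct", R_fit = .data$R_gen,
                  random_covariate = FALSE),
    dplyr::mutate(dplyr::filter(grid, .data$R_gen == 1L), fit = "underspecified",
                  R_fit = 0L, random_covariate = FALSE),
    dplyr::mutate(dplyr::filter(grid, .data$R_gen == 0L), fit = "overspecified",
                  R_fit = 1L, random_covariate = TRUE)
  )
  dplyr::arrange(fits, .data$R_gen, .data$N, .data$rep, .data$fit)
}

#' Scenario list for the information-criteria study
#'
#' Generation and fit specifications for the model-selection study: replicate
#' datasets from one frozen three-feature, one-covariate truth, each fit with
#' K in `K_fits`. All replicates share the same truth parameters and differ
#' only through the seeds driving allocations, scores, covariates and noise.
#'
#' @param n_datasets Number of replicate datasets (default 50).
#' @param N Curves per dataset (default 120).
#' @param n_points Points per curve (default 25).
#' @param K_true,R,P,M Truth dimensions (defaults K = 3 features, one
#'   covariate, P = 8, M = 3).
#' @param K_fits Feature counts to fit (default 2:5).
#' @param sigma2,phi_scale Truth conditions for this study: low noise and
#'   strong feature-specific covariance (the generator defaults), the regime
#'   in which the number of features is statistically identifiable from
#'   moderate samples.
#' @param seed Master seed.
#' @return A tibble with one row per (dataset, fitted K).
#' @export
study2_scenario <- function(n_datasets = 50L, N = 120L, n_points = 25L,
                            K_true = 3L, R = 1L, P = 8L, M = 3L,
                            K_fits = 2:5, sigma2 = 0.0025, phi_scale = 2,
                            seed = 1L) {
  grid <- tidyr::expand_grid(dataset = seq_len(n_datasets),
                             K_fit = as.integer(K_fits))
  grid$K_true <- as.integer(K_true)
  grid$R <- as.integer(R)
  grid$P <- as.integer(P)
  grid$M <- as.integer(M)
  grid$N <- as.integer(N)
  grid$n_points <- as.integer(n_points)
  grid$sigma2 <- sigma2
  grid$phi_scale <- phi_scale
  grid$data_seed <- seed + 17L * grid$dataset
  grid
}
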