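# Shared builders for small test instances. Everything is generated in code;
# no fixture files.

tiny_basis <- function(P = 4L, order = min(4L, P), domain = c(0, 1)) {
  fmm_basis(domain, P = P, order = order)
}

# a deterministic small dataset: N curves on a shared regular grid
tiny_data <- function(N = 4L, n = 6L, R = 0L, seed = 42L) {
  set.seed(seed)
  tgrid <- seq(0, 1, length.out = n)
  curves <- tibble::tibble(
    id = rep(sprintf("c%02d", seq_len(N)), each = n),
    t = rep(tgrid, N),
    y = rnorm(N * n))
  covs <- if (R > 0) {
    X <- matrix(rnorm(N * R), N, R)
    X <- scale(X)[, , drop = FALSE]
    cbind(data.frame(id = sprintf("c%02d", seq_len(N))),
          as.data.frame(matrix(as.numeric(X), N, R,
                               dimnames = list(NULL, paste0("x", seq_len(R))))))
  }
  fmm_data(curves, covs)
}

# a valid random state matched to data dimensions
tiny_state <- function(data, basis, K = 2L, M = 1L, seed = 7L, sigma2 = 0.5) {
  set.seed(seed)
  P <- basis$P
  Zr <- vapply(seq_len(data$N), function(i) {
    g <- rgamma(K, 2, 1); g / sum(g)
  }, numeric(K))
  Z <- if (K == 1L) matrix(1, data$N, 1L) else t(Zr)
  fmm_state(
    v = matrix(rnorm(K * P), K, P),
    eta = array(rnorm(P * data$R * K, 0, 0.5), dim = c(P, data$R, K)),
    phi = array(rnorm(P * M * K, 0, 0.5), dim = c(P, M, K)),
    chi = matrix(rnorm(data$N * M), data$N, M),
    Z = Z, sigma2 = sigma2)
}

# replace the observations of `data` with draws from the conditional model
with_model_values <- function(data, state, basis, noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fmmm:::curve_mean_vectors(state, data, basis)
  values <- lapply(mu, function(m) {
    if (noise) m + rnorm(length(m), 0, sqrt(state$sigma2)) else m
  })
  curves <- tibble::tibble(
    id = rep(data$ids, data$n_i),
    t = unlist(data$times, use.names = FALSE),
    y = unlist(values, use.names = FALSE))
  covs <- if (data$R > 0) {
    cbind(data.frame(id = data$ids), as.data.frame(data$X))
  }
  fmm_data(curves, covs)
}

fast_control <- function(n_iter = 200L, burnin = 50L, ...) {
  fmm_control(n_iter = n_iter, burnin = burnin, ...)
}

# permutation applied to every feature-indexed block of a single draw,
# used to build chains with artificial label switching
flip_draw_labels <- function(fit, s) {
  fmmm:::permute_fit_draw(fit, s, rev(seq_len(fit$K)))
}

# independent dense multivariate normal log-density (solve/determinant route,
# deliberately different from the package's Cholesky/Woodbury paths)
dmvnorm_log <- function(y, mu, V) {
  r <- as.numeric(y - mu)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * length(r) * log(2 * pi) - 0.5 * ld - 0.5 * sum(r * solve(V, r))
}
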