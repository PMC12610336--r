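all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0L) {
      out[[length(out) + 1L]] <<- prefix
    } else {
      for (j in seq_along(rest)) rec(c(prefix, rest[j]), rest[-j])
    }
  }
  rec(integer(0), seq_len(K))
  out
}

permute_fit_draw <- function(fit, s, perm) {
  d <- fit$draws
  d$v[s, , ] <- d$v[s, perm, , drop = FALSE]
  if (dim(d$eta)[3] > 0) d$eta[s, , , ] <- d$eta[s, , , perm, drop = FALSE]
  d$phi[s, , , ] <- d$phi[s, , , perm, drop = FALSE]
  d$gamma[s, , , ] <- d$gamma[s, , , perm, drop = FALSE]
  d$Z[s, , ] <- d$Z[s, , perm, drop = FALSE]
  d$delta[s, , ] <- d$delta[s, , perm, drop = FALSE]
  d$a1[s, ] <- d$a1[s, perm]
  d$a2[s, ] <- d$a2[s, perm]
  d$tau_v[s, ] <- d$tau_v[s, perm]
  if (dim(d$tau_eta)[2] > 0) d$tau_eta[s, , ] <- d$tau_eta[s, , perm, drop = FALSE]
  d$pi[s, ] <- d$pi[s, perm]
  fit$draws <- d
  fit
}

#' Resolve label switching across stored draws
#'
#' Mixed membership posteriors are invariant to permuting the feature labels,
#' so a chain can switch labels between draws. For each draw this finds the
#' permutation minimizing the summed L2 distance between the draw's
#' population-level feature mean curves (at covariates zero, on `grid`) and
#' those of a reference draw (the draw with maximal marginal log-likelihood),
#' and applies it simultaneously to every feature-indexed block (`v`, `eta`,
#' `phi`, `gamma`, `delta`, `a1`, `a2`, `tau_v`, `tau_eta`, `Z` columns and
#' `pi`). Relabeling is a pure reparameterization: it leaves every draw's
#' likelihood unchanged.
#'
#' @param fit An `fmm_fit`.
#' @param grid Number of grid points for the curve distance (default 100).
#' @return The relabeled `fmm_fit`; attribute `"permutations"` records the
#'   permutation applied to each draw.
#' @export
relabel_draws <- function(fit, grid = 100L) {
  stopifnot(inherits(fit, "fmm_fit"))
  S <- n_draws(fit)
  K <- fit$K
  g <- seq(fit$basis$domain[1], fit$basis$domain[2], length.out = grid)
  B <- eval_basis(fit$basis, g)              # P x G
  ref_s <- which.max(fit$loglik)
  ref <- matrix(fit$draws$v[ref_s, , ], K, fit$P) %*% B   # K x G
  perms <- all_permutations(K)
  applied <- matrix(0L, S, K)
  for (s in seq_len(S)) {
    cur <- matrix(fit$draws$v[s, , ], K, fit$P) %*% B
    cost <- matrix(0, K, K)
    for (k in seq_len(K)) for (j in seq_len(K)) {
      cost[k, j] <- sum((cur[j, ] - ref[k, ])^2)   # assign old j to slot k
    }
    best <- perms[[which.min(vapply(perms, function(p) {
      sum(cost[cbind(seq_len(K), p)])
    }, numeric(1)))]]
    applied[s, ] <- best
    if (!identical(best, seq_len(K))) fit <- permute_fit_draw(fit, s, best)
  }
  attr(fit, "permutations") <- applied
  fit
}

#' Rescale a two-feature chain to satisfy the separability condition
#'
#' The allocation structure is identifiable only up to invertible affine
#' maps of the simplex unless at least one observation belongs entirely to
#' each feature (the separability condition). For K = 2 this is enforced by
#' post-processing: in each draw the first allocation column is affinely
#' rescaled so its minimum is 0 and maximum is 1, and the feature blocks
#' (`v`, `eta`, and each pseudo-eigenfunction slice of `phi`) receive the
#' compensating inverse linear map, so every curve's marginal mean and
#' covariance - and hence its likelihood - are unchanged. Draws whose first
#' allocation column is constant cannot be rescaled and are flagged instead.
#'
#' @param fit An `fmm_fit` with K = 2.
#' @return The rescaled `fmm_fit`; attribute `"degenerate"` flags draws left
#'   untransformed.
#' @export
rescale_separability <- function(fit) {
  stopifnot(inherits(fit, "fmm_fit"))
  if (fit$K != 2L) {
    abort("Separability rescaling is implemented for K = 2 only; for three or more features the weaker sufficiently-scattered post-processing is out of scope.")
  }
  S <- n_draws(fit)
  N <- dim(fit$draws$Z)[2]
  degenerate <- logical(S)
  for (s in seq_len(S)) {
    z1 <- fit$draws$Z[s, , 1]
    lo <- min(z1); hi <- max(z1)
    if (hi - lo < 1e-12) {
      degenerate[s] <- TRUE
      next
    }
    a <- 1 / (hi - lo)
    cc <- -lo / (hi - lo)
    Tm <- rbind(c(a + cc, 1 - a - cc),
                c(cc, 1 - cc))
    Tinv <- solve(Tm)
    # direct affine map: the extreme curves land exactly on 0 and 1
    z1 <- (fit$draws$Z[s, , 1] - lo) / (hi - lo)
    z1 <- pmin(pmax(z1, 0), 1)
    fit$draws$Z[s, , ] <- cbind(z1, 1 - z1)
    fit$draws$v[s, , ] <- Tinv %*% matrix(fit$draws$v[s, , ], 2, fit$P)
    R <- dim(fit$draws$eta)[3]
    for (r in seq_len(R)) {
      E <- t(matrix(fit$draws$eta[s, , r, ], fit$P, 2))   # 2 x P
      fit$draws$eta[s, , r, ] <- t(Tinv %*% E)
    }
    for (m in seq_len(fit$M)) {
      Phi <- t(matrix(fit$draws$phi[s, , m, ], fit$P, 2)) # 2 x P
      fit$draws$phi[s, , m, ] <- t(Tinv %*% Phi)
    }
  }
  attr(fit, "degenerate") <- degenerate
  fit
}

trapezoid_weights <- function(g) {
  G <- length(g)
  w <- numeric(G)
  w[1] <- (g[2] - g[1]) / 2
  w[G] <- (g[G] - g[G - 1]) / 2
  if (G > 2) w[2:(G - 1)] <- (g[3:G] - g[1:(G - 2)]) / 2
  w
}

eigen_from_surface <- function(C, g, n_keep) {
  C <- (C + t(C)) / 2
  w <- trapezoid_weights(g)
  sw <- sqrt(w)
  A <- sweep(sweep(C, 1, sw, `*`), 2, sw, `*`)
  e <- eigen(A, symmetric = TRUE)
  lambda <- e$values
  funs <- sweep(e$vectors, 1, sw, `/`)
  for (j in seq_len(ncol(funs))) {
    jmax <- which.max(abs(funs[, j]))
    if (funs[jmax, j] < 0) funs[, j] <- -funs[, j]
  }
  list(lambda = lambda[seq_len(n_keep)], functions = funs[, seq_len(n_keep), drop = FALSE])
}

#' Eigen-analysis of the posterior covariance surfaces
#'
#' The sampler works with unconstrained scaled pseudo-eigenfunctions, so the
#' individual loading vectors are not interpretable. A proper eigen-analysis
#' reconstructs each draw's covariance surface on a grid, discretizes the
#' covariance operator with trapezoid quadrature weights, and
#' eigendecomposes, yielding eigenvalues and eigenfunctions orthonormal in
#' L2 on the grid. Eigenfunction signs are fixed so the largest-magnitude
#' value is positive.
#'
#' @param fit An `fmm_fit`, or a single [fmm_state()] (then `basis` must be
#'   supplied).
#' @param grid Evaluation grid (numeric vector) or a point count (default
#'   101 equispaced points over the domain).
#' @param which `"pooled"` (average of all covariance and cross-covariance
#'   surfaces, the covariance of an evenly allocated curve) or an integer
#'   feature index `k` (the surface `C_kk`); or `c(k, k2)` for a specific
#'   pair.
#' @param n_keep Number of leading eigenpairs to keep (default M).
#' @param basis Required when `fit` is an `fmm_state`.
#' @return A list of class `fmm_eigen`: `grid`, `lambda` (draws x n_keep)
#'   and `functions` (draws x grid x n_keep arrays), plus a tidy `summary`
#'   tibble of posterior-median eigenvalues.
#' @export
covariance_eigen <- function(fit, grid = 101L, which = "pooled",
                             n_keep = NULL, basis = NULL) {
  single <- inherits(fit, "fmm_state")
  if (single) {
    state1 <- fit
    if (is.null(basis)) abort("Supply `basis` when giving a single state.")
    S <- 1L; M <- state1$M
    dom <- basis$domain
  } else {
    stopifnot(inherits(fit, "fmm_fit"))
    S <- n_draws(fit); M <- fit$M
    basis <- fit$basis
    dom <- basis$domain
  }
  g <- if (length(grid) == 1L) seq(dom[1], dom[2], length.out = grid) else grid
  G <- length(g)
  if (is.null(n_keep)) n_keep <- M
  n_keep <- min(n_keep, G)
  lambda <- matrix(0, S, n_keep)
  funs <- array(0, dim = c(S, G, n_keep))
  for (s in seq_len(S)) {
    st <- if (single) state1 else state_from_draw(fit, s)
    C <- matrix(0, G, G)
    if (identical(which, "pooled")) {
      for (k in seq_len(st$K)) for (k2 in seq_len(st$K)) {
        C <- C + covariance_surface(st, k, k2, g, g, basis) / st$K^2
      }
    } else {
      kk <- as.integer(which)
      if (length(kk) == 1L) kk <- c(kk, kk)
      C <- covariance_surface(st, kk[1], kk[2], g, g, basis)
    }
    e <- eigen_from_surface(C, g, n_keep)
    lambda[s, ] <- e$lambda
    funs[s, , ] <- e$functions
  }
  summary <- tibble(component = seq_len(n_keep),
                    lambda_median = apply(lambda, 2, median),
                    lambda_lower = apply(lambda, 2, quantile, 0.025),
                    lambda_upper = apply(lambda, 2, quantile, 0.975))
  structure(list(grid = g, lambda = lambda, functions = funs,
                 summary = summary, which = which),
            class = "fmm_eigen")
}

band_tbl <- function(mat, g, probs) {
  tibble(t = g,
         median = apply(mat, 2, median),
         lower = apply(mat, 2, quantile, probs[1]),
         upper = apply(mat, 2, quantile, probs[2]))
}

#' Posterior summaries: feature mean bands, allocations and trajectories
#'
#' Produces the standard posterior reports: pointwise median and credible
#' bands for each feature's mean curve at requested covariate values;
#' posterior summaries of each curve's allocations; and trajectory estimates
#' conditional on fixed allocation vectors `z*` (plugging `z*` into the mean
#' structure), the construction used to compare e.g. percentile-conditional
#' developmental trajectories.
#'
#' @param fit An `fmm_fit` (typically after [relabel_draws()]).
#' @param x_values A list of covariate vectors (standardized scale), a data
#'   frame with one row per covariate setting, or `NULL` for covariates at
#'   zero.
#' @param grid Grid points (count or vector; default 100 equispaced).
#' @param quantiles Lower/upper band probabilities (default central 95%).
#' @param z_star Optional list of allocation vectors for conditional
#'   trajectories; entries must lie on the simplex.
#' @param z_percentiles Optional numeric percentiles in (0, 1); for K = 2,
#'   trajectories are also computed at the empirical percentiles of the
#'   posterior-median first allocation column.
#' @return A list of tibbles: `means` (feature, x_label, t, median, lower,
#'   upper), `allocations` (id, feature, mean, median, lower, upper) and
#'   `trajectories` (z_label, x_label, t, median, lower, upper).
#' @export
summarize_fit <- function(fit, x_values = NULL, grid = 100L,
                          quantiles = c(0.025, 0.975), z_star = NULL,
                          z_percentiles = NULL) {
  stopifnot(inherits(fit, "fmm_fit"))
  if (any(quantiles <= 0 | quantiles >= 1)) abort("`quantiles` must be inside (0, 1).")
  probs <- sort(quantiles[1:2])
  R <- dim(fit$draws$eta)[3]
  if (is.null(x_values)) x_values <- list(rep(0, R))
  if (is.data.frame(x_values)) {
    x_values <- lapply(seq_len(nrow(x_values)), function(i) as.numeric(x_values[i, ]))
  }
  g <- if (length(grid) == 1L) {
    seq(fit$basis$domain[1], fit$basis$domain[2], length.out = grid)
  } else grid
  B <- eval_basis(fit$basis, g)              # P x G
  S <- n_draws(fit); K <- fit$K
  N <- dim(fit$draws$Z)[2]

  # draw-by-feature-by-x mean curves
  curves <- vector("list", length(x_values))
  for (xi in seq_along(x_values)) {
    x <- as.numeric(x_values[[xi]])
    if (length(x) != R) abort(sprintf("x_values[[%d]] has length %d, expected R = %d.", xi, length(x), R))
    curves[[xi]] <- lapply(seq_len(K), function(k) {
      coefs <- matrix(fit$draws$v[, k, ], S, fit$P)
      if (R > 0) {
        for (r in seq_len(R)) {
          coefs <- coefs + matrix(fit$draws$eta[, , r, k], S, fit$P) * x[r]
        }
      }
      coefs %*% B                            # S x G
    })
  }
  x_labels <- vapply(x_values, function(x) {
    if (length(x) == 0) "x=()" else paste0("x=(", paste(signif(x, 3), collapse = ","), ")")
  }, character(1))

  means <- dplyr::bind_rows(lapply(seq_along(x_values), function(xi) {
    dplyr::bind_rows(lapply(seq_len(K), function(k) {
      dplyr::mutate(band_tbl(curves[[xi]][[k]], g, probs),
                    feature = k, x_label = x_labels[xi], .before = 1)
    }))
  }))

  alloc <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    Zk <- matrix(fit$draws$Z[, , k], S, N)
    tibble(id = fit$data$ids, feature = k,
           mean = colMeans(Zk),
           median = apply(Zk, 2, median),
           lower = apply(Zk, 2, quantile, probs[1]),
           upper = apply(Zk, 2, quantile, probs[2]))
  }))

  zs <- z_star %||% list()
  zlabels <- if (length(zs)) {
    vapply(zs, function(z) paste0("z=(", paste(signif(z, 3), collapse = ","), ")"),
           character(1))
  } else character(0)
  if (!is.null(z_percentiles) && K == 2L) {
    zmed <- apply(matrix(fit$draws$Z[, , 1], S, N), 2, median)
    for (p in z_percentiles) {
      q <- as.numeric(quantile(zmed, p))
      zs <- c(zs, list(c(q, 1 - q)))
      zlabels <- c(zlabels, sprintf("pct=%g", 100 * p))
    }
  }
  trajectories <- if (length(zs)) {
    dplyr::bind_rows(lapply(seq_along(zs), function(j) {
      z <- zs[[j]]
      if (length(z) != K || abs(sum(z) - 1) > 1e-8) {
        abort("Each z* must be a length-K vector on the simplex.")
      }
      dplyr::bind_rows(lapply(seq_along(x_values), function(xi) {
        m <- Reduce(`+`, lapply(seq_len(K), function(k) z[k] * curves[[xi]][[k]]))
        dplyr::mutate(band_tbl(m, g, probs),
                      z_label = zlabels[j], x_label = x_labels[xi], .before = 1)
      }))
    }))
  } else {
    tibble(z_label = character(0), x_label = character(0), t = numeric(0),
           median = numeric(0), lower = numeric(0), upper = numeric(0))
  }

  list(means = means, allocations = alloc, trajectories = trajectories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
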