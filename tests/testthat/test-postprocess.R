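small_fit <- function(K = 2, R = 1, seed = 31, n_iter = 300, burnin = 100,
                      sigma2 = 0.04, phi_scale = 0.5, N = 12) {
  bs <- fmm_basis(c(0, 1), 6)
  tr <- make_truth_parameters(K, R, 2, bs, phi_scale = phi_scale)
  sim <- simulate_fmm_data(N, K = K, R = R, M = 2, P = 6, n_points = 12,
                           sigma2 = sigma2, truth = tr, seed = seed)
  fit <- fmm_fit(sim$data, K = K, P = 6, M = 2,
                 control = fmm_control(n_iter = n_iter, burnin = burnin),
                 seed = seed + 1)
  list(fit = fit, sim = sim)
}

fit_loglik_by_draw <- function(fit) {
  packed <- fmmm:::pack_data(fit$data, fit$basis)
  vapply(seq_len(n_draws(fit)), function(s) {
    fmmm:::cpp_marginal_loglik(packed, fmmm:::state_to_cpp(state_from_draw(fit, s)))
  }, numeric(1))
}

test_that("relabeling aligns deliberately flipped draws and is likelihood-preserving", {
  sf <- small_fit()
  fit <- sf$fit
  ll_before <- fit_loglik_by_draw(fit)

  # no-switch chain: relabeling applies the identity everywhere
  rl <- relabel_draws(fit)
  perms <- attr(rl, "permutations")
  expect_true(all(perms == rep(1:2, each = nrow(perms))))

  # flip labels on odd draws: relabeling must undo exactly that
  flipped <- fit
  odd <- seq(1, n_draws(fit), by = 2)
  for (s in odd) flipped <- flip_draw_labels(flipped, s)
  var_flipped <- var(flipped$draws$v[, 1, 1])
  fixed <- relabel_draws(flipped)
  # all draws end up in one consistent orientation: either the original or
  # the globally flipped one (the reference draw may itself be a flipped one)
  all_flipped <- fit
  for (s in seq_len(n_draws(fit))) all_flipped <- flip_draw_labels(all_flipped, s)
  match_orig <- isTRUE(all.equal(fixed$draws$v, fit$draws$v))
  match_flip <- isTRUE(all.equal(fixed$draws$v, all_flipped$draws$v))
  expect_true(match_orig || match_flip)
  expect_lt(var(fixed$draws$v[, 1, 1]), var_flipped)

  ll_after <- fit_loglik_by_draw(fixed)
  expect_equal(ll_after, ll_before, tolerance = 1e-10)
})

test_that("separability rescaling pins allocations to [0, 1] and preserves likelihoods", {
  sf <- small_fit()
  fit <- relabel_draws(sf$fit)
  ll_before <- fit_loglik_by_draw(fit)
  rs <- rescale_separability(fit)
  S <- n_draws(rs)
  for (s in seq_len(S)) {
    z1 <- rs$draws$Z[s, , 1]
    expect_equal(min(z1), 0)
    expect_equal(max(z1), 1)
    Z <- matrix(rs$draws$Z[s, , ], ncol = 2)
    expect_true(all(Z >= 0 & Z <= 1))
    expect_equal(rowSums(Z), rep(1, nrow(Z)), tolerance = 1e-12)
  }
  ll_after <- fit_loglik_by_draw(rs)
  expect_equal(ll_after, ll_before, tolerance = 1e-6)
  # reparameterizations are exact: relative error below 1e-8
  expect_lt(max(abs(ll_after - ll_before)) / max(1, max(abs(ll_before))), 1e-8)
})

test_that("rescaling an already separable draw is the identity and degenerate draws are flagged", {
  bs <- fmm_basis(c(0, 1), 5)
  d <- tiny_data(N = 3, n = 7)
  st <- tiny_state(d, bs, K = 2, M = 1)
  st$Z <- rbind(c(1, 0), c(0, 1), c(0.4, 0.6))
  fit <- list(draws = list(
                v = array(st$v, dim = c(1, 2, 5)),
                eta = array(0, dim = c(1, 5, 0, 2)),
                phi = array(st$phi, dim = c(1, 5, 1, 2)),
                chi = array(st$chi, dim = c(1, 3, 1)),
                Z = array(st$Z, dim = c(1, 3, 2)),
                sigma2 = st$sigma2,
                gamma = array(1, dim = c(1, 5, 1, 2)),
                delta = array(1, dim = c(1, 1, 2)),
                a1 = matrix(2, 1, 2), a2 = matrix(3, 1, 2),
                tau_v = matrix(1, 1, 2), tau_eta = array(1, dim = c(1, 0, 2)),
                pi = matrix(0.5, 1, 2), alpha3 = 1),
              loglik = 0, K = 2L, P = 5L, M = 1L,
              basis = bs, data = d)
  class(fit) <- "fmm_fit"
  rs <- rescale_separability(fit)
  expect_equal(rs$draws$Z[1, , ], st$Z, ignore_attr = TRUE)
  expect_equal(rs$draws$v[1, , ], st$v, ignore_attr = TRUE)
  expect_false(any(attr(rs, "degenerate")))

  # constant first allocation column cannot be rescaled
  fit$draws$Z[1, , ] <- matrix(0.5, 3, 2)
  rs2 <- rescale_separability(fit)
  expect_true(attr(rs2, "degenerate")[1])
  expect_equal(rs2$draws$Z[1, , ], matrix(0.5, 3, 2), ignore_attr = TRUE)
})

test_that("covariance eigen-analysis recovers planted orthogonal structure", {
  bs <- fmm_basis(c(0, 1), 8)
  g <- seq(0, 1, length.out = 201)
  w <- fmmm:::trapezoid_weights(g)
  # orthonormalize two basis-representable functions on this very grid
  B <- t(eval_basis(bs, g))                  # G x P
  c1 <- fmmm:::project_to_basis(function(t) sin(2 * pi * t), bs)
  c2 <- fmmm:::project_to_basis(function(t) cos(2 * pi * t), bs)
  f1 <- B %*% c1
  f1 <- f1 / sqrt(sum(w * f1^2))
  f2 <- B %*% c2
  f2 <- f2 - f1 * sum(w * f1 * f2)
  f2 <- f2 / sqrt(sum(w * f2^2))
  # coefficients reproducing f1, f2 exactly on the grid (LS in the basis)
  WB <- sweep(B, 1, w, `*`)
  proj <- solve(crossprod(B, WB), t(WB))
  u1 <- proj %*% f1; u2 <- proj %*% f2
  lam <- c(2.0, 0.5)
  phi <- array(0, dim = c(8, 2, 1))
  phi[, 1, 1] <- sqrt(lam[1]) * u1
  phi[, 2, 1] <- sqrt(lam[2]) * u2
  st <- fmm_state(v = matrix(0, 1, 8), phi = phi, chi = matrix(0, 1, 2),
                  Z = matrix(1, 1, 1), sigma2 = 1)
  eig <- covariance_eigen(st, grid = g, which = 1L, basis = bs)
  expect_equal(as.numeric(eig$lambda[1, ]), lam, tolerance = 1e-8)
  err1 <- min(sqrt(sum(w * (eig$functions[1, , 1] - f1)^2)),
              sqrt(sum(w * (eig$functions[1, , 1] + f1)^2)))
  err2 <- min(sqrt(sum(w * (eig$functions[1, , 2] - f2)^2)),
              sqrt(sum(w * (eig$functions[1, , 2] + f2)^2)))
  expect_lt(err1, 1e-6)
  expect_lt(err2, 1e-6)
})

test_that("eigenvalues are nonnegative, at most M are nonzero, and vanish for zero loadings", {
  sf <- small_fit(n_iter = 120, burnin = 40)
  eig <- covariance_eigen(sf$fit, grid = 41L, which = "pooled", n_keep = 4)
  expect_true(all(eig$lambda > -1e-8))
  st0 <- tiny_state(tiny_data(N = 2, n = 5), tiny_basis(P = 4), K = 2, M = 1)
  st0$phi[] <- 0
  e0 <- covariance_eigen(st0, grid = 31L, which = "pooled", basis = tiny_basis(P = 4))
  expect_equal(max(abs(e0$lambda)), 0)
  # rank bound: counting relative to the largest eigenvalue
  stm <- tiny_state(tiny_data(N = 2, n = 5), tiny_basis(P = 6), K = 2, M = 2)
  em <- covariance_eigen(stm, grid = 51L, which = 1L, n_keep = 6,
                         basis = tiny_basis(P = 6))
  big <- sum(em$lambda[1, ] > 1e-8 * em$lambda[1, 1])
  expect_lte(big, stm$M)
})

test_that("posterior summaries degenerate correctly and respect convexity endpoints", {
  sf <- small_fit(n_iter = 150, burnin = 50)
  fit <- sf$fit
  sm <- summarize_fit(fit, x_values = list(0), grid = 21L,
                      z_star = list(c(1, 0)))
  f1 <- dplyr::filter(sm$means, .data$feature == 1)
  tr <- sm$trajectories
  expect_equal(tr$median, f1$median)
  expect_equal(tr$lower, f1$lower)

  # single-draw chain: medians equal that draw's curve, bands collapse
  one <- fit
  keep1 <- function(a) {
    d <- dim(a); d[1] <- 1L
    array(utils::head(a, prod(d)), dim = d)
  }
  one$draws <- lapply(fit$draws, function(a) {
    if (is.null(dim(a))) a[1] else {
      ix <- as.list(rep(TRUE, length(dim(a)))); ix[[1]] <- 1L
      out <- do.call(`[`, c(list(a), ix, list(drop = FALSE)))
      out
    }
  })
  one$loglik <- fit$loglik[1]
  sm1 <- summarize_fit(one, x_values = list(0), grid = 11L)
  st1 <- state_from_draw(one, 1)
  expect_equal(dplyr::filter(sm1$means, .data$feature == 2)$median,
               mean_function(st1, 2, 0, seq(0, 1, length.out = 11), fit$basis))
  expect_equal(sm1$means$lower, sm1$means$upper)
  expect_error(summarize_fit(fit, quantiles = c(0, 1.2)), "inside")
})

test_that("summaries are equivariant under relabeling", {
  sf <- small_fit(n_iter = 150, burnin = 50)
  fit <- sf$fit
  flipped <- fit
  for (s in seq_len(n_draws(fit))) flipped <- flip_draw_labels(flipped, s)
  sm_orig <- summarize_fit(fit, x_values = list(0), grid = 15L)
  sm_flip <- summarize_fit(flipped, x_values = list(0), grid = 15L)
  a <- dplyr::arrange(sm_orig$means, .data$feature, .data$t)
  b <- dplyr::arrange(dplyr::mutate(sm_flip$means, feature = 3 - .data$feature),
                      .data$feature, .data$t)
  expect_equal(a$median, b$median)
  expect_equal(a$lower, b$lower)
})
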