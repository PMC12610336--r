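# Unit oracles for the Gibbs / MH update kernels. Each block is exercised
# through fmm_update(), i.e. the same compiled kernels run_mcmc() uses.

draw_block <- function(state, data, basis, block, n, hyper = fmm_hyper(),
                       control = fmm_control(), extract) {
  out <- vector("list", n)
  for (j in seq_len(n)) {
    out[[j]] <- extract(fmm_update(state, data, basis, block, hyper, control))
  }
  out
}

test_that("noise-variance update is the conjugate inverse-gamma", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 3, n = 6)
  st <- tiny_state(d, bs, K = 2, M = 1)
  h <- fmm_hyper(alpha0 = 3, beta0 = 2)
  # zero residuals: sigma2 | rest ~ IG(alpha0 + n_tot/2, beta0)
  d0 <- with_model_values(d, st, bs, noise = FALSE)
  set.seed(1)
  s2 <- vapply(1:4000, function(j) {
    fmm_update(st, d0, bs, "variance", hyper = h)$sigma2
  }, numeric(1))
  shape <- h$alpha0 + sum(d0$n_i) / 2
  expect_true(all(s2 > 0))
  expect_equal(mean(s2), h$beta0 / (shape - 1), tolerance = 0.05)

  # doubling the residuals quadruples the rate increment
  mu <- fmmm:::curve_mean_vectors(st, d0, bs)
  r_fixed <- lapply(d0$values, function(v) v * 0 + 0.3)   # constant residual
  d1 <- d0; d1$values <- Map(`+`, mu, r_fixed)
  d2 <- d0; d2$values <- Map(`+`, mu, lapply(r_fixed, `*`, 2))
  sse1 <- sum(unlist(r_fixed)^2); sse2 <- sum((2 * unlist(r_fixed))^2)
  expect_equal(sse2, 4 * sse1)
  set.seed(2)
  m1 <- mean(vapply(1:4000, function(j) fmm_update(st, d1, bs, "variance", hyper = h)$sigma2, numeric(1)))
  set.seed(3)
  m2 <- mean(vapply(1:4000, function(j) fmm_update(st, d2, bs, "variance", hyper = h)$sigma2, numeric(1)))
  expect_equal(m1, (h$beta0 + sse1 / 2) / (shape - 1), tolerance = 0.05)
  expect_equal(m2, (h$beta0 + sse2 / 2) / (shape - 1), tolerance = 0.05)
})

test_that("factor-score update reverts to the standard-normal prior when uninformative", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 6, n = 6)
  st <- tiny_state(d, bs, K = 2, M = 2)

  # phi = 0: conditional is exactly N(0, 1) per score
  st0 <- st; st0$phi[] <- 0
  set.seed(4)
  chi <- vapply(1:3000, function(j) fmm_update(st0, d, bs, "scores")$chi[1, 1],
                numeric(1))
  expect_equal(mean(chi), 0, tolerance = 0.06)
  expect_equal(var(chi), 1, tolerance = 0.08)

  # sigma2 -> large: conditional reverts to the prior as well
  stb <- st; stb$sigma2 <- 1e8
  set.seed(5)
  chib <- vapply(1:3000, function(j) fmm_update(stb, d, bs, "scores")$chi[2, 1],
                 numeric(1))
  expect_equal(mean(chib), 0, tolerance = 0.06)
  expect_equal(var(chib), 1, tolerance = 0.08)
})

test_that("factor-score update matches the hand-derived scalar conditional (M = 1)", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 2, n = 6)
  st <- tiny_state(d, bs, K = 2, M = 1, sigma2 = 0.4)
  i <- 1L
  S <- t(eval_basis(bs, d$times[[i]]))
  Phib <- st$Z[i, 1] * st$phi[, 1, 1] + st$Z[i, 2] * st$phi[, 1, 2]
  a <- st$Z[i, 1] * st$v[1, ] + st$Z[i, 2] * st$v[2, ]
  psi <- as.numeric(S %*% Phib)
  r <- d$values[[i]] - as.numeric(S %*% a)
  prec <- 1 + sum(psi^2) / st$sigma2
  mean_exp <- sum(psi * r) / st$sigma2 / prec
  set.seed(6)
  chi <- vapply(1:4000, function(j) fmm_update(st, d, bs, "scores")$chi[i, 1],
                numeric(1))
  expect_equal(mean(chi), mean_exp, tolerance = 4 * sqrt(1 / prec / 4000) + 0.01)
  expect_equal(var(chi), 1 / prec, tolerance = 0.1 / prec)
})

test_that("mean-coefficient update matches the normal-normal posterior (K = 1, P = 2)", {
  # P = 2, order 2 (linear splines) keeps the conditional two-dimensional;
  # with tau_v ~ 0 the RW1 prior is negligible and the posterior is the
  # textbook Gaussian regression posterior
  bs <- tiny_basis(P = 2, order = 2)
  d <- tiny_data(N = 1, n = 8)
  st <- tiny_state(d, bs, K = 1, M = 1, sigma2 = 0.25)
  st$phi[] <- 0; st$chi[] <- 0
  st$tau_v <- 1e-10
  S <- t(eval_basis(bs, d$times[[1]]))
  XtX <- crossprod(S)
  post_var <- solve(XtX / 0.25)
  post_mean <- post_var %*% crossprod(S, d$values[[1]]) / 0.25
  set.seed(7)
  vs <- t(vapply(1:4000, function(j) fmm_update(st, d, bs, "means")$v[1, ],
                 numeric(2)))
  se <- sqrt(diag(post_var) / 4000)
  expect_lt(max(abs(colMeans(vs) - as.numeric(post_mean)) / se), 4)
  expect_equal(cov(vs), post_var, tolerance = 0.15)
})

test_that("huge RW1 precision forces numerically constant mean coefficients", {
  bs <- tiny_basis(P = 5)
  d <- tiny_data(N = 3, n = 7)
  st <- tiny_state(d, bs, K = 1, M = 1)
  st$tau_v <- 1e12
  set.seed(8)
  up <- fmm_update(st, d, bs, "means")
  expect_lt(max(abs(diff(up$v[1, ]))), 1e-3)
})

test_that("loading update reverts to the MGP prior when the data carry no signal", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 4, n = 6)
  st <- tiny_state(d, bs, K = 2, M = 1)
  # feature 2 has zero allocation everywhere and all scores are zero:
  # its loadings are drawn from the MGP prior N(0, 1/(gamma tau))
  st$Z <- cbind(rep(1 - 1e-12, 4), rep(1e-12, 4))
  st$Z <- st$Z / rowSums(st$Z)
  st$chi[] <- 0
  st$gamma[, , 2] <- 2
  st$delta[, 2] <- 3
  set.seed(9)
  ph <- t(vapply(1:4000, function(j) fmm_update(st, d, bs, "loadings")$phi[, 1, 2],
                 numeric(bs$P)))
  expect_lt(max(abs(colMeans(ph))), 0.05)
  expect_equal(apply(ph, 2, var), rep(1 / 6, bs$P), tolerance = 0.1)
})

test_that("shrinkage updates match the conjugate gamma conditionals", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 2, n = 6)
  st <- tiny_state(d, bs, K = 1, M = 1)
  h <- fmm_hyper()
  # phi = 0: gamma | rest ~ Gamma((nu+1)/2, nu/2)
  st0 <- st; st0$phi[] <- 0
  set.seed(10)
  g <- vapply(1:4000, function(j) fmm_update(st0, d, bs, "shrinkage", hyper = h)$gamma[1, 1, 1],
              numeric(1))
  expect_equal(mean(g), (h$nu_gamma + 1) / h$nu_gamma, tolerance = 0.06)

  # delta with M = 1: Gamma(a1 + P/2, 1 + 0.5 sum_p gamma phi^2)
  set.seed(11)
  reps <- t(vapply(1:4000, function(j) {
    up <- fmm_update(st, d, bs, "shrinkage", hyper = h)
    c(up$delta[1, 1], up$a1[1], sum(up$gamma[, 1, 1] * st$phi[, 1, 1]^2))
  }, numeric(3)))
  # condition on the refreshed gamma and a1 draw by draw: E[delta] matches
  expect_equal(mean(reps[, 1]),
               mean((reps[, 2] + bs$P / 2) / (1 + 0.5 * reps[, 3])),
               tolerance = 0.08)

  # MGP shape MH updates move and stay strictly inside (0, 1) acceptance
  set.seed(12)
  st_chain <- st
  acc <- 0
  for (j in 1:300) {
    up <- fmm_update(st_chain, d, bs, "shrinkage", hyper = h)
    if (up$a1[1] != st_chain$a1[1]) acc <- acc + 1
    st_chain <- up
  }
  expect_gt(acc, 0)
  expect_lt(acc, 300)
})

test_that("smoothing precisions follow their conjugate gamma conditionals", {
  bs <- tiny_basis(P = 5)
  d <- tiny_data(N = 2, n = 7)
  h <- fmm_hyper(alpha_v = 2, beta_v = 3)
  st <- tiny_state(d, bs, K = 1, M = 1)
  # constant v: tau_v ~ Gamma(alpha_v + (P-1)/2, beta_v) exactly
  st$v[1, ] <- 1.7
  set.seed(13)
  tv <- vapply(1:4000, function(j) fmm_update(st, d, bs, "smoothing", hyper = h)$tau_v[1],
               numeric(1))
  shape <- h$alpha_v + (bs$P - 1) / 2
  expect_equal(mean(tv), shape / h$beta_v, tolerance = 0.05 * shape / h$beta_v)

  # scaling v by c multiplies the rate increment by c^2
  st2 <- tiny_state(d, bs, K = 1, M = 1)
  pen <- sum(diff(st2$v[1, ])^2)
  st3 <- st2; st3$v <- 3 * st3$v
  set.seed(14)
  m2 <- mean(vapply(1:4000, function(j) fmm_update(st2, d, bs, "smoothing", hyper = h)$tau_v[1], numeric(1)))
  set.seed(15)
  m3 <- mean(vapply(1:4000, function(j) fmm_update(st3, d, bs, "smoothing", hyper = h)$tau_v[1], numeric(1)))
  expect_equal(m2, shape / (h$beta_v + pen / 2), tolerance = 0.05)
  expect_equal(m3, shape / (h$beta_v + 9 * pen / 2), tolerance = 0.05)
})

test_that("allocation MH proposals preserve the simplex and revert to the prior under a flat likelihood", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 5, n = 6)
  st <- tiny_state(d, bs, K = 3, M = 1)
  st$alpha3 <- 6; st$pi <- c(0.5, 0.3, 0.2)
  # flat likelihood: no loadings and enormous noise variance
  st$phi[] <- 0; st$sigma2 <- 1e10
  set.seed(16)
  packed <- fmmm:::pack_data(d, bs)
  zs <- fmmm:::cpp_z_chain(packed, fmmm:::state_to_cpp(st),
                           fmmm:::hyper_to_cpp(fmm_hyper(), 3),
                           kappa = 10, n_sweeps = 20000, thin = 5)
  expect_true(all(zs >= 0 & zs <= 1))
  # stationary marginal of z_1 under Dir(alpha3 pi): Beta(a1, a2+a3)
  a <- st$alpha3 * st$pi
  expect_equal(mean(zs), a[1] / sum(a), tolerance = 0.02)
  expect_equal(var(as.numeric(zs)),
               a[1] * (sum(a) - a[1]) / (sum(a)^2 * (sum(a) + 1)),
               tolerance = 0.01)
})

test_that("tempered sweep with an empty ladder is bitwise identical to the plain MH sweep", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 4, n = 6)
  st <- tiny_state(d, bs, K = 2, M = 1)
  ctl <- fmm_control(ladder = numeric(0))
  set.seed(17)
  up1 <- fmm_update(st, d, bs, "allocations", control = ctl)
  set.seed(17)
  up2 <- fmm_update(st, d, bs, "tempered", control = ctl)
  expect_identical(up1$Z, up2$Z)
})

test_that("tempered sweep always accepts when the likelihood is flat", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 3, n = 6)
  st <- tiny_state(d, bs, K = 2, M = 1)
  st$phi[] <- 0; st$sigma2 <- 1e12
  ctl <- fmm_control(ladder = fmm_ladder(4, 0.2))
  set.seed(18)
  for (j in 1:20) {
    up <- fmm_update(st, d, bs, "tempered", control = ctl)
    acc <- attr(up, "accept")$tempered
    expect_equal(acc[1], acc[2])   # every tempered transition accepted
    st <- up
  }
})

test_that("tempered transitions cross between modes that trap the plain chain", {
  # deliberately bimodal two-curve toy: both features share a zero mean but
  # have opposite loadings (phi_2 = -phi_1), so the marginal covariance
  # depends on z only through (z_1 - z_2)^2 and the allocation posterior has
  # two symmetric modes separated by a deep valley at z = (1/2, 1/2)
  bs <- tiny_basis(P = 4)
  n <- 10
  tg <- seq(0, 1, length.out = n)
  u <- fmmm:::project_to_basis(function(t) sin(pi * t), bs)
  phi <- array(0, dim = c(4, 1, 2))
  phi[, 1, 1] <- 2 * u; phi[, 1, 2] <- -2 * u
  st <- fmm_state(v = matrix(0, 2, 4), phi = phi,
                  chi = matrix(c(1, -1), 2, 1), Z = matrix(0.5, 2, 2),
                  sigma2 = 0.04, alpha3 = 1, pi = c(0.5, 0.5))
  S <- t(eval_basis(bs, tg))
  y1 <- 1.5 * 0.8 * as.numeric(S %*% (2 * u))    # curve generated at z1 - z2 = 0.8
  y2 <- -1.2 * 0.8 * as.numeric(S %*% (2 * u))
  d <- fmm_data(data.frame(id = rep(1:2, each = n), t = rep(tg, 2),
                           y = c(y1, y2)))
  h <- fmm_hyper()
  ctl_plain <- fmm_control(kappa = 20)
  ctl_temp <- fmm_control(kappa = 20, ladder = fmm_ladder(8, 0.02))
  run_chain <- function(block, ctl, sweeps, seed) {
    set.seed(seed)
    s <- st
    # settle into one basin first with a few plain sweeps
    z_trace <- numeric(sweeps)
    for (j in seq_len(sweeps)) {
      s <- fmm_update(s, d, bs, block, hyper = h, control = ctl)
      z_trace[j] <- s$Z[1, 1]
    }
    z_trace
  }
  z_plain <- run_chain("allocations", ctl_plain, 500, seed = 19)
  z_temp <- run_chain("tempered", ctl_temp, 500, seed = 19)
  modes_visited <- function(z) (any(z > 0.75)) + (any(z < 0.25))
  expect_equal(modes_visited(z_plain), 1)   # local walk stays in one basin
  expect_equal(modes_visited(z_temp), 2)    # tempered ladder crosses
})

test_that("run_mcmc is reproducible, stores the right number of draws and valid states", {
  sim <- simulate_fmm_data(8, K = 2, R = 1, M = 1, P = 5, n_points = 10,
                           seed = 21, sigma2 = 0.04,
                           truth = make_truth_parameters(2, 1, 1, fmm_basis(c(0, 1), 5), phi_scale = 0.5))
  ctl <- fmm_control(n_iter = 120, burnin = 40, thin = 2)
  fit1 <- fmm_fit(sim$data, K = 2, P = 5, M = 1, control = ctl, seed = 99)
  fit2 <- fmm_fit(sim$data, K = 2, P = 5, M = 1, control = ctl, seed = 99)
  expect_identical(fit1$draws, fit2$draws)
  expect_identical(fit1$loglik, fit2$loglik)
  expect_equal(n_draws(fit1), (120 - 40) / 2)
  # every stored draw is a valid parameter state
  for (s in c(1L, 17L, n_draws(fit1))) {
    expect_no_error(fmmm:::check_state(state_from_draw(fit1, s)))
  }
  expect_true(all(is.finite(fit1$loglik)))
})

test_that("with K = 1 and R = 0 the fit matches penalized basis regression", {
  # single feature, no covariates: the posterior mean curve should agree
  # with a directly coded ridge-penalized spline fit pooling all curves
  set.seed(22)
  bs <- fmm_basis(c(0, 1), 6)
  tg <- seq(0, 1, length.out = 15)
  f <- function(t) sin(2 * pi * t)
  curves <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(id = i, t = tg, y = f(tg) + rnorm(15, 0, 0.1))
  }))
  d <- fmm_data(curves)
  fit <- fmm_fit(d, K = 1, P = 6, M = 1,
                 control = fmm_control(n_iter = 600, burnin = 200), seed = 5)
  g <- seq(0, 1, length.out = 50)
  est <- as.numeric(apply(fit$draws$v[, 1, ], 2, median) %*% eval_basis(bs, g))
  # direct generalized ridge fit with a weak RW1 penalty
  S <- do.call(rbind, lapply(d$times, function(t) t(eval_basis(bs, t))))
  y <- unlist(d$values)
  Dp <- difference_penalty(6L)
  beta <- solve(crossprod(S) + 0.1 * crossprod(Dp), crossprod(S, y))
  direct <- as.numeric(crossprod(eval_basis(bs, g), beta))
  expect_lt(sqrt(mean((est - direct)^2)) / diff(range(direct)), 0.03)
})
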