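test_that("feature means are linear in the basis and affine in covariates", {
  bs <- tiny_basis(P = 5)
  d <- tiny_data(N = 3, n = 6, R = 1)
  st <- tiny_state(d, bs, K = 2, M = 1)
  g <- seq(0, 1, length.out = 11)

  st0 <- st
  st0$v[] <- 0; st0$eta[] <- 0
  expect_equal(mean_function(st0, 1, 0, g, bs), rep(0, 11))

  stc <- st
  stc$v[1, ] <- 2.5; stc$eta[] <- 0
  expect_equal(mean_function(stc, 1, 0, g, bs), rep(2.5, 11))

  # affine in x at every t: mu(0) is the midpoint of mu(-1) and mu(1)
  mm <- vapply(c(-1, 0, 1), function(x) mean_function(st, 2, x, g, bs),
               numeric(11))
  expect_equal(mm[, 2], (mm[, 1] + mm[, 3]) / 2)
  expect_error(mean_function(st, 1, c(0, 0), g, bs), "length")
})

test_that("covariance surfaces are symmetric, PSD for k = k' and transpose-symmetric across pairs", {
  bs <- tiny_basis(P = 5)
  d <- tiny_data(N = 2, n = 5, R = 0)
  st <- tiny_state(d, bs, K = 2, M = 1)
  g1 <- seq(0, 1, length.out = 13); g2 <- seq(0.1, 0.9, length.out = 7)

  st0 <- st; st0$phi[] <- 0
  expect_equal(covariance_surface(st0, 1, 1, g1, g1, bs),
               matrix(0, 13, 13))

  C11 <- covariance_surface(st, 1, 1, g1, g1, bs)
  expect_equal(C11, t(C11))
  ev <- eigen(C11, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_equal(qr(C11)$rank, st$M)   # rank-1 for M = 1

  C12 <- covariance_surface(st, 1, 2, g1, g2, bs)
  C21 <- covariance_surface(st, 2, 1, g2, g1, bs)
  expect_equal(C12, t(C21))
})

test_that("conditional log-likelihood matches hand-computed values and symmetries", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 2, n = 5, R = 0)
  st <- tiny_state(d, bs, K = 2, M = 1, sigma2 = 1 / (2 * pi))
  # zero residuals with sigma2 = 1/(2pi) gives log-likelihood exactly 0
  d0 <- with_model_values(d, st, bs, noise = FALSE)
  expect_equal(conditional_loglik(st, d0, bs), 0)

  # K = 1 reduces to a single-feature basis regression density (coded directly)
  st1 <- tiny_state(d, bs, K = 1, M = 1, sigma2 = 0.3)
  ll <- conditional_loglik(st1, d, bs)
  direct <- 0
  for (i in 1:d$N) {
    S <- t(eval_basis(bs, d$times[[i]]))
    mu <- S %*% (st1$v[1, ] + st1$phi[, 1, 1] * st1$chi[i, 1])
    direct <- direct + sum(dnorm(d$values[[i]], mu, sqrt(0.3), log = TRUE))
  }
  expect_equal(ll, direct)

  # invariance under simultaneous feature relabeling
  st2 <- tiny_state(d, bs, K = 2, M = 1)
  stp <- st2
  perm <- c(2, 1)
  stp$v <- stp$v[perm, ]; stp$phi <- stp$phi[, , perm, drop = FALSE]
  stp$Z <- stp$Z[, perm]; stp$pi <- stp$pi[perm]
  expect_equal(conditional_loglik(stp, d, bs), conditional_loglik(st2, d, bs))
  expect_equal(marginal_loglik(stp, d, bs), marginal_loglik(st2, d, bs))
})

test_that("marginal log-likelihood equals the analytic Gaussian integral of the conditional", {
  # tiny instance: N = 1, n = 3, P = 3, M = 1, K = 2
  sim <- simulate_fmm_data(1, K = 2, R = 0, M = 1, P = 3, n_points = 3,
                           seed = 3, anchor = FALSE)
  st <- sim$truth$state; d <- sim$data; bs <- sim$basis
  S <- t(eval_basis(bs, d$times[[1]]))
  Phib <- st$Z[1, 1] * st$phi[, , 1] + st$Z[1, 2] * st$phi[, , 2]
  mu <- as.numeric(S %*% (st$Z[1, 1] * st$v[1, ] + st$Z[1, 2] * st$v[2, ]))
  Psi <- as.numeric(S %*% Phib)
  V <- outer(Psi, Psi) + st$sigma2 * diag(3)
  oracle <- dmvnorm_log(d$values[[1]], mu, V)
  expect_equal(marginal_loglik(st, d, bs), oracle, tolerance = 1e-8)

  # phi = 0 reduces the marginal to the conditional at chi = 0
  st0 <- st; st0$phi[] <- 0; st0$chi[] <- 0
  expect_equal(marginal_loglik(st0, d, bs), conditional_loglik(st0, d, bs))

  # compiled path agrees with the R path
  packed <- fmmm:::pack_data(d, bs)
  expect_equal(fmmm:::cpp_marginal_loglik(packed, fmmm:::state_to_cpp(st)),
               marginal_loglik(st, d, bs), tolerance = 1e-10)
})

test_that("log prior matches hand-coded densities on its proper components", {
  bs <- tiny_basis(P = 4)
  d <- tiny_data(N = 3, n = 6, R = 1)
  h <- fmm_hyper()
  st <- tiny_state(d, bs, K = 2, M = 2)

  # constant v contributes no RW1 exponent: changing tau_v only moves the
  # tau^{(P-1)/2} factor
  stc <- st
  stc$v[1, ] <- 4
  lp1 <- log_prior(stc, h, bs)
  stc2 <- stc; stc2$tau_v[1] <- stc$tau_v[1] * 7
  # difference must be exactly the log of the tau factor + gamma prior change
  expected <- 0.5 * (bs$P - 1) * log(7) +
    fmmm:::ldgamma(stc2$tau_v[1], h$alpha_v, h$beta_v) -
    fmmm:::ldgamma(stc$tau_v[1], h$alpha_v, h$beta_v)
  expect_equal(log_prior(stc2, h, bs) - lp1, expected)

  # hierarchical Dirichlet block equals an independently coded density
  alpha <- st$alpha3 * st$pi
  hand <- function(z, a) lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(z))
  lp_full <- log_prior(st, h, bs)
  stz <- st
  stz$Z[1, ] <- c(0.25, 0.75)
  expect_equal(log_prior(stz, h, bs) - lp_full,
               hand(c(0.25, 0.75), alpha) - hand(st$Z[1, ], alpha))

  # out-of-support states give -Inf, never an error
  stb <- st; stb$sigma2 <- -1
  expect_identical(log_prior(stb, h, bs), -Inf)
})

test_that("MGP prior variances stochastically shrink with the eigen-index when alpha2 > beta2", {
  h <- fmm_hyper(alpha2 = 3, beta2 = 1)
  set.seed(123)
  n <- 1e5
  a1 <- rgamma(n, h$alpha1, h$beta1)
  a2 <- rgamma(n, h$alpha2, h$beta2)
  d1 <- rgamma(n, a1, 1)
  d2 <- rgamma(n, a2, 1)
  d3 <- rgamma(n, a2, 1)
  tt1 <- d1; tt2 <- d1 * d2; tt3 <- d1 * d2 * d3
  # the loading prior variance is 1/tau-tilde; it should shrink as m grows,
  # both in the median and in log-mean (the plain mean of 1/tau-tilde is
  # heavy-tailed under the gamma hierarchy)
  expect_gt(median(1 / tt1), median(1 / tt2))
  expect_gt(median(1 / tt2), median(1 / tt3))
  expect_gt(mean(log(1 / tt1)), mean(log(1 / tt2)))
  expect_gt(mean(log(1 / tt2)), mean(log(1 / tt3)))
  # cumulative precisions grow in expectation: E[tau_m] = E[a1] E[a2]^(m-1)
  expect_equal(mean(tt1), h$alpha1 / h$beta1, tolerance = 0.05)
  expect_equal(mean(tt2), (h$alpha1 / h$beta1) * (h$alpha2 / h$beta2),
               tolerance = 0.05)
})

test_that("allocation design matrix has the stated rows, row sums and rank behavior", {
  C1 <- allocation_design(matrix(c(1, 0), 1, 2))
  expect_equal(as.numeric(C1$C), c(1, 0, 0))

  set.seed(4)
  Z <- t(vapply(1:8, function(i) { g <- rgamma(3, 1); g / sum(g) }, numeric(3)))
  ad <- allocation_design(Z)
  expect_equal(rowSums(ad$C), rep(1, 8))
  expect_equal(ncol(ad$C), 6L)
  expect_true(ad$full_rank)

  Zd <- matrix(rep(c(0.3, 0.7), each = 5), 5, 2)
  add <- allocation_design(Zd)
  expect_equal(add$rank, 1L)
  expect_false(add$full_rank)
})
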