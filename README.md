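# fmmm — covariate-adjusted functional mixed membership models

`fmmm` fits Bayesian mixed membership models for functional data in which
every observed curve is a convex combination of K latent functional
features whose means depend on scalar covariates:

```
Y_i(t) = Σ_k Z_ik f^(k)(x_i, t) + ε_i(t),      z_i on the unit simplex,
f^(k)(x, t) = (v_k + η_k x)ᵀ B(t) + Σ_m χ_m φ_kmᵀ B(t)
```

with equidistant-knot B-splines `B(t)`, a truncated multivariate
Karhunen–Loève representation of the joint feature covariance (M scaled
pseudo-eigenfunctions `φ_km`), and iid Gaussian noise. Unlike mixtures of
regressions, each observation may *partially* belong to several features —
the natural model for, e.g., developmental EEG spectra that mix an aperiodic
1/f trend with an age-shifting alpha peak in continuously varying
proportions.

The posterior is explored by a Gibbs sampler (conjugate updates for means,
covariate effects, loadings, scores, noise, multiplicative-gamma-process
shrinkage and random-walk smoothing precisions) with Metropolis–Hastings and
slice moves for the simplex allocations, optional Neal-style tempered
transitions for multimodal membership posteriors, label-switching and
separability post-processing, covariance eigen-analysis, and AIC/BIC/DIC,
elbow and CPO/pseudo-marginal-likelihood tools for choosing K. A synthetic
generator simulates from the model's own generative process so every stage
is testable end to end. The sampler's hot loop is RcppArmadillo.

## Worked example

```r
library(fmmm)

# simulate 80 curves from a two-feature model with one covariate
sim <- simulate_fmm_data(80, K = 2, R = 1, M = 2, P = 8, n_points = 25,
                         sigma2 = 0.04,
                         truth = make_truth_parameters(2, 1, 2,
                                   fmm_basis(c(0, 1), 8), phi_scale = 0.5),
                         seed = 1)

fit <- fmm_fit(sim$data, K = 2, P = 8, M = 2,
               control = fmm_control(n_iter = 1500, burnin = 500), seed = 2)
fit <- rescale_separability(relabel_draws(fit))

glance(fit, cpo = FALSE)
#> # A tibble: 1 x 11
#>       K     P     M     N     R n_draws loglik_hat   AIC    BIC   DIC accept_alloc
#>   <int> <int> <int> <int> <int>   <int>      <dbl> <dbl>  <dbl> <dbl>        <dbl>
#> 1     2     8     2    80     1    1000       29.9  230. -1042.  40.5        0.299
```

`loglik_hat` is the maximum marginal log-likelihood over stored draws; `BIC`
is reported on the largest-is-best scale. How well did we recover the truth?

```r
recovery_metrics(fit, sim$truth)[, 1:3]
#> # A tibble: 1 x 3
#>   rmise_mean_marginal rmise_mean_surface rmse_alloc
#>                 <dbl>              <dbl>      <dbl>
#> 1               0.145              0.322     0.0407
```

Feature-mean R-MISE well below 1% and allocation RMSE of 0.04: the fitted
population-level feature curves and each curve's memberships essentially
match the generating ones. Posterior summaries and plots:

```r
sm <- summarize_fit(fit, x_values = list(-1, 0, 1))   # bands per covariate value
autoplot(fit, x_values = list(-1, 0, 1))              # feature mean bands
plot_allocations(fit)                                 # membership intervals
covariance_eigen(fit)$summary                         # eigenvalues of the covariance
```

Model choice across K:

```r
fits <- lapply(2:4, function(K) fmm_fit(sim$data, K = K, P = 8, M = 2, seed = 2))
dplyr::bind_rows(lapply(fits, information_criteria))
elbow_table(fits)
```

There is also a thin command-line entry point over the same functions:

```
inst/exec/fmmm simulate|fit|select-k|report --config cfg.yaml [--seed S] [--out DIR]
```

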