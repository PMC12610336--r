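---
title: "Covariate-adjusted functional mixed membership: model, sampler, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted functional mixed membership: model, sampler, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmmm)
```

## The model

Functional mixed membership assumes each observed curve is a *convex
combination* of K latent functional features rather than a member of exactly
one cluster. Observation $i$ carries simplex-valued allocations
$z_i = (Z_{i1}, \dots, Z_{iK})$, $Z_{ik} \in [0,1]$, $\sum_k Z_{ik} = 1$, and
the curve is

$$ Y_i(t) = \sum_{k=1}^K Z_{ik}\, f^{(k)}(x_i, t) + \epsilon_i(t), $$

where $f^{(k)}$ is a Gaussian-process feature whose mean depends linearly on
a vector of $R$ standardized scalar covariates $x_i$ and
$\epsilon_i \sim N(0, \sigma^2)$ iid. The motivating setting is
developmental EEG: relative alpha-band power spectra mix an aperiodic
$1/f$-type trend with a periodic alpha-peak component, in proportions that
vary continuously across children, and both components drift with age — so
one wants covariate-dependent features with observation-level memberships.

All features live in a $P$-dimensional spline space with equidistant-knot
B-splines $B(t)$ (order 4 by default; equidistant knots are part of the
identifiability conditions, so the knot vector is never user-set). The joint
covariance of the $K$ features is represented by a truncated multivariate
Karhunen–Loève expansion with $M$ *pseudo-eigenfunctions*
$\phi_{km}^\top B(t)$ and iid standard-normal scores $\chi_{im}$:

$$ Y_i(t_i) \mid \Theta \sim N\!\Big(\textstyle\sum_k Z_{ik}\big(S_i^\top(v_k
 + \eta_k x_i) + \sum_m \chi_{im} S_i^\top \phi_{km}\big),\; \sigma^2 I\Big), $$

with $S_i$ the basis design at the observation times. Integrating the scores
out gives the marginal form with mean
$\sum_k Z_{ik} S_i^\top (v_k + \eta_k x_i)$ and covariance
$V(t_i, z_i) + \sigma^2 I$,
$V = \sum_{k,k'} Z_{ik} Z_{ik'} S_i^\top (\sum_m \phi_{km}\phi_{k'm}^\top)
S_i$. The loadings are *not* constrained to be orthogonal — sampling happens
on an unconstrained space — and the genuine eigenstructure is recovered
after the fact by eigendecomposing reconstructed covariance surfaces
(`covariance_eigen()`).

## Priors

* Loadings $\phi_{kpm}$: multiplicative gamma process (MGP) shrinkage,
  $\phi_{kpm} \sim N(0, \gamma_{kpm}^{-1}\tilde\tau_{mk}^{-1})$ with
  $\gamma_{kpm}\sim\Gamma(\nu_\gamma/2,\nu_\gamma/2)$,
  $\tilde\tau_{mk} = \prod_{n\le m}\delta_{nk}$,
  $\delta_{1k}\sim\Gamma(a_{1k},1)$, $\delta_{jk}\sim\Gamma(a_{2k},1)$,
  $a_{1k}\sim\Gamma(\alpha_1,\beta_1)$, $a_{2k}\sim\Gamma(\alpha_2,\beta_2)$
  with $\alpha_2 > \beta_2$ enforced. Under this hierarchy the *expected
  cumulative precisions grow* geometrically,
  $E[\tilde\tau_{mk}] = E[a_{1k}]\,E[a_{2k}]^{m-1}$, which is exactly what
  makes the implied loading variances $1/\tilde\tau_{mk}$ stochastically
  shrink with the eigen-index $m$ — so one can set $M$ generously and let
  the prior switch off unneeded directions.
* Mean coefficients $v_k$ and each covariate column of $\eta_k$: improper
  first-order random-walk (RW1) smoothing priors
  $\propto \tau^{\mathrm{rank}/2}\exp(-\tfrac{\tau}{2}\|\Delta v\|^2)$ with
  $\tau \sim \Gamma(\alpha_v,\beta_v)$ (resp. $\Gamma(\alpha_\eta,
  \beta_\eta)$). The $\tau^{(P-1)/2}$ factor is kept so the conjugate
  $\tau$ updates are exact. A `mean_ridge` option adds
  $\varepsilon I$ to $\Delta^\top\Delta$, making the prior proper; it is off
  by default and used by prior-predictive simulation and the
  simulation-based sampler test.
* Allocations: hierarchical Dirichlet, $z_i \sim \mathrm{Dir}(\alpha_3\pi)$,
  $\pi \sim \mathrm{Dir}(c_\pi)$, $\alpha_3 \sim \mathrm{Exp}(b)$;
  noise $\sigma^2 \sim IG(\alpha_0,\beta_0)$.

Default hyperparameters (`fmm_hyper()`): $\nu_\gamma = 3$,
$(\alpha_1,\beta_1) = (2,1)$, $(\alpha_2,\beta_2) = (3,1)$,
$(\alpha_v,\beta_v) = (\alpha_\eta,\beta_\eta) = (1,1)$, $c_\pi = 10$,
$b = 1$, $(\alpha_0,\beta_0) = (1,1)$. These are configuration defaults, not
estimates; all are exposed.

## Identifiability and its diagnostics

Mixed membership models are invariant to relabeling, and — more insidiously
— to invertible affine maps of the allocation polytope. The mean and
covariance structure are identified (up to labels) when (i) the standardized
design is full rank with the intercept outside its span, (ii) the
allocations satisfy the separability condition (an anchor observation fully
in each feature) or the weaker sufficiently-scattered condition, together
with full column rank of the $N \times K(K+1)/2$ quadratic allocation design
(`allocation_design()`), and (iii) paths are regularly sampled with
$n_i > P$ on equidistant-knot B-splines. `validate_fmm_data()` checks what
is checkable up front; irregular grids warn rather than fail because
estimation still works, only the theoretical guarantee is stated for regular
designs.

## Posterior computation

`fmm_fit()` runs a fixed-order sweep: scores $\chi$, loadings $\phi$, means
$v$, covariate effects $\eta$, noise $\sigma^2$, shrinkage
$(\gamma,\delta,a)$, smoothing $\tau$, allocations, a score refresh, mixing
$(\pi,\alpha_3)$.
All Gaussian and gamma blocks are exact conjugate draws (derived from the
conditional likelihood above); the MGP shapes $a_{1k}, a_{2k}$ use log-scale
random-walk MH; $\pi$ uses a logistic-normal (additive log-ratio) random
walk and $\alpha_3$ a log-scale walk. Allocation updates target the
*marginal* likelihood (scores integrated out), which removes the tight
$z$–$\chi$ coupling.

Allocations get two complementary kernels per sweep:

1. the Dirichlet-proposal MH step, $z' \sim \mathrm{Dir}(\kappa z + 0.1)$
   with asymmetric-proposal correction, $\kappa$ adapted during burn-in
   towards 20–40% acceptance and frozen afterwards; and
2. a pairwise *slice-sampling* pass: for each curve, mass is moved between
   two features along $z_k + z_{k'} = \text{const}$ by shrinkage slice
   sampling. This kernel is tuning-free and makes global moves. It matters
   because at high signal-to-noise the curve-level allocation posterior is
   extremely narrow: the Dirichlet walk then takes $O(10^{-2})$ steps and
   chains can stall in degenerate modes where inflated loadings absorb the
   allocation structure. The slice pass eliminates that failure mode while
   the MH step retains the documented proposal mechanism (and is what the
   stationarity oracle tests exercise in isolation).

Because the allocation kernels target the score-*marginalized* likelihood,
the scores are redrawn from their full conditional immediately after the
allocation block (partially collapsed Gibbs requires the marginalized
parameter to be refreshed before the state is used as a coherent joint
draw — without the refresh the stored draws pair new allocations with stale
scores, which the simulation-based sampler test detects as a biased joint).

Optional Neal-style *tempered transitions* wrap the allocation block: MH
sweeps climb a geometric ladder of flattened likelihoods
(`fmm_ladder(L, beta_min)`, default $L=10$ down to $\beta\approx 0.1$) and
descend again, with a single global accept/reject computed from the exact
path-reversal ratio (the prior terms telescope out). With an empty ladder
the kernel reduces bitwise to one plain MH sweep. Tempering targets
multimodality in the memberships — e.g. symmetric modes induced by
sign-flips of covariance-only structure — and is applied every
`temper_every` sweeps when enabled.

Initialization fits per-curve ridge coefficients, k-means clusters them,
sets the starting allocations to the simplex-constrained least-squares fit
of each curve's coefficients on the cluster centers (softened 0.8/0.2
towards the barycenter), and starts the loadings and scores at the principal
components of the coefficient residuals. A cold start of the factor
structure was the slowest part of burn-in by far; seeding it from residual
PCA removes that transient without affecting the stationary distribution.

Runs are reproducible: given `seed`, the sweep order, adaptation schedule
and all draws are deterministic. Draws are stored as named draw-major arrays
(`v, eta, phi, chi, Z, sigma2, gamma, delta, a1, a2, tau_v, tau_eta, pi,
alpha3`); the command-line interface persists them as RDS.

## Post-processing

`relabel_draws()` resolves label switching by aligning each draw's
population-level mean curves to those of the maximum-likelihood draw (L2
cost, exact minimization over permutations). `rescale_separability()`
(K = 2) affinely maps each draw's first allocation column onto $[0,1]$ and
applies the compensating inverse linear map to $(v, \eta, \phi)$, so every
curve's marginal mean and covariance are unchanged — both operations are
pure reparameterizations and are tested to preserve each draw's likelihood
to $10^{-8}$. For three or more features the analogous
sufficiently-scattered post-processing is not implemented (for $K \ge 4$ it
is an open problem); `relabel_draws()` still applies for any K.

`summarize_fit()` produces pointwise posterior medians and central credible
bands (default 95%) for feature means at requested covariate values, for
allocations, and for trajectories conditional on fixed allocation vectors
$z^\*$ — the construction used to compare, e.g., percentile-conditional
developmental trajectories. Bands are pointwise, not simultaneous.

## Choosing the number of features

`information_criteria()` uses the maximum marginal log-likelihood over draws
$\hat L$ and the parameter count $p = KP(1+R) + KPM + N(K-1) + 1$:
$\mathrm{AIC} = 2p - 2\hat L$ (smallest best),
$\mathrm{BIC} = 2\hat L - p\log n_{tot}$ (reported on the largest-is-best
scale, with the conventional $-\mathrm{BIC}$ alongside), and
$\mathrm{DIC} = 2\bar D - D(\hat\theta)$ with the plug-in at the
maximum-likelihood draw — the posterior mean of a mixed membership state can
violate the simplex constraints before relabeling, so the ML draw is the
safer plug-in. Counting the $N(K-1)$ allocation coordinates in $p$ makes
BIC's per-curve penalty $\log n_{tot}$; this is deliberately conservative
and is applied consistently across K so comparisons are fair.
`elbow_table()` and `cpo_psml()` (harmonic-mean conditional predictive
ordinates, computed in log space) complete the toolkit.

## The synthetic generator and the study conditions

`simulate_fmm_data()` draws data from the model's own generative process:
standardized Gaussian covariates, $z_i \sim \mathrm{Dir}(1.5, \dots, 1.5)$
with one pure anchor observation planted per feature (so separability holds
by construction), $\chi_{im} \sim N(0,1)$, and Gaussian noise on a regular
grid of 25 points per curve. Truth parameters (`make_truth_parameters()`)
are basis projections of a fixed library of smooth shapes — a decaying
aperiodic-like trend, peaked oscillations, a linear decline (amplitudes
roughly 4–6) — with loadings built from shifted sinusoids whose magnitudes
decay geometrically.

Two study regimes are declared as package defaults:

* **Structure recovery** (`study1_scenarios()`): noise variance 0.04
  (noise sd 0.2 against curve amplitudes of several units) and leading
  loading scale 0.5. In this regime chains converge for every replicate and
  estimation error is dominated by sample size, which is what the study
  measures: nine scenarios ($R \in \{0,1,2\} \times N \in \{40,80,160\}$),
  plus the stated misspecified fits (drop the covariate from $R=1$ data; add
  a random covariate to $R=0$ data).
* **Model selection** (`study2_scenario()`): noise variance 0.0025 and
  leading loading scale 2 (K = 3 truth, one covariate, fits
  $K \in \{2,3,4,5\}$). Feature-count selection is only statistically
  informative at high SNR here: an omitted feature is largely absorbed as
  extra low-rank covariance, at a per-curve likelihood cost of roughly
  $\tfrac12\log(\text{SNR})$ per missing direction, which must exceed BIC's
  per-curve penalty $\log n_{tot} \approx 7$ under the conservative
  parameter count above. Smoothed spectral curves are in fact a high-SNR
  data type, so the regime is also the substantively relevant one.

What the generator does *not* emulate: spectral shape constraints
(positivity, unit integral of relative power), irregular or subject-specific
grids, non-Gaussian noise, and covariate distributions other than Gaussian.
Tests passing on these simulations therefore demonstrate correctness of the
machinery and recoverability under the model's own assumptions — not
robustness to model misspecification.

## Test-scale choices

The shipped test suite runs the studies at desk scale, chosen so the whole
suite completes in tens of minutes on one CPU: the selection study uses 6
replicate datasets of $N = 60$ curves with 2,000 sweeps (500 burn-in) per
fit, expecting BIC correct in at least 5 of 6 and AIC/DIC no better than
BIC; the recovery study uses 4 replicates per sample size with 1,500 sweeps.
The scenario builders default to the full-size designs (50 replicates,
$N = 120$) for users who want cluster-scale replications.
`scripts/acceptance.R` re-runs both studies from scratch at a similar
reduced scale and writes the headline numbers as JSON.

## Numerical choices

* Marginal likelihoods factor $\sigma^2 I + \Psi\Psi^\top$ by the
  Woodbury/determinant identities through a Cholesky of the $M \times M$
  capacitance matrix; the R reference path uses a dense Cholesky with a
  one-shot jitter of $10^{-10}\,\mathrm{tr}(V)/n$ and the two are
  cross-checked in the tests.
* Gaussian full conditionals are drawn from their precision form; a
  $10^{-8}$-scaled jitter retry guards the (theoretically impossible with
  positive $\tau$ and data) singular case before erroring.
* Rank decisions use singular values above $10^{-8}$ times the largest.
* Eigenfunctions are orthonormalized with trapezoid quadrature weights and
  sign-fixed so the largest-magnitude element is positive.
* Covariates are standardized with the sample (n−1) standard deviation;
  centers and scales are stored so effects can be mapped back to raw units.
* Duplicate `(id, t)` rows are an error, not averaged; constant covariate
  columns are an error (they would put the intercept into the design span).

## Known limitations

* Separability rescaling is K = 2 only; K ≥ 3 chains are relabeled but not
  geometrically anchored, so feature-level (as opposed to
  allocation-weighted) summaries for K ≥ 3 inherit the affine ambiguity
  when no posterior anchors emerge.
* The covariance is covariate-independent; only means depend on x.
* CPO via harmonic means is known to be noisy when per-curve likelihoods
  vary over many orders of magnitude across draws.
* Information criteria depend on the stated parameter-count convention;
  comparisons are only meaningful within one convention.
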