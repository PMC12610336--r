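// Gibbs / Metropolis-Hastings kernels for the covariate-adjusted functional
// mixed membership model. All kernels draw through R's RNG so results are
// reproducible from set.seed(). The same kernels back both run_mcmc() and the
// single-block update wrappers used by the unit oracles.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uword;

struct Data {
  vec y;                 // concatenated observations, length n_tot
  mat S;                 // n_tot x P basis design (row j = B(t_j)')
  arma::uvec off;        // N+1 offsets into y / rows of S (0-based)
  mat X;                 // N x R standardized covariates (R may be 0)
  int N, P, R;
  std::vector<mat> G;    // per-curve S_i' S_i (P x P)
};

struct State {
  mat v;       // K x P
  cube eta;    // P x R x K
  cube phi;    // P x M x K
  mat chi;     // N x M
  mat Z;       // N x K
  double sigma2;
  cube gamma;  // P x M x K
  mat delta;   // M x K
  vec a1, a2, tau_v;  // K
  mat tau_eta;        // R x K
  vec pi;             // K
  double alpha3;
  int K, M;
};

struct Hyper {
  double nu_gamma, alpha1, beta1, alpha2, beta2;
  double alpha_v, beta_v, alpha_eta, beta_eta;
  vec c_pi;
  double b, alpha0, beta0;
  double mean_ridge;
};

static Data make_data(const List& d_) {
  Data d;
  d.y = as<vec>(d_["y"]);
  d.S = as<mat>(d_["S"]);
  d.off = as<arma::uvec>(d_["off"]);
  d.X = as<mat>(d_["X"]);
  d.N = as<int>(d_["N"]);
  d.P = d.S.n_cols;
  d.R = d.X.n_cols;
  d.G.resize(d.N);
  for (int i = 0; i < d.N; ++i) {
    mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
    d.G[i] = Si.t() * Si;
  }
  return d;
}

static State make_state(const List& s_) {
  State s;
  s.v = as<mat>(s_["v"]);
  s.K = s.v.n_rows;
  NumericVector eta_ = s_["eta"];
  IntegerVector de = eta_.attr("dim");
  s.eta = cube(eta_.begin(), de[0], de[1], de[2]);
  NumericVector phi_ = s_["phi"];
  IntegerVector dp = phi_.attr("dim");
  s.phi = cube(phi_.begin(), dp[0], dp[1], dp[2]);
  s.M = dp[1];
  s.chi = as<mat>(s_["chi"]);
  s.Z = as<mat>(s_["Z"]);
  s.sigma2 = as<double>(s_["sigma2"]);
  NumericVector g_ = s_["gamma"];
  IntegerVector dg = g_.attr("dim");
  s.gamma = cube(g_.begin(), dg[0], dg[1], dg[2]);
  s.delta = as<mat>(s_["delta"]);
  s.a1 = as<vec>(s_["a1"]);
  s.a2 = as<vec>(s_["a2"]);
  s.tau_v = as<vec>(s_["tau_v"]);
  s.tau_eta = as<mat>(s_["tau_eta"]);
  s.pi = as<vec>(s_["pi"]);
  s.alpha3 = as<double>(s_["alpha3"]);
  return s;
}

static List state_to_list(const State& s, int P, int R, int N) {
  NumericVector eta_(P * R * s.K);
  std::copy(s.eta.begin(), s.eta.end(), eta_.begin());
  eta_.attr("dim") = IntegerVector::create(P, R, s.K);
  NumericVector phi_(P * s.M * s.K);
  std::copy(s.phi.begin(), s.phi.end(), phi_.begin());
  phi_.attr("dim") = IntegerVector::create(P, s.M, s.K);
  NumericVector g_(P * s.M * s.K);
  std::copy(s.gamma.begin(), s.gamma.end(), g_.begin());
  g_.attr("dim") = IntegerVector::create(P, s.M, s.K);
  return List::create(
    _["v"] = s.v, _["eta"] = eta_, _["phi"] = phi_, _["chi"] = s.chi,
    _["Z"] = s.Z, _["sigma2"] = s.sigma2, _["gamma"] = g_,
    _["delta"] = s.delta, _["a1"] = s.a1, _["a2"] = s.a2,
    _["tau_v"] = s.tau_v, _["tau_eta"] = s.tau_eta, _["pi"] = s.pi,
    _["alpha3"] = s.alpha3);
}

static Hyper make_hyper(const List& h_, int K) {
  Hyper h;
  h.nu_gamma = as<double>(h_["nu_gamma"]);
  h.alpha1 = as<double>(h_["alpha1"]);
  h.beta1 = as<double>(h_["beta1"]);
  h.alpha2 = as<double>(h_["alpha2"]);
  h.beta2 = as<double>(h_["beta2"]);
  h.alpha_v = as<double>(h_["alpha_v"]);
  h.beta_v = as<double>(h_["beta_v"]);
  h.alpha_eta = as<double>(h_["alpha_eta"]);
  h.beta_eta = as<double>(h_["beta_eta"]);
  vec c_pi = as<vec>(h_["c_pi"]);
  h.c_pi = (c_pi.n_elem == (uword)K) ? c_pi : vec(K, arma::fill::value(c_pi(0)));
  h.b = as<double>(h_["b"]);
  h.alpha0 = as<double>(h_["alpha0"]);
  h.beta0 = as<double>(h_["beta0"]);
  h.mean_ridge = as<double>(h_["mean_ridge"]);
  return h;
}

// ---- small numerics -------------------------------------------------------

static mat rw1_Q(int P, double ridge) {
  mat Q(P, P, arma::fill::zeros);
  for (int p = 0; p < P - 1; ++p) {
    Q(p, p) += 1.0; Q(p + 1, p + 1) += 1.0;
    Q(p, p + 1) -= 1.0; Q(p + 1, p) -= 1.0;
  }
  Q.diag() += ridge;
  return Q;
}

// draw N(Q^{-1} l, Q^{-1}) given precision Q and linear term l
static vec rmvn_canonical(mat Q, const vec& l) {
  mat U;
  if (!arma::chol(U, Q)) {
    Q.diag() += 1e-8 * arma::trace(Q) / Q.n_rows;
    if (!arma::chol(U, Q)) stop("Singular precision matrix in a Gaussian full conditional.");
  }
  vec w = arma::solve(arma::trimatl(U.t()), l);
  vec mu = arma::solve(arma::trimatu(U), w);
  vec z(Q.n_rows);
  for (uword j = 0; j < z.n_elem; ++j) z(j) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

static double ldgamma(double x, double shape, double rate) {
  if (x <= 0.0) return -arma::datum::inf;
  return shape * std::log(rate) - R::lgammafn(shape) + (shape - 1.0) * std::log(x) - rate * x;
}

static double lddirichlet(const vec& z, const vec& alpha) {
  if (z.min() <= 0.0 || std::abs(arma::accu(z) - 1.0) > 1e-8) return -arma::datum::inf;
  double out = R::lgammafn(arma::accu(alpha));
  for (uword k = 0; k < z.n_elem; ++k) {
    out += -R::lgammafn(alpha(k)) + (alpha(k) - 1.0) * std::log(z(k));
  }
  return out;
}

static vec rdirichlet(const vec& alpha) {
  vec g(alpha.n_elem);
  for (uword k = 0; k < alpha.n_elem; ++k) g(k) = R::rgamma(alpha(k), 1.0);
  double s = arma::accu(g);
  if (s <= 0.0) { g.fill(1e-300); s = arma::accu(g); }
  return g / s;
}

// feature-combined coefficients for curve i: a = sum_k Z_ik (v_k + eta_k x_i),
// Phib = sum_k Z_ik phi_k, optionally with an overriding allocation row
static void curve_coef(const State& s, const Data& d, int i, const vec& zrow,
                       vec& a, mat& Phib) {
  a.zeros(d.P);
  Phib.zeros(d.P, s.M);
  for (int k = 0; k < s.K; ++k) {
    vec ck = s.v.row(k).t();
    if (d.R > 0) ck += s.eta.slice(k) * d.X.row(i).t();
    a += zrow(k) * ck;
    Phib += zrow(k) * s.phi.slice(k);
  }
}

static vec fitted_all(const State& s, const Data& d) {
  vec mu(d.y.n_elem);
  vec a; mat Phib;
  for (int i = 0; i < d.N; ++i) {
    curve_coef(s, d, i, s.Z.row(i).t(), a, Phib);
    mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
    mu.subvec(d.off(i), d.off(i + 1) - 1) = Si * (a + Phib * s.chi.row(i).t());
  }
  return mu;
}

// marginal (chi integrated out) Gaussian log density for one curve, by the
// Woodbury / matrix determinant identities on sigma2 I + Psi Psi'
static double marg_ll_curve(const State& s, const Data& d, int i, const vec& zrow) {
  vec a; mat Phib;
  curve_coef(s, d, i, zrow, a, Phib);
  mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
  vec r = d.y.subvec(d.off(i), d.off(i + 1) - 1) - Si * a;
  mat Psi = Si * Phib;                       // n x M
  int n = r.n_elem;
  mat C = s.sigma2 * arma::eye(s.M, s.M) + Psi.t() * Psi;
  mat U;
  if (!arma::chol(U, C)) stop("Capacitance matrix not positive definite in marginal likelihood.");
  double logdet = (n - s.M) * std::log(s.sigma2) + 2.0 * arma::accu(arma::log(U.diag()));
  vec pr = Psi.t() * r;
  vec w = arma::solve(arma::trimatl(U.t()), pr);
  double quad = (arma::dot(r, r) - arma::dot(w, w)) / s.sigma2;
  return -0.5 * n * std::log(2.0 * M_PI) - 0.5 * logdet - 0.5 * quad;
}

static double marg_ll_total(const State& s, const Data& d) {
  double out = 0.0;
  for (int i = 0; i < d.N; ++i) out += marg_ll_curve(s, d, i, s.Z.row(i).t());
  return out;
}

// ---- Gibbs blocks ---------------------------------------------------------

static void upd_chi(State& s, const Data& d) {
  vec a; mat Phib;
  for (int i = 0; i < d.N; ++i) {
    curve_coef(s, d, i, s.Z.row(i).t(), a, Phib);
    mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
    mat Psi = Si * Phib;
    vec r = d.y.subvec(d.off(i), d.off(i + 1) - 1) - Si * a;
    mat Q = arma::eye(s.M, s.M) + Psi.t() * Psi / s.sigma2;
    vec l = Psi.t() * r / s.sigma2;
    s.chi.row(i) = rmvn_canonical(Q, l).t();
  }
}

static void upd_phi(State& s, const Data& d) {
  vec r = d.y - fitted_all(s, d);
  for (int k = 0; k < s.K; ++k) {
    vec tau_tilde = arma::cumprod(s.delta.col(k));
    for (int m = 0; m < s.M; ++m) {
      vec phi_old = s.phi.slice(k).col(m);
      mat Gsum(d.P, d.P, arma::fill::zeros);
      vec l(d.P, arma::fill::zeros);
      for (int i = 0; i < d.N; ++i) {
        double c = s.Z(i, k) * s.chi(i, m);
        if (c == 0.0) continue;
        mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
        Gsum += (c * c) * d.G[i];
        l += c * (Si.t() * r.subvec(d.off(i), d.off(i + 1) - 1));
      }
      mat Q = Gsum / s.sigma2;
      Q.diag() += tau_tilde(m) * s.gamma.slice(k).col(m);
      l = l / s.sigma2 + (Gsum * phi_old) / s.sigma2;
      vec phi_new = rmvn_canonical(Q, l);
      s.phi.slice(k).col(m) = phi_new;
      vec dcoef = phi_new - phi_old;
      for (int i = 0; i < d.N; ++i) {
        double c = s.Z(i, k) * s.chi(i, m);
        if (c == 0.0) continue;
        mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
        r.subvec(d.off(i), d.off(i + 1) - 1) -= c * (Si * dcoef);
      }
    }
  }
}

static void upd_v(State& s, const Data& d, const Hyper& h, const mat& Q0) {
  vec r = d.y - fitted_all(s, d);
  for (int k = 0; k < s.K; ++k) {
    vec v_old = s.v.row(k).t();
    mat Gsum(d.P, d.P, arma::fill::zeros);
    vec l(d.P, arma::fill::zeros);
    for (int i = 0; i < d.N; ++i) {
      double c = s.Z(i, k);
      if (c == 0.0) continue;
      mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
      Gsum += (c * c) * d.G[i];
      l += c * (Si.t() * r.subvec(d.off(i), d.off(i + 1) - 1));
    }
    mat Q = s.tau_v(k) * Q0 + Gsum / s.sigma2;
    l = l / s.sigma2 + (Gsum * v_old) / s.sigma2;
    vec v_new = rmvn_canonical(Q, l);
    s.v.row(k) = v_new.t();
    vec dcoef = v_new - v_old;
    for (int i = 0; i < d.N; ++i) {
      double c = s.Z(i, k);
      if (c == 0.0) continue;
      mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
      r.subvec(d.off(i), d.off(i + 1) - 1) -= c * (Si * dcoef);
    }
  }
}

static void upd_eta(State& s, const Data& d, const Hyper& h, const mat& Q0) {
  if (d.R == 0) return;
  vec r = d.y - fitted_all(s, d);
  for (int k = 0; k < s.K; ++k) {
    for (int rr = 0; rr < d.R; ++rr) {
      vec e_old = s.eta.slice(k).col(rr);
      mat Gsum(d.P, d.P, arma::fill::zeros);
      vec l(d.P, arma::fill::zeros);
      for (int i = 0; i < d.N; ++i) {
        double c = s.Z(i, k) * d.X(i, rr);
        if (c == 0.0) continue;
        mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
        Gsum += (c * c) * d.G[i];
        l += c * (Si.t() * r.subvec(d.off(i), d.off(i + 1) - 1));
      }
      mat Q = s.tau_eta(rr, k) * Q0 + Gsum / s.sigma2;
      l = l / s.sigma2 + (Gsum * e_old) / s.sigma2;
      vec e_new = rmvn_canonical(Q, l);
      s.eta.slice(k).col(rr) = e_new;
      vec dcoef = e_new - e_old;
      for (int i = 0; i < d.N; ++i) {
        double c = s.Z(i, k) * d.X(i, rr);
        if (c == 0.0) continue;
        mat Si = d.S.rows(d.off(i), d.off(i + 1) - 1);
        r.subvec(d.off(i), d.off(i + 1) - 1) -= c * (Si * dcoef);
      }
    }
  }
}

static void upd_sigma2(State& s, const Data& d, const Hyper& h) {
  vec r = d.y - fitted_all(s, d);
  double sse = arma::dot(r, r);
  double shape = h.alpha0 + 0.5 * d.y.n_elem;
  double rate = h.beta0 + 0.5 * sse;
  s.sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);
}

static void upd_gamma(State& s, const Data& d, const Hyper& h) {
  for (int k = 0; k < s.K; ++k) {
    vec tau_tilde = arma::cumprod(s.delta.col(k));
    for (int m = 0; m < s.M; ++m) {
      for (int p = 0; p < d.P; ++p) {
        double ph = s.phi(p, m, k);
        double shape = 0.5 * (h.nu_gamma + 1.0);
        double rate = 0.5 * (h.nu_gamma + tau_tilde(m) * ph * ph);
        s.gamma(p, m, k) = R::rgamma(shape, 1.0 / rate);
      }
    }
  }
}

static void upd_delta(State& s, const Data& d, const Hyper& h) {
  for (int k = 0; k < s.K; ++k) {
    // theta_m = sum_p gamma_kpm phi_kpm^2
    vec theta(s.M);
    for (int m = 0; m < s.M; ++m) {
      theta(m) = arma::dot(s.gamma.slice(k).col(m),
                           arma::square(s.phi.slice(k).col(m)));
    }
    for (int j = 0; j < s.M; ++j) {
      double shape = (j == 0 ? s.a1(k) : s.a2(k)) + 0.5 * d.P * (s.M - j);
      double rate = 1.0;
      for (int m = j; m < s.M; ++m) {
        double prod = 1.0;
        for (int n = 0; n <= m; ++n) if (n != j) prod *= s.delta(n, k);
        rate += 0.5 * prod * theta(m);
      }
      s.delta(j, k) = R::rgamma(shape, 1.0 / rate);
    }
  }
}

static void upd_a(State& s, const Hyper& h, double step, arma::ivec& acc, arma::ivec& att) {
  for (int k = 0; k < s.K; ++k) {
    // a1: Gamma(alpha1, beta1) prior, Gamma(delta_1k; a1, 1) likelihood
    {
      double cur = s.a1(k);
      double prop = std::exp(std::log(cur) + step * R::norm_rand());
      double lcur = ldgamma(cur, h.alpha1, h.beta1) + ldgamma(s.delta(0, k), cur, 1.0) + std::log(cur);
      double lprop = ldgamma(prop, h.alpha1, h.beta1) + ldgamma(s.delta(0, k), prop, 1.0) + std::log(prop);
      att(0) += 1;
      if (std::log(R::unif_rand()) < lprop - lcur) { s.a1(k) = prop; acc(0) += 1; }
    }
    {
      double cur = s.a2(k);
      double prop = std::exp(std::log(cur) + step * R::norm_rand());
      double lcur = ldgamma(cur, h.alpha2, h.beta2) + std::log(cur);
      double lprop = ldgamma(prop, h.alpha2, h.beta2) + std::log(prop);
      for (int j = 1; j < s.M; ++j) {
        lcur += ldgamma(s.delta(j, k), cur, 1.0);
        lprop += ldgamma(s.delta(j, k), prop, 1.0);
      }
      att(1) += 1;
      if (std::log(R::unif_rand()) < lprop - lcur) { s.a2(k) = prop; acc(1) += 1; }
    }
  }
}

static void upd_tau(State& s, const Data& d, const Hyper& h, const mat& Q0, int rank_q) {
  for (int k = 0; k < s.K; ++k) {
    vec vk = s.v.row(k).t();
    double rate = h.beta_v + 0.5 * arma::as_scalar(vk.t() * Q0 * vk);
    s.tau_v(k) = R::rgamma(h.alpha_v + 0.5 * rank_q, 1.0 / rate);
    for (int rr = 0; rr < d.R; ++rr) {
      vec e = s.eta.slice(k).col(rr);
      double rate_e = h.beta_eta + 0.5 * arma::as_scalar(e.t() * Q0 * e);
      s.tau_eta(rr, k) = R::rgamma(h.alpha_eta + 0.5 * rank_q, 1.0 / rate_e);
    }
  }
}

struct ZSweepResult { int acc; int att; double delta_ll; };

// one Metropolis-Hastings sweep over all allocation rows, targeting
// likelihood^beta_temp x Dir(alpha3 pi). delta_ll accumulates
// sum(ll_before - ll_after) over accepted moves (used by tempered sweeps).
static ZSweepResult upd_Z_sweep(State& s, const Data& d, const Hyper& h,
                                double kappa, double beta_temp) {
  ZSweepResult res{0, 0, 0.0};
  if (s.K < 2) return res;
  const double eps = 0.1;
  vec apar = s.alpha3 * s.pi;
  for (int i = 0; i < d.N; ++i) {
    vec z = s.Z.row(i).t();
    vec zp = rdirichlet(kappa * z + eps);
    if (zp.min() <= 0.0) { res.att += 1; continue; }
    double ll_cur = marg_ll_curve(s, d, i, z);
    double ll_prop = marg_ll_curve(s, d, i, zp);
    double la = beta_temp * (ll_prop - ll_cur)
      + lddirichlet(zp, apar) - lddirichlet(z, apar)
      + lddirichlet(z, kappa * zp + eps) - lddirichlet(zp, kappa * z + eps);
    res.att += 1;
    if (!std::isfinite(la)) la = std::isfinite(ll_prop + lddirichlet(zp, apar)) ? arma::datum::inf : -arma::datum::inf;
    if (std::log(R::unif_rand()) < la) {
      s.Z.row(i) = zp.t();
      res.acc += 1;
      res.delta_ll += ll_cur - ll_prop;
    }
  }
  return res;
}

// shrinkage slice sampler on pairwise simplex coordinates: for each curve,
// move mass between two features along the line z_k + z_k2 = const, leaving
// the marginal-likelihood x Dirichlet-prior target invariant without tuning.
// Complements the Dirichlet-proposal MH sweep, whose random-walk steps become
// very small when the likelihood is sharply peaked.
static void slice_Z_sweep(State& s, const Data& d, const Hyper& h, int n_pairs) {
  if (s.K < 2) return;
  vec apar = s.alpha3 * s.pi;
  for (int i = 0; i < d.N; ++i) {
    int pairs = (s.K == 2) ? 1 : n_pairs;
    for (int rep = 0; rep < pairs; ++rep) {
      int k = (int)std::floor(R::unif_rand() * s.K);
      int k2 = (int)std::floor(R::unif_rand() * (s.K - 1));
      if (k2 >= k) k2 += 1;
      if (k >= s.K || k2 >= s.K) continue;
      vec z = s.Z.row(i).t();
      double c = z(k) + z(k2);
      if (c < 1e-10) continue;
      auto logp = [&](double u) {
        vec zp = z;
        zp(k) = u; zp(k2) = c - u;
        double pr = lddirichlet(zp, apar);
        if (!std::isfinite(pr)) return -arma::datum::inf;
        return marg_ll_curve(s, d, i, zp) + pr;
      };
      double cur = z(k);
      double ly = logp(cur) - R::exp_rand();
      double lo = 0.0, hi = c;
      for (int tries = 0; tries < 60; ++tries) {
        double u = lo + R::unif_rand() * (hi - lo);
        if (logp(u) >= ly) {
          s.Z(i, k) = u;
          s.Z(i, k2) = c - u;
          break;
        }
        if (u < cur) lo = u; else hi = u;
      }
    }
  }
}

// Neal-style tempered transition on the allocation block: MH sweeps through
// the ladder of flattened likelihoods, up then down, with one global accept.
static bool tempered_Z(State& s, const Data& d, const Hyper& h,
                       double kappa, const vec& ladder) {
  const int L = ladder.n_elem;
  mat Z0 = s.Z;
  double L_start = marg_ll_total(s, d);
  double logw = 0.0;
  for (int l = 0; l < L; ++l) {
    ZSweepResult r = upd_Z_sweep(s, d, h, kappa, ladder(l));
    logw += ladder(l) * r.delta_ll;
  }
  for (int l = L - 1; l >= 0; --l) {
    ZSweepResult r = upd_Z_sweep(s, d, h, kappa, ladder(l));
    logw += ladder(l) * r.delta_ll;
  }
  double L_end = marg_ll_total(s, d);
  logw += L_end - L_start;
  if (std::log(R::unif_rand()) < logw) return true;
  s.Z = Z0;
  return false;
}

static void upd_mixing(State& s, const Hyper& h, double step_pi,
                       double step_a3, arma::ivec& acc, arma::ivec& att) {
  // pi: random walk on the additive log-ratio transform (logistic-normal
  // proposal); Jacobian of the transform enters the acceptance ratio.
  if (s.K > 1) {
    vec u(s.K - 1);
    for (int k = 0; k < s.K - 1; ++k) u(k) = std::log(s.pi(k) / s.pi(s.K - 1));
    vec up = u;
    for (int k = 0; k < s.K - 1; ++k) up(k) += step_pi * R::norm_rand();
    vec ep(s.K);
    for (int k = 0; k < s.K - 1; ++k) ep(k) = std::exp(up(k));
    ep(s.K - 1) = 1.0;
    vec pip = ep / arma::accu(ep);
    double lcur = lddirichlet(s.pi, h.c_pi) + arma::accu(arma::log(s.pi));
    double lprop = lddirichlet(pip, h.c_pi) + arma::accu(arma::log(pip));
    for (int i = 0; i < (int)s.Z.n_rows; ++i) {
      lcur += lddirichlet(s.Z.row(i).t(), s.alpha3 * s.pi);
      lprop += lddirichlet(s.Z.row(i).t(), s.alpha3 * pip);
    }
    att(0) += 1;
    double la = lprop - lcur;
    if (!std::isfinite(la)) la = std::isfinite(lprop) ? arma::datum::inf : -arma::datum::inf;
    if (std::log(R::unif_rand()) < la) { s.pi = pip; acc(0) += 1; }
  }
  // alpha3: log-scale random walk
  {
    double cur = s.alpha3;
    double prop = std::exp(std::log(cur) + step_a3 * R::norm_rand());
    double lcur = -h.b * cur + std::log(cur);
    double lprop = -h.b * prop + std::log(prop);
    for (int i = 0; i < (int)s.Z.n_rows; ++i) {
      lcur += lddirichlet(s.Z.row(i).t(), cur * s.pi);
      lprop += lddirichlet(s.Z.row(i).t(), prop * s.pi);
    }
    att(1) += 1;
    double la = lprop - lcur;
    if (!std::isfinite(la)) la = std::isfinite(lprop) ? arma::datum::inf : -arma::datum::inf;
    if (std::log(R::unif_rand()) < la) { s.alpha3 = prop; acc(1) += 1; }
  }
}

// ---- exported entry points ------------------------------------------------

// [[Rcpp::export]]
double cpp_marginal_loglik(List data_, List state_) {
  Data d = make_data(data_);
  State s = make_state(state_);
  return marg_ll_total(s, d);
}

// [[Rcpp::export]]
NumericVector cpp_curve_marginal_loglik(List data_, List state_) {
  Data d = make_data(data_);
  State s = make_state(state_);
  NumericVector out(d.N);
  for (int i = 0; i < d.N; ++i) out[i] = marg_ll_curve(s, d, i, s.Z.row(i).t());
  return out;
}

// long plain-MH allocation chain for stationarity checks: returns the first
// allocation coordinate of every curve at each thinned sweep
// [[Rcpp::export]]
NumericMatrix cpp_z_chain(List data_, List state_, List hyper_, double kappa,
                          int n_sweeps, int thin) {
  Data d = make_data(data_);
  State s = make_state(state_);
  Hyper h = make_hyper(hyper_, s.K);
  int keep = n_sweeps / thin;
  NumericMatrix out(keep, d.N);
  int stored = 0;
  for (int it = 0; it < n_sweeps; ++it) {
    upd_Z_sweep(s, d, h, kappa, 1.0);
    if ((it + 1) % thin == 0) {
      for (int i = 0; i < d.N; ++i) out(stored, i) = s.Z(i, 0);
      stored += 1;
    }
    if ((it + 1) % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_update_blocks(CharacterVector blocks, List data_, List state_,
                       List hyper_, List control_) {
  Data d = make_data(data_);
  State s = make_state(state_);
  Hyper h = make_hyper(hyper_, s.K);
  double kappa = as<double>(control_["kappa"]);
  double step_a = as<double>(control_["step_a"]);
  double step_pi = as<double>(control_["step_pi"]);
  double step_a3 = as<double>(control_["step_alpha3"]);
  vec ladder = as<vec>(control_["ladder"]);
  mat Q0 = rw1_Q(d.P, h.mean_ridge);
  int rank_q = (h.mean_ridge > 0.0) ? d.P : d.P - 1;
  arma::ivec acc_a(2, arma::fill::zeros), att_a(2, arma::fill::zeros);
  arma::ivec acc_m(2, arma::fill::zeros), att_m(2, arma::fill::zeros);
  int z_acc = 0, z_att = 0, t_acc = 0, t_att = 0;
  for (int b = 0; b < blocks.size(); ++b) {
    std::string blk = as<std::string>(blocks[b]);
    if (blk == "scores") upd_chi(s, d);
    else if (blk == "loadings") upd_phi(s, d);
    else if (blk == "means") upd_v(s, d, h, Q0);
    else if (blk == "covariate_effects") upd_eta(s, d, h, Q0);
    else if (blk == "variance") upd_sigma2(s, d, h);
    else if (blk == "shrinkage") {
      upd_gamma(s, d, h); upd_delta(s, d, h); upd_a(s, h, step_a, acc_a, att_a);
    }
    else if (blk == "smoothing") upd_tau(s, d, h, Q0, rank_q);
    else if (blk == "allocations") {
      ZSweepResult r = upd_Z_sweep(s, d, h, kappa, 1.0);
      z_acc += r.acc; z_att += r.att;
    }
    else if (blk == "allocations_slice") slice_Z_sweep(s, d, h, 2);
    else if (blk == "tempered") {
      if (ladder.n_elem == 0) {
        ZSweepResult r = upd_Z_sweep(s, d, h, kappa, 1.0);
        z_acc += r.acc; z_att += r.att;
      } else {
        t_att += 1;
        if (tempered_Z(s, d, h, kappa, ladder)) t_acc += 1;
      }
    }
    else if (blk == "mixing") upd_mixing(s, h, step_pi, step_a3, acc_m, att_m);
    else stop("Unknown update block: " + blk);
  }
  return List::create(
    _["state"] = state_to_list(s, d.P, d.R, d.N),
    _["accept"] = List::create(
      _["allocations"] = NumericVector::create(z_acc, z_att),
      _["tempered"] = NumericVector::create(t_acc, t_att),
      _["a_shape"] = NumericVector::create(acc_a(0) + acc_a(1), att_a(0) + att_a(1)),
      _["mixing"] = NumericVector::create(acc_m(0) + acc_m(1), att_m(0) + att_m(1))));
}

// [[Rcpp::export]]
List cpp_run_mcmc(List data_, List state_, List hyper_, List control_) {
  Data d = make_data(data_);
  State s = make_state(state_);
  Hyper h = make_hyper(hyper_, s.K);
  const int n_iter = as<int>(control_["n_iter"]);
  const int burnin = as<int>(control_["burnin"]);
  const int thin = as<int>(control_["thin"]);
  double kappa = as<double>(control_["kappa"]);
  double step_a = as<double>(control_["step_a"]);
  double step_pi = as<double>(control_["step_pi"]);
  double step_a3 = as<double>(control_["step_alpha3"]);
  const bool adapt = as<bool>(control_["adapt"]);
  const bool verbose = as<bool>(control_["verbose"]);
  const int report_every = as<int>(control_["report_every"]);
  vec ladder = as<vec>(control_["ladder"]);
  const int temper_every = as<int>(control_["temper_every"]);

  const int K = s.K, M = s.M, P = d.P, R = d.R, N = d.N;
  const int S_keep = (n_iter - burnin) / thin;
  mat Q0 = rw1_Q(P, h.mean_ridge);
  int rank_q = (h.mean_ridge > 0.0) ? P : P - 1;

  NumericVector v_d(S_keep * K * P), eta_d(S_keep * P * R * K),
    phi_d(S_keep * P * M * K), chi_d(S_keep * N * M), Z_d(S_keep * N * K),
    gamma_d(S_keep * P * M * K), delta_d(S_keep * M * K),
    a1_d(S_keep * K), a2_d(S_keep * K), tauv_d(S_keep * K),
    taue_d(S_keep * R * K), pi_d(S_keep * K), s2_d(S_keep),
    a3_d(S_keep), ll_d(S_keep);

  int z_acc = 0, z_att = 0, t_acc = 0, t_att = 0;
  arma::ivec tot_acc_a(2, arma::fill::zeros), tot_att_a(2, arma::fill::zeros);
  arma::ivec tot_acc_m(2, arma::fill::zeros), tot_att_m(2, arma::fill::zeros);
  arma::ivec acc_a(2, arma::fill::zeros), att_a(2, arma::fill::zeros);
  arma::ivec acc_m(2, arma::fill::zeros), att_m(2, arma::fill::zeros);
  int w_zacc = 0, w_zatt = 0;  // adaptation window counters
  const int adapt_window = 50;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    upd_chi(s, d);
    upd_phi(s, d);
    upd_v(s, d, h, Q0);
    upd_eta(s, d, h, Q0);
    upd_sigma2(s, d, h);
    upd_gamma(s, d, h);
    upd_delta(s, d, h);
    upd_a(s, h, step_a, acc_a, att_a);
    upd_tau(s, d, h, Q0, rank_q);
    bool tempered_now = (ladder.n_elem > 0) && (temper_every > 0) &&
      ((it + 1) % temper_every == 0);
    if (tempered_now) {
      t_att += 1;
      if (tempered_Z(s, d, h, kappa, ladder)) t_acc += 1;
    } else {
      ZSweepResult r = upd_Z_sweep(s, d, h, kappa, 1.0);
      z_acc += r.acc; z_att += r.att;
      w_zacc += r.acc; w_zatt += r.att;
    }
    slice_Z_sweep(s, d, h, 2);
    // the allocation kernels target the score-marginalized likelihood, so
    // the scores must be refreshed from their full conditional before the
    // state is treated as a coherent joint draw
    upd_chi(s, d);
    upd_mixing(s, h, step_pi, step_a3, acc_m, att_m);

    if (adapt && it < burnin && (it + 1) % adapt_window == 0) {
      if (w_zatt > 0) {
        double rate = (double)w_zacc / w_zatt;
        kappa = std::min(1e5, std::max(1.0, std::exp(std::log(kappa) + 2.0 * (0.3 - rate))));
      }
      double ra = (arma::accu(att_a) > 0) ? (double)arma::accu(acc_a) / arma::accu(att_a) : 0.35;
      step_a = std::min(10.0, std::max(1e-3, std::exp(std::log(step_a) + (ra - 0.35))));
      double rm = (att_m(0) > 0) ? (double)acc_m(0) / att_m(0) : 0.35;
      step_pi = std::min(10.0, std::max(1e-3, std::exp(std::log(step_pi) + (rm - 0.35))));
      double r3 = (att_m(1) > 0) ? (double)acc_m(1) / att_m(1) : 0.35;
      step_a3 = std::min(10.0, std::max(1e-3, std::exp(std::log(step_a3) + (r3 - 0.35))));
      w_zacc = 0; w_zatt = 0;
      tot_acc_a += acc_a; tot_att_a += att_a;
      tot_acc_m += acc_m; tot_att_m += att_m;
      acc_a.zeros(); att_a.zeros(); acc_m.zeros(); att_m.zeros();
    }

    if (it >= burnin && (it - burnin + 1) % thin == 0) {
      int sidx = kept;
      for (int k = 0; k < K; ++k) for (int p = 0; p < P; ++p)
        v_d[sidx + S_keep * (k + (long)K * p)] = s.v(k, p);
      for (int k = 0; k < K; ++k) for (int rr = 0; rr < R; ++rr) for (int p = 0; p < P; ++p)
        eta_d[sidx + S_keep * (p + (long)P * (rr + (long)R * k))] = s.eta(p, rr, k);
      for (int k = 0; k < K; ++k) for (int m = 0; m < M; ++m) for (int p = 0; p < P; ++p) {
        phi_d[sidx + S_keep * (p + (long)P * (m + (long)M * k))] = s.phi(p, m, k);
        gamma_d[sidx + S_keep * (p + (long)P * (m + (long)M * k))] = s.gamma(p, m, k);
      }
      for (int m = 0; m < M; ++m) for (int i = 0; i < N; ++i)
        chi_d[sidx + S_keep * (i + (long)N * m)] = s.chi(i, m);
      for (int k = 0; k < K; ++k) for (int i = 0; i < N; ++i)
        Z_d[sidx + S_keep * (i + (long)N * k)] = s.Z(i, k);
      for (int k = 0; k < K; ++k) for (int m = 0; m < M; ++m)
        delta_d[sidx + S_keep * (m + (long)M * k)] = s.delta(m, k);
      for (int k = 0; k < K; ++k) {
        a1_d[sidx + S_keep * k] = s.a1(k);
        a2_d[sidx + S_keep * k] = s.a2(k);
        tauv_d[sidx + S_keep * k] = s.tau_v(k);
        pi_d[sidx + S_keep * k] = s.pi(k);
        for (int rr = 0; rr < R; ++rr)
          taue_d[sidx + S_keep * (rr + (long)R * k)] = s.tau_eta(rr, k);
      }
      s2_d[sidx] = s.sigma2;
      a3_d[sidx] = s.alpha3;
      double ll = marg_ll_total(s, d);
      if (!std::isfinite(ll)) stop("Non-finite marginal log-likelihood at sweep %d.", it + 1);
      ll_d[sidx] = ll;
      kept += 1;
    }
    if (verbose && report_every > 0 && (it + 1) % report_every == 0) {
      Rcpp::Rcout << "sweep " << (it + 1) << "/" << n_iter
                  << "  sigma2 = " << s.sigma2
                  << "  kappa = " << kappa << std::endl;
    }
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  v_d.attr("dim") = IntegerVector::create(S_keep, K, P);
  eta_d.attr("dim") = IntegerVector::create(S_keep, P, R, K);
  phi_d.attr("dim") = IntegerVector::create(S_keep, P, M, K);
  gamma_d.attr("dim") = IntegerVector::create(S_keep, P, M, K);
  chi_d.attr("dim") = IntegerVector::create(S_keep, N, M);
  Z_d.attr("dim") = IntegerVector::create(S_keep, N, K);
  delta_d.attr("dim") = IntegerVector::create(S_keep, M, K);
  a1_d.attr("dim") = IntegerVector::create(S_keep, K);
  a2_d.attr("dim") = IntegerVector::create(S_keep, K);
  tauv_d.attr("dim") = IntegerVector::create(S_keep, K);
  taue_d.attr("dim") = IntegerVector::create(S_keep, R, K);
  pi_d.attr("dim") = IntegerVector::create(S_keep, K);

  List draws = List::create(
    _["v"] = v_d, _["eta"] = eta_d, _["phi"] = phi_d, _["chi"] = chi_d,
    _["Z"] = Z_d, _["sigma2"] = s2_d, _["gamma"] = gamma_d,
    _["delta"] = delta_d, _["a1"] = a1_d, _["a2"] = a2_d,
    _["tau_v"] = tauv_d, _["tau_eta"] = taue_d, _["pi"] = pi_d,
    _["alpha3"] = a3_d);
  tot_acc_a += acc_a; tot_att_a += att_a;
  tot_acc_m += acc_m; tot_att_m += att_m;
  List accept = List::create(
    _["allocations"] = (z_att > 0) ? (double)z_acc / z_att : NA_REAL,
    _["tempered"] = (t_att > 0) ? (double)t_acc / t_att : NA_REAL,
    _["a_shape"] = (arma::accu(tot_att_a) > 0) ? (double)arma::accu(tot_acc_a) / arma::accu(tot_att_a) : NA_REAL,
    _["pi"] = (tot_att_m(0) > 0) ? (double)tot_acc_m(0) / tot_att_m(0) : NA_REAL,
    _["alpha3"] = (tot_att_m(1) > 0) ? (double)tot_acc_m(1) / tot_att_m(1) : NA_REAL);
  return List::create(
    _["draws"] = draws, _["loglik"] = ll_d, _["accept"] = accept,
    _["final_state"] = state_to_list(s, P, R, N),
    _["tuned"] = List::create(_["kappa"] = kappa, _["step_a"] = step_a,
                              _["step_pi"] = step_pi, _["step_alpha3"] = step_a3));
}
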