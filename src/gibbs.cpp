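// Gibbs sampler core for the joint longitudinal / interval-censored model.
//
// All randomness goes through R's Rmath generators (norm_rand, unif_rand,
// exp_rand, R::rgamma, R::rbeta), so chains are bit-reproducible under
// set.seed() on the R side. Every full conditional is a standard
// distribution; there are no Metropolis steps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- primitives

// Robert (1995) exponential-proposal rejection sampler for a standard normal
// truncated to (a, b) with a >= 0 (b may be +Inf). Used when the tail
// probabilities underflow double precision.
static double rtnorm_tail(double a, double b) {
  const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a - std::log(R::unif_rand()) / alpha;
    if (z > b) continue;
    double d = z - alpha;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return z;
  }
}

// standard normal truncated to (a, b); tail-parametrized inverse CDF keeps
// full relative precision for regions far (>> 5 sd) from the mode.
static double rtnorm_std(double a, double b) {
  if (!(a < b)) stop("rtruncnorm: lower >= upper");
  if (a >= 0.0) {
    double qa = R::pnorm(a, 0.0, 1.0, 0, 0);              // upper-tail probs
    double qb = (b == R_PosInf) ? 0.0 : R::pnorm(b, 0.0, 1.0, 0, 0);
    if (qa > 1e-300) {
      double u = qb + R::unif_rand() * (qa - qb);
      return R::qnorm(u, 0.0, 1.0, 0, 0);
    }
    return rtnorm_tail(a, b);                              // underflow regime
  }
  if (b <= 0.0) return -rtnorm_std(-b, -a);
  double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
  double pb = R::pnorm(b, 0.0, 1.0, 1, 0);
  return R::qnorm(pa + R::unif_rand() * (pb - pa), 0.0, 1.0, 1, 0);
}

static double rtnorm1(double mean, double sd, double lo, double hi) {
  if (!(sd > 0.0)) stop("rtruncnorm: sd must be positive");
  return mean + sd * rtnorm_std((lo - mean) / sd, (hi - mean) / sd);
}

// inverse-Gaussian draw, mean/shape parametrization (Michael-Schucany-Haas).
// Worked in units of the mean with the conjugate form of the smaller root,
// x1/mu = 1 - 2y/(y + sqrt(y(4 phi + y))), which stays strictly positive for
// any mean/shape ratio (the textbook form cancels catastrophically when the
// mean is many orders of magnitude above the shape).
static double rinvgauss1(double mu, double lambda) {
  if (!(mu > 0.0) || !(lambda > 0.0)) stop("rinvgauss: nonpositive parameter");
  double phi = lambda / mu;
  double y = R::norm_rand();
  y *= y;
  double s = std::sqrt(y * (4.0 * phi + y));
  double x1r = 1.0 - 2.0 * y / (y + s);      // smaller root, in (0, 1]
  if (x1r <= 0.0) x1r = phi / (y + phi);     // asymptotic limit, y >> phi
  if (R::unif_rand() <= 1.0 / (1.0 + x1r)) return mu * x1r;
  return mu / x1r;
}

// draw from N(P^{-1} b, scale * P^{-1}) given the (unscaled) precision P
static arma::vec mvn_prec(const arma::mat& P, const arma::vec& b,
                          double scale = 1.0) {
  arma::mat U;
  if (!arma::chol(U, P)) stop("non-positive-definite precision matrix");
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  arma::vec zz(b.n_elem);
  for (arma::uword i = 0; i < zz.n_elem; ++i) zz[i] = R::norm_rand();
  return mu + std::sqrt(scale) * arma::solve(arma::trimatu(U), zz);
}

// [[Rcpp::export]]
NumericVector cpp_rtruncnorm(int n, NumericVector mean, NumericVector sd,
                             NumericVector lower, NumericVector upper) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rtnorm1(mean[i % mean.size()], sd[i % sd.size()],
                     lower[i % lower.size()], upper[i % upper.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rinvgauss(int n, NumericVector mean, NumericVector shape) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rinvgauss1(mean[i % mean.size()], shape[i % shape.size()]);
  return out;
}

// ------------------------------------------------------------- model structs

struct Data {
  arma::vec y;        // stacked longitudinal responses
  arma::uvec subj;    // 0-based subject index per observation
  arma::mat Mlong;    // n_obs x K_mu M-spline basis at t_ij
  arma::mat X;        // n x p covariates
  arma::vec m;        // visits per subject
  arma::ivec delta;   // 1 left / 2 interval / 3 right censored
  arma::mat Banchor;  // n x K_alpha I-spline basis at anchor times
  arma::uvec ic;      // 0-based indices of interval-censored subjects
  arma::mat Bdiff;    // n_ic x K_alpha, b(R) - b(L) (nonnegative)
  arma::mat A;        // K_mu x K_mu, sum_ij M(t_ij) M(t_ij)'
  arma::mat XtX;      // sum_i X_i X_i'
  arma::mat XtmX;     // sum_i m_i X_i X_i'
  arma::vec Wk;       // sum_i b_k(t_i)^2 per basis function
  int n, p;
};

struct Prior {
  int variant;  // 1 BL, 2 BAL, 3 SS, 4 GB
  double a_u, b_u, a_xi, b_xi, a_eps, b_eps, m0, v0, a_rho, b_rho;
  arma::vec eta0; arma::mat Seta_inv;
  double a_lambda, b_lambda;
  double a_omega, b_omega, s_spike2, s_slab2;
  arma::vec beta0, theta0; arma::mat Sbeta_inv, Stheta_inv;
};

struct State {
  arma::vec z, r, beta, theta, tau_s2, tau_l2, lambda2_s, lambda2_l, eta, u, xi;
  arma::vec omega_s, omega_l;   // per-coefficient inclusion probabilities
  arma::ivec delta_s, delta_l;
  double r0, rho, sigma_u2, sigma_xi2, sigma_eps2;
};

static Data as_data(const List& prep) {
  Data d;
  d.y = as<arma::vec>(prep["y"]);
  d.subj = as<arma::uvec>(prep["subj"]);
  d.Mlong = as<arma::mat>(prep["Mlong"]);
  d.X = as<arma::mat>(prep["X"]);
  d.m = as<arma::vec>(prep["m"]);
  d.delta = as<arma::ivec>(prep["delta"]);
  d.Banchor = as<arma::mat>(prep["Banchor"]);
  d.ic = as<arma::uvec>(prep["ic"]);
  d.Bdiff = as<arma::mat>(prep["Bdiff"]);
  d.A = as<arma::mat>(prep["A"]);
  d.XtX = as<arma::mat>(prep["XtX"]);
  d.XtmX = as<arma::mat>(prep["XtmX"]);
  d.Wk = arma::sum(arma::square(d.Banchor), 0).t();
  d.n = d.X.n_rows; d.p = d.X.n_cols;
  return d;
}

static Prior as_prior(const List& pr) {
  Prior p;
  p.variant = as<int>(pr["variant_code"]);
  p.a_u = pr["a_u"]; p.b_u = pr["b_u"];
  p.a_xi = pr["a_xi"]; p.b_xi = pr["b_xi"];
  p.a_eps = pr["a_eps"]; p.b_eps = pr["b_eps"];
  p.m0 = pr["m0"]; p.v0 = pr["v0"];
  p.a_rho = pr["a_rho"]; p.b_rho = pr["b_rho"];
  p.eta0 = as<arma::vec>(pr["eta0"]);
  p.Seta_inv = as<arma::mat>(pr["Sigma_eta_inv"]);
  p.a_lambda = pr["a_lambda"]; p.b_lambda = pr["b_lambda"];
  p.a_omega = pr["a_omega"]; p.b_omega = pr["b_omega"];
  p.s_spike2 = pr["sigma_spike2"]; p.s_slab2 = pr["sigma_slab2"];
  p.beta0 = as<arma::vec>(pr["beta0"]);
  p.theta0 = as<arma::vec>(pr["theta0"]);
  p.Sbeta_inv = as<arma::mat>(pr["Sigma_beta_inv"]);
  p.Stheta_inv = as<arma::mat>(pr["Sigma_theta_inv"]);
  return p;
}

static State as_state(const List& st) {
  State s;
  s.z = as<arma::vec>(st["z"]);
  s.r0 = st["r0"];
  s.r = as<arma::vec>(st["r"]);
  s.rho = st["rho"];
  s.beta = as<arma::vec>(st["beta"]);
  s.theta = as<arma::vec>(st["theta"]);
  s.tau_s2 = as<arma::vec>(st["tau_s2"]);
  s.tau_l2 = as<arma::vec>(st["tau_l2"]);
  s.lambda2_s = as<arma::vec>(st["lambda2_s"]);
  s.lambda2_l = as<arma::vec>(st["lambda2_l"]);
  s.delta_s = as<arma::ivec>(st["delta_s"]);
  s.delta_l = as<arma::ivec>(st["delta_l"]);
  s.omega_s = as<arma::vec>(st["omega_s"]);
  s.omega_l = as<arma::vec>(st["omega_l"]);
  s.eta = as<arma::vec>(st["eta"]);
  s.u = as<arma::vec>(st["u"]);
  s.xi = as<arma::vec>(st["xi"]);
  s.sigma_u2 = st["sigma_u2"]; s.sigma_xi2 = st["sigma_xi2"];
  s.sigma_eps2 = st["sigma_eps2"];
  return s;
}

// plain R vectors (not 1-column matrices) so state components combine
// freely with vector arithmetic on the R side
static NumericVector rvec(const arma::vec& v) {
  return NumericVector(v.begin(), v.end());
}
static IntegerVector rvec(const arma::ivec& v) {
  return IntegerVector(v.begin(), v.end());
}

static List state_to_list(const State& s) {
  return List::create(
    _["z"] = rvec(s.z), _["r0"] = s.r0, _["r"] = rvec(s.r), _["rho"] = s.rho,
    _["beta"] = rvec(s.beta), _["theta"] = rvec(s.theta),
    _["tau_s2"] = rvec(s.tau_s2), _["tau_l2"] = rvec(s.tau_l2),
    _["lambda2_s"] = rvec(s.lambda2_s), _["lambda2_l"] = rvec(s.lambda2_l),
    _["delta_s"] = rvec(s.delta_s), _["delta_l"] = rvec(s.delta_l),
    _["omega_s"] = rvec(s.omega_s), _["omega_l"] = rvec(s.omega_l),
    _["eta"] = rvec(s.eta), _["u"] = rvec(s.u), _["xi"] = rvec(s.xi),
    _["sigma_u2"] = s.sigma_u2, _["sigma_xi2"] = s.sigma_xi2,
    _["sigma_eps2"] = s.sigma_eps2);
}

// ------------------------------------------------------------- block updates

static void upd_z(State& s, const Data& d) {
  arma::vec mean = s.r0 + d.Banchor * s.r + d.X * s.beta + s.u;
  arma::vec lo(d.n), hi(d.n);
  for (int i = 0; i < d.n; ++i) {
    if (d.delta[i] == 1)      { lo[i] = 0.0;    hi[i] = R_PosInf; }
    else if (d.delta[i] == 3) { lo[i] = R_NegInf; hi[i] = 0.0; }
  }
  arma::vec gd = d.Bdiff * s.r;  // alpha(R) - alpha(L) per IC subject
  for (arma::uword j = 0; j < d.ic.n_elem; ++j) {
    if (!(gd[j] > 0.0)) stop("nonmonotone alpha: alpha(L) >= alpha(R)");
    lo[d.ic[j]] = -gd[j]; hi[d.ic[j]] = 0.0;
  }
  for (int i = 0; i < d.n; ++i) s.z[i] = rtnorm1(mean[i], 1.0, lo[i], hi[i]);
}

static void upd_r0(State& s, const Data& d, const Prior& p) {
  double W0 = p.v0 + d.n;
  double E0 = (p.v0 * p.m0 +
               arma::accu(s.z - d.Banchor * s.r - d.X * s.beta - s.u)) / W0;
  s.r0 = E0 + R::norm_rand() / std::sqrt(W0);
}

static void upd_r(State& s, const Data& d) {
  arma::vec base = s.z - s.r0 - d.X * s.beta - s.u;
  arma::vec fit = d.Banchor * s.r;
  arma::vec gd = d.Bdiff * s.r;
  const int K = s.r.n_elem;
  for (int k = 0; k < K; ++k) {
    double old = s.r[k];
    double draw;
    if (d.Wk[k] == 0.0) {
      draw = R::exp_rand() / s.rho;
    } else {
      const arma::vec bk = d.Banchor.col(k);
      double Ek = (arma::dot(bk, base - fit + old * bk) - s.rho) / d.Wk[k];
      double dstar = 0.0;  // max(c_k*, 0): feasibility bound from IC subjects
      for (arma::uword j = 0; j < d.ic.n_elem; ++j) {
        double bd = d.Bdiff(j, k);
        if (bd > 0.0) {
          double c = (-s.z[d.ic[j]] - (gd[j] - old * bd)) / bd;
          if (c > dstar) dstar = c;
        }
      }
      draw = rtnorm1(Ek, 1.0 / std::sqrt(d.Wk[k]), dstar, R_PosInf);
    }
    double shift = draw - old;
    if (shift != 0.0) {
      fit += shift * d.Banchor.col(k);
      if (d.ic.n_elem) gd += shift * d.Bdiff.col(k);
    }
    s.r[k] = draw;
  }
}

static void upd_rho(State& s, const Prior& p) {
  s.rho = R::rgamma(p.a_rho + s.r.n_elem,
                    1.0 / (p.b_rho + arma::accu(s.r)));
}

static void upd_beta(State& s, const Data& d, const Prior& p) {
  arma::vec resid = s.z - (s.r0 + d.Banchor * s.r) - s.u;
  arma::vec b = d.X.t() * resid;
  arma::mat P = d.XtX;
  if (p.variant == 1 || p.variant == 2) {
    P.diag() += 1.0 / s.tau_s2;
  } else if (p.variant == 3) {
    for (int j = 0; j < d.p; ++j)
      P(j, j) += 1.0 / (s.delta_s[j] ? p.s_slab2 : p.s_spike2);
  } else {
    P += p.Sbeta_inv;
    b += p.Sbeta_inv * p.beta0;
  }
  s.beta = mvn_prec(P, b);
}

// The gamma full conditionals of the Lasso penalties are conjugate for the
// squared penalty (normal scale mixture with Exp(lambda^2 / 2) mixing), so
// the sampled quantity is lambda^2 throughout; the latent-scale precision is
// then IG(sqrt(lambda^2) / |coef|, lambda^2).
static void upd_shrink_s(State& s, const Data& d, const Prior& p) {
  const double guard = 1e-10;
  if (p.variant == 1) {                       // Bayesian Lasso
    double lam2 = R::rgamma(d.p + p.a_lambda,
                            1.0 / (0.5 * arma::accu(s.tau_s2) + p.b_lambda));
    s.lambda2_s[0] = lam2;
    for (int j = 0; j < d.p; ++j) {
      double ab = std::max(std::abs(s.beta[j]), guard);
      s.tau_s2[j] = 1.0 / rinvgauss1(std::sqrt(lam2) / ab, lam2);
    }
  } else if (p.variant == 2) {                // adaptive Lasso
    for (int j = 0; j < d.p; ++j) {
      double lam2 = R::rgamma(1.0 + p.a_lambda,
                              1.0 / (0.5 * s.tau_s2[j] + p.b_lambda));
      s.lambda2_s[j] = lam2;
      double ab = std::max(std::abs(s.beta[j]), guard);
      s.tau_s2[j] = 1.0 / rinvgauss1(std::sqrt(lam2) / ab, lam2);
    }
  } else if (p.variant == 3) {                // spike-and-slab
    double sd_ratio = std::sqrt(p.s_slab2 / p.s_spike2);
    double prec_diff = 1.0 / p.s_spike2 - 1.0 / p.s_slab2;
    for (int j = 0; j < d.p; ++j) {
      double R_j = std::exp(-0.5 * s.beta[j] * s.beta[j] * prec_diff) * sd_ratio;
      double pj = 1.0 / (1.0 + R_j * (1.0 - s.omega_s[j]) / s.omega_s[j]);
      s.delta_s[j] = (R::unif_rand() < pj) ? 1 : 0;
      s.omega_s[j] = R::rbeta(p.a_omega + s.delta_s[j],
                              p.b_omega + 1 - s.delta_s[j]);
    }
  }                                           // GB: no-op
}

static void upd_theta(State& s, const Data& d, const Prior& p) {
  arma::vec robs = d.y - d.Mlong * s.eta;
  arma::vec sres(d.n, arma::fill::zeros);
  for (arma::uword o = 0; o < d.y.n_elem; ++o) sres[d.subj[o]] += robs[o];
  sres -= d.m % (s.u + s.xi);
  arma::vec b = d.X.t() * sres;
  arma::mat P = d.XtmX;
  if (p.variant == 1 || p.variant == 2) {
    P.diag() += 1.0 / s.tau_l2;
    s.theta = mvn_prec(P, b, s.sigma_eps2);
  } else if (p.variant == 3) {
    for (int j = 0; j < d.p; ++j)
      P(j, j) += 1.0 / (s.delta_l[j] ? p.s_slab2 : p.s_spike2);
    s.theta = mvn_prec(P, b, s.sigma_eps2);
  } else {
    P = p.Stheta_inv + d.XtmX / s.sigma_eps2;
    b = p.Stheta_inv * p.theta0 + d.X.t() * sres / s.sigma_eps2;
    s.theta = mvn_prec(P, b);
  }
}

static void upd_shrink_l(State& s, const Data& d, const Prior& p) {
  const double guard = 1e-10;
  double se = std::sqrt(s.sigma_eps2);
  if (p.variant == 1) {
    double lam2 = R::rgamma(d.p + p.a_lambda,
                            1.0 / (0.5 * arma::accu(s.tau_l2) + p.b_lambda));
    s.lambda2_l[0] = lam2;
    for (int j = 0; j < d.p; ++j) {
      double ab = std::max(std::abs(s.theta[j]) / se, guard);
      s.tau_l2[j] = 1.0 / rinvgauss1(std::sqrt(lam2) / ab, lam2);
    }
  } else if (p.variant == 2) {
    for (int j = 0; j < d.p; ++j) {
      double lam2 = R::rgamma(1.0 + p.a_lambda,
                              1.0 / (0.5 * s.tau_l2[j] + p.b_lambda));
      s.lambda2_l[j] = lam2;
      double ab = std::max(std::abs(s.theta[j]) / se, guard);
      s.tau_l2[j] = 1.0 / rinvgauss1(std::sqrt(lam2) / ab, lam2);
    }
  } else if (p.variant == 3) {
    double sd_ratio = std::sqrt(p.s_slab2 / p.s_spike2);
    double prec_diff = 1.0 / p.s_spike2 - 1.0 / p.s_slab2;
    for (int j = 0; j < d.p; ++j) {
      double t2 = s.theta[j] * s.theta[j] / s.sigma_eps2;
      double R_j = std::exp(-0.5 * t2 * prec_diff) * sd_ratio;
      double pj = 1.0 / (1.0 + R_j * (1.0 - s.omega_l[j]) / s.omega_l[j]);
      s.delta_l[j] = (R::unif_rand() < pj) ? 1 : 0;
      s.omega_l[j] = R::rbeta(p.a_omega + s.delta_l[j],
                              p.b_omega + 1 - s.delta_l[j]);
    }
  }
}

static void upd_eta(State& s, const Data& d, const Prior& p) {
  arma::vec xt = d.X * s.theta;
  arma::vec robs = d.y;
  for (arma::uword o = 0; o < d.y.n_elem; ++o)
    robs[o] -= xt[d.subj[o]] + s.u[d.subj[o]] + s.xi[d.subj[o]];
  arma::mat P = p.Seta_inv + d.A / s.sigma_eps2;
  arma::vec b = p.Seta_inv * p.eta0 + d.Mlong.t() * robs / s.sigma_eps2;
  s.eta = mvn_prec(P, b);
}

static void upd_u(State& s, const Data& d) {
  arma::vec muv = d.Mlong * s.eta;
  arma::vec xt = d.X * s.theta;
  arma::vec sres(d.n, arma::fill::zeros);
  for (arma::uword o = 0; o < d.y.n_elem; ++o)
    sres[d.subj[o]] += d.y[o] - muv[o];
  sres -= d.m % (xt + s.xi);
  arma::vec zres = s.z - (s.r0 + d.Banchor * s.r) - d.X * s.beta;
  for (int i = 0; i < d.n; ++i) {
    double Vi = d.m[i] / s.sigma_eps2 + 1.0 / s.sigma_u2 + 1.0;
    double mean = (sres[i] / s.sigma_eps2 + zres[i]) / Vi;
    s.u[i] = mean + R::norm_rand() / std::sqrt(Vi);
  }
}

static void upd_sigma_u(State& s, const Data& d, const Prior& p) {
  s.sigma_u2 = 1.0 / R::rgamma(0.5 * d.n + p.a_u,
                               1.0 / (0.5 * arma::dot(s.u, s.u) + p.b_u));
}

static void upd_xi(State& s, const Data& d) {
  arma::vec muv = d.Mlong * s.eta;
  arma::vec xt = d.X * s.theta;
  arma::vec sres(d.n, arma::fill::zeros);
  for (arma::uword o = 0; o < d.y.n_elem; ++o)
    sres[d.subj[o]] += d.y[o] - muv[o];
  sres -= d.m % (xt + s.u);
  for (int i = 0; i < d.n; ++i) {
    double Vi = d.m[i] / s.sigma_eps2 + 1.0 / s.sigma_xi2;
    s.xi[i] = (sres[i] / s.sigma_eps2) / Vi + R::norm_rand() / std::sqrt(Vi);
  }
}

static void upd_sigma_xi(State& s, const Data& d, const Prior& p) {
  s.sigma_xi2 = 1.0 / R::rgamma(0.5 * d.n + p.a_xi,
                                1.0 / (0.5 * arma::dot(s.xi, s.xi) + p.b_xi));
}

static void upd_sigma_eps(State& s, const Data& d, const Prior& p) {
  arma::vec muv = d.Mlong * s.eta;
  arma::vec xt = d.X * s.theta;
  double ssr = 0.0;
  for (arma::uword o = 0; o < d.y.n_elem; ++o) {
    double e = d.y[o] - muv[o] - xt[d.subj[o]] - s.u[d.subj[o]] - s.xi[d.subj[o]];
    ssr += e * e;
  }
  double shape = p.a_eps + 0.5 * arma::accu(d.m);
  double rate = p.b_eps + 0.5 * ssr;
  if (p.variant == 1 || p.variant == 2) {     // theta prior scaled by sigma_eps2
    shape += 0.5 * d.p;
    rate += 0.5 * arma::accu(arma::square(s.theta) / s.tau_l2);
  } else if (p.variant == 3) {
    shape += 0.5 * d.p;
    for (int j = 0; j < d.p; ++j)
      rate += 0.5 * s.theta[j] * s.theta[j] /
        (s.delta_l[j] ? p.s_slab2 : p.s_spike2);
  }                                           // GB: theta prior unscaled
  s.sigma_eps2 = 1.0 / R::rgamma(shape, 1.0 / rate);
}

// ------------------------------------------------------------------- driving

static void run_block(const std::string& bl, State& s, const Data& d,
                      const Prior& p) {
  if      (bl == "z")         upd_z(s, d);
  else if (bl == "r0")        upd_r0(s, d, p);
  else if (bl == "r")         upd_r(s, d);
  else if (bl == "rho")       upd_rho(s, p);
  else if (bl == "beta")      upd_beta(s, d, p);
  else if (bl == "shrink_s")  upd_shrink_s(s, d, p);
  else if (bl == "theta")     upd_theta(s, d, p);
  else if (bl == "shrink_l")  upd_shrink_l(s, d, p);
  else if (bl == "eta")       upd_eta(s, d, p);
  else if (bl == "u")         upd_u(s, d);
  else if (bl == "sigma_u")   upd_sigma_u(s, d, p);
  else if (bl == "xi")        upd_xi(s, d);
  else if (bl == "sigma_xi")  upd_sigma_xi(s, d, p);
  else if (bl == "sigma_eps") upd_sigma_eps(s, d, p);
  else stop("unknown Gibbs block: " + bl);
}

static std::vector<std::string> sweep_order(int variant) {
  if (variant == 3)  // spike-and-slab: indicators before coefficients
    return {"z", "r0", "r", "rho", "shrink_s", "beta", "shrink_l", "theta",
            "eta", "u", "sigma_u", "xi", "sigma_xi", "sigma_eps"};
  if (variant == 4)  // general normal priors: no shrinkage blocks
    return {"z", "r0", "r", "rho", "beta", "theta",
            "eta", "u", "sigma_u", "xi", "sigma_xi", "sigma_eps"};
  return {"z", "r0", "r", "rho", "beta", "shrink_s", "theta", "shrink_l",
          "eta", "u", "sigma_u", "xi", "sigma_xi", "sigma_eps"};
}

// [[Rcpp::export]]
List cpp_sweep(List prep, List state, List prior, CharacterVector blocks) {
  Data d = as_data(prep);
  Prior p = as_prior(prior);
  State s = as_state(state);
  std::vector<std::string> bls;
  if (blocks.size() == 1 && as<std::string>(blocks[0]) == "all")
    bls = sweep_order(p.variant);
  else
    for (int i = 0; i < blocks.size(); ++i)
      bls.push_back(as<std::string>(blocks[i]));
  for (const auto& bl : bls) run_block(bl, s, d, p);
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_chain(List prep, List state, List prior,
               int iters, int burnin, int thin) {
  Data d = as_data(prep);
  Prior p = as_prior(prior);
  State s = as_state(state);
  std::vector<std::string> order = sweep_order(p.variant);
  const int nret = (iters - burnin) / thin;
  arma::mat beta_d(nret, d.p), theta_d(nret, d.p),
            r_d(nret, s.r.n_elem), eta_d(nret, s.eta.n_elem);
  arma::vec r0_d(nret), rho_d(nret), su_d(nret), sxi_d(nret), seps_d(nret);
  arma::mat ds_d, dl_d;
  if (p.variant == 3) { ds_d.set_size(nret, d.p); dl_d.set_size(nret, d.p); }
  int kept = 0;
  for (int it = 1; it <= iters; ++it) {
    for (const auto& bl : order) {
      try {
        run_block(bl, s, d, p);
      } catch (std::exception& e) {
        stop("Gibbs block '" + bl + "' failed at iteration " +
             std::to_string(it) + ": " + e.what());
      }
    }
    if (it > burnin && (it - burnin) % thin == 0 && kept < nret) {
      beta_d.row(kept) = s.beta.t();
      theta_d.row(kept) = s.theta.t();
      r_d.row(kept) = s.r.t();
      eta_d.row(kept) = s.eta.t();
      r0_d[kept] = s.r0; rho_d[kept] = s.rho;
      su_d[kept] = s.sigma_u2; sxi_d[kept] = s.sigma_xi2;
      seps_d[kept] = s.sigma_eps2;
      if (p.variant == 3) {
        ds_d.row(kept) = arma::conv_to<arma::rowvec>::from(s.delta_s);
        dl_d.row(kept) = arma::conv_to<arma::rowvec>::from(s.delta_l);
      }
      ++kept;
    }
  }
  List draws = List::create(
    _["beta"] = beta_d, _["theta"] = theta_d,
    _["r0"] = r0_d, _["r"] = r_d, _["rho"] = rho_d, _["eta"] = eta_d,
    _["sigma_u2"] = su_d, _["sigma_xi2"] = sxi_d, _["sigma_eps2"] = seps_d);
  if (p.variant == 3) { draws["delta_s"] = ds_d; draws["delta_l"] = dl_d; }
  return List::create(_["draws"] = draws, _["final_state"] = state_to_list(s));
}
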