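// Closed-form two-compartment kinetics and the FOCE-I estimation core.
//
// Conventions shared with the R side:
//   - log-scale individual parameters logp = (logCL, logVc, logQ, logVp),
//     logp = D * theta + eta, with D the per-subject 4 x 11 covariate
//     design matrix and eta the subject's random effects.
//   - proportional residual error: DV ~ N(f, sigma^2 f^2).
//   - OFV = -2 log(marginal likelihood), constants (2*pi) included.

// keep solver retries quiet: failed factorizations are handled explicitly
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

struct TwoCmt {
  double Vc, k10, alpha, beta, A, B;
  bool onecmt;

  void init(double CL, double Vc_, double Q, double Vp) {
    Vc = Vc_;
    k10 = CL / Vc;
    if (Q <= 0.0 || Vp <= 0.0) {
      onecmt = true;
      alpha = k10; beta = 0.0; A = 1.0; B = 0.0;
      return;
    }
    onecmt = false;
    double k12 = Q / Vc, k21 = Q / Vp;
    double s = k10 + k12 + k21, p = k10 * k21;
    double disc = s * s - 4.0 * p;
    disc = disc > 0.0 ? std::sqrt(disc) : 0.0;
    alpha = 0.5 * (s + disc);
    beta  = 0.5 * (s - disc);
    if (alpha - beta < 1e-12 * alpha) beta = alpha * (1.0 - 1e-9);
    A = (alpha - k21) / (alpha - beta);
    B = (k21 - beta) / (alpha - beta);
  }

  // concentration from a single dose, u = time since dose start (days)
  double conc1(double u, double amt, double dur) const {
    if (u <= 0.0 || amt <= 0.0) return 0.0;
    if (onecmt) {
      if (dur <= 0.0) return amt / Vc * std::exp(-k10 * u);
      double r0 = amt / dur;
      if (u <= dur) return r0 / (Vc * k10) * (1.0 - std::exp(-k10 * u));
      return r0 / (Vc * k10) * (1.0 - std::exp(-k10 * dur)) *
             std::exp(-k10 * (u - dur));
    }
    if (dur <= 0.0) {
      return amt / Vc * (A * std::exp(-alpha * u) + B * std::exp(-beta * u));
    }
    double r0 = amt / dur;
    if (u <= dur) {
      return r0 / Vc * (A / alpha * (1.0 - std::exp(-alpha * u)) +
                        B / beta  * (1.0 - std::exp(-beta  * u)));
    }
    return r0 / Vc *
           (A / alpha * (1.0 - std::exp(-alpha * dur)) * std::exp(-alpha * (u - dur)) +
            B / beta  * (1.0 - std::exp(-beta  * dur)) * std::exp(-beta  * (u - dur)));
  }
};


// fast evaluation for ascending times: each exponential term is carried
// as a running sum decayed between consecutive observation times, so the
// per-profile exp() count is O(n_obs + n_dose) instead of
// O(n_obs * n_dose) and no e^{+lambda*t} overflow can occur
static void profile_sorted(const TwoCmt& m,
                           const arma::vec& dt, const arma::vec& da,
                           const arma::vec& du, const arma::vec& t,
                           arma::vec& out) {
  const int nl = m.onecmt ? 1 : 2;
  double lam[2] = {m.alpha, m.beta};
  double co[2] = {m.A, m.B};
  double S[2] = {0.0, 0.0};
  double tprev = 0.0;
  arma::uword dnext = 0;
  std::vector<arma::uword> pend;   // doses begun, infusion still running
  for (arma::uword i = 0; i < t.n_elem; ++i) {
    double ti = t(i);
    for (int l = 0; l < nl; ++l)
      S[l] *= std::exp(-lam[l] * (ti - tprev));
    // doses starting strictly before ti join; completed infusions fold
    // into the running sums
    while (dnext < dt.n_elem && dt(dnext) < ti) pend.push_back(dnext++);
    double cur = 0.0;
    for (size_t p = 0; p < pend.size(); ) {
      arma::uword d = pend[p];
      double tend = dt(d) + du(d);
      if (du(d) <= 0.0 || tend < ti) {
        // fold post-infusion (or bolus) contribution, valued at ti
        for (int l = 0; l < nl; ++l) {
          double P;
          if (du(d) <= 0.0) {
            P = da(d) / m.Vc * co[l] * std::exp(-lam[l] * (ti - dt(d)));
          } else {
            double r0 = da(d) / du(d);
            P = r0 / m.Vc * co[l] / lam[l] *
                (1.0 - std::exp(-lam[l] * du(d))) *
                std::exp(-lam[l] * (ti - tend));
          }
          S[l] += P;
        }
        pend.erase(pend.begin() + p);
      } else {
        // infusion running at ti (u <= dur)
        double r0 = da(d) / du(d), u = ti - dt(d);
        for (int l = 0; l < nl; ++l)
          cur += r0 / m.Vc * co[l] / lam[l] * (1.0 - std::exp(-lam[l] * u));
        ++p;
      }
    }
    out(i) = S[0] + S[1] + cur;
    tprev = ti;
  }
}

static arma::vec profile(double CL, double Vc, double Q, double Vp,
                         const arma::vec& dt, const arma::vec& da,
                         const arma::vec& du, const arma::vec& t) {
  TwoCmt m; m.init(CL, Vc, Q, Vp);
  arma::vec out(t.n_elem, arma::fill::zeros);
  if (t.is_sorted() && dt.is_sorted() && t.n_elem > 2) {
    profile_sorted(m, dt, da, du, t, out);
    return out;
  }
  for (arma::uword i = 0; i < t.n_elem; ++i) {
    double c = 0.0;
    for (arma::uword d = 0; d < dt.n_elem; ++d)
      c += m.conc1(t(i) - dt(d), da(d), du(d));
    out(i) = c;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
arma::vec cpp_conc_profile(double CL, double Vc, double Q, double Vp,
                           const arma::vec& dose_time, const arma::vec& dose_amt,
                           const arma::vec& dose_dur, const arma::vec& t) {
  return profile(CL, Vc, Q, Vp, dose_time, dose_amt, dose_dur, t);
}

// ------------------------------------------------------------------
// estimation machinery

struct Sub {
  arma::vec t, y, dt, da, du;
  arma::mat D;   // 4 x 11
};

static Sub get_sub(const List& s) {
  Sub out;
  out.t  = as<arma::vec>(s["t"]);
  out.y  = as<arma::vec>(s["y"]);
  out.dt = as<arma::vec>(s["dt"]);
  out.da = as<arma::vec>(s["da"]);
  out.du = as<arma::vec>(s["du"]);
  out.D  = as<arma::mat>(s["D"]);
  return out;
}

static const double FMIN = 1e-12;

// f(logp) with clamping away from zero (proportional error degenerates at 0)
static arma::vec fpred(const Sub& s, const arma::vec& logp) {
  arma::vec lp = arma::clamp(logp, -30.0, 30.0);
  arma::vec f = profile(std::exp(lp(0)), std::exp(lp(1)), std::exp(lp(2)),
                        std::exp(lp(3)), s.dt, s.da, s.du, s.t);
  return arma::clamp(f, FMIN, arma::datum::inf);
}

// f plus Jacobian wrt logp (== Jacobian wrt eta), forward differences
static void fpred_jac(const Sub& s, const arma::vec& logp,
                      arma::vec& f, arma::mat& J) {
  const double h = 1e-5;
  f = fpred(s, logp);
  J.set_size(f.n_elem, 4);
  for (int k = 0; k < 4; ++k) {
    arma::vec lp = logp; lp(k) += h;
    J.col(k) = (fpred(s, lp) - f) / h;
  }
}

// -2 log joint (up to eta-free constants): the MAP inner objective
static double inner_obj(const Sub& s, const arma::vec& theta,
                        const arma::mat& Oinv, const arma::uvec& act,
                        double sig2, const arma::vec& eta) {
  arma::vec logp = s.D * theta + eta;
  arma::vec f = fpred(s, logp);
  double g = 0.0;
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    double r = s.y(j) - f(j);
    double v = sig2 * f(j) * f(j);
    g += r * r / v + std::log(v);
  }
  if (act.n_elem > 0) {
    arma::vec ea = eta(act);
    g += arma::as_scalar(ea.t() * Oinv * ea);
  }
  return g;
}

// damped Gauss-Newton for the conditional mode; returns convergence flag.
// Etas are kept within +/- 7.5 prior SDs: beyond that the random-effect
// density is negligible and extreme values only create numerically
// degenerate kinetics.
static bool map_eta(const Sub& s, const arma::vec& theta,
                    const arma::mat& Oinv, const arma::uvec& act,
                    double sig2, const arma::vec& bound, arma::vec& eta) {
  if (s.y.n_elem == 0 || act.n_elem == 0) { eta.zeros(); return true; }
  double lambda = 1e-3;
  double g = inner_obj(s, theta, Oinv, act, sig2, eta);
  arma::vec f; arma::mat J;
  for (int it = 0; it < 200; ++it) {
    arma::vec logp = s.D * theta + eta;
    fpred_jac(s, logp, f, J);
    arma::mat Ja = J.cols(act);
    // analytic gradient in f-space: d/df [(y-f)^2/(s2 f^2) + log(s2 f^2)]
    arma::vec dldf(f.n_elem), w(f.n_elem);
    for (arma::uword j = 0; j < f.n_elem; ++j) {
      double fj = f(j), yj = s.y(j);
      dldf(j) = -2.0 * yj * (yj - fj) / (sig2 * fj * fj * fj) + 2.0 / fj;
      w(j) = 2.0 / (sig2 * fj * fj);
    }
    arma::vec ea = eta(act);
    arma::vec grad = Ja.t() * dldf + 2.0 * Oinv * ea;
    if (arma::norm(grad, "inf") < 1e-7 * (1.0 + std::fabs(g))) return true;
    arma::mat H = Ja.t() * (Ja.each_col() % w) + 2.0 * Oinv;
    bool stepped = false;
    for (int tries = 0; tries < 25; ++tries) {
      arma::mat Hd = H;
      Hd.diag() += lambda * (arma::abs(H.diag()) + 1e-8);
      arma::vec d;
      bool ok = arma::solve(d, Hd, -grad,
                            arma::solve_opts::likely_sympd +
                            arma::solve_opts::no_approx);
      if (!ok || !d.is_finite()) {
        lambda *= 10.0; continue;
      }
      arma::vec etan = eta;
      etan(act) = ea + d;
      etan = arma::min(arma::max(etan, -bound), bound);
      double gn = inner_obj(s, theta, Oinv, act, sig2, etan);
      if (std::isfinite(gn) && gn <= g) {
        double dn = arma::norm(d, 2);
        eta = etan;
        g = gn;
        lambda = std::max(lambda / 3.0, 1e-10);
        stepped = true;
        if (dn < 1e-9) return true;
        break;
      }
      lambda *= 10.0;
    }
    if (!stepped) {
      // damped-Newton direction failed: try plain steepest descent with
      // backtracking before giving up (handles cliff-like regions far
      // from the mode)
      double step = 1.0 / (1.0 + arma::norm(grad, 2));
      for (int tries = 0; tries < 30; ++tries) {
        arma::vec etan = eta;
        etan(act) = ea - step * grad;
        etan = arma::min(arma::max(etan, -bound), bound);
        double gn = inner_obj(s, theta, Oinv, act, sig2, etan);
        if (std::isfinite(gn) && gn < g) {
          eta = etan; g = gn; stepped = true; break;
        }
        step *= 0.5;
      }
      if (!stepped) return false;
    }
  }
  return false;
}

// Approximate -2 log marginal likelihood contribution of one subject
// with eta held at the conditional mode. method = 0: FOCE-I (linearize f
// around eta-hat, residual variance at the individual prediction);
// method = 1: Laplace with interaction (exact joint at the mode plus
// Gauss-Newton log-curvature).
static double ofv_sub(const Sub& s, const arma::vec& theta,
                      const arma::mat& Omega, const arma::uvec& act,
                      double sig2, const arma::vec& eta, int method) {
  arma::uword n = s.y.n_elem;
  if (n == 0) return 0.0;
  arma::vec logp = s.D * theta + eta;
  arma::vec f; arma::mat J;
  fpred_jac(s, logp, f, J);
  if (method == 1 && act.n_elem > 0) {
    arma::mat Oa = Omega(act, act);
    arma::mat Oinv;
    if (!arma::inv_sympd(Oinv, Oa)) return arma::datum::inf;
    arma::mat Ja = J.cols(act);
    double val = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      double r = s.y(j) - f(j);
      double v = sig2 * f(j) * f(j);
      val += r * r / v + std::log(v) + LOG2PI;
    }
    arma::vec ea = eta(act);
    val += arma::as_scalar(ea.t() * Oinv * ea);
    double ld_O, sign;
    arma::log_det(ld_O, sign, Oa);
    arma::vec w(n);
    for (arma::uword j = 0; j < n; ++j) w(j) = 1.0 / (sig2 * f(j) * f(j));
    arma::mat Hh = Ja.t() * (Ja.each_col() % w) + Oinv;
    double ld_H;
    if (!arma::log_det_sympd(ld_H, Hh)) return arma::datum::inf;
    return val + ld_O + ld_H;
  }
  arma::mat C;
  arma::vec r = s.y - f;
  if (act.n_elem > 0) {
    arma::mat Ja = J.cols(act);
    arma::mat Oa = Omega(act, act);
    C = Ja * Oa * Ja.t();
    r += Ja * eta(act);
  } else {
    C.zeros(n, n);
  }
  C.diag() += sig2 * (f % f);
  C = 0.5 * (C + C.t());
  if (!C.is_finite()) return arma::datum::inf;
  arma::mat L;
  bool ok = arma::chol(L, C, "lower");
  for (double jit = 1e-10; !ok && jit <= 1e-3; jit *= 100.0) {
    C.diag() += jit * arma::mean(C.diag());
    ok = arma::chol(L, C, "lower");
  }
  if (!ok) return arma::datum::inf;
  arma::vec z;
  if (!arma::solve(z, arma::trimatl(L), r, arma::solve_opts::no_approx))
    return arma::datum::inf;
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  return n * LOG2PI + logdet + arma::dot(z, z);
}


// Adaptive Gauss-Hermite (3 nodes per active dimension) around the
// conditional mode, curvature from the Gauss-Newton Hessian of the
// joint. Falls back to the linearized value when the curvature is not
// positive definite.
static double ofv_sub_agq(const Sub& s, const arma::vec& theta,
                          const arma::mat& Omega, const arma::uvec& act,
                          const arma::mat& Oinv, double sig2,
                          const arma::vec& eta) {
  arma::uword n = s.y.n_elem, d = act.n_elem;
  if (n == 0) return 0.0;
  if (d == 0) return ofv_sub(s, theta, Omega, act, sig2, eta, 0);
  arma::vec logp = s.D * theta + eta;
  arma::vec f; arma::mat J;
  fpred_jac(s, logp, f, J);
  arma::mat Ja = J.cols(act);
  arma::vec w(n);
  for (arma::uword j = 0; j < n; ++j) w(j) = 2.0 / (sig2 * f(j) * f(j));
  arma::mat Hess = Ja.t() * (Ja.each_col() % w) + 2.0 * Oinv;
  arma::mat Sig = 2.0 * arma::inv_sympd(Hess);
  arma::mat L;
  if (!arma::chol(L, Sig, "lower"))
    return ofv_sub(s, theta, Omega, act, sig2, eta, 0);
  double g0 = inner_obj(s, theta, Oinv, act, sig2, eta);
  // 3-node Gauss-Hermite (weight e^{-z^2}): nodes 0, +/- sqrt(3/2)
  const double nodes[3] = {-1.2247448713915890, 0.0, 1.2247448713915890};
  const double wts[3] = {0.2954089751509194, 1.1816359006036774,
                         0.2954089751509194};
  int npts = 1;
  for (arma::uword k = 0; k < d; ++k) npts *= 3;
  double S = 0.0;
  arma::vec z(d), etak;
  for (int idx = 0; idx < npts; ++idx) {
    int rem = idx;
    double W = 1.0, z2 = 0.0;
    for (arma::uword k = 0; k < d; ++k) {
      int c = rem % 3; rem /= 3;
      z(k) = nodes[c];
      W *= wts[c];
      z2 += z(k) * z(k);
    }
    double gk;
    if (z2 == 0.0) {
      gk = g0;
    } else {
      etak = eta;
      etak(act) = eta(act) + std::sqrt(2.0) * (L * z);
      gk = inner_obj(s, theta, Oinv, act, sig2, etak);
    }
    if (std::isfinite(gk)) S += W * std::exp(z2 - 0.5 * (gk - g0));
  }
  if (!(S > 0.0)) return ofv_sub(s, theta, Omega, act, sig2, eta, 0);
  double ld_O, sgn;
  arma::log_det(ld_O, sgn, arma::mat(Omega(act, act)));
  double J0 = g0 + n * LOG2PI + d * LOG2PI + ld_O;
  double logdetL = arma::sum(arma::log(L.diag()));
  return J0 - d * std::log(2.0) - 2.0 * logdetL - 2.0 * std::log(S);
}

static arma::uvec active_set(const arma::mat& Omega) {
  std::vector<arma::uword> idx;
  for (arma::uword k = 0; k < 4; ++k)
    if (Omega(k, k) > 0.0) idx.push_back(k);
  return arma::uvec(idx);
}

//' @noRd
// [[Rcpp::export]]
List cpp_foce(const List& subjects, const arma::vec& theta,
              const arma::mat& Omega, double sigma,
              const arma::mat& etas0, bool reopt, int method = 0) {
  int n = subjects.size();
  double sig2 = sigma * sigma;
  arma::uvec act = active_set(Omega);
  arma::mat Oinv;
  if (act.n_elem > 0) {
    if (!arma::inv_sympd(Oinv, arma::mat(Omega(act, act))))
      return List::create(_["ofv"] = arma::datum::inf,
                          _["etas"] = etas0, _["n_nonconv"] = n);
  }
  arma::vec bound = 7.5 * arma::sqrt(arma::abs(Omega.diag())) + 1e-12;
  arma::mat etas = etas0;
  arma::vec ofv_i(n);
  int nonconv = 0;
  for (int i = 0; i < n; ++i) {
    Sub s = get_sub(subjects[i]);
    arma::vec eta = etas.row(i).t();
    if (reopt) {
      bool ok = map_eta(s, theta, Oinv, act, sig2, bound, eta);
      double g1 = inner_obj(s, theta, Oinv, act, sig2, eta);
      arma::vec zero(4, arma::fill::zeros);
      double gz = inner_obj(s, theta, Oinv, act, sig2, zero);
      if (!ok || !std::isfinite(g1) || g1 > gz) {
        // the warm start led nowhere good: re-solve from the prior mode
        // and keep the better candidate
        arma::vec eta0 = zero;
        bool ok0 = map_eta(s, theta, Oinv, act, sig2, bound, eta0);
        double g0 = inner_obj(s, theta, Oinv, act, sig2, eta0);
        if (!std::isfinite(g1) || g0 < g1) eta = eta0;
        if (!ok0 && !ok) ++nonconv;
      }
      etas.row(i) = eta.t();
    }
    ofv_i(i) = method == 2 ?
      ofv_sub_agq(s, theta, Omega, act, Oinv, sig2, eta) :
      ofv_sub(s, theta, Omega, act, sig2, eta, method);
  }
  return List::create(_["ofv"] = arma::accu(ofv_i), _["ofv_i"] = ofv_i,
                      _["etas"] = etas, _["n_nonconv"] = nonconv);
}

//' @noRd
// [[Rcpp::export]]
List cpp_map_eta(const List& subject, const arma::vec& theta,
                 const arma::mat& Omega, double sigma, const arma::vec& eta0) {
  Sub s = get_sub(subject);
  double sig2 = sigma * sigma;
  arma::uvec act = active_set(Omega);
  arma::mat Oinv;
  if (act.n_elem > 0 && !arma::inv_sympd(Oinv, arma::mat(Omega(act, act))))
    stop("Omega is singular on its active block");
  arma::vec bound = 7.5 * arma::sqrt(arma::abs(Omega.diag())) + 1e-12;
  arma::vec eta = eta0;
  bool conv = map_eta(s, theta, Oinv, act, sig2, bound, eta);
  double obj = inner_obj(s, theta, act.n_elem ? Oinv : arma::mat(), act, sig2, eta);
  return List::create(_["eta"] = eta, _["objective"] = obj,
                      _["converged"] = conv);
}

//' @noRd
// [[Rcpp::export]]
List cpp_ipred(const List& subjects, const arma::vec& theta, const arma::mat& etas) {
  int n = subjects.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    Sub s = get_sub(subjects[i]);
    arma::vec logp = s.D * theta + etas.row(i).t();
    out[i] = fpred(s, logp);
  }
  return out;
}
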