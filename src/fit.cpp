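#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Maximum-likelihood machinery for the 2IFC performance function
//   psi(x) = gamma + (1 - gamma - lambda) / (1 + exp(-beta * (x - alpha)))
// with x in intensity units (100 - dilution), gamma/lambda fixed and
// (alpha, beta) free.  Everything here is driven by R's RNG (RNGScope),
// so set.seed() on the R side makes simulation and bootstrap runs
// reproducible.

namespace {

const double EPS_P = 1e-10;       // psi clamp inside logs
const double BOUND_TOL = 1e-3;    // "estimate sits at a box bound" tolerance

struct Box {
  double alo, ahi;  // alpha bounds, intensity units
  double blo, bhi;  // beta bounds, per percent intensity
};

struct Dataset {
  std::vector<double> x;  // intensity
  std::vector<double> n;  // trials
  std::vector<double> k;  // correct
};

inline double clamp_p(double p) {
  if (p < EPS_P) return EPS_P;
  if (p > 1.0 - EPS_P) return 1.0 - EPS_P;
  return p;
}

double nll_core(double alpha, double beta, double gamma, double lambda,
                const Dataset& d) {
  double s = 0.0;
  const double span = 1.0 - gamma - lambda;
  for (size_t i = 0; i < d.x.size(); ++i) {
    if (d.n[i] <= 0.0) continue;
    double F = 1.0 / (1.0 + std::exp(-beta * (d.x[i] - alpha)));
    double psi = clamp_p(gamma + span * F);
    s -= d.k[i] * std::log(psi) + (d.n[i] - d.k[i]) * std::log1p(-psi);
  }
  return s;
}

// Objective over (alpha, log beta): NLL at the box-projected point plus a
// soft quadratic penalty for leaving the box, so Nelder-Mead is pushed back
// instead of wandering on a plateau.
double objective(double a, double lb, double gamma, double lambda,
                 const Box& box, const Dataset& d) {
  double pen = 0.0;
  double ac = a;
  double b = std::exp(lb);
  if (ac < box.alo) { pen += (box.alo - ac) * (box.alo - ac); ac = box.alo; }
  if (ac > box.ahi) { pen += (ac - box.ahi) * (ac - box.ahi); ac = box.ahi; }
  if (b < box.blo) { double t = std::log(box.blo / b); pen += t * t; b = box.blo; }
  if (b > box.bhi) { double t = std::log(b / box.bhi); pen += t * t; b = box.bhi; }
  return nll_core(ac, b, gamma, lambda, d) + 100.0 * pen;
}

struct NMResult {
  double a, lb, f;
  bool converged;
};

// Compact Nelder-Mead on (alpha, log beta).
NMResult nelder_mead(double a0, double lb0, double gamma, double lambda,
                     const Box& box, const Dataset& d,
                     int maxit = 500, double ftol = 1e-10) {
  double va[3] = { a0, a0 + 2.0, a0 };
  double vl[3] = { lb0, lb0, lb0 + 0.4 };
  double vf[3];
  for (int i = 0; i < 3; ++i)
    vf[i] = objective(va[i], vl[i], gamma, lambda, box, d);

  int it = 0;
  for (; it < maxit; ++it) {
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (vf[i] < vf[lo]) lo = i;
      if (vf[i] >= vf[hi]) hi = i;
    }
    if (lo == hi) break;  // all equal
    int mid = 3 - lo - hi;

    double fspread = std::fabs(vf[hi] - vf[lo]);
    double xspread = std::fabs(va[hi] - va[lo]) + std::fabs(va[mid] - va[lo]) +
                     std::fabs(vl[hi] - vl[lo]) + std::fabs(vl[mid] - vl[lo]);
    if (fspread < ftol * (std::fabs(vf[lo]) + ftol) && xspread < 1e-7) break;

    double ca = 0.5 * (va[lo] + va[mid]);
    double cl = 0.5 * (vl[lo] + vl[mid]);

    double ra = ca + (ca - va[hi]);
    double rl = cl + (cl - vl[hi]);
    double rf = objective(ra, rl, gamma, lambda, box, d);

    if (rf < vf[lo]) {
      double ea = ca + 2.0 * (ca - va[hi]);
      double el = cl + 2.0 * (cl - vl[hi]);
      double ef = objective(ea, el, gamma, lambda, box, d);
      if (ef < rf) { va[hi] = ea; vl[hi] = el; vf[hi] = ef; }
      else         { va[hi] = ra; vl[hi] = rl; vf[hi] = rf; }
    } else if (rf < vf[mid]) {
      va[hi] = ra; vl[hi] = rl; vf[hi] = rf;
    } else {
      double cca, ccl;
      if (rf < vf[hi]) { cca = ca + 0.5 * (ra - ca); ccl = cl + 0.5 * (rl - cl); }
      else             { cca = ca + 0.5 * (va[hi] - ca); ccl = cl + 0.5 * (vl[hi] - cl); }
      double ccf = objective(cca, ccl, gamma, lambda, box, d);
      if (ccf < std::min(rf, vf[hi])) {
        va[hi] = cca; vl[hi] = ccl; vf[hi] = ccf;
      } else {
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          va[i] = va[lo] + 0.5 * (va[i] - va[lo]);
          vl[i] = vl[lo] + 0.5 * (vl[i] - vl[lo]);
          vf[i] = objective(va[i], vl[i], gamma, lambda, box, d);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (vf[i] < vf[lo]) lo = i;
  NMResult r;
  r.a = va[lo]; r.lb = vl[lo]; r.f = vf[lo];
  r.converged = (it < maxit);
  return r;
}

// Alpha start: intensity where the observed proportion correct crosses the
// criterion, by linear interpolation over levels sorted by intensity;
// falls back to the level whose proportion is closest to the criterion.
double crossing_start(const Dataset& d, double criterion) {
  std::vector<size_t> idx;
  for (size_t i = 0; i < d.x.size(); ++i)
    if (d.n[i] > 0.0) idx.push_back(i);
  if (idx.empty()) return 0.0;
  std::sort(idx.begin(), idx.end(),
            [&](size_t a, size_t b) { return d.x[a] < d.x[b]; });

  for (size_t j = 0; j + 1 < idx.size(); ++j) {
    double p0 = d.k[idx[j]] / d.n[idx[j]];
    double p1 = d.k[idx[j + 1]] / d.n[idx[j + 1]];
    if ((p0 - criterion) * (p1 - criterion) <= 0.0 && p0 != p1) {
      double w = (criterion - p0) / (p1 - p0);
      return d.x[idx[j]] + w * (d.x[idx[j + 1]] - d.x[idx[j]]);
    }
  }
  size_t best = idx[0];
  double bd = std::fabs(d.k[best] / d.n[best] - criterion);
  for (size_t j = 1; j < idx.size(); ++j) {
    double dd = std::fabs(d.k[idx[j]] / d.n[idx[j]] - criterion);
    if (dd < bd) { bd = dd; best = idx[j]; }
  }
  return d.x[best];
}

struct FitAB {
  double alpha, beta, nll;
  bool converged, at_bound;
};

// Multi-start ML fit.  Starts: alpha at the observed criterion crossing,
// beta log-spaced over the plausible slope range; `jitter` > 0 perturbs the
// starts (used on bootstrap retries) and draws from R's RNG.
FitAB fit_ab(const Dataset& d, double gamma, double lambda, const Box& box,
             int n_starts, double criterion, double jitter) {
  double a0 = crossing_start(d, criterion);
  double b_lo = std::max(box.blo * 10.0, 0.02);
  double b_hi = std::min(box.bhi * 0.3, 3.0);

  double best_f = R_PosInf;
  double best_a = a0, best_lb = std::log(0.3);
  bool best_conv = false;

  for (int s = 0; s < n_starts; ++s) {
    double frac = (n_starts == 1) ? 0.5 : (double)s / (double)(n_starts - 1);
    double lb0 = std::log(b_lo) + frac * (std::log(b_hi) - std::log(b_lo));
    double as = a0;
    if (jitter > 0.0) {
      as += R::runif(-jitter, jitter);
      lb0 += R::runif(-1.0, 1.0);
    }
    NMResult r = nelder_mead(as, lb0, gamma, lambda, box, d);
    if (r.f < best_f) {
      best_f = r.f; best_a = r.a; best_lb = r.lb; best_conv = r.converged;
    }
  }

  FitAB out;
  out.alpha = std::min(std::max(best_a, box.alo), box.ahi);
  out.beta = std::min(std::max(std::exp(best_lb), box.blo), box.bhi);
  out.nll = nll_core(out.alpha, out.beta, gamma, lambda, d);
  out.converged = best_conv;
  out.at_bound =
    (out.alpha <= box.alo + BOUND_TOL) || (out.alpha >= box.ahi - BOUND_TOL) ||
    (out.beta <= box.blo * (1.0 + BOUND_TOL)) ||
    (out.beta >= box.bhi * (1.0 - BOUND_TOL));
  return out;
}

Dataset as_dataset(const NumericVector& x, const NumericVector& n,
                   const NumericVector& k) {
  Dataset d;
  d.x.assign(x.begin(), x.end());
  d.n.assign(n.begin(), n.end());
  d.k.assign(k.begin(), k.end());
  return d;
}

Dataset pool(const Dataset& a, const Dataset& b) {
  Dataset d = a;
  d.x.insert(d.x.end(), b.x.begin(), b.x.end());
  d.n.insert(d.n.end(), b.n.begin(), b.n.end());
  d.k.insert(d.k.end(), b.k.begin(), b.k.end());
  return d;
}

double max_prop(const Dataset& d) {
  double m = R_NegInf;
  for (size_t i = 0; i < d.x.size(); ++i)
    if (d.n[i] > 0.0) m = std::max(m, d.k[i] / d.n[i]);
  return m;
}

bool fit_ok(const FitAB& f, const Dataset& d, double criterion) {
  return f.converged && !f.at_bound && max_prop(d) >= criterion;
}

}  // namespace

// [[Rcpp::export(name = ".nll_cpp")]]
double nll_cpp(NumericVector x, NumericVector n, NumericVector k,
               double alpha, double beta, double gamma, double lambda) {
  Dataset d = as_dataset(x, n, k);
  return nll_core(alpha, beta, gamma, lambda, d);
}

// [[Rcpp::export(name = ".fit_ab_cpp")]]
List fit_ab_cpp(NumericVector x, NumericVector n, NumericVector k,
                double gamma, double lambda,
                double alpha_lo, double alpha_hi,
                double beta_lo, double beta_hi,
                int n_starts, double criterion, double jitter) {
  Dataset d = as_dataset(x, n, k);
  Box box = { alpha_lo, alpha_hi, beta_lo, beta_hi };
  FitAB f = fit_ab(d, gamma, lambda, box, n_starts, criterion, jitter);
  return List::create(
    _["alpha"] = f.alpha, _["beta"] = f.beta, _["nll"] = f.nll,
    _["converged"] = f.converged, _["at_bound"] = f.at_bound,
    _["max_prop"] = max_prop(d));
}

// Parametric bootstrap for the 1PF-vs-2PF likelihood-ratio test.  Each
// replicate draws binomial counts for both conditions from the null (1PF)
// performance function at the observed levels and trial counts, refits 2PF
// (each condition) and 1PF (pooled), and records lr = exp(ll1 - ll2).
// A replicate whose refits fail (optimizer at a bound, no level reaching
// the criterion, or ll1 > ll2 beyond tolerance) is retried with jittered
// starts up to `max_retries` times, then redrawn.
// [[Rcpp::export(name = ".lr_boot_cpp")]]
List lr_boot_cpp(NumericVector xa, NumericVector na,
                 NumericVector xb, NumericVector nb,
                 double alpha0, double beta0,
                 double gamma, double lambda,
                 double lr_obs, int n_sims, int n_starts,
                 double alpha_lo, double alpha_hi,
                 double beta_lo, double beta_hi,
                 double criterion, int max_retries) {
  Box box = { alpha_lo, alpha_hi, beta_lo, beta_hi };
  Dataset da, db;
  da.x.assign(xa.begin(), xa.end());
  da.n.assign(na.begin(), na.end());
  da.k.assign(na.size(), 0.0);
  db.x.assign(xb.begin(), xb.end());
  db.n.assign(nb.begin(), nb.end());
  db.k.assign(nb.size(), 0.0);

  const double span = 1.0 - gamma - lambda;
  std::vector<double> pa(da.x.size()), pb(db.x.size());
  for (size_t i = 0; i < da.x.size(); ++i)
    pa[i] = gamma + span / (1.0 + std::exp(-beta0 * (da.x[i] - alpha0)));
  for (size_t i = 0; i < db.x.size(); ++i)
    pb[i] = gamma + span / (1.0 + std::exp(-beta0 * (db.x[i] - alpha0)));

  NumericVector lr_sims(n_sims);
  int n_smaller = 0, n_redraws = 0, n_retried = 0;
  const int redraw_cap = std::max(100, n_sims);

  for (int s = 0; s < n_sims; ++s) {
    bool done = false;
    while (!done) {
      for (size_t i = 0; i < da.x.size(); ++i)
        da.k[i] = R::rbinom(da.n[i], pa[i]);
      for (size_t i = 0; i < db.x.size(); ++i)
        db.k[i] = R::rbinom(db.n[i], pb[i]);
      Dataset dj = pool(da, db);

      for (int attempt = 0; attempt <= max_retries; ++attempt) {
        double jit = (attempt == 0) ? 0.0 : 6.0;
        if (attempt > 0) ++n_retried;
        FitAB f2a = fit_ab(da, gamma, lambda, box, n_starts, criterion, jit);
        FitAB f2b = fit_ab(db, gamma, lambda, box, n_starts, criterion, jit);
        FitAB f1 = fit_ab(dj, gamma, lambda, box, n_starts, criterion, jit);
        if (!(fit_ok(f2a, da, criterion) && fit_ok(f2b, db, criterion) &&
              f1.converged && !f1.at_bound))
          continue;
        double ll1 = -f1.nll;
        double ll2 = -(f2a.nll + f2b.nll);
        if (ll1 > ll2 + 1e-6) continue;  // 2PF optimum missed; retry
        double lr = std::exp(std::min(ll1 - ll2, 0.0));
        lr_sims[s] = lr;
        if (lr < lr_obs) ++n_smaller;
        done = true;
        break;
      }
      if (!done) {
        ++n_redraws;
        if (n_redraws > redraw_cap)
          stop("parametric bootstrap: too many simulated datasets could not be refit");
      }
    }
  }

  return List::create(
    _["n_smaller"] = n_smaller, _["lr_sims"] = lr_sims,
    _["n_redraws"] = n_redraws, _["n_retried"] = n_retried);
}
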