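#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One-generation recursions for the three symbiont/mitotype models.
// model codes: 1 = fixed benefit (par: B, mu, t)
//              2 = frequency-dependent benefit (par: b, c, mu, t)
//              3 = cytoplasmic incompatibility (par: h, mu, t)
// State order: p (resident mito + symbiont), q (resident, uninfected),
//              r (novel mito + symbiont),    s (novel, uninfected).
//
// Return codes: 0 ok, 1 degenerate denominator, 2 conservation failure.
static inline int step_once(const int model, const double* par,
                            const double* x, double* y) {
  const double p = x[0], q = x[1], r = x[2], s = x[3];
  double n0, n1, n2, n3, den;

  if (model == 1) {
    const double B = par[0], mu = par[1], t = par[2];
    const double w = 1.0 + B;
    n0 = p * (1.0 - mu) * w;
    n1 = p * w * mu + q;
    n2 = r * w * (1.0 - mu) * (1.0 + t);
    n3 = (r * w * mu + s) * (1.0 + t);
    den = p * w + q + (r * w + s) * (1.0 + t);
  } else if (model == 2) {
    const double b = par[0], c = par[1], mu = par[2], t = par[3];
    // benefit evaluated at current-generation overall symbiont frequency
    const double w = 1.0 + b * (1.0 - (p + r)) - c;
    n0 = p * (1.0 - mu) * w;
    n1 = p * w * mu + q;
    n2 = r * w * (1.0 - mu) * (1.0 + t);
    n3 = (r * w * mu + s) * (1.0 + t);
    den = p * w + q + (r * w + s) * (1.0 + t);
  } else {
    const double h = par[0], mu = par[1], t = par[2];
    // survival of offspring of uninfected mothers under random mating:
    // incompatible crosses (infected fathers, frequency p + r) survive at 1 - h
    const double compat = (p + r) * (1.0 - h) + q + s;
    n0 = p * (1.0 - mu);
    n1 = (p * mu + q) * compat;
    n2 = r * (1.0 - mu) * (1.0 + t);
    n3 = (r * mu + s) * (1.0 + t) * compat;
    den = n0 + n1 + n2 + n3;  // Phi, the total offspring output
  }

  if (!(den > 0.0)) return 1;
  y[0] = n0 / den; y[1] = n1 / den; y[2] = n2 / den; y[3] = n3 / den;

  double sum = 0.0;
  for (int i = 0; i < 4; ++i) {
    if (y[i] < 0.0 && y[i] > -1e-15) y[i] = 0.0;  // roundoff guard only
    sum += y[i];
  }
  const double dev = std::abs(sum - 1.0);
  if (dev > 1e-9) return 2;                 // a real formula bug, not roundoff
  if (dev > 1e-12) for (int i = 0; i < 4; ++i) y[i] /= sum;
  return 0;
}

// [[Rcpp::export]]
List cpp_step(NumericVector state, int model, NumericVector par) {
  double y[4];
  int code = step_once(model, par.begin(), state.begin(), y);
  return List::create(_["state"] = NumericVector(y, y + 4), _["code"] = code);
}

// Iterate the map until successive states differ by < tol in max-norm, the
// mutant lineage (r + s) drops below stop_mutant_below (early exit used by
// outcome classification), or max_gen generations elapse.
// [[Rcpp::export]]
List cpp_iterate(NumericVector state, int model, NumericVector par,
                 double tol, int max_gen,
                 double stop_mutant_below = 0.0, bool record = false) {
  double x[4] = {state[0], state[1], state[2], state[3]};
  double y[4];
  std::vector<double> traj;
  if (record) {
    traj.reserve(4096);
    for (int i = 0; i < 4; ++i) traj.push_back(x[i]);
  }

  bool converged = false, mutant_lost = false;
  int gen = 0, code = 0;
  for (gen = 0; gen < max_gen; ++gen) {
    code = step_once(model, par.begin(), x, y);
    if (code != 0) break;
    double diff = 0.0;
    for (int i = 0; i < 4; ++i) {
      double d = std::abs(y[i] - x[i]);
      if (d > diff) diff = d;
      x[i] = y[i];
    }
    if (record) for (int i = 0; i < 4; ++i) traj.push_back(x[i]);
    if (tol > 0.0 && diff < tol) { converged = true; ++gen; break; }
    if (stop_mutant_below > 0.0 && x[2] + x[3] < stop_mutant_below) {
      mutant_lost = true; ++gen; break;
    }
  }

  List out = List::create(
    _["state"] = NumericVector(x, x + 4),
    _["generations"] = gen,
    _["converged"] = converged,
    _["mutant_lost"] = mutant_lost,
    _["code"] = code);
  if (record) {
    NumericMatrix m(traj.size() / 4, 4);
    for (R_xlen_t i = 0; i < m.nrow(); ++i)
      for (int j = 0; j < 4; ++j) m(i, j) = traj[4 * i + j];
    out["trajectory"] = m;
  }
  return out;
}
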