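#include <Rcpp.h>
using namespace Rcpp;

// Log10 potency rho of the kinetic-proofreading model for one data point.
// Parameters on natural scale; returns NA_REAL when the ligand cannot reach
// the activation threshold (argument of the final log <= 0).
static inline double rho_point(double n, double kp, double lambda_hat,
                               double gamma_, double delta_hat,
                               double kd, double kon) {
  double koff = kon * kd;
  double lb = log10(1.0 + koff / kp);
  double b = pow(10.0, n * lb); // (1 + koff/kp)^N
  double denom = lambda_hat * b - 1.0 / gamma_;
  // reachable only when lambda*(1+koff/kp)^N < 1 <=> denom < 0
  if (denom >= 0.0) return NA_REAL;
  double arg = 1.0 - delta_hat * kd / denom;
  if (arg <= 0.0 || !R_finite(arg)) return NA_REAL;
  return log10(lambda_hat) + n * lb + log10(arg);
}

// Sum of squared log10-potency residuals across all experiments.
// theta layout (fitting scale): [N, log10(gamma), log10(delta_hat),
// log10(kp_1..I), log10(lambda_hat_1..I)]. expt is 0-based.
static double distance_theta(const double* theta, int I,
                             const NumericVector& kd,
                             const NumericVector& logp,
                             const IntegerVector& expt,
                             double kon) {
  double n = theta[0];
  double gamma_ = pow(10.0, theta[1]);
  double delta_hat = pow(10.0, theta[2]);
  double d = 0.0;
  for (int j = 0; j < kd.size(); j++) {
    int i = expt[j];
    double kp = pow(10.0, theta[3 + i]);
    double lh = pow(10.0, theta[3 + I + i]);
    double r = rho_point(n, kp, lh, gamma_, delta_hat, kd[j], kon);
    if (!R_finite(r)) return R_PosInf;
    double res = r - logp[j];
    d += res * res;
  }
  return d;
}

// [[Rcpp::export(name = ".kp_distance_cpp")]]
double kp_distance_cpp(NumericVector theta, int I, NumericVector kd,
                       NumericVector logp, IntegerVector expt, double kon) {
  return distance_theta(REAL(theta), I, kd, logp, expt, kon);
}

// One annealed Metropolis-Hastings chain. Uses R's RNG so results are
// reproducible under set.seed(). Perturbation: independent uniform shift of
// +/- step_frac * prior width per coordinate, reflected at the bounds.
// The annealing temperature xi drops to xis[k] when the accepted distance
// first reaches thresholds[k]; the chain stops when the distance falls below
// `termination` or after max_steps proposals.
// [[Rcpp::export(name = ".kp_chain_cpp")]]
List kp_chain_cpp(NumericVector theta0, NumericVector lower,
                  NumericVector upper, int I, NumericVector kd,
                  NumericVector logp, IntegerVector expt, double kon,
                  double xi0, NumericVector thresholds, NumericVector xis,
                  double termination, double max_steps, double step_frac,
                  bool switch_on_candidate) {
  int p = theta0.size();
  std::vector<double> cur(theta0.begin(), theta0.end());
  std::vector<double> cand(p);
  std::vector<double> halfw(p);
  for (int k = 0; k < p; k++)
    halfw[k] = step_frac * (upper[k] - lower[k]);

  double d_cur = distance_theta(cur.data(), I, kd, logp, expt, kon);
  double xi = xi0;
  int stage = 0;
  int nthr = thresholds.size();
  double steps = 0;
  double accepted = 0;
  bool converged = d_cur < termination;

  while (!converged && steps < max_steps) {
    steps += 1;
    for (int k = 0; k < p; k++) {
      double v = cur[k] + R::runif(-halfw[k], halfw[k]);
      // reflect at the violated bound (shift is < width, one pass suffices)
      if (v < lower[k]) v = 2.0 * lower[k] - v;
      if (v > upper[k]) v = 2.0 * upper[k] - v;
      cand[k] = v;
    }
    double d_cand = distance_theta(cand.data(), I, kd, logp, expt, kon);

    if (switch_on_candidate && R_finite(d_cand)) {
      while (stage < nthr && d_cand <= thresholds[stage]) {
        xi = xis[stage];
        stage++;
      }
    }

    bool accept;
    if (d_cand < d_cur) {
      accept = true;
    } else if (!R_finite(d_cand)) {
      accept = false;
    } else {
      accept = R::unif_rand() < exp(-(d_cand - d_cur) / xi);
    }
    if (accept) {
      std::copy(cand.begin(), cand.end(), cur.begin());
      d_cur = d_cand;
      accepted += 1;
      if (!switch_on_candidate) {
        while (stage < nthr && d_cur <= thresholds[stage]) {
          xi = xis[stage];
          stage++;
        }
      }
      if (d_cur < termination) converged = true;
    }
  }

  return List::create(_["theta"] = NumericVector(cur.begin(), cur.end()),
                      _["distance"] = d_cur, _["steps"] = steps,
                      _["accepted"] = accepted, _["converged"] = converged,
                      _["xi_final"] = xi);
}

// Exact stochastic simulation (Gillespie) of the proofreading chain:
//   L + R -> C0        (kon * L * R, per-molecule kon)
//   Ci -> Ci+1         (kp * Ci, i = 0..n-1)
//   Ci -> L + R        (koff * Ci, i = 0..n)
// Returns the count in the final step at t_end for each realisation.
// [[Rcpp::export(name = ".gillespie_cn_cpp")]]
NumericVector gillespie_cn_cpp(int n, double kp, double kon, double koff,
                               double l0, double r0, double t_end,
                               int n_realisations) {
  NumericVector out(n_realisations);
  std::vector<double> c(n + 1);
  for (int rep = 0; rep < n_realisations; rep++) {
    double L = l0, R = r0, ctot = 0.0;
    std::fill(c.begin(), c.end(), 0.0);
    double t = 0.0;
    for (;;) {
      double a_bind = kon * L * R;
      double a_step = (n > 0) ? kp * (ctot - c[n]) : 0.0;
      double a_off = koff * ctot;
      double a_tot = a_bind + a_step + a_off;
      if (a_tot <= 0.0) break;
      t += R::exp_rand() / a_tot;
      if (t > t_end) break;
      double u = R::unif_rand() * a_tot;
      if (u < a_bind) {
        L -= 1; R -= 1; c[0] += 1; ctot += 1;
      } else if (u < a_bind + a_step) {
        // pick which Ci advances, proportional to kp*c[i], i < n
        double v = (u - a_bind) / kp;
        int i = 0;
        double acc = c[0];
        while (i < n - 1 && v >= acc) { i++; acc += c[i]; }
        c[i] -= 1; c[i + 1] += 1;
      } else {
        // pick which Ci unbinds, proportional to c[i]
        double v = (u - a_bind - a_step) / koff;
        int i = 0;
        double acc = c[0];
        while (i < n && v >= acc) { i++; acc += c[i]; }
        c[i] -= 1; ctot -= 1; L += 1; R += 1;
      }
    }
    out[rep] = c[n];
  }
  return out;
}
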