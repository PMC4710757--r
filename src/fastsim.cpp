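// Piecewise-analytic simulation of the delayed-rectifier current
// formulations under step voltage-clamp protocols. This mirrors the R
// reference implementation in R/models.R; tests assert agreement between
// the two paths. Compiled because the optimizers evaluate the residual
// vector millions of times.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// x / (1 - exp(-x/s)), removable singularity at x = 0 (limit s)
inline double ratio_one_minus_exp(double x, double s) {
  if (std::fabs(x) < 1e-7) return s + x / 2.0;
  return x / (-std::expm1(-x / s));
}

// x / (exp(x/s) - 1), removable singularity at x = 0 (limit s)
inline double ratio_expm1(double x, double s) {
  if (std::fabs(x) < 1e-7) return s - x / 2.0;
  return x / std::expm1(x / s);
}

// scale * (V + a) / (1 - exp(-(V + b)/s)); removable only when a == b
inline double rate_alpha_form(double V, double scale, double a, double b,
                              double s) {
  if (std::fabs(a - b) < 1e-9) return scale * ratio_one_minus_exp(V + b, s);
  return scale * (V + a) / (-std::expm1(-(V + b) / s));
}

struct GateKin { double inf; double tau; };

// model ids: 1 = IKr, 2 = IKur, 3 = IKs; gate index g within model
inline GateKin kinetics(int model, int g, const double* p, double V) {
  GateKin k;
  if (model == 1) { // xr
    double a = rate_alpha_form(V, p[5], p[6], p[7], p[8]);
    double b = p[9] * ratio_expm1(V - p[10], p[11]);
    k.inf = 1.0 / (1.0 + std::exp(-(V + p[3]) / p[4]));
    k.tau = 1.0 / (a + b);
  } else if (model == 2 && g == 0) { // ua
    double a = p[5] / (std::exp(-(V + p[6]) / p[7]) +
                       std::exp(-(V - p[8]) / p[9]));
    double b = p[10] / (p[11] + std::exp((V + p[12]) / p[13]));
    k.inf = 1.0 / (1.0 + std::exp(-(V + p[14]) / p[15]));
    k.tau = 1.0 / ((a + b) * 3.0); // K_Q10 = 3 (fixed constant)
  } else if (model == 2) { // ui
    double a = p[16] / (p[17] + std::exp(-(V - p[18]) / p[19]));
    double b = p[20] * std::exp((V - p[21]) / p[22]);
    k.inf = 1.0 / (1.0 + std::exp((V - p[23]) / p[24]));
    k.tau = 1.0 / ((a + b) * 3.0);
  } else { // xs
    double a = rate_alpha_form(V, p[1], -p[2], -p[3], p[4]);
    double b = p[5] * ratio_expm1(V - p[6], p[7]);
    k.inf = std::pow(1.0 + std::exp(-(V - p[9]) / p[10]), -0.5);
    k.tau = p[8] / (a + b);
  }
  return k;
}

inline int n_gates(int model) { return model == 2 ? 2 : 1; }

inline double current_at(int model, const double* p, double V, double EK,
                         const double* x) {
  if (model == 1)
    return p[0] * x[0] * (V - EK) / (1.0 + std::exp((V + p[1]) / p[2]));
  if (model == 2)
    return (p[0] + p[1] / (1.0 + std::exp(-(V - p[2]) / p[3]))) *
           std::pow(x[0], p[4]) * x[1] * (V - EK);
  return p[0] * x[0] * x[0] * (V - EK); // IKs, exponent 2 fixed
}

// Simulate one sweep into out[0..n_samples-1]. Returns false if any gate
// time constant is non-finite or non-positive.
bool sim_sweep(int model, const double* p, double EK,
               const NumericVector& dur, const NumericVector& volt,
               double dt, int n_samples, double* out) {
  int ng = n_gates(model);
  double x0[2], xinf[2], xtau[2];
  for (int g = 0; g < ng; ++g) {
    GateKin k = kinetics(model, g, p, volt[0]);
    x0[g] = k.inf;
  }
  int nseg = dur.size();
  double start = 0.0;
  int idx = 0;
  for (int s = 0; s < nseg; ++s) {
    double V = volt[s];
    for (int g = 0; g < ng; ++g) {
      GateKin k = kinetics(model, g, p, V);
      if (!std::isfinite(k.tau) || k.tau <= 0.0 || !std::isfinite(k.inf))
        return false;
      xinf[g] = k.inf;
      xtau[g] = k.tau;
    }
    double end = start + dur[s];
    bool last = (s == nseg - 1);
    // Samples within a segment are uniformly spaced, so the decaying
    // exponential advances by a constant ratio per sample; the per-segment
    // factors of the current are likewise constant in t.
    double ratio[2], decay[2];
    bool primed = false;
    double fac = 0.0, gcond = 0.0;
    if (model == 1) {
      fac = p[0] * (V - EK) / (1.0 + std::exp((V + p[1]) / p[2]));
    } else if (model == 2) {
      gcond = (p[0] + p[1] / (1.0 + std::exp(-(V - p[2]) / p[3]))) * (V - EK);
    } else {
      fac = p[0] * (V - EK);
    }
    while (idx < n_samples) {
      double t = idx * dt;
      if (t > end || (!last && t >= end - 1e-9)) break;
      if (!primed) {
        for (int g = 0; g < ng; ++g) {
          ratio[g] = std::exp(-dt / xtau[g]);
          decay[g] = std::exp(-(t - start) / xtau[g]);
        }
        primed = true;
      }
      if (model == 2) {
        double ua = xinf[0] + (x0[0] - xinf[0]) * decay[0];
        double ui = xinf[1] + (x0[1] - xinf[1]) * decay[1];
        out[idx] = gcond * std::pow(ua, p[4]) * ui;
      } else {
        double x = xinf[0] + (x0[0] - xinf[0]) * decay[0];
        out[idx] = model == 1 ? fac * x : fac * x * x;
      }
      for (int g = 0; g < ng; ++g) decay[g] *= ratio[g];
      ++idx;
    }
    for (int g = 0; g < ng; ++g)
      x0[g] = xinf[g] + (x0[g] - xinf[g]) * std::exp(-dur[s] / xtau[g]);
    start = end;
  }
  return idx == n_samples;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_simulate(int model, NumericVector p, List seg_dur,
                           List seg_volt, double dt, double EK,
                           int n_samples) {
  int n_sweeps = seg_dur.size();
  NumericMatrix out(n_samples, n_sweeps);
  for (int j = 0; j < n_sweeps; ++j) {
    NumericVector dur = seg_dur[j], volt = seg_volt[j];
    if (!sim_sweep(model, REAL(p), EK, dur, volt, dt, n_samples,
                   &out(0, j))) {
      std::fill(out.begin(), out.end(), NA_REAL);
      out.attr("invalid") = true;
      return out;
    }
  }
  return out;
}

// Residuals I(p) - I_obs, concatenated column-wise (sweep-major). Returns a
// length-0 vector when the parameter vector is invalid (tau <= 0 or
// non-finite kinetics at a protocol voltage).
// [[Rcpp::export]]
NumericVector cpp_residuals(int model, NumericVector p, List seg_dur,
                            List seg_volt, double dt, double EK,
                            NumericMatrix obs) {
  int n_samples = obs.nrow(), n_sweeps = obs.ncol();
  NumericVector out(n_samples * n_sweeps);
  std::vector<double> buf(n_samples);
  for (int j = 0; j < n_sweeps; ++j) {
    NumericVector dur = seg_dur[j], volt = seg_volt[j];
    if (!sim_sweep(model, REAL(p), EK, dur, volt, dt, n_samples, buf.data()))
      return NumericVector(0);
    for (int i = 0; i < n_samples; ++i)
      out[j * n_samples + i] = buf[i] - obs(i, j);
  }
  return out;
}

// Sum of squared residuals; +Inf for invalid parameter vectors.
// [[Rcpp::export]]
double cpp_sse(int model, NumericVector p, List seg_dur, List seg_volt,
               double dt, double EK, NumericMatrix obs) {
  int n_samples = obs.nrow(), n_sweeps = obs.ncol();
  std::vector<double> buf(n_samples);
  double acc = 0.0;
  for (int j = 0; j < n_sweeps; ++j) {
    NumericVector dur = seg_dur[j], volt = seg_volt[j];
    if (!sim_sweep(model, REAL(p), EK, dur, volt, dt, n_samples, buf.data()))
      return R_PosInf;
    for (int i = 0; i < n_samples; ++i) {
      double r = buf[i] - obs(i, j);
      acc += r * r;
    }
  }
  if (!std::isfinite(acc)) return R_PosInf;
  return acc;
}
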