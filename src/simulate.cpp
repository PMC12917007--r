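// Trial-level simulator for the diffusion model for conflict tasks (DMC).
//
// A single diffusion process accumulates the superimposed drift of a
// constant target input (mu_t, optionally delayed by onset_delay) and a
// transient distractor input whose expected activation is a rescaled gamma
// density peaking at amp when t = (aa_shape - 1) * tau.  Euler-Maruyama
// integration with fixed step dt; two absorbing boundaries at +/- bound;
// starting point drawn from a symmetric beta on (-bound, bound); residual
// (non-decision) time is normal(res_mean, res_sd) truncated at zero.
//
// The RNG is self-contained (xoshiro-seeded mt19937_64 + Box-Muller) so a
// given integer seed reproduces byte-identical trials regardless of the
// caller's R RNG state; this is what makes common random numbers across
// optimizer cost evaluations cheap.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {

// Ziggurat tables for the standard normal (Doornik's ZIGNOR layout,
// 128 layers), built once at load time.
constexpr int kZigC = 128;
constexpr double kZigR = 3.442619855899;
constexpr double kZigV = 9.91256303526217e-3;

struct ZigTables {
  double x[kZigC + 1];
  double ratio[kZigC];
  ZigTables() {
    double f = std::exp(-0.5 * kZigR * kZigR);
    x[0] = kZigV / f;
    x[1] = kZigR;
    x[kZigC] = 0.0;
    for (int i = 2; i < kZigC; ++i) {
      x[i] = std::sqrt(-2.0 * std::log(kZigV / x[i - 1] + f));
      f = std::exp(-0.5 * x[i] * x[i]);
    }
    for (int i = 0; i < kZigC; ++i) ratio[i] = x[i + 1] / x[i];
  }
};
const ZigTables kZig;

struct Rng {
  std::mt19937_64 gen;

  explicit Rng(uint64_t seed) : gen(seed) {}

  double unif() {
    // 53-bit uniform in (0, 1); never exactly 0 so logs are safe
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double norm_tail(bool negative) {
    double x, y;
    do {
      x = std::log(unif()) / kZigR;
      y = std::log(unif());
    } while (-2.0 * y < x * x);
    return negative ? x - kZigR : kZigR - x;
  }

  double norm() {
    for (;;) {
      uint64_t bits = gen();
      int i = static_cast<int>(bits & 0x7F);
      double u = 2.0 * (((bits >> 11) + 0.5) * (1.0 / 9007199254740992.0)) -
                 1.0;
      if (std::fabs(u) < kZig.ratio[i]) return u * kZig.x[i];
      if (i == 0) return norm_tail(u < 0.0);
      double x = u * kZig.x[i];
      double f0 = std::exp(-0.5 * (kZig.x[i] * kZig.x[i] - x * x));
      double f1 = std::exp(-0.5 * (kZig.x[i + 1] * kZig.x[i + 1] - x * x));
      if (f1 + unif() * (f0 - f1) < 1.0) return x;
    }
  }

  // Marsaglia-Tsang; valid for any shape > 0
  double gamma(double shape) {
    if (shape < 1.0) {
      double u = unif();
      return gamma(shape + 1.0) * std::pow(u, 1.0 / shape);
    }
    double d = shape - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = norm();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

  double beta_sym(double shape) {
    double x = gamma(shape);
    double y = gamma(shape);
    return x / (x + y);
  }
};

// d/dt of the expected distractor activation
// E[X_A(t)] = amp * exp(-t/tau) * (t*e / ((a-1)*tau))^(a-1)
double auto_drift(double t, double amp, double tau, double a) {
  if (t <= 0.0) {
    if (a == 2.0) return amp * M_E / tau;     // continuity limit
    if (a > 2.0) return 0.0;
    t = 1e-9;                                 // 1 < a < 2: diverges; clamp
  }
  double act = amp * std::exp(-t / tau) *
               std::pow(t * M_E / ((a - 1.0) * tau), a - 1.0);
  return act * ((a - 1.0) / t - 1.0 / tau);
}

struct TrialBatch {
  std::vector<double> decision_time;
  std::vector<double> rt;
  std::vector<char> correct;
  std::vector<char> responded;
};

// Core Euler-Maruyama loop shared by the user-facing simulator and the
// fitting objective.  With antithetic = true, odd-numbered trials mirror
// the noise of their even-numbered twin (negated path increments and
// residual deviate, reflected starting point); every trial keeps the
// exact marginal distribution but quantile and accuracy estimates gain a
// variance reduction, which is why the fitting objective uses it.  When a
// mirrored trial survives longer than its twin the extra steps use fresh
// draws.
void run_trials(double amp, double tau, double aa_shape, double mu_t,
                double sigma, double bound, double res_mean, double res_sd,
                double sp_shape, double onset_delay, double dt, double t_max,
                int cong_sign, int n, Rng& rng, TrialBatch& out,
                bool antithetic = false) {
  const int n_steps = static_cast<int>(std::ceil(t_max / dt));
  std::vector<double> mu(n_steps);
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;  // drift evaluated at the left endpoint of the step
    double target = (t >= onset_delay) ? mu_t : 0.0;
    mu[k] = (cong_sign * auto_drift(t, amp, tau, aa_shape) + target) * dt;
  }
  const double noise_sd = sigma * std::sqrt(dt);
  out.decision_time.assign(n, NA_REAL);
  out.rt.assign(n, NA_REAL);
  out.correct.assign(n, 0);
  out.responded.assign(n, 0);
  std::vector<double> twin_z;
  double twin_b = 0.5, twin_res = 0.0;
  int twin_used = 0;
  bool twin_res_valid = false;
  for (int i = 0; i < n; ++i) {
    bool mirror = antithetic && (i % 2 == 1);
    double b;
    if (!mirror) {
      b = rng.beta_sym(sp_shape);
      if (antithetic) {
        twin_b = b;
        twin_z.clear();
        twin_used = 0;
        twin_res_valid = false;
      }
    } else {
      b = 1.0 - twin_b;
    }
    double x = (2.0 * b - 1.0) * bound;
    for (int k = 0; k < n_steps; ++k) {
      double z;
      if (mirror) {
        z = (k < twin_used) ? -twin_z[k] : rng.norm();
      } else {
        z = rng.norm();
        if (antithetic) twin_z.push_back(z);
      }
      x += mu[k] + noise_sd * z;
      if (x >= bound || x <= -bound) {
        out.responded[i] = 1;
        out.correct[i] = (x >= bound) ? 1 : 0;
        out.decision_time[i] = (k + 1) * dt;
        double rz;
        if (mirror && twin_res_valid) {
          rz = -twin_res;
        } else {
          rz = rng.norm();
          if (antithetic && !mirror) {
            twin_res = rz;
            twin_res_valid = true;
          }
        }
        double res = res_mean + res_sd * rz;
        out.rt[i] = out.decision_time[i] + std::max(0.0, res);
        break;
      }
    }
    if (!mirror && antithetic) twin_used = static_cast<int>(twin_z.size());
  }
}

// Empirical quantiles by linear interpolation of order statistics with
// plotting positions (k - 0.5)/n (stats::quantile type 5); x must be sorted.
double quantile5(const std::vector<double>& x, double p) {
  const int n = static_cast<int>(x.size());
  double h = n * p + 0.5;
  if (h <= 1.0) return x[0];
  if (h >= n) return x[n - 1];
  int lo = static_cast<int>(std::floor(h));
  double g = h - lo;
  return x[lo - 1] + g * (x[lo] - x[lo - 1]);
}

}  // namespace

// Simulate n trials of one congruency.  cong_sign is +1 (congruent) or -1
// (incongruent): evidence toward the correct response is positive and the
// distractor input enters with that sign.  Returns decision_time and rt in
// ms (NA when no boundary is reached by t_max), correct and responded flags.
// [[Rcpp::export(name = ".sim_trials_cpp")]]
List sim_trials_cpp(double amp, double tau, double aa_shape, double mu_t,
                    double sigma, double bound, double res_mean, double res_sd,
                    double sp_shape, double onset_delay, double dt,
                    double t_max, int cong_sign, int n, double seed,
                    bool antithetic) {
  if (n < 1) stop("n must be >= 1");
  if (cong_sign != 1 && cong_sign != -1) stop("cong_sign must be +1 or -1");

  Rng rng(static_cast<uint64_t>(seed));
  TrialBatch batch;
  run_trials(amp, tau, aa_shape, mu_t, sigma, bound, res_mean, res_sd,
             sp_shape, onset_delay, dt, t_max, cong_sign, n, rng, batch,
             antithetic);

  NumericVector decision_time(n), rt(n);
  LogicalVector correct(n), responded(n);
  for (int i = 0; i < n; ++i) {
    decision_time[i] = batch.decision_time[i];
    rt[i] = batch.rt[i];
    correct[i] = batch.correct[i] != 0;
    responded[i] = batch.responded[i] != 0;
  }
  return List::create(_["decision_time"] = decision_time, _["rt"] = rt,
                      _["correct"] = correct, _["responded"] = responded);
}

// Fitting objective evaluated wholly in compiled code: simulate n_sim
// trials per congruency at the candidate parameters (congruent stream
// seeded with `seed`, incongruent with `seed + 1`, matching
// predict_summaries()), summarize them into type-5 CDF quantiles of
// correct RTs and equal-count CAF bin accuracies, and return the pooled
// weighted RMSE against the observed summaries.  Returns Inf when the
// candidate yields too few correct or responded trials to summarize.
// [[Rcpp::export(name = ".dmc_cost_cpp")]]
double dmc_cost_cpp(double amp, double tau, double aa_shape, double mu_t,
                    double sigma, double bound, double res_mean,
                    double res_sd, double sp_shape, double onset_delay,
                    double dt, double t_max, NumericVector cdf_probs,
                    int n_caf_bins, double caf_weight,
                    NumericVector obs_q_cong, NumericVector obs_q_incong,
                    NumericVector obs_caf_cong, NumericVector obs_caf_incong,
                    int n_sim, double seed, bool antithetic) {
  if (obs_q_cong.size() != cdf_probs.size() ||
      obs_q_incong.size() != cdf_probs.size())
    stop("observed quantile grid does not match cdf_probs");
  if (obs_caf_cong.size() != n_caf_bins || obs_caf_incong.size() != n_caf_bins)
    stop("observed CAF does not match n_caf_bins");

  TrialBatch batch;
  double ss = 0.0;
  int n_resid = 0;
  std::vector<double> correct_rt;
  std::vector<std::pair<double, int> > resp;  // (rt, correct)

  for (int s = 0; s < 2; ++s) {
    int sign = (s == 0) ? 1 : -1;
    Rng rng(static_cast<uint64_t>(seed) + s);
    run_trials(amp, tau, aa_shape, mu_t, sigma, bound, res_mean, res_sd,
               sp_shape, onset_delay, dt, t_max, sign, n_sim, rng, batch,
               antithetic);
    correct_rt.clear();
    resp.clear();
    for (int i = 0; i < n_sim; ++i) {
      if (!batch.responded[i]) continue;
      resp.push_back(std::make_pair(batch.rt[i], (int)batch.correct[i]));
      if (batch.correct[i]) correct_rt.push_back(batch.rt[i]);
    }
    if ((int)correct_rt.size() < 2 || (int)resp.size() < n_caf_bins)
      return R_PosInf;
    std::sort(correct_rt.begin(), correct_rt.end());
    const NumericVector& oq = (s == 0) ? obs_q_cong : obs_q_incong;
    for (int j = 0; j < cdf_probs.size(); ++j) {
      double r = oq[j] - quantile5(correct_rt, cdf_probs[j]);
      ss += r * r;
      ++n_resid;
    }
    std::stable_sort(resp.begin(), resp.end(),
                     [](const std::pair<double, int>& a,
                        const std::pair<double, int>& b) {
                       return a.first < b.first;
                     });
    const NumericVector& oc = (s == 0) ? obs_caf_cong : obs_caf_incong;
    int n = (int)resp.size();
    int base = n / n_caf_bins, rem = n % n_caf_bins, pos = 0;
    for (int b = 0; b < n_caf_bins; ++b) {
      int size = base + (b < rem ? 1 : 0);
      int n_corr = 0;
      for (int k = 0; k < size; ++k) n_corr += resp[pos + k].second;
      pos += size;
      double r = caf_weight * (oc[b] - (double)n_corr / size);
      ss += r * r;
      ++n_resid;
    }
  }
  return std::sqrt(ss / n_resid);
}

// Symmetric-beta starting points on (-bound, bound), for tests of the
// sampler in isolation.
// [[Rcpp::export(name = ".draw_start_cpp")]]
NumericVector draw_start_cpp(double sp_shape, double bound, int n,
                             double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (2.0 * rng.beta_sym(sp_shape) - 1.0) * bound;
  return out;
}
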