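#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Gas constant in kcal/(mol K); must match R_KCAL on the R side.
static const double R_KCAL = 1.987204e-3;

struct SysDef {
  double k1, x1, e1;      // reactant diabat: 0.5*k1*(x-x1)^2 + e1
  double k2, x2, e2p;     // product diabat, gas shift already folded into e2p
  double h12;             // off-diagonal coupling
  double xs;              // bath switching / strain centre along x
  double vh, vw;          // shared strain term: vh * exp(-(x-xs)^2/(2 vw^2))
  std::vector<double> bkR, bkTS, bw;
  int nb;
};

static SysDef parse_sys(const List& s) {
  SysDef d;
  d.k1  = as<double>(s["k1"]);
  d.x1  = as<double>(s["x1"]);
  d.e1  = as<double>(s["e1"]);
  d.k2  = as<double>(s["k2"]);
  d.x2  = as<double>(s["x2"]);
  d.e2p = as<double>(s["e2p"]);
  d.h12 = as<double>(s["h12"]);
  d.xs  = as<double>(s["x_switch"]);
  d.vh  = as<double>(s["strain_height"]);
  d.vw  = as<double>(s["strain_width"]);
  NumericVector kR = s["bath_k_reactant"], kTS = s["bath_k_ts"], w = s["bath_width"];
  d.nb = kR.size();
  d.bkR.assign(kR.begin(), kR.end());
  d.bkTS.assign(kTS.begin(), kTS.end());
  d.bw.assign(w.begin(), w.end());
  return d;
}

inline double strainf(const SysDef& s, double x) {
  if (s.vh == 0.0) return 0.0;
  double z = (x - s.xs) / s.vw;
  return s.vh * std::exp(-0.5 * z * z);
}
inline double eps1f(const SysDef& s, double x) {
  double d = x - s.x1; return 0.5 * s.k1 * d * d + s.e1 + strainf(s, x);
}
inline double eps2f(const SysDef& s, double x) {
  double d = x - s.x2; return 0.5 * s.k2 * d * d + s.e2p + strainf(s, x);
}
inline double egf(double e1, double e2, double h12) {
  double d = e1 - e2;
  return 0.5 * (e1 + e2) - 0.5 * std::sqrt(d * d + 4.0 * h12 * h12);
}
inline double kmode(const SysDef& s, int i, double x) {
  double z = (x - s.xs) / s.bw[i];
  return s.bkR[i] + (s.bkTS[i] - s.bkR[i]) * std::exp(-0.5 * z * z);
}
inline double bath_energy(const SysDef& s, double x, const std::vector<double>& q) {
  double u = 0.0;
  for (int i = 0; i < s.nb; ++i) u += 0.5 * kmode(s, i, x) * q[i] * q[i];
  return u;
}

static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Metropolis sampling of the mapping potential eps_m = (1-lam)*eps1 + lam*eps2'
// plus explicit harmonic bath modes whose stiffness depends on x.  One sweep =
// a Gaussian trial move in x (bath energy enters the acceptance ratio at fixed
// bath coordinates) followed by an exact Gibbs resample of every bath mode
// from its Gaussian conditional.  Step size is tuned toward 30-50% acceptance
// during burn-in only, so detailed balance holds throughout production.
// [[Rcpp::export(".mc_sample_window")]]
List mc_sample_window(List sysdef, double lam, double temperature,
                      int n_steps, int burn_in, int stride,
                      int seed_hi, int seed_lo,
                      double x0, NumericVector q0,
                      double step0, bool tune, bool store_bath) {
  SysDef s = parse_sys(sysdef);
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (temperature <= 0) stop("temperature must be positive");
  if (stride < 1) stride = 1;
  const double RT = R_KCAL * temperature;

  uint64_t seed = (static_cast<uint64_t>(static_cast<uint32_t>(seed_hi)) << 32) |
                  static_cast<uint64_t>(static_cast<uint32_t>(seed_lo));
  std::mt19937_64 rng(splitmix64(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double x = x0;
  std::vector<double> q(s.nb, 0.0);
  if (q0.size() == s.nb) for (int i = 0; i < s.nb; ++i) q[i] = q0[i];

  double step = step0 > 0 ? step0 : std::sqrt(RT / std::max(s.k1, s.k2));

  double em_cur = (1.0 - lam) * eps1f(s, x) + lam * eps2f(s, x) + bath_energy(s, x, q);

  int n_prod = n_steps - burn_in;
  if (n_prod < 1) stop("n_steps must exceed burn_in");
  int n_keep = n_prod / stride;
  if (n_prod % stride != 0) ++n_keep;
  int ncol = 7 + (store_bath ? s.nb : 0);
  NumericMatrix frames(n_keep, ncol);

  long acc_prod = 0, tot_prod = 0;
  int acc_win = 0, win = 0, row = 0;

  for (int it = 0; it < n_steps; ++it) {
    double xp = x + step * gauss(rng);
    double em_p = (1.0 - lam) * eps1f(s, xp) + lam * eps2f(s, xp) + bath_energy(s, xp, q);
    bool accept = false;
    double dU = em_p - em_cur;
    if (dU <= 0.0 || unif(rng) < std::exp(-dU / RT)) accept = true;
    if (accept) { x = xp; em_cur = em_p; }

    // exact conditional resample of bath coordinates at the current x
    for (int i = 0; i < s.nb; ++i) {
      double ki = kmode(s, i, x);
      q[i] = std::sqrt(RT / ki) * gauss(rng);
    }
    if (s.nb > 0)
      em_cur = (1.0 - lam) * eps1f(s, x) + lam * eps2f(s, x) + bath_energy(s, x, q);

    if (it < burn_in) {
      if (tune) {
        if (accept) ++acc_win;
        if (++win == 50) {
          double r = acc_win / 50.0;
          if (r > 0.5) step *= 1.15;
          else if (r < 0.3) step /= 1.15;
          acc_win = 0; win = 0;
        }
      }
    } else {
      ++tot_prod;
      if (accept) ++acc_prod;
      int pstep = it - burn_in;
      if (pstep % stride == 0) {
        double e1 = eps1f(s, x), e2 = eps2f(s, x);
        double eg = egf(e1, e2, s.h12);
        double em = (1.0 - lam) * e1 + lam * e2;
        frames(row, 0) = pstep + 1;
        frames(row, 1) = x;
        frames(row, 2) = e1;
        frames(row, 3) = e2;
        frames(row, 4) = e1 - e2;
        frames(row, 5) = eg;
        frames(row, 6) = em;
        if (store_bath) for (int i = 0; i < s.nb; ++i) frames(row, 7 + i) = q[i];
        ++row;
      }
    }
  }

  NumericVector qout(s.nb);
  for (int i = 0; i < s.nb; ++i) qout[i] = q[i];
  return List::create(
    _["frames"] = frames,
    _["acceptance"] = tot_prod > 0 ? static_cast<double>(acc_prod) / tot_prod : NA_REAL,
    _["step_size"] = step,
    _["x_final"] = x,
    _["q_final"] = qout);
}
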