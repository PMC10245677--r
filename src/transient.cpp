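// Hot numerical kernels: the quadrature-recycling transient likelihood and
// exact stochastic simulation of (time-dependent) bursty transcription.
//
// All randomness goes through R's RNG so set.seed() governs the samplers.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline double bprof(double t, double b1, double b2, double b3,
                           double tau1, double tau2) {
  if (t < tau1) return b1;
  if (t <= tau2) return b2;
  return b3;
}

// Closed-form nascent characteristic of the splicing/degradation pair.
static inline cplx UN_char(const cplx &uN, const cplx &uM, double s,
                           double beta, double gamma) {
  if (std::fabs(beta - gamma) < 1e-9)
    return uN * std::exp(-beta * s) + uM * (beta * s * std::exp(-beta * s));
  return uN * std::exp(-beta * s) +
         uM * (beta / (beta - gamma) * (std::exp(-gamma * s) - std::exp(-beta * s)));
}

// Shared quadrature grid: 0 plus the sorted unique cell times, densified by
// midpoint insertion when fewer than dense_below cell times are supplied.
static std::vector<double> make_nodes(const std::vector<double> &times,
                                      int dense_below, int target) {
  std::vector<double> s(times);
  s.push_back(0.0);
  std::sort(s.begin(), s.end());
  s.erase(std::unique(s.begin(), s.end()), s.end());
  if ((int)times.size() >= dense_below) return s;
  while ((int)s.size() < target) {
    std::vector<double> t;
    t.reserve(2 * s.size());
    for (size_t i = 0; i + 1 < s.size(); ++i) {
      t.push_back(s[i]);
      t.push_back(0.5 * (s[i] + s[i + 1]));
    }
    t.push_back(s.back());
    s.swap(t);
  }
  return s;
}

// Per-cell observation probabilities of the transient bursty model, via the
// recycled trapezoidal quadrature over the shared grid and single-entry
// inverse DFT at each cell's observed count pair.
// theta = (b1, b2, b3, alpha, beta, gamma) on the natural scale; times are
// the (already clock-transformed) cell ages, taus the transformed stage
// switch times.
// [[Rcpp::export]]
NumericVector cpp_transient_cellprobs(NumericVector theta, double tau1, double tau2,
                                      NumericVector times, IntegerVector xN,
                                      IntegerVector xM, int sN, int sM,
                                      int dense_below, int target_nodes) {
  const double b1 = theta[0], b2 = theta[1], b3 = theta[2];
  const double alpha = theta[3], beta = theta[4], gamma = theta[5];
  const double lamN0 = alpha * b1 / beta, lamM0 = alpha * b1 / gamma;
  const int nc = times.size();
  if (xN.size() != nc || xM.size() != nc)
    stop("times and counts must have equal length");

  std::vector<double> tv(times.begin(), times.end());
  for (int c = 1; c < nc; ++c)
    if (tv[c] < tv[c - 1]) stop("times must be sorted ascending");
  std::vector<double> s = make_nodes(tv, dense_below, target_nodes);
  const int ns = (int)s.size();

  // spectral grid u = g - 1 on the FFT roots of unity
  const int ng = sN * sM;
  std::vector<cplx> uN(sN), uM(sM);
  for (int k = 0; k < sN; ++k)
    uN[k] = std::polar(1.0, 2.0 * M_PI * k / sN) - 1.0;
  for (int l = 0; l < sM; ++l)
    uM[l] = std::polar(1.0, 2.0 * M_PI * l / sM) - 1.0;

  // characteristics at every node for every grid point (g fastest over kN)
  std::vector<cplx> UNmat((size_t)ng * ns);
  for (int j = 0; j < ns; ++j) {
    const double sj = s[j];
    const double eb = std::exp(-beta * sj);
    cplx coefM;
    if (std::fabs(beta - gamma) < 1e-9)
      coefM = beta * sj * eb;
    else
      coefM = beta / (beta - gamma) * (std::exp(-gamma * sj) - eb);
    for (int l = 0; l < sM; ++l) {
      const cplx mterm = uM[l] * coefM;
      for (int k = 0; k < sN; ++k)
        UNmat[(size_t)j * ng + l * sN + k] = uN[k] * eb + mterm;
    }
  }

  // map each cell to its node index
  std::vector<int> cell_node(nc);
  for (int c = 0; c < nc; ++c) {
    int j = (int)(std::lower_bound(s.begin(), s.end(), tv[c]) - s.begin());
    if (j >= ns || s[j] != tv[c]) stop("internal error: cell time missing from grid");
    cell_node[c] = j;
  }

  // The burst profile takes only three values, so the trapezoidal rule over
  // the shared grid can be decomposed into stage-wise cumulative prefix
  // tables: C_k[j] = trapz_{s_0}^{s_j} f_k, with f_k = b_k U/(1 - b_k U).
  // A cell's integral is then a sum of at most three prefix differences
  // plus at most two stage-straddling intervals handled explicitly.  This
  // reproduces the row-quadrature of the recycled TQ/DQ/MQ scheme exactly.
  const double bvals[3] = {b1, b2, b3};
  std::vector<std::vector<cplx>> fk(3), Ck(3);
  for (int k = 0; k < 3; ++k) {
    fk[k].resize((size_t)ng * ns);
    Ck[k].resize((size_t)ng * (ns + 1));
    for (int j = 0; j < ns; ++j) {
      const cplx *un = &UNmat[(size_t)j * ng];
      cplx *f = &fk[k][(size_t)j * ng];
      for (int g = 0; g < ng; ++g) {
        cplx z = bvals[k] * un[g];
        if (std::abs(1.0 - z) < 1e-12)
          stop("integrand singularity (1 - b U -> 0) at node s = %f", s[j]);
        f[g] = z / (1.0 - z);
      }
    }
    std::fill(Ck[k].begin(), Ck[k].begin() + ng, cplx(0.0, 0.0));
    for (int j = 1; j <= ns; ++j) {
      const double h = (j < ns) ? 0.5 * (s[j] - s[j - 1]) : 0.0;
      const cplx *cprev = &Ck[k][(size_t)(j - 1) * ng];
      cplx *ccur = &Ck[k][(size_t)j * ng];
      if (j < ns) {
        const cplx *fa = &fk[k][(size_t)(j - 1) * ng];
        const cplx *fb = &fk[k][(size_t)j * ng];
        for (int g = 0; g < ng; ++g) ccur[g] = cprev[g] + h * (fa[g] + fb[g]);
      }
    }
  }
  // stage of the burst-profile argument tc - s (1-based in the math; 0-based
  // index into bvals here)
  auto stage_of = [&](double arg) { return arg < tau1 ? 0 : (arg <= tau2 ? 1 : 2); };

  NumericVector out(nc);
  std::vector<cplx> integral(ng), G(ng);
  int prev_node = -1;
  for (int c = 0; c < nc; ++c) {
    const int j = cell_node[c];
    if (j != prev_node) {
      const double tc = s[j];
      std::fill(integral.begin(), integral.end(), cplx(0.0, 0.0));
      // pure-stage runs -> prefix differences; straddling intervals explicit
      int run_start = 0;
      int run_k = (j > 0) ? stage_of(tc - s[0]) : 0;
      for (int i = 0; i < j; ++i) {
        const int ka = stage_of(tc - s[i]);
        const int kb = stage_of(tc - s[i + 1]);
        if (ka == kb) continue;
        // close the pure run of intervals [run_start .. i-1] (stage ka)
        {
          const cplx *chi = &Ck[run_k][(size_t)i * ng];
          const cplx *clo = &Ck[run_k][(size_t)run_start * ng];
          for (int g = 0; g < ng; ++g) integral[g] += chi[g] - clo[g];
        }
        // the straddling interval [i, i+1]
        const double h = 0.5 * (s[i + 1] - s[i]);
        const cplx *fa = &fk[ka][(size_t)i * ng];
        const cplx *fb = &fk[kb][(size_t)(i + 1) * ng];
        for (int g = 0; g < ng; ++g) integral[g] += h * (fa[g] + fb[g]);
        run_start = i + 1;
        run_k = kb;
      }
      if (j > run_start) {
        const cplx *chi = &Ck[run_k][(size_t)j * ng];
        const cplx *clo = &Ck[run_k][(size_t)run_start * ng];
        for (int g = 0; g < ng; ++g) integral[g] += chi[g] - clo[g];
      }
      const double eg = std::exp(-gamma * tc);
      const cplx *unj = &UNmat[(size_t)j * ng];
      for (int l = 0; l < sM; ++l) {
        const cplx mterm = lamM0 * (uM[l] * eg);
        for (int k = 0; k < sN; ++k) {
          const int g = l * sN + k;
          G[g] = std::exp(lamN0 * unj[g] + mterm + alpha * integral[g]);
        }
      }
      prev_node = j;
    }
    // single-entry inverse DFT at (xN_c, xM_c)
    const int xn = xN[c], xm = xM[c];
    if (xn < 0 || xn >= sN || xm < 0 || xm >= sM)
      stop("observed count outside the evaluation grid");
    cplx acc(0.0, 0.0);
    for (int l = 0; l < sM; ++l) {
      const cplx phM = std::polar(1.0, -2.0 * M_PI * (double)(l * xm) / sM);
      cplx inner(0.0, 0.0);
      for (int k = 0; k < sN; ++k) {
        const cplx phN = std::polar(1.0, -2.0 * M_PI * (double)(k * xn) / sN);
        inner += G[l * sN + k] * phN;
      }
      acc += inner * phM;
    }
    out[c] = acc.real() / ng;
  }
  return out;
}

// Exact SSA for the transient bursty model: bursts arrive at rate alpha with
// geometric sizes of mean b(t); nascent molecules splice at rate beta and
// mature molecules degrade at rate gamma.  Only the burst-size law is
// time-dependent, so event rates are constant between events and the
// standard algorithm is exact.  One trajectory per (age, rep); the initial
// state is bivariate Poisson with the stage-1 stationary means.
// [[Rcpp::export]]
IntegerMatrix cpp_ssa_transient(NumericVector theta, double tau1, double tau2,
                                NumericVector ages, int reps) {
  const double b1 = theta[0], b2 = theta[1], b3 = theta[2];
  const double alpha = theta[3], beta = theta[4], gamma = theta[5];
  const double lamN0 = alpha * b1 / beta, lamM0 = alpha * b1 / gamma;
  const int nc = ages.size();
  IntegerMatrix out(nc * reps, 2);
  int row = 0;
  for (int c = 0; c < nc; ++c) {
    const double tend = ages[c];
    for (int r = 0; r < reps; ++r, ++row) {
      double t = 0.0;
      int xN = (int)R::rpois(lamN0);
      int xM = (int)R::rpois(lamM0);
      for (;;) {
        const double rate = alpha + beta * xN + gamma * xM;
        t += R::exp_rand() / rate;
        if (t > tend) break;
        const double u = unif_rand() * rate;
        if (u < alpha) {
          const double b = bprof(t, b1, b2, b3, tau1, tau2);
          xN += (int)R::rgeom(1.0 / (1.0 + b));
        } else if (u < alpha + beta * xN) {
          --xN; ++xM;
        } else {
          --xM;
        }
      }
      out(row, 0) = xN;
      out(row, 1) = xM;
    }
  }
  return out;
}

// Exact SSA for the (optionally bursty) autocatalytic one-species network:
// production bursts at rate alpha (geometric mean b, or single molecules
// when b <= 0), autocatalysis X -> 2X at rate q*x, degradation at rate
// gamma*x.  Returns the state at tend for each of `reps` trajectories
// started at 0.
// [[Rcpp::export]]
IntegerVector cpp_ssa_autocat(double alpha, double q, double gamma, double b,
                              double tend, int reps) {
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double t = 0.0;
    long x = 0;
    for (;;) {
      const double rate = alpha + (q + gamma) * x;
      t += R::exp_rand() / rate;
      if (t > tend) break;
      const double u = unif_rand() * rate;
      if (u < alpha) {
        x += (b > 0) ? (long)R::rgeom(1.0 / (1.0 + b)) : 1L;
      } else if (u < alpha + q * x) {
        ++x;
      } else {
        --x;
      }
      if (x > 100000L) stop("autocatalytic trajectory exploded");
    }
    out[r] = (int)x;
  }
  return out;
}
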