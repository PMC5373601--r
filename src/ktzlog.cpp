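// Compiled kernels for the KTLog/KTzLog maps.  Everything here is a plain
// deterministic loop; all scientific decisions (thresholds, fit windows,
// classification rules) live on the R side.  The sweep kernel duplicates the
// R-level spike detector and ISI histogram exactly (same constants); a unit
// test pins the two implementations together.

#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// gain codes: 0 = logistic u/(1+|u|), 1 = tanh (argument clamped at +-350
// so exp() cannot overflow; tanh is +-1 to double precision long before that)
static inline double gain_f(double u, int g) {
  if (g == 0) return u / (1.0 + std::fabs(u));
  if (u > 350.0) u = 350.0; else if (u < -350.0) u = -350.0;
  return std::tanh(u);
}

static inline double gain_d(double u, int g) {
  if (g == 0) { double d = 1.0 + std::fabs(u); return 1.0 / (d * d); }
  if (u > 350.0) u = 350.0; else if (u < -350.0) u = -350.0;
  double t = std::tanh(u);
  return 1.0 - t * t;
}

struct Par { double K, T, H, del, lam, xR; int g; };

static inline Par unpack(const NumericVector& par, int gain) {
  Par p;
  p.K = par[0]; p.T = par[1]; p.H = par[2];
  p.del = par[3]; p.lam = par[4]; p.xR = par[5];
  p.g = gain;
  return p;
}

// synchronous update: all components read the OLD state
static inline void map_step(const Par& p, double& x, double& y, double& z,
                            double I) {
  double u  = (x - p.K * y + z + p.H + I) / p.T;
  double nx = gain_f(u, p.g);
  double nz = (1.0 - p.del) * z - p.lam * (x - p.xR);
  y = x; x = nx; z = nz;
}

// [[Rcpp::export]]
NumericMatrix sim_cpp(NumericVector par, int gain, NumericVector init,
                      int n_steps, int discard, NumericVector I) {
  Par p = unpack(par, gain);
  double x = init[0], y = init[1], z = init[2];
  const int total = n_steps + discard;
  const bool has_I = I.size() > 0;
  if (has_I && I.size() < total)
    stop("stimulus series shorter than simulation (%d < %d)",
         (int)I.size(), total);
  NumericMatrix out(n_steps, 3);
  for (int t = 0; t < total; ++t) {
    if (t >= discard) {
      int r = t - discard;
      out(r, 0) = x; out(r, 1) = y; out(r, 2) = z;
    }
    map_step(p, x, y, z, has_I ? I[t] : 0.0);
    if (!std::isfinite(x) || !std::isfinite(z))
      stop("non-finite state at step %d", t + 1);
  }
  return out;
}

// twin trajectories from init and init + (eps, 0, 0); returns |x2 - x1| for
// t = 0..horizon (length horizon + 1)
// [[Rcpp::export]]
NumericVector twin_div_cpp(NumericVector par, int gain, NumericVector init,
                           double eps, int horizon) {
  Par p = unpack(par, gain);
  double x1 = init[0], y1 = init[1], z1 = init[2];
  double x2 = init[0] + eps, y2 = init[1], z2 = init[2];
  NumericVector dx(horizon + 1);
  dx[0] = std::fabs(x2 - x1);
  for (int t = 1; t <= horizon; ++t) {
    map_step(p, x1, y1, z1, 0.0);
    map_step(p, x2, y2, z2, 0.0);
    dx[t] = std::fabs(x2 - x1);
  }
  return dx;
}

// Eckmann-Ruelle: accumulate tangent-space Jacobian products along the orbit
// with periodic Gram-Schmidt re-orthonormalisation.  Dimension is 2 for the
// fast subsystem (delta = lambda = 0), 3 otherwise.
// [[Rcpp::export]]
List lyap_er_cpp(NumericVector par, int gain, NumericVector init,
                 int n_steps, int discard, int renorm_every) {
  Par p = unpack(par, gain);
  const int d = (p.del == 0.0 && p.lam == 0.0) ? 2 : 3;
  double x = init[0], y = init[1], z = init[2];
  for (int t = 0; t < discard; ++t) map_step(p, x, y, z, 0.0);

  // V columns = tangent vectors, start orthonormal
  double V[3][3] = {{0}};
  for (int i = 0; i < d; ++i) V[i][i] = 1.0;
  double sums[3] = {0.0, 0.0, 0.0};
  int n_renorm_steps = 0;

  for (int t = 0; t < n_steps; ++t) {
    double u = (x - p.K * y + z + p.H) / p.T;
    double a = gain_d(u, p.g) / p.T;
    // J = [[a, -K a, a], [1, 0, 0], [-lam, 0, 1-del]] (first d rows/cols)
    double W[3][3];
    for (int c = 0; c < d; ++c) {
      double v0 = V[0][c], v1 = V[1][c], v2 = (d == 3) ? V[2][c] : 0.0;
      W[0][c] = a * v0 - p.K * a * v1 + ((d == 3) ? a * v2 : 0.0);
      W[1][c] = v0;
      if (d == 3) W[2][c] = -p.lam * v0 + (1.0 - p.del) * v2;
    }
    for (int r = 0; r < d; ++r)
      for (int c = 0; c < d; ++c) V[r][c] = W[r][c];

    map_step(p, x, y, z, 0.0);

    if ((t + 1) % renorm_every == 0 || t == n_steps - 1) {
      // modified Gram-Schmidt on columns
      for (int c = 0; c < d; ++c) {
        for (int k = 0; k < c; ++k) {
          double dot = 0.0;
          for (int r = 0; r < d; ++r) dot += V[r][k] * V[r][c];
          for (int r = 0; r < d; ++r) V[r][c] -= dot * V[r][k];
        }
        double nrm = 0.0;
        for (int r = 0; r < d; ++r) nrm += V[r][c] * V[r][c];
        nrm = std::sqrt(nrm);
        if (nrm <= 0.0 || !std::isfinite(nrm))
          stop("tangent vector collapsed at step %d", t + 1);
        sums[c] += std::log(nrm);
        for (int r = 0; r < d; ++r) V[r][c] /= nrm;
      }
      n_renorm_steps = t + 1;
    }
  }
  NumericVector ex(d);
  for (int c = 0; c < d; ++c) ex[c] = sums[c] / n_renorm_steps;
  return List::create(_["exponents"] = ex, _["n_steps"] = n_renorm_steps,
                      _["dim"] = d);
}

// ---- ISI sweep -----------------------------------------------------------
// Spike detector: upward crossing of `thr` after having been armed below
// thr - hyst.  ISI histogram: quarter-octave log2 bins, bin = floor(4*log2(isi)).
// Modes: runs of bins with count >= 2% of total, separated by sub-threshold
// bins; a run is a mode if its mass >= 5% of total.  Constants are mirrored
// in the R reference implementation (isi_modes / oscillation_summary).

#define NBIN 96

struct WinAcc {
  double xmin, xmax;
  long   n;           // ISI count
  double mean, m2;    // Welford
  double isi_max;
  double cnt[NBIN], sum[NBIN];
  void init() {
    xmin = 1e300; xmax = -1e300; n = 0; mean = 0.0; m2 = 0.0; isi_max = 0.0;
    for (int i = 0; i < NBIN; ++i) { cnt[i] = 0.0; sum[i] = 0.0; }
  }
  void add_x(double x) { if (x < xmin) xmin = x; if (x > xmax) xmax = x; }
  void add_isi(double isi) {
    ++n;
    double dlt = isi - mean;
    mean += dlt / n;
    m2 += dlt * (isi - mean);
    if (isi > isi_max) isi_max = isi;
    int b = (int)std::floor(4.0 * std::log2(isi));
    if (b < 0) b = 0; if (b >= NBIN) b = NBIN - 1;
    cnt[b] += 1.0; sum[b] += isi;
  }
  // out: n_modes, mode1_mean, modeL_mean
  void modes(double* out) const {
    out[0] = 0; out[1] = NA_REAL; out[2] = NA_REAL;
    if (n == 0) return;
    double gap_thr = 0.02 * n, mass_thr = 0.05 * n;
    int b = 0, nm = 0;
    while (b < NBIN) {
      if (cnt[b] > gap_thr) {
        double mass = 0.0, msum = 0.0;
        int b0 = b;
        while (b < NBIN && cnt[b] > gap_thr) {
          mass += cnt[b]; msum += sum[b]; ++b;
        }
        (void)b0;
        if (mass >= mass_thr) {
          ++nm;
          if (nm == 1) out[1] = msum / mass;
          out[2] = msum / mass;
        }
      } else ++b;
    }
    out[0] = nm;
  }
};

// which codes: 0=K 1=T 2=H 3=delta 4=lambda 5=xR
// Output columns, for each window w in {full, half1, half2}:
//   amp, n_isi, mean_isi, var_isi, max_isi, n_modes, mode1_mean, modeL_mean
// [[Rcpp::export]]
NumericMatrix sweep_cpp(NumericVector par, int gain,
                        int which1, NumericVector v1,
                        int which2, NumericVector v2,
                        NumericVector init, int window, int discard,
                        double thr, double hyst) {
  const int ncell = v1.size();
  if (v2.size() != ncell) stop("v1/v2 length mismatch");
  NumericMatrix out(ncell, 24);
  const int half = window / 2;

  for (int cell = 0; cell < ncell; ++cell) {
    NumericVector pv = clone(par);
    pv[which1] = v1[cell];
    if (which2 >= 0) pv[which2] = v2[cell];
    Par p = unpack(pv, gain);
    double x = init[0], y = init[1], z = init[2];
    for (int t = 0; t < discard; ++t) map_step(p, x, y, z, 0.0);

    WinAcc full, h1, h2;
    full.init(); h1.init(); h2.init();
    bool armed = (x < thr - hyst);
    long last_spike = -1;
    for (int t = 0; t < window; ++t) {
      full.add_x(x);
      (t < half ? h1 : h2).add_x(x);
      if (armed && x >= thr) {
        armed = false;
        if (last_spike >= 0) {
          double isi = (double)(t - last_spike);
          full.add_isi(isi);
          (t < half ? h1 : h2).add_isi(isi);
        }
        last_spike = t;
      } else if (!armed && x < thr - hyst) {
        armed = true;
      }
      map_step(p, x, y, z, 0.0);
    }

    const WinAcc* ws[3] = {&full, &h1, &h2};
    for (int w = 0; w < 3; ++w) {
      const WinAcc& a = *ws[w];
      double mo[3]; a.modes(mo);
      int o = 8 * w;
      out(cell, o + 0) = (a.xmax >= a.xmin) ? a.xmax - a.xmin : 0.0;
      out(cell, o + 1) = (double)a.n;
      out(cell, o + 2) = a.n > 0 ? a.mean : NA_REAL;
      out(cell, o + 3) = a.n > 1 ? a.m2 / (a.n - 1) : NA_REAL;
      out(cell, o + 4) = a.n > 0 ? a.isi_max : NA_REAL;
      out(cell, o + 5) = mo[0];
      out(cell, o + 6) = mo[1];
      out(cell, o + 7) = mo[2];
    }
    if (cell % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// box counting over (x, y); eps are fractions of the larger bounding-box side
// [[Rcpp::export]]
NumericVector box_count_cpp(NumericVector x, NumericVector y,
                            NumericVector eps) {
  const R_xlen_t n = x.size();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0.0) { // all points coincide
    NumericVector ones(eps.size(), 1.0);
    return ones;
  }
  NumericVector counts(eps.size());
  for (int e = 0; e < eps.size(); ++e) {
    double h = eps[e] * span;
    std::unordered_set<int64_t> boxes;
    boxes.reserve(1 << 16);
    for (R_xlen_t i = 0; i < n; ++i) {
      int64_t ix = (int64_t)std::floor((x[i] - xmin) / h);
      int64_t iy = (int64_t)std::floor((y[i] - ymin) / h);
      boxes.insert(ix * 2097152LL + iy);
    }
    counts[e] = (double)boxes.size();
  }
  return counts;
}

// Streaming box counts of the (x, y) attractor on dyadic grids.
// Iterates the map for n_steps after `discard`, inserting each point into
// the finest grid (side 2^-m_finest of the bounding box established by a
// pilot run); coarser counts follow exactly by index shifting because the
// grids share origin and are power-of-two refinements.  Returns counts for
// m = 1..m_finest (eps = 2^-m).
// [[Rcpp::export]]
List box_count_stream_cpp(NumericVector par, int gain, NumericVector init,
                          double n_steps, int discard, int m_finest,
                          int n_pilot) {
  Par p = unpack(par, gain);
  double x = init[0], y = init[1], z = init[2];
  for (int t = 0; t < discard; ++t) map_step(p, x, y, z, 0.0);
  // pilot pass for the bounding box
  double x0 = x, y0 = y, z0 = z;
  double xmin = x, xmax = x, ymin = y, ymax = y;
  for (int t = 0; t < n_pilot; ++t) {
    map_step(p, x, y, z, 0.0);
    if (x < xmin) xmin = x; if (x > xmax) xmax = x;
    if (y < ymin) ymin = y; if (y > ymax) ymax = y;
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0.0) stop("degenerate attractor (a fixed point?)");
  // pad so stray points beyond the pilot bbox stay inside
  xmin -= 0.01 * span; ymin -= 0.01 * span; span *= 1.02;
  const double h = span / (double)(1LL << m_finest);
  std::unordered_set<int64_t> fine;
  fine.reserve(1 << 20);
  x = x0; y = y0; z = z0;
  const int64_t lim = (1LL << m_finest) + 2;
  for (double t = 0; t < n_steps; ++t) {
    int64_t ix = (int64_t)std::floor((x - xmin) / h);
    int64_t iy = (int64_t)std::floor((y - ymin) / h);
    if (ix < 0) ix = 0; if (ix > lim) ix = lim;
    if (iy < 0) iy = 0; if (iy > lim) iy = lim;
    fine.insert((ix << 22) | iy);
    map_step(p, x, y, z, 0.0);
    if (((long long)t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector counts(m_finest);
  std::vector<int64_t> keys(fine.begin(), fine.end());
  counts[m_finest - 1] = (double)keys.size();
  for (int m = m_finest - 1; m >= 1; --m) {
    int shift = m_finest - m;
    std::unordered_set<int64_t> coarse;
    coarse.reserve(keys.size());
    for (int64_t k : keys) {
      int64_t ix = (k >> 22) >> shift, iy = (k & 0x3FFFFF) >> shift;
      coarse.insert((ix << 22) | iy);
    }
    counts[m - 1] = (double)coarse.size();
  }
  return List::create(_["m"] = seq_len(m_finest), _["counts"] = counts,
                      _["n_points"] = n_steps);
}

// Subdivision box cover of the case-I attractor closure.
//
// Box-counting an orbit sample under-covers a strongly multifractal
// attractor: filaments of tiny natural measure are visited too rarely to
// register.  The capacity dimension is a property of the SET (the attractor
// closure), so we compute an invariant box cover instead: starting from a
// dilated orbit cover on a dyadic grid, iterate the selection step
// S <- image(S) /\ S until stable, then subdivide every kept box into 4 and
// repeat at the next level.  Because x' = f((x - K y + H)/T) is monotone
// (increasing in x, decreasing in y) and y' = x spans exactly one grid row,
// the image cover of a box is an exact interval of cells: no sampling of
// box interiors, hence no missed cells.
//
// Returns N_m for m = m0..m1 (eps = span / 2^m of the fixed domain
// [-1.02, 1.02]^2).
// [[Rcpp::export]]
List attractor_cover_cpp(NumericVector par, int gain, NumericVector init,
                         int m0, int m1, double n_orbit, int discard,
                         int max_sweeps, int dilate) {
  Par p = unpack(par, gain);
  if (p.del != 0.0 || p.lam != 0.0) stop("cover method is 2-D (case I) only");
  const double O = -1.02, span = 2.04;

  auto key = [](int64_t i, int64_t j) { return (i << 26) | j; };
  auto ki = [](int64_t k) { return k >> 26; };
  auto kj = [](int64_t k) { return k & ((1LL << 26) - 1); };

  // seed: orbit cover at level m0, dilated by one cell
  double x = init[0], y = init[1], z = init[2];
  for (int t = 0; t < discard; ++t) map_step(p, x, y, z, 0.0);
  std::unordered_set<int64_t> S;
  {
    double eps = span / (double)(1LL << m0);
    std::unordered_set<int64_t> orbit;
    for (double t = 0; t < n_orbit; ++t) {
      orbit.insert(key((int64_t)((x - O) / eps), (int64_t)((y - O) / eps)));
      map_step(p, x, y, z, 0.0);
    }
    const int64_t lim = (1LL << m0) - 1;
    for (int64_t k : orbit)
      for (int64_t di = -dilate; di <= dilate; ++di)
        for (int64_t dj = -dilate; dj <= dilate; ++dj) {
          int64_t i = ki(k) + di, j = kj(k) + dj;
          if (i >= 0 && i <= lim && j >= 0 && j <= lim) S.insert(key(i, j));
        }
  }

  std::vector<int> ms; std::vector<double> Ns;
  for (int m = m0; m <= m1; ++m) {
    double eps = span / (double)(1LL << m);
    const int64_t lim = (1LL << m) - 1;
    // selection sweeps: keep cells of S hit by the exact image cover of S
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      std::unordered_set<int64_t> hit;
      hit.reserve(S.size());
      for (int64_t k : S) {
        int64_t i = ki(k), j = kj(k);
        double xlo = O + i * eps, xhi = xlo + eps;
        double ylo = O + j * eps, yhi = ylo + eps;
        double umin = (xlo - p.K * yhi + p.H) / p.T;
        double umax = (xhi - p.K * ylo + p.H) / p.T;
        double flo = gain_f(umin, p.g), fhi = gain_f(umax, p.g);
        int64_t kx0 = (int64_t)std::floor((flo - O) / eps);
        int64_t kx1 = (int64_t)std::floor((fhi - O) / eps);
        if (kx0 < 0) kx0 = 0; if (kx1 > lim) kx1 = lim;
        for (int64_t kx = kx0; kx <= kx1; ++kx) {
          int64_t tgt = key(kx, i);   // y' = x lands in row i
          if (S.count(tgt)) hit.insert(tgt);
        }
      }
      bool stable = hit.size() == S.size();
      S.swap(hit);
      if (stable) break;
      Rcpp::checkUserInterrupt();
    }
    ms.push_back(m); Ns.push_back((double)S.size());
    if (m == m1) break;
    // subdivide every kept box into its 4 children
    std::unordered_set<int64_t> S2;
    S2.reserve(S.size() * 4);
    for (int64_t k : S) {
      int64_t i = ki(k) * 2, j = kj(k) * 2;
      S2.insert(key(i, j)); S2.insert(key(i + 1, j));
      S2.insert(key(i, j + 1)); S2.insert(key(i + 1, j + 1));
    }
    S.swap(S2);
  }
  return List::create(_["m"] = wrap(ms), _["counts"] = wrap(Ns),
                      _["span"] = span);
}

// Per-level box occupancy with singleton/doubleton counts, for
// coverage-corrected (Chao1) box-count estimates:
//   N_hat = N_obs + f1^2 / (2 f2),
// where f1/f2 are boxes hit exactly once/twice.  Returns, per level m,
// (N_obs, f1, f2).
// [[Rcpp::export]]
List box_count_chao_cpp(NumericVector par, int gain, NumericVector init,
                        double n_steps, int discard, int m_finest,
                        int n_pilot) {
  Par p = unpack(par, gain);
  double x = init[0], y = init[1], z = init[2];
  for (int t = 0; t < discard; ++t) map_step(p, x, y, z, 0.0);
  double x0 = x, y0 = y, z0 = z;
  double xmin = x, xmax = x, ymin = y, ymax = y;
  for (int t = 0; t < n_pilot; ++t) {
    map_step(p, x, y, z, 0.0);
    if (x < xmin) xmin = x; if (x > xmax) xmax = x;
    if (y < ymin) ymin = y; if (y > ymax) ymax = y;
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0.0) stop("degenerate attractor (a fixed point?)");
  xmin -= 0.01 * span; ymin -= 0.01 * span; span *= 1.02;
  const double h = span / (double)(1LL << m_finest);
  std::unordered_map<int64_t, int> fine;
  fine.reserve(1 << 21);
  x = x0; y = y0; z = z0;
  const int64_t lim = (1LL << m_finest) + 2;
  for (double t = 0; t < n_steps; ++t) {
    int64_t ix = (int64_t)std::floor((x - xmin) / h);
    int64_t iy = (int64_t)std::floor((y - ymin) / h);
    if (ix < 0) ix = 0; if (ix > lim) ix = lim;
    if (iy < 0) iy = 0; if (iy > lim) iy = lim;
    auto it = fine.find((ix << 22) | iy);
    if (it == fine.end()) fine[(ix << 22) | iy] = 1;
    else if (it->second < 3) ++(it->second);
    map_step(p, x, y, z, 0.0);
    if (((long long)t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(m_finest, 3);
  // NOTE: counts capped at 3, enough for f1/f2; coarser levels need true
  // sums, so re-aggregate capped counts (f1/f2 at coarser levels are only
  // approximate lower bounds when fine counts saturate; exact when a coarse
  // box contains a single occupied fine box)
  std::vector<std::pair<int64_t,int>> keys(fine.begin(), fine.end());
  for (int m = m_finest; m >= 1; --m) {
    int shift = m_finest - m;
    std::unordered_map<int64_t, int> coarse;
    coarse.reserve(keys.size());
    for (auto& kv : keys) {
      int64_t ix = (kv.first >> 22) >> shift,
              iy = (kv.first & 0x3FFFFF) >> shift;
      int64_t k = (ix << 22) | iy;
      auto it = coarse.find(k);
      if (it == coarse.end()) coarse[k] = kv.second;
      else it->second = std::min(3, it->second + kv.second);
    }
    double Nobs = (double)coarse.size(), f1 = 0, f2 = 0;
    for (auto& kv : coarse) {
      if (kv.second == 1) f1 += 1;
      else if (kv.second == 2) f2 += 1;
    }
    out(m - 1, 0) = Nobs; out(m - 1, 1) = f1; out(m - 1, 2) = f2;
  }
  colnames(out) = CharacterVector::create("N_obs", "f1", "f2");
  return List::create(_["m"] = seq_len(m_finest), _["table"] = out,
                      _["n_points"] = n_steps);
}

// gap-junction network; topology: 0 = directed chain (i -> i+1),
// 1 = complete graph, 2 = undirected pair (N = 2)
// I_ext (optional) is injected into neuron 0 only.
// Returns x(t) for all neurons, n_steps x N, after discarding `discard`.
// [[Rcpp::export]]
NumericMatrix network_cpp(NumericVector par, int gain, int topology, double G,
                          NumericMatrix init, int n_steps, int discard,
                          NumericVector I_ext) {
  Par p = unpack(par, gain);
  const int N = init.nrow();
  const int total = n_steps + discard;
  const bool has_I = I_ext.size() > 0;
  if (has_I && I_ext.size() < total) stop("I_ext shorter than simulation");
  std::vector<double> x(N), y(N), z(N), Isyn(N), nx(N), nz(N);
  for (int i = 0; i < N; ++i) { x[i] = init(i,0); y[i] = init(i,1); z[i] = init(i,2); }
  NumericMatrix out(n_steps, N);

  for (int t = 0; t < total; ++t) {
    if (t >= discard)
      for (int i = 0; i < N; ++i) out(t - discard, i) = x[i];
    // 1) synaptic signals from OLD potentials, 2) sum per neuron
    if (topology == 0) {
      Isyn[0] = 0.0;
      for (int i = 1; i < N; ++i) Isyn[i] = G * (x[i-1] - x[i]);
    } else if (topology == 1) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += x[i];
      for (int i = 0; i < N; ++i) Isyn[i] = G * (s - N * x[i]);
    } else {
      Isyn[0] = G * (x[1] - x[0]);
      Isyn[1] = G * (x[0] - x[1]);
    }
    if (has_I) Isyn[0] += I_ext[t];
    // 3) advance every neuron synchronously
    for (int i = 0; i < N; ++i) {
      double u = (x[i] - p.K * y[i] + z[i] + p.H + Isyn[i]) / p.T;
      nx[i] = gain_f(u, p.g);
      nz[i] = (1.0 - p.del) * z[i] - p.lam * (x[i] - p.xR);
    }
    for (int i = 0; i < N; ++i) { y[i] = x[i]; x[i] = nx[i]; z[i] = nz[i]; }
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
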