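// Core sifting / EMD / CEEMDAN routines.
//
// Envelopes are natural cubic splines through the extrema, with two extrema
// mirrored past each end of the series to suppress spline edge swing.  The
// sifting stop is the Cauchy-type SD criterion.  CEEMDAN follows the Torres
// scheme: the k-th mode is the ensemble mean of the first EMD mode of
// (current residual + eps_k * k-1-th EMD mode of the noise realization),
// with raw noise used at the first stage.  Noise is generated by the caller
// so that all randomness flows through R's RNG.
//
// All scratch vectors live in a per-call workspace: sifting converges in a
// handful of iterations, so allocation would otherwise dominate runtime.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Workspace {
  std::vector<int> imax, imin;
  std::vector<double> tu, yu, tl, yl, upper, lower;
  std::vector<double> sh, sa, sb, sc, sd, sM;    // spline scratch
  std::vector<double> h, env, y, acc;
};

// locate strict interior extrema; plateaus take their midpoint
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  imax.clear(); imin.clear();
  const int n = (int)x.size();
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[j]) ++j;      // plateau
      if (j < n - 1 && x[j + 1] < x[j]) imax.push_back((i + j) / 2);
      i = j + 1;
    } else if (x[i] < x[i - 1]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[j]) ++j;
      if (j < n - 1 && x[j + 1] > x[j]) imin.push_back((i + j) / 2);
      i = j + 1;
    } else {
      ++i;
    }
  }
}

static int count_zero_crossings(const std::vector<double>& x) {
  int cnt = 0;
  double prev = 0.0;
  for (size_t i = 0; i < x.size(); ++i) {
    if (x[i] == 0.0) continue;
    if (prev != 0.0 && ((prev > 0) != (x[i] > 0))) ++cnt;
    prev = x[i];
  }
  return cnt;
}

// natural cubic spline through (t, y), evaluated at integers 0..n-1
static void spline_eval(const std::vector<double>& t, const std::vector<double>& y,
                        int n, std::vector<double>& out, Workspace& ws) {
  const int m = (int)t.size();
  out.resize(n);
  if (m == 1) { std::fill(out.begin(), out.end(), y[0]); return; }
  if (m == 2) {
    const double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = y[0] + slope * (i - t[0]);
    return;
  }
  // second derivatives via the Thomas algorithm, natural BCs
  std::vector<double>& h = ws.sh; std::vector<double>& a = ws.sa;
  std::vector<double>& b = ws.sb; std::vector<double>& c = ws.sc;
  std::vector<double>& d = ws.sd; std::vector<double>& M = ws.sM;
  h.resize(m - 1); a.assign(m, 0.0); b.assign(m, 0.0); c.assign(m, 0.0);
  d.assign(m, 0.0); M.resize(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  b[0] = 1.0; b[m - 1] = 1.0;
  for (int i = 1; i < m - 1; ++i) {
    a[i] = h[i - 1];
    b[i] = 2.0 * (h[i - 1] + h[i]);
    c[i] = h[i];
    d[i] = 6.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  }
  for (int i = 1; i < m; ++i) {
    const double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  M[m - 1] = d[m - 1] / b[m - 1];
  for (int i = m - 2; i >= 0; --i) M[i] = (d[i] - c[i] * M[i + 1]) / b[i];
  // single sweep: evaluation points are the sorted integers 0..n-1
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    const double xv = (double)i;
    while (seg < m - 2 && xv > t[seg + 1]) ++seg;
    const double hl = h[seg];
    const double A = (t[seg + 1] - xv) / hl, B = (xv - t[seg]) / hl;
    out[i] = A * y[seg] + B * y[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * hl * hl / 6.0;
  }
}

// knot list with two extrema mirrored beyond each end
static void mirrored_knots(const std::vector<int>& idx, const std::vector<double>& x,
                           int n, std::vector<double>& t, std::vector<double>& y) {
  t.clear(); y.clear();
  const int m = (int)idx.size();
  const int l0 = idx[0], l1 = idx[std::min(1, m - 1)];
  const int r0 = idx[m - 1], r1 = idx[std::max(m - 2, 0)];
  // left mirror about sample 0
  if (-l1 < -l0) { t.push_back(-(double)l1); y.push_back(x[l1]); }
  if (-l0 < l0)  { t.push_back(-(double)l0); y.push_back(x[l0]); }
  for (int k = 0; k < m; ++k) { t.push_back((double)idx[k]); y.push_back(x[idx[k]]); }
  const double e = (double)(n - 1);
  if (2 * e - r0 > r0) { t.push_back(2 * e - r0); y.push_back(x[r0]); }
  if (2 * e - r1 > 2 * e - r0) { t.push_back(2 * e - r1); y.push_back(x[r1]); }
}

// one mean-envelope computation; returns false when too few extrema
static bool mean_envelope(const std::vector<double>& x, std::vector<double>& env,
                          Workspace& ws) {
  find_extrema(x, ws.imax, ws.imin);
  if (ws.imax.size() < 2 || ws.imin.size() < 2) return false;
  const int n = (int)x.size();
  mirrored_knots(ws.imax, x, n, ws.tu, ws.yu);
  mirrored_knots(ws.imin, x, n, ws.tl, ws.yl);
  spline_eval(ws.tu, ws.yu, n, ws.upper, ws);
  spline_eval(ws.tl, ws.yl, n, ws.lower, ws);
  env.resize(n);
  for (int i = 0; i < n; ++i) env[i] = 0.5 * (ws.upper[i] + ws.lower[i]);
  return true;
}

// sift x down to a candidate IMF in ws.h; returns iterations used
static int sift_core(const std::vector<double>& x, double sd_thresh,
                     int max_iters, Workspace& ws) {
  ws.h = x;
  int it = 0;
  while (it < max_iters) {
    if (!mean_envelope(ws.h, ws.env, ws)) break;
    double num = 0.0, den = 0.0;
    for (size_t i = 0; i < ws.h.size(); ++i) {
      num += ws.env[i] * ws.env[i];
      den += ws.h[i] * ws.h[i];
    }
    for (size_t i = 0; i < ws.h.size(); ++i) ws.h[i] -= ws.env[i];
    ++it;
    if (den <= 0.0 || num / den < sd_thresh) break;
  }
  return it;
}

static bool is_siftable(const std::vector<double>& x, Workspace& ws) {
  find_extrema(x, ws.imax, ws.imin);
  return ws.imax.size() >= 2 && ws.imin.size() >= 2;
}

// [[Rcpp::export(name = ".sift_cpp")]]
List sift_cpp(NumericVector x, double sd_thresh, int max_iters) {
  Workspace ws;
  std::vector<double> xv(x.begin(), x.end());
  if (!is_siftable(xv, ws))
    return List::create(_["ok"] = false, _["imf"] = NumericVector(0),
                        _["iters"] = 0, _["converged"] = false);
  int it = sift_core(xv, sd_thresh, max_iters, ws);
  find_extrema(ws.h, ws.imax, ws.imin);
  int next = (int)(ws.imax.size() + ws.imin.size());
  int nzc = count_zero_crossings(ws.h);
  return List::create(_["ok"] = true,
                      _["imf"] = NumericVector(ws.h.begin(), ws.h.end()),
                      _["iters"] = it, _["converged"] = it < max_iters,
                      _["n_extrema"] = next, _["n_zero_crossings"] = nzc,
                      _["imf_condition"] = std::abs(next - nzc) <= 1);
}

static int emd_core(const std::vector<double>& x, int max_imfs, double sd_thresh,
                    int max_iters, std::vector< std::vector<double> >& imfs,
                    std::vector<double>& resid, Workspace& ws) {
  resid = x;
  imfs.clear();
  for (int k = 0; k < max_imfs; ++k) {
    if (!is_siftable(resid, ws)) break;
    sift_core(resid, sd_thresh, max_iters, ws);
    imfs.push_back(ws.h);
    for (size_t i = 0; i < resid.size(); ++i) resid[i] -= ws.h[i];
  }
  return (int)imfs.size();
}

static NumericMatrix pack_imfs(const std::vector< std::vector<double> >& imfs, int n) {
  NumericMatrix m((int)imfs.size(), n);
  for (size_t k = 0; k < imfs.size(); ++k)
    for (int i = 0; i < n; ++i) m((int)k, i) = imfs[k][i];
  return m;
}

// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_imfs, double sd_thresh, int max_iters) {
  Workspace ws;
  std::vector<double> xv(x.begin(), x.end());
  std::vector< std::vector<double> > imfs;
  std::vector<double> resid;
  emd_core(xv, max_imfs, sd_thresh, max_iters, imfs, resid, ws);
  return List::create(_["imfs"] = pack_imfs(imfs, (int)xv.size()),
                      _["residual"] = NumericVector(resid.begin(), resid.end()));
}

static double pop_sd(const std::vector<double>& x) {
  double mu = 0.0;
  for (double v : x) mu += v;
  mu /= x.size();
  double s = 0.0;
  for (double v : x) s += (v - mu) * (v - mu);
  return std::sqrt(s / x.size());
}

// noise: n x I matrix of unit-variance realizations supplied by the caller
// [[Rcpp::export(name = ".ceemdan_cpp")]]
List ceemdan_cpp(NumericVector x, NumericMatrix noise, double noise_scale,
                 int max_imfs, double sd_thresh, int max_iters) {
  Workspace ws;
  const int n = x.size(), I = noise.ncol();
  std::vector<double> xv(x.begin(), x.end());
  const double sdx = pop_sd(xv);
  std::vector< std::vector<double> > imfs;
  std::vector<double> resid(xv);
  if (sdx == 0.0 || !is_siftable(xv, ws)) {
    return List::create(_["imfs"] = pack_imfs(imfs, n),
                        _["residual"] = NumericVector(resid.begin(), resid.end()));
  }
  // EMD of each noise realization, reused across stages
  std::vector< std::vector< std::vector<double> > > wmodes(I);
  std::vector<double> wres;
  std::vector<double> w(n);
  for (int i = 0; i < I; ++i) {
    for (int j = 0; j < n; ++j) w[j] = noise(j, i);
    emd_core(w, max_imfs, sd_thresh, max_iters, wmodes[i], wres, ws);
  }
  ws.y.resize(n);
  ws.acc.resize(n);
  for (int k = 0; k < max_imfs; ++k) {
    if (!is_siftable(resid, ws)) break;
    const double eps = noise_scale * (k == 0 ? sdx : pop_sd(resid));
    std::fill(ws.acc.begin(), ws.acc.end(), 0.0);
    for (int i = 0; i < I; ++i) {
      bool have_noise = (k == 0) || ((int)wmodes[i].size() >= k);
      for (int j = 0; j < n; ++j) {
        double nz = k == 0 ? noise(j, i) : (have_noise ? wmodes[i][k - 1][j] : 0.0);
        ws.y[j] = resid[j] + eps * nz;
      }
      if (is_siftable(ws.y, ws)) {
        sift_core(ws.y, sd_thresh, max_iters, ws);
        for (int j = 0; j < n; ++j) ws.acc[j] += ws.h[j];
      } else {
        for (int j = 0; j < n; ++j) ws.acc[j] += ws.y[j];
      }
    }
    std::vector<double> imf(n);
    for (int j = 0; j < n; ++j) imf[j] = ws.acc[j] / I;
    imfs.push_back(imf);
    for (int j = 0; j < n; ++j) resid[j] -= imf[j];
  }
  return List::create(_["imfs"] = pack_imfs(imfs, n),
                      _["residual"] = NumericVector(resid.begin(), resid.end()));
}
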