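// Sliding-window texture feature sweep.
//
// Computes, for each requested pixel, the 21 window-texture features
// (5 FOS + 7 GLCM + 5 NGTDM + 4 FD log-counts) with the same definitions as
// the single-window R functions (fos_features, glcm_features,
// ngtdm_features, fd_features).  Windows wrap circularly across the angular
// seam (rows) and clip at the depth edges (columns).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS = 1e-12;

struct Window {
  int wr, wc;
  std::vector<double> raw;  // column-major wr x wc
  std::vector<int> q;
};

static void fill_window(const NumericMatrix& img, const IntegerMatrix& qm,
                        int row0, int col0, int half, Window& w) {
  int n_r = img.nrow(), n_c = img.ncol();
  int c_lo = std::max(0, col0 - half), c_hi = std::min(n_c - 1, col0 + half);
  w.wr = 2 * half + 1;
  w.wc = c_hi - c_lo + 1;
  w.raw.resize((size_t)w.wr * w.wc);
  w.q.resize((size_t)w.wr * w.wc);
  for (int dc = 0; dc < w.wc; ++dc) {
    int cc = c_lo + dc;
    for (int dr = 0; dr < w.wr; ++dr) {
      int rr = ((row0 - half + dr) % n_r + n_r) % n_r;
      w.raw[dr + (size_t)dc * w.wr] = img(rr, cc);
      w.q[dr + (size_t)dc * w.wr] = qm(rr, cc);
    }
  }
}

static void fos(const Window& w, double* out) {
  size_t n = w.raw.size();
  long double acc = 0;
  for (size_t k = 0; k < n; ++k) acc += w.raw[k];
  double m = (double)(acc / n);
  long double a2 = 0, a3 = 0, a4 = 0;
  for (size_t k = 0; k < n; ++k) {
    double d = w.raw[k] - m;
    a2 += d * d; a3 += d * d * d; a4 += d * d * d * d;
  }
  double v = (double)(a2 / n);
  std::vector<double> s(w.raw);
  std::sort(s.begin(), s.end());
  double med = (n % 2) ? s[n / 2] : 0.5 * (s[n / 2 - 1] + s[n / 2]);
  double sk = 0, ku = 0;
  if (v >= 1e-300) {
    sk = (double)(a3 / n) / std::pow(v, 1.5);
    ku = (double)(a4 / n) / (v * v);
  }
  out[0] = m; out[1] = v; out[2] = med; out[3] = sk; out[4] = ku;
}

static void glcm(const Window& w, int levels, double* out) {
  static const int offs[4][2] = {{0, 1}, {-1, 1}, {-1, 0}, {-1, -1}};
  std::vector<double> P((size_t)levels * levels);
  std::vector<double> pi_m(levels), pj_m(levels);
  double acc[7] = {0, 0, 0, 0, 0, 0, 0};
  for (int a = 0; a < 4; ++a) {
    std::fill(P.begin(), P.end(), 0.0);
    int dr = offs[a][0], dc = offs[a][1];
    int r_lo = std::max(0, -dr), r_hi = std::min(w.wr - 1, w.wr - 1 - dr);
    int c_lo = std::max(0, -dc), c_hi = std::min(w.wc - 1, w.wc - 1 - dc);
    double tot = 0;
    for (int i = r_lo; i <= r_hi; ++i)
      for (int j = c_lo; j <= c_hi; ++j) {
        int g1 = w.q[i + (size_t)j * w.wr] - 1;
        int g2 = w.q[(i + dr) + (size_t)(j + dc) * w.wr] - 1;
        P[g1 + (size_t)g2 * levels] += 1;
        P[g2 + (size_t)g1 * levels] += 1;
        tot += 2;
      }
    if (tot > 0)
      for (auto& p : P) p /= tot;
    std::fill(pi_m.begin(), pi_m.end(), 0.0);
    std::fill(pj_m.begin(), pj_m.end(), 0.0);
    for (int jj = 0; jj < levels; ++jj)
      for (int ii = 0; ii < levels; ++ii) {
        double p = P[ii + (size_t)jj * levels];
        pi_m[ii] += p; pj_m[jj] += p;
      }
    double mu_i = 0, mu_j = 0;
    for (int t = 0; t < levels; ++t) {
      mu_i += (t + 1) * pi_m[t]; mu_j += (t + 1) * pj_m[t];
    }
    double s_i = 0, s_j = 0;
    for (int t = 0; t < levels; ++t) {
      s_i += (t + 1 - mu_i) * (t + 1 - mu_i) * pi_m[t];
      s_j += (t + 1 - mu_j) * (t + 1 - mu_j) * pj_m[t];
    }
    s_i = std::sqrt(s_i); s_j = std::sqrt(s_j);
    long double corr = 0, contrast = 0, dissim = 0, energy = 0,
                entropy = 0, homog = 0;
    double maxp = 0;
    for (int jj = 0; jj < levels; ++jj)
      for (int ii = 0; ii < levels; ++ii) {
        double p = P[ii + (size_t)jj * levels];
        double d = (double)(ii - jj);
        contrast += d * d * p;
        dissim += std::fabs(d) * p;
        energy += p * p;
        homog += p / (1.0 + d * d);
        if (p > 0) entropy -= p * std::log2(p);
        if (p > maxp) maxp = p;
        corr += (ii + 1 - mu_i) * (jj + 1 - mu_j) * p;
      }
    double corr_v = (s_i < 1e-300 || s_j < 1e-300)
                        ? 1.0 : (double)corr / (s_i * s_j);
    acc[0] += corr_v; acc[1] += (double)contrast; acc[2] += (double)dissim;
    acc[3] += (double)energy; acc[4] += (double)entropy;
    acc[5] += (double)homog; acc[6] += maxp;
  }
  for (int k = 0; k < 7; ++k) out[k] = acc[k] / 4.0;
}

static void ngtdm(const Window& w, int levels, double* out) {
  std::vector<double> s(levels + 1, 0.0);
  std::vector<double> cnt(levels + 1, 0.0);
  int N = 0;
  for (int i = 1; i < w.wr - 1; ++i)
    for (int j = 1; j < w.wc - 1; ++j) {
      int g = w.q[i + (size_t)j * w.wr];
      int sum = 0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          sum += w.q[(i + di) + (size_t)(j + dj) * w.wr];
      double a_bar = (sum - g) / 8.0;
      s[g] += std::fabs((double)g - a_bar);
      cnt[g] += 1; ++N;
    }
  std::vector<int> tones;
  for (int t = 1; t <= levels; ++t)
    if (cnt[t] > 0) tones.push_back(t);
  int Ng = (int)tones.size();
  double sps = 0, ssum = 0;
  for (int t : tones) { sps += (cnt[t] / N) * s[t]; ssum += s[t]; }
  double coarse = 1.0 / (EPS + sps);
  if (Ng <= 1 || N == 0) {
    out[0] = 0; out[1] = 0; out[2] = 0; out[3] = coarse; out[4] = 0;
    return;
  }
  long double contr_pp = 0, busy_den = 0, compl_ = 0, str_num = 0;
  for (int a = 0; a < Ng; ++a) {
    double pa = cnt[tones[a]] / N, ta = tones[a];
    for (int b = 0; b < Ng; ++b) {
      double pb = cnt[tones[b]] / N, tb = tones[b];
      double d = ta - tb;
      contr_pp += pa * pb * d * d;
      busy_den += std::fabs(ta * pa - tb * pb);
      compl_ += std::fabs(d) / (N * (pa + pb)) *
                (pa * s[tones[a]] + pb * s[tones[b]]);
      str_num += (pa + pb) * d * d;
    }
  }
  double contr = ((double)contr_pp / (Ng * (Ng - 1))) * (ssum / N);
  double busy = (busy_den < EPS) ? 0 : sps / (double)busy_den;
  out[0] = busy; out[1] = contr; out[2] = (double)compl_;
  out[3] = coarse; out[4] = (double)str_num / (EPS + ssum);
}

static void fd(const Window& w, const IntegerVector& scales,
               double gmin, double gmax, double* out) {
  int M = std::min(w.wr, w.wc);
  double G = gmax - gmin;
  for (int k = 0; k < scales.size(); ++k) {
    int s = scales[k];
    double h = s * G / M;
    long double tot = 0;
    for (int r0 = 0; r0 < w.wr; r0 += s)
      for (int c0 = 0; c0 < w.wc; c0 += s) {
        double cmin = R_PosInf, cmax = R_NegInf;
        for (int i = r0; i < std::min(r0 + s, w.wr); ++i)
          for (int j = c0; j < std::min(c0 + s, w.wc); ++j) {
            double v = w.raw[i + (size_t)j * w.wr];
            if (v < cmin) cmin = v;
            if (v > cmax) cmax = v;
          }
        if (h <= 0) { tot += 1; continue; }
        tot += std::ceil((cmax - gmin) / h) - std::ceil((cmin - gmin) / h) + 1;
      }
    out[k] = std::log((double)tot);
  }
}

// [[Rcpp::export]]
NumericMatrix texture_sweep_cpp(NumericMatrix img, IntegerMatrix q,
                                int levels, IntegerVector rows0,
                                IntegerVector cols0, int window_px,
                                IntegerVector scales, double gmin,
                                double gmax) {
  int n = rows0.size();
  int half = window_px / 2;
  int nf = 17 + scales.size();
  NumericMatrix out(n, nf);
  Window w;
  std::vector<double> row(nf);
  for (int k = 0; k < n; ++k) {
    fill_window(img, q, rows0[k], cols0[k], half, w);
    fos(w, row.data());
    glcm(w, levels, row.data() + 5);
    ngtdm(w, levels, row.data() + 12);
    fd(w, scales, gmin, gmax, row.data() + 17);
    for (int f = 0; f < nf; ++f) out(k, f) = row[f];
  }
  return out;
}
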