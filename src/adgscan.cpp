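#include <Rcpp.h>
#include <cmath>
#include <climits>
#include <vector>
using namespace Rcpp;

// Lattice dynamic program over the PWM score distribution under a
// 0-order background. Scores (bits) are rounded to the nearest multiple
// of `granularity`; the distribution of the rounded column sum is exact.
// logodds: W x 4 matrix (bits); bg: length-4 background probabilities.
// [[Rcpp::export]]
List cpp_score_dist_lattice(NumericMatrix logodds, NumericVector bg,
                            double granularity) {
  if (granularity <= 0.0) stop("granularity must be > 0");
  int W = logodds.nrow();
  if (logodds.ncol() != 4) stop("logodds must have 4 columns");
  std::vector<std::vector<long> > K(W, std::vector<long>(4));
  std::vector<long> mins(W), maxs(W);
  for (int w = 0; w < W; ++w) {
    long mn = LONG_MAX, mx = LONG_MIN;
    for (int b = 0; b < 4; ++b) {
      double lo = logodds(w, b);
      if (!std::isfinite(lo))
        stop("non-finite log-odds score; use a positive pseudocount");
      long k = (long) std::llround(lo / granularity);
      K[w][b] = k;
      if (k < mn) mn = k;
      if (k > mx) mx = k;
    }
    mins[w] = mn; maxs[w] = mx;
  }
  double total = 0.0;
  for (int w = 0; w < W; ++w) total += (double)(maxs[w] - mins[w]);
  if (total > 2e8) stop("score lattice too large; increase granularity");

  std::vector<double> prev(1, 1.0);
  long runMin = 0;
  for (int w = 0; w < W; ++w) {
    long colMin = mins[w], colMax = maxs[w];
    std::vector<double> next(prev.size() + (size_t)(colMax - colMin), 0.0);
    for (int b = 0; b < 4; ++b) {
      double p = bg[b];
      size_t off = (size_t)(K[w][b] - colMin);
      for (size_t i = 0; i < prev.size(); ++i) {
        double v = prev[i];
        if (v > 0.0) next[i + off] += v * p;
      }
    }
    prev.swap(next);
    runMin += colMin;
  }
  NumericVector pmf(prev.size()), support(prev.size());
  for (size_t i = 0; i < prev.size(); ++i) {
    pmf[i] = prev[i];
    support[i] = (double)((long)i + runMin) * granularity;
  }
  return List::create(_["support"] = support, _["pmf"] = pmf);
}

// Exhaustive-substring ZOOPS seed screen. Every valid width-W substring
// of every region is evaluated as a one-site seed under a two-value
// match/mismatch log-odds model; the seed with the best ZOOPS
// log-likelihood (base 2, relative to the all-background model) wins.
// Regions are integer-coded A=0,C=1,G=2,T=3, N(or masked)=4; windows and
// seeds containing code 4 are skipped. The match-count computation walks
// diagonals of each region pair so the cost per (seed, window) pair is
// O(1) amortized.
// [[Rcpp::export]]
List cpp_seed_screen(List regions, int W, double match_lod,
                     double mismatch_lod, double gamma) {
  int nR = regions.size();
  std::vector<std::vector<int> > X(nR);
  std::vector<int> len(nR), nwin(nR), mvalid(nR, 0);
  std::vector<std::vector<bool> > valid(nR);
  for (int r = 0; r < nR; ++r) {
    IntegerVector v = regions[r];
    X[r].assign(v.begin(), v.end());
    len[r] = v.size();
    int nw = len[r] - W + 1; if (nw < 0) nw = 0;
    nwin[r] = nw;
    valid[r].assign(nw, false);
    std::vector<int> pn(len[r] + 1, 0);
    for (int i = 0; i < len[r]; ++i) pn[i + 1] = pn[i] + (X[r][i] > 3 ? 1 : 0);
    for (int j = 0; j < nw; ++j)
      if (pn[j + W] - pn[j] == 0) { valid[r][j] = true; mvalid[r]++; }
  }
  double delta = match_lod - mismatch_lod;
  std::vector<double> pow2(W + 1);
  for (int m = 0; m <= W; ++m) pow2[m] = std::pow(2.0, delta * m);
  double CW = std::pow(2.0, (double)W * mismatch_lod);

  double bestLL = R_NegInf;
  int bestR = -1, bestOff = -1;
  for (int s = 0; s < nR; ++s) {
    int ns = nwin[s];
    if (ns <= 0 || mvalid[s] == 0) continue;
    std::vector<double> S((size_t)ns * nR, 0.0);
    for (int t = 0; t < nR; ++t) {
      if (nwin[t] <= 0) continue;
      const std::vector<int>& xs = X[s];
      const std::vector<int>& xt = X[t];
      int Ls = len[s], Lt = len[t];
      for (int d = -(Lt - 1); d <= Ls - 1; ++d) {
        int i0 = d > 0 ? d : 0;
        int j0 = d > 0 ? 0 : -d;
        int L = std::min(Ls - i0, Lt - j0);
        if (L < W) continue;
        int m = 0;
        for (int k = 0; k < W; ++k)
          m += (xs[i0 + k] == xt[j0 + k] && xs[i0 + k] < 4) ? 1 : 0;
        for (int k = 0;; ++k) {
          int i = i0 + k, j = j0 + k;
          if (valid[t][j]) S[(size_t)i * nR + t] += pow2[m];
          if (k == L - W) break;
          m -= (xs[i0 + k] == xt[j0 + k] && xs[i0 + k] < 4) ? 1 : 0;
          m += (xs[i0 + k + W] == xt[j0 + k + W] && xs[i0 + k + W] < 4) ? 1 : 0;
        }
      }
    }
    for (int i = 0; i < ns; ++i) {
      if (!valid[s][i]) continue;
      double ll = 0.0;
      for (int t = 0; t < nR; ++t) {
        if (mvalid[t] <= 0) continue;
        double inner = (1.0 - gamma) +
          (gamma / (double)mvalid[t]) * CW * S[(size_t)i * nR + t];
        ll += std::log2(inner);
      }
      if (ll > bestLL) { bestLL = ll; bestR = s; bestOff = i; }
    }
  }
  return List::create(_["region"] = bestR + 1, _["offset"] = bestOff + 1,
                      _["loglik"] = bestLL);
}

// Per-offset PWM log-odds scores for every region; windows containing
// code 4 (N/masked) score -Inf.
// [[Rcpp::export]]
List cpp_window_scores(List regions, NumericMatrix logodds) {
  int W = logodds.nrow();
  int nR = regions.size();
  List out(nR);
  for (int r = 0; r < nR; ++r) {
    IntegerVector x = regions[r];
    int L = x.size();
    int nw = L - W + 1; if (nw < 0) nw = 0;
    NumericVector sc(nw);
    for (int j = 0; j < nw; ++j) {
      double s = 0.0; bool ok = true;
      for (int k = 0; k < W; ++k) {
        int b = x[j + k];
        if (b > 3) { ok = false; break; }
        s += logodds(k, b);
      }
      sc[j] = ok ? s : R_NegInf;
    }
    out[r] = sc;
  }
  return out;
}

// Posterior-weighted base counts for the ZOOPS M-step.
// z: per-region numeric vectors of site posteriors per offset.
// [[Rcpp::export]]
NumericMatrix cpp_weighted_counts(List regions, List z, int W) {
  int nR = regions.size();
  NumericMatrix cnt(W, 4);
  for (int r = 0; r < nR; ++r) {
    IntegerVector x = regions[r];
    NumericVector zz = z[r];
    int nw = zz.size();
    for (int j = 0; j < nw; ++j) {
      double w = zz[j];
      if (w <= 0.0) continue;
      for (int k = 0; k < W; ++k) {
        int b = x[j + k];
        if (b < 4) cnt(k, b) += w;
      }
    }
  }
  return cnt;
}
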