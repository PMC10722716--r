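#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding-window peak-to-peak range of a series: out[i] = max(x[i..i+w-1]) -
// min(x[i..i+w-1]), computed in O(n) with monotonic deques.
// [[Rcpp::export]]
NumericVector window_ranges(NumericVector x, int w) {
  int n = x.size();
  if (w < 1 || w > n) stop("window length out of range");
  int m = n - w + 1;
  NumericVector out(m);
  std::deque<int> mx, mn;
  for (int i = 0; i < n; ++i) {
    while (!mx.empty() && x[mx.back()] <= x[i]) mx.pop_back();
    mx.push_back(i);
    while (!mn.empty() && x[mn.back()] >= x[i]) mn.pop_back();
    mn.push_back(i);
    int lo = i - w + 1;
    if (lo >= 0) {
      while (mx.front() < lo) mx.pop_front();
      while (mn.front() < lo) mn.pop_front();
      out[lo] = x[mx.front()] - x[mn.front()];
    }
  }
  return out;
}

// Artifact rejection over an [epoch, channel, sample] array (R array layout,
// epoch index fastest). Returns per-epoch code: 0 = keep, 1 = max-diff rule
// (some channel's w_diff-sample window has range > thr_diff), 2 = low-activity
// rule (some channel's w_flat-sample window has range < thr_flat).
// The max-diff rule takes precedence when both fire.
// [[Rcpp::export]]
IntegerVector epoch_reject_core(NumericVector data, int n_epochs,
                                int n_channels, int n_samples,
                                int w_diff, double thr_diff,
                                int w_flat, double thr_flat) {
  IntegerVector code(n_epochs);
  std::vector<double> x(n_samples);
  for (int e = 0; e < n_epochs; ++e) {
    bool maxdiff = false, flat = false;
    for (int c = 0; c < n_channels && !maxdiff; ++c) {
      for (int s = 0; s < n_samples; ++s)
        x[s] = data[e + (R_xlen_t)n_epochs * (c + (R_xlen_t)n_channels * s)];
      std::deque<int> mx, mn;
      // single pass; track both window lengths (w_flat <= w_diff not assumed)
      for (int rule = 0; rule < 2; ++rule) {
        int w = rule == 0 ? w_diff : w_flat;
        if (w > n_samples) continue;
        mx.clear(); mn.clear();
        bool hit = false;
        for (int i = 0; i < n_samples; ++i) {
          while (!mx.empty() && x[mx.back()] <= x[i]) mx.pop_back();
          mx.push_back(i);
          while (!mn.empty() && x[mn.back()] >= x[i]) mn.pop_back();
          mn.push_back(i);
          int lo = i - w + 1;
          if (lo >= 0) {
            while (mx.front() < lo) mx.pop_front();
            while (mn.front() < lo) mn.pop_front();
            double rng = x[mx.front()] - x[mn.front()];
            if (rule == 0 ? (rng > thr_diff) : (rng < thr_flat)) {
              hit = true; break;
            }
          }
        }
        if (rule == 0 && hit) { maxdiff = true; break; }
        if (rule == 1 && hit) flat = true;
      }
    }
    code[e] = maxdiff ? 1 : (flat ? 2 : 0);
  }
  return code;
}
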