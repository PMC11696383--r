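#include <Rcpp.h>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Local-maximum candidates: interior samples with v[i] > v[i-1] and
// v[i] >= v[i+1] (the leftmost sample of a flat-topped plateau qualifies),
// their topographic prominences, and greedy taller-first selection under a
// minimum separation.  Works in sample indices; the R wrapper converts
// seconds to samples.
//
// Prominence of a peak at i: walk outward on each side to the nearest
// strictly higher sample (or the record edge), take the minimum value seen
// on each side, and subtract the higher of the two minima from the peak
// height.

// [[Rcpp::export]]
List detect_peaks_cpp(NumericVector v, double min_prominence,
                      double min_height, int min_sep_samples) {
  const int n = v.size();
  std::vector<int> cand;
  for (int i = 1; i + 1 < n; ++i) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1]) cand.push_back(i);
  }

  std::vector<int> kept;
  std::vector<double> prom;
  kept.reserve(cand.size());
  prom.reserve(cand.size());
  for (size_t c = 0; c < cand.size(); ++c) {
    const int i = cand[c];
    const double h = v[i];
    if (h < min_height) continue;
    double left_min = h;
    for (int j = i - 1; j >= 0; --j) {
      if (v[j] > h) break;
      if (v[j] < left_min) left_min = v[j];
    }
    double right_min = h;
    for (int j = i + 1; j < n; ++j) {
      if (v[j] > h) break;
      if (v[j] < right_min) right_min = v[j];
    }
    const double p = h - std::max(left_min, right_min);
    if (p < min_prominence) continue;
    kept.push_back(i);
    prom.push_back(p);
  }

  // taller-first greedy selection; ties broken toward the earlier peak
  const int m = kept.size();
  std::vector<int> order(m);
  for (int k = 0; k < m; ++k) order[k] = k;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[kept[a]] != v[kept[b]]) return v[kept[a]] > v[kept[b]];
    return kept[a] < kept[b];
  });
  std::vector<bool> selected(m, false);
  std::set<int> sel_pos;  // positions of selected peaks, ordered
  for (int k = 0; k < m; ++k) {
    const int cidx = order[k];
    const int pos = kept[cidx];
    bool blocked = false;
    std::set<int>::iterator it = sel_pos.lower_bound(pos);
    if (it != sel_pos.end() && *it - pos < min_sep_samples) blocked = true;
    if (!blocked && it != sel_pos.begin() &&
        pos - *std::prev(it) < min_sep_samples) {
      blocked = true;
    }
    if (!blocked) {
      selected[cidx] = true;
      sel_pos.insert(pos);
    }
  }

  std::vector<int> out_idx;
  std::vector<double> out_prom;
  for (int k = 0; k < m; ++k) {
    if (selected[k]) {
      out_idx.push_back(kept[k] + 1);  // 1-based for R
      out_prom.push_back(prom[k]);
    }
  }
  return List::create(_["indices"] = wrap(out_idx),
                      _["prominences"] = wrap(out_prom));
}

// Direct-form II transposed IIR filter with explicit initial state, the
// building block of the zero-phase (forward-backward) filter.  b and a are
// same-length coefficient vectors with a[0] == 1; zi has length
// length(b) - 1.
// [[Rcpp::export]]
NumericVector iir_df2t_cpp(NumericVector b, NumericVector a, NumericVector x,
                           NumericVector zi) {
  const int n = x.size();
  const int order = b.size() - 1;
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (order > 0 ? z[0] : 0.0);
    for (int k = 0; k < order - 1; ++k) {
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    }
    if (order > 0) z[order - 1] = b[order] * xi - a[order] * yi;
    y[i] = yi;
  }
  return y;
}
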