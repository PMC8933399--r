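#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of the first n entries of buf (buf is scratch, modified in place)
static double median_of(std::vector<double>& buf, int n) {
  int h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
  double m = buf[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// For each permutation (row of `perms`, 1-based subject indices whose first
// n_high entries form the "high" group), compute per-ROI
// median(high) - median(avg) on the subjects x ROI matrix `metric`, and count
// the ROIs with positive and with negative differences (exact zeros count in
// neither tail).  The per-ROI differences of the first row are returned so
// the caller can use row 1 as the observed labelling.
// [[Rcpp::export]]
List mcs_count_engine(NumericMatrix metric, IntegerMatrix perms, int n_high) {
  const int n_subj = metric.nrow();
  const int n_roi = metric.ncol();
  const int n_perm = perms.nrow();
  const int n_avg = n_subj - n_high;
  if (perms.ncol() != n_subj)
    stop("permutation rows must index all subjects");
  if (n_high < 2 || n_avg < 2)
    stop("need at least 2 subjects per group");

  IntegerVector n_pos(n_perm), n_neg(n_perm);
  NumericVector first_diff(n_roi);
  std::vector<double> bh(n_high), ba(n_avg);

  for (int p = 0; p < n_perm; ++p) {
    int pos = 0, neg = 0;
    for (int r = 0; r < n_roi; ++r) {
      for (int s = 0; s < n_high; ++s)
        bh[s] = metric(perms(p, s) - 1, r);
      for (int s = 0; s < n_avg; ++s)
        ba[s] = metric(perms(p, n_high + s) - 1, r);
      double d = median_of(bh, n_high) - median_of(ba, n_avg);
      if (d > 0) ++pos;
      else if (d < 0) ++neg;
      if (p == 0) first_diff[r] = d;
    }
    n_pos[p] = pos;
    n_neg[p] = neg;
  }
  return List::create(_["n_pos"] = n_pos, _["n_neg"] = n_neg,
                      _["first_diff"] = first_diff);
}
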