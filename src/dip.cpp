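#include <Rcpp.h>
using namespace Rcpp;

// Hartigan & Hartigan's dip statistic for unimodality, computed on a sorted
// sample. The empirical cdf is squeezed between the greatest convex minorant
// (gcm, fitted through the cdf's left limits) and the least concave majorant
// (lcm, fitted through its right values) over a shrinking candidate modal
// interval; the dip is half the largest deviation (in probability units)
// that any unimodal cdf must then incur. Deviations are tracked in counts
// and divided by 2n at the end; outside the modal interval the one-sided
// deviations of the cdf from the hull fits accumulate (a shifted hull splits
// a one-sided deviation evenly, hence the same 1/(2n) scaling).
//
// Count conventions (0-based sorted sample x[0..n-1]):
//   cdf right value at x[i]  : i + 1
//   cdf left limit  at x[i]  : i
//   gcm fitted through (x[i], i); lcm fitted through (x[i], i + 1).
// Hull shapes are computed with y = index; the constant offsets cancel.

static inline double chord_at(const NumericVector& x, int a, int b,
                              double ya, double yb, int i) {
  if (x[b] <= x[a]) return yb;  // vertical (tied) segment: use upper end
  return ya + (x[i] - x[a]) * (yb - ya) / (x[b] - x[a]);
}

// [[Rcpp::export]]
double dip_stat_sorted(NumericVector x) {
  const int n = x.size();
  if (n < 2) return 0.0;
  for (int i = 1; i < n; ++i) {
    if (x[i] < x[i - 1]) stop("input must be sorted");
  }
  if (x[n - 1] == x[0]) return 0.0;

  // hull predecessor chains over the whole sample
  std::vector<int> mn(n), mj(n);
  mn[0] = 0;
  for (int j = 1; j < n; ++j) {
    mn[j] = j - 1;
    while (true) {
      int mnj = mn[j];
      int mnmnj = mn[mnj];
      if (mnj == 0 ||
          (x[j] - x[mnj]) * (mnj - mnmnj) < (x[mnj] - x[mnmnj]) * (j - mnj))
        break;
      mn[j] = mnmnj;
    }
  }
  mj[n - 1] = n - 1;
  for (int k = n - 2; k >= 0; --k) {
    mj[k] = k + 1;
    while (true) {
      int mjk = mj[k];
      int mjmjk = mj[mjk];
      if (mjk == n - 1 ||
          (x[k] - x[mjk]) * (mjk - mjmjk) < (x[mjk] - x[mjmjk]) * (k - mjk))
        break;
      mj[k] = mjmjk;
    }
  }

  int low = 0, high = n - 1;
  double dipv = 1.0;  // in counts; the minimal dip is 1/(2n)

  while (true) {
    // gcm corners ascending low..high; lcm corners ascending low..high
    std::vector<int> gcm, lcm;
    for (int i = high; ; i = mn[i]) { gcm.push_back(i); if (i <= low) break; }
    std::reverse(gcm.begin(), gcm.end());
    for (int i = low; ; i = mj[i]) { lcm.push_back(i); if (i >= high) break; }
    const int ng = (int) gcm.size(), nl = (int) lcm.size();

    // largest gap between the lcm and gcm fits, over corners of either hull
    double d = 0.0;
    int arg_low = low, arg_high = high;
    // gcm corners against the lcm chord containing them
    for (int gi = 0, li = 0; gi < ng; ++gi) {
      int i = gcm[gi];
      while (li < nl - 1 && lcm[li + 1] < i) ++li;
      int a = lcm[li], b = (li < nl - 1) ? lcm[li + 1] : lcm[li];
      double ch = (a == b) ? (a + 1.0)
                           : chord_at(x, a, b, a + 1.0, b + 1.0, i);
      double dx = ch - i;  // lcm fit minus gcm fit at a gcm corner
      if (dx > d) { d = dx; arg_low = i; arg_high = b; }
    }
    // lcm corners against the gcm chord containing them
    for (int li = 0, gi = 0; li < nl; ++li) {
      int i = lcm[li];
      while (gi < ng - 1 && gcm[gi + 1] <= i) ++gi;
      int a = (gi > 0) ? gcm[gi] : gcm[0];
      int c = gcm[gi], dd = (gi < ng - 1) ? gcm[gi + 1] : gcm[gi];
      (void) a;
      double ch = (c == dd) ? (double) c
                            : chord_at(x, c, dd, (double) c, (double) dd, i);
      double dx = (i + 1.0) - ch;  // lcm fit minus gcm fit at an lcm corner
      if (dx > d) { d = dx; arg_low = c; arg_high = i; }
    }

    if (d <= dipv) break;

    // one-sided deviations outside the new modal interval [arg_low, arg_high]
    double dip_l = 0.0;
    for (int gi = 0; gi < ng - 1 && gcm[gi] < arg_low; ++gi) {
      int a = gcm[gi], b = gcm[gi + 1];
      for (int j = a + 1; j < b; ++j) {
        double ch = chord_at(x, a, b, (double) a, (double) b, j);
        double dx = (j + 1.0) - ch;  // cdf right value above the gcm fit
        if (dx > dip_l) dip_l = dx;
      }
    }
    double dip_u = 0.0;
    for (int li = 0; li < nl - 1; ++li) {
      if (lcm[li] < arg_high) continue;
      int a = lcm[li], b = lcm[li + 1];
      for (int j = a + 1; j < b; ++j) {
        double ch = chord_at(x, a, b, a + 1.0, b + 1.0, j);
        double dx = ch - j;          // lcm fit above the cdf left limit
        if (dx > dip_u) dip_u = dx;
      }
    }
    if (dip_l > dipv) dipv = dip_l;
    if (dip_u > dipv) dipv = dip_u;

    if (arg_low == low && arg_high == high) break;  // no further progress
    low = arg_low;
    high = arg_high;
  }
  return dipv / (2.0 * n);
}
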