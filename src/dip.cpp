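#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hartigan & Hartigan's dip statistic.
//
// Works on the sorted sample with the empirical cdf in "count" units (steps
// of 1), iteratively narrowing a modal interval [low, high]:
//   1. build the greatest convex minorant (gcm) and least concave majorant
//      (lcm) of the ecdf on [low, high];
//   2. find the largest vertical gap d between the two hulls (the candidate
//      modal region); if d does not exceed the current dip, stop;
//   3. otherwise measure the maximal ecdf deviation from the gcm chords left
//      of the modal region and from the lcm chords right of it, update the
//      dip, and recurse into the modal region.
// The returned statistic is the count-unit dip divided by 2n, so it lies in
// [1/(2n), 1/4].

static inline double gcm_interp(const NumericVector& x, int a, int b, double xv) {
  // chord of the convex minorant between touch points a < b (1-based counts)
  if (x[b - 1] > x[a - 1])
    return a + (xv - x[a - 1]) * (double)(b - a) / (x[b - 1] - x[a - 1]);
  return a; // vertical tie column: minorant takes the lower count
}

static inline double lcm_interp(const NumericVector& x, int a, int b, double xv) {
  if (x[b - 1] > x[a - 1])
    return a + (xv - x[a - 1]) * (double)(b - a) / (x[b - 1] - x[a - 1]);
  return b; // vertical tie column: majorant takes the upper count
}

static double dip_sorted(const NumericVector& x);

// [[Rcpp::export]]
double dip_cpp(NumericVector x) {
  return dip_sorted(x);
}

// Monte-Carlo null distribution of the dip for Uniform(0,1) samples of size n.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int B) {
  NumericVector out(B), u(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) u[i] = R::runif(0.0, 1.0);
    std::sort(u.begin(), u.end());
    out[b] = dip_sorted(u);
  }
  return out;
}

static double dip_sorted(const NumericVector& x) {
  const int n = x.size();
  if (n < 1) stop("empty sample");
  for (int k = 1; k < n; ++k)
    if (x[k] < x[k - 1]) stop("sample must be sorted");
  if (n < 2 || x[n - 1] == x[0]) return 1.0 / (2.0 * n);

  std::vector<int> mn(n + 2), mj(n + 2), gcm(n + 2), lcm(n + 2);
  int low = 1, high = n;
  double dip = 1.0; // count units

  for (int guard = 0; guard < 2 * n + 10; ++guard) {
    // predecessor pointers of gcm touch points on [low, high]
    mn[low] = low;
    for (int j = low + 1; j <= high; ++j) {
      mn[j] = j - 1;
      for (;;) {
        int mnj = mn[j], mnmnj = mn[mnj];
        if (mnj == low ||
            (x[j - 1] - x[mnj - 1]) * (mnj - mnmnj) <
            (x[mnj - 1] - x[mnmnj - 1]) * (j - mnj)) break;
        mn[j] = mnmnj;
      }
    }
    // successor pointers of lcm touch points on [low, high]
    mj[high] = high;
    for (int k = high - 1; k >= low; --k) {
      mj[k] = k + 1;
      for (;;) {
        int mjk = mj[k], mjmjk = mj[mjk];
        if (mjk == high ||
            (x[k - 1] - x[mjk - 1]) * (mjk - mjmjk) <
            (x[mjk - 1] - x[mjmjk - 1]) * (k - mjk)) break;
        mj[k] = mjmjk;
      }
    }
    // gcm[1..l_gcm]: touch points low = gcm[1] < ... < gcm[l_gcm] = high
    int l_gcm = 0;
    {
      int i = high, cnt = 0;
      while (i > low) { gcm[++cnt] = i; i = mn[i]; }
      gcm[++cnt] = low;
      l_gcm = cnt;
      for (int a = 1, b = l_gcm; a < b; ++a, --b) std::swap(gcm[a], gcm[b]);
    }
    // lcm[1..l_lcm]: touch points low = lcm[1] < ... < lcm[l_lcm] = high
    int l_lcm = 0;
    {
      int i = low, cnt = 0;
      while (i < high) { lcm[++cnt] = i; i = mj[i]; }
      lcm[++cnt] = high;
      l_lcm = cnt;
    }

    // largest gap between the hulls; remember the bracketing touch points
    double d = 0.0;
    int new_low = low, new_high = high;
    if (l_gcm > 2 || l_lcm > 2) {
      // gap at every lcm vertex (against the gcm chord containing it)
      int a = 1; // gcm segment [gcm[a], gcm[a+1]]
      for (int v = 1; v <= l_lcm; ++v) {
        int idx = lcm[v];
        while (a + 1 <= l_gcm && gcm[a + 1] < idx) ++a;
        double gi;
        if (idx == gcm[a] || a + 1 > l_gcm) gi = idx; // coincident touch point
        else gi = gcm_interp(x, gcm[a], gcm[a + 1], x[idx - 1]);
        double dx = idx - gi + 1.0;
        if (dx >= d) { d = dx; new_low = gcm[a]; new_high = idx; }
      }
      // gap at every gcm vertex (against the lcm chord containing it)
      int b = 1; // lcm segment [lcm[b], lcm[b+1]]
      for (int v = 1; v <= l_gcm; ++v) {
        int idx = gcm[v];
        while (b + 1 <= l_lcm && lcm[b + 1] < idx) ++b;
        double li;
        int right;
        if (idx == lcm[b] || b + 1 > l_lcm) { li = idx; right = idx; }
        else { li = lcm_interp(x, lcm[b], lcm[b + 1], x[idx - 1]); right = lcm[b + 1]; }
        double dx = li - idx + 1.0;
        if (dx > d) { d = dx; new_low = idx; new_high = right; }
      }
    }
    if (d <= dip) break;

    // maximal ecdf deviation above the gcm chords on [low, new_low]
    double dip_l = 0.0;
    for (int v = 1; v + 1 <= l_gcm && gcm[v + 1] <= new_low; ++v) {
      int jb = gcm[v], je = gcm[v + 1];
      double max_t = 1.0;
      if (je - jb > 1 && x[je - 1] != x[jb - 1]) {
        double C = (double)(je - jb) / (x[je - 1] - x[jb - 1]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (jj - jb + 1.0) - (x[jj - 1] - x[jb - 1]) * C;
          if (t > max_t) max_t = t;
        }
      }
      if (max_t > dip_l) dip_l = max_t;
    }
    // maximal ecdf deviation below the lcm chords on [new_high, high]
    double dip_u = 0.0;
    for (int v = 1; v + 1 <= l_lcm; ++v) {
      int jb = lcm[v], je = lcm[v + 1];
      if (jb < new_high) continue;
      double max_t = 1.0;
      if (je - jb > 1 && x[je - 1] != x[jb - 1]) {
        double C = (double)(je - jb) / (x[je - 1] - x[jb - 1]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (x[jj - 1] - x[jb - 1]) * C - (jj - jb - 1.0);
          if (t > max_t) max_t = t;
        }
      }
      if (max_t > dip_u) dip_u = max_t;
    }

    double dipnew = (dip_l > dip_u) ? dip_l : dip_u;
    if (dipnew > dip) dip = dipnew;
    if (new_low == low && new_high == high) break; // no progress possible
    low = new_low;
    high = new_high;
  }
  return dip / (2.0 * n);
}
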