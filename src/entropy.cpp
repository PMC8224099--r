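#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-matching entropy cores. All estimators compare length-m delay
// vectors ("templates") under the Chebyshev (max-norm) distance. Loops
// accumulate streaming counts/sums; no N x N distance matrix is ever
// stored. The default configuration (m = 2, tau = 1) has specialized
// inner loops; the generic strided path covers other settings.

static inline double cheb_dist(const double* x, const double* y,
                               int i, int j, int m, int tau) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k * tau] - y[j + k * tau]);
    if (a > d) d = a;
  }
  return d;
}

// memberships below exp(-EXPO_SKIP) ~ 1e-13 are treated as zero; the
// skipped mass is orders of magnitude below the 1e-10 agreement the
// estimators are validated to
static const double EXPO_SKIP = 30.0;

// Sample entropy match counts: n_t = N - m templates (so templates of
// length m and m+1 both exist for every index), pairs i < j, self-matches
// excluded. Returns (B, A): matches at m and at m+1.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int N = x.size();
  int nt = N - m;
  if (nt < 2) stop("series too short for embedding dimension m");
  const double* xv = x.begin();
  double B = 0.0, A = 0.0;
  if (m == 2) {
    for (int i = 0; i < nt - 1; ++i) {
      double xi0 = xv[i], xi1 = xv[i + 1], xi2 = xv[i + 2];
      for (int j = i + 1; j < nt; ++j) {
        double d = std::fabs(xi0 - xv[j]);
        if (d > r) continue;
        double b = std::fabs(xi1 - xv[j + 1]);
        if (b > r) continue;
        B += 1.0;
        if (std::fabs(xi2 - xv[j + 2]) <= r) A += 1.0;
      }
    }
  } else {
    for (int i = 0; i < nt - 1; ++i)
      for (int j = i + 1; j < nt; ++j) {
        double d = cheb_dist(xv, xv, i, j, m, 1);
        if (d <= r) {
          B += 1.0;
          if (std::fabs(xv[i + m] - xv[j + m]) <= r) A += 1.0;
        }
      }
  }
  return NumericVector::create(B, A);
}

// Fuzzy entropy membership sums. Templates are baseline-removed (each
// template's own mean subtracted) before the Chebyshev distance; the
// membership is exp(-d^2 / r). Returns (phi_m, phi_m1) as mean
// memberships over i < j pairs.
// [[Rcpp::export]]
NumericVector cpp_fuzzyen_phis(NumericVector x, int m, double r) {
  int N = x.size();
  int nt = N - m;
  if (nt < 2) stop("series too short for embedding dimension m");
  const double* xv = x.begin();
  std::vector<double> mu_m(nt), mu_m1(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += xv[i + k];
    mu_m[i] = s / m;
    mu_m1[i] = (s + xv[i + m]) / (m + 1);
  }
  // membership exp(-d^2/r) negligible beyond d = sqrt(r * EXPO_SKIP)
  double dskip = std::sqrt(r * EXPO_SKIP);
  long double sm = 0.0L, sm1 = 0.0L;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs((xv[i + k] - mu_m[i]) - (xv[j + k] - mu_m[j]));
        if (a > dm) dm = a;
        double b = std::fabs((xv[i + k] - mu_m1[i]) - (xv[j + k] - mu_m1[j]));
        if (b > dm1) dm1 = b;
      }
      double c = std::fabs((xv[i + m] - mu_m1[i]) - (xv[j + m] - mu_m1[j]));
      if (c > dm1) dm1 = c;
      if (dm < dskip) sm += std::exp(-(dm * dm) / r);
      if (dm1 < dskip) sm1 += std::exp(-(dm1 * dm1) / r);
    }
  }
  double np = 0.5 * (double)nt * (nt - 1);
  return NumericVector::create((double)(sm / np), (double)(sm1 / np));
}

static double hist_entropy(const std::vector<double>& cnt, double np, int B) {
  double H = 0.0;
  for (int b = 0; b < B; ++b)
    if (cnt[b] > 0.0) {
      double p = cnt[b] / np;
      H -= p * std::log2(p);
    }
  return H / std::log2((double)B);
}

// Distribution entropy: normalized Shannon entropy of the histogram of
// all pairwise template distances (i != j), B equal-width bins on
// [0, max distance]. Two O(N^2) passes: max, then histogram.
// [[Rcpp::export]]
double cpp_disten(NumericVector x, int m, int B) {
  int N = x.size();
  int nt = N - m + 1;
  if (nt < 2) stop("series too short for embedding dimension m");
  const double* xv = x.begin();
  double dmax = 0.0;
  if (m == 2) {
    for (int i = 0; i < nt - 1; ++i) {
      double xi0 = xv[i], xi1 = xv[i + 1];
      for (int j = i + 1; j < nt; ++j) {
        double a = std::fabs(xi0 - xv[j]);
        double b = std::fabs(xi1 - xv[j + 1]);
        double d = a > b ? a : b;
        if (d > dmax) dmax = d;
      }
    }
  } else {
    for (int i = 0; i < nt - 1; ++i)
      for (int j = i + 1; j < nt; ++j) {
        double d = cheb_dist(xv, xv, i, j, m, 1);
        if (d > dmax) dmax = d;
      }
  }
  if (dmax <= 0.0) return 0.0;  // all distances identical (zero)
  std::vector<double> cnt(B, 0.0);
  double sc = (double)B / dmax;
  if (m == 2) {
    for (int i = 0; i < nt - 1; ++i) {
      double xi0 = xv[i], xi1 = xv[i + 1];
      for (int j = i + 1; j < nt; ++j) {
        double a = std::fabs(xi0 - xv[j]);
        double b = std::fabs(xi1 - xv[j + 1]);
        double d = a > b ? a : b;
        int bi = (int)(d * sc);
        if (bi >= B) bi = B - 1;
        cnt[bi] += 1.0;
      }
    }
  } else {
    for (int i = 0; i < nt - 1; ++i)
      for (int j = i + 1; j < nt; ++j) {
        int bi = (int)(cheb_dist(xv, xv, i, j, m, 1) * sc);
        if (bi >= B) bi = B - 1;
        cnt[bi] += 1.0;
      }
  }
  double np = 0.5 * (double)nt * (nt - 1);
  return hist_entropy(cnt, np, B);
}

// Cross-sample entropy match counts: templates of x compared against
// templates of y with time delay tau; all ordered pairs (i, j) counted
// (there is no self-match between distinct signals). n_t = N - m*tau for
// both template lengths. Returns (B, A).
// [[Rcpp::export]]
NumericVector cpp_xsampen_counts(NumericVector x, NumericVector y,
                                 int m, int tau, double r) {
  int N = x.size();
  if (y.size() != N) stop("x and y must have equal length");
  int nt = N - m * tau;
  if (nt < 2) stop("series too short for embedding (m, tau)");
  const double* xv = x.begin();
  const double* yv = y.begin();
  double B = 0.0, A = 0.0;
  if (m == 2 && tau == 1) {
    for (int i = 0; i < nt; ++i) {
      double xi0 = xv[i], xi1 = xv[i + 1], xi2 = xv[i + 2];
      for (int j = 0; j < nt; ++j) {
        double d = std::fabs(xi0 - yv[j]);
        if (d > r) continue;
        if (std::fabs(xi1 - yv[j + 1]) > r) continue;
        B += 1.0;
        if (std::fabs(xi2 - yv[j + 2]) <= r) A += 1.0;
      }
    }
  } else {
    for (int i = 0; i < nt; ++i)
      for (int j = 0; j < nt; ++j) {
        double d = cheb_dist(xv, yv, i, j, m, tau);
        if (d <= r) {
          B += 1.0;
          if (std::fabs(xv[i + m * tau] - yv[j + m * tau]) <= r) A += 1.0;
        }
      }
  }
  return NumericVector::create(B, A);
}

// Cross-fuzzy entropy membership sums, membership exp(-ln(2) (d/r)^2)
// (equal to 1/2 exactly at d = r), pairs i != j.
// [[Rcpp::export]]
NumericVector cpp_xfuzzyen_phis(NumericVector x, NumericVector y,
                                int m, int tau, double r) {
  int N = x.size();
  if (y.size() != N) stop("x and y must have equal length");
  int nt = N - m * tau;
  if (nt < 2) stop("series too short for embedding (m, tau)");
  const double* xv = x.begin();
  const double* yv = y.begin();
  const double ln2 = std::log(2.0);
  const double c = ln2 / (r * r);
  const double dskip = r * std::sqrt(EXPO_SKIP / ln2);
  long double sm = 0.0L, sm1 = 0.0L;
  long long np = (long long)nt * (nt - 1);
  if (m == 2 && tau == 1) {
    for (int i = 0; i < nt; ++i) {
      double xi0 = xv[i], xi1 = xv[i + 1], xi2 = xv[i + 2];
      for (int j = 0; j < nt; ++j) {
        if (i == j) continue;
        double d = std::fabs(xi0 - yv[j]);
        double b = std::fabs(xi1 - yv[j + 1]);
        if (b > d) d = b;
        if (d < dskip) {
          sm += std::exp(-c * d * d);
          double e = std::fabs(xi2 - yv[j + 2]);
          if (e > d) d = e;
          if (d < dskip) sm1 += std::exp(-c * d * d);
        }
      }
    }
  } else {
    for (int i = 0; i < nt; ++i)
      for (int j = 0; j < nt; ++j) {
        if (i == j) continue;
        double d = cheb_dist(xv, yv, i, j, m, tau);
        double d1 = d;
        double a = std::fabs(xv[i + m * tau] - yv[j + m * tau]);
        if (a > d1) d1 = a;
        if (d < dskip) sm += std::exp(-c * d * d);
        if (d1 < dskip) sm1 += std::exp(-c * d1 * d1);
      }
  }
  return NumericVector::create((double)(sm / np), (double)(sm1 / np));
}

// Joint distribution entropy: the joint distance of template pair (i, j)
// is the geometric mean sqrt(dx_ij * dy_ij) of the within-x and within-y
// template distances; histogram as in cpp_disten. Reduces exactly to
// DistEn(x) when y == x.
// [[Rcpp::export]]
double cpp_jdisten(NumericVector x, NumericVector y, int m, int tau, int B) {
  int N = x.size();
  if (y.size() != N) stop("x and y must have equal length");
  int nt = N - (m - 1) * tau;
  if (nt < 2) stop("series too short for embedding (m, tau)");
  const double* xv = x.begin();
  const double* yv = y.begin();
  bool fast = (m == 2 && tau == 1);
  double d2max = 0.0;  // squared joint distance, avoids sqrt in pass 1
  for (int i = 0; i < nt - 1; ++i) {
    double xi0 = xv[i], xi1 = xv[i + 1];
    double yi0 = yv[i], yi1 = yv[i + 1];
    for (int j = i + 1; j < nt; ++j) {
      double dx, dy;
      if (fast) {
        double a = std::fabs(xi0 - xv[j]);
        double b = std::fabs(xi1 - xv[j + 1]);
        dx = a > b ? a : b;
        a = std::fabs(yi0 - yv[j]);
        b = std::fabs(yi1 - yv[j + 1]);
        dy = a > b ? a : b;
      } else {
        dx = cheb_dist(xv, xv, i, j, m, tau);
        dy = cheb_dist(yv, yv, i, j, m, tau);
      }
      double d2 = dx * dy;
      if (d2 > d2max) d2max = d2;
    }
  }
  if (d2max <= 0.0) return 0.0;
  std::vector<double> cnt(B, 0.0);
  double sc = (double)B / std::sqrt(d2max);
  for (int i = 0; i < nt - 1; ++i) {
    double xi0 = xv[i], xi1 = xv[i + 1];
    double yi0 = yv[i], yi1 = yv[i + 1];
    for (int j = i + 1; j < nt; ++j) {
      double dx, dy;
      if (fast) {
        double a = std::fabs(xi0 - xv[j]);
        double b = std::fabs(xi1 - xv[j + 1]);
        dx = a > b ? a : b;
        a = std::fabs(yi0 - yv[j]);
        b = std::fabs(yi1 - yv[j + 1]);
        dy = a > b ? a : b;
      } else {
        dx = cheb_dist(xv, xv, i, j, m, tau);
        dy = cheb_dist(yv, yv, i, j, m, tau);
      }
      int bi = (int)(std::sqrt(dx * dy) * sc);
      if (bi >= B) bi = B - 1;
      cnt[bi] += 1.0;
    }
  }
  double np = 0.5 * (double)nt * (nt - 1);
  return hist_entropy(cnt, np, B);
}

// Direct-form II transposed IIR filter with explicit initial state, the
// building block of the zero-phase filtering helper.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size(), N = x.size();
  int n = std::max(nb, na);
  std::vector<double> bb(n, 0.0), aa(n, 0.0), z(n, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < n - 1 && i < zi.size(); ++i) z[i] = zi[i];
  double a0 = aa[0];
  for (int i = 0; i < n; ++i) { bb[i] /= a0; aa[i] /= a0; }
  NumericVector y(N);
  for (int i = 0; i < N; ++i) {
    double yi = bb[0] * x[i] + z[0];
    for (int k = 0; k < n - 1; ++k)
      z[k] = bb[k + 1] * x[i] + (k + 1 < n - 1 ? z[k + 1] : 0.0) -
             aa[k + 1] * yi;
    y[i] = yi;
  }
  return y;
}
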