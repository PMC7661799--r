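#include <Rcpp.h>
#include <cmath>
#include <functional>
using namespace Rcpp;

double bvn_cdf(double h, double k, double r);

// Brent's localmin (Brent 1973) on [a, b]; tol is the x-tolerance.
static double brent_min(std::function<double(double)> f, double a, double b,
                        double tol, double *fmin) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 200; iter++) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-12;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, rr = 0.0;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      rr = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * rr;
      q = 2.0 * (q - rr);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) &&
          p > q * (a - x) && p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (x < m) ? tol1 : -tol1;
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fmin = fx;
  return x;
}

// Negative log-likelihood of an r x c contingency table under the
// bivariate-normal model with fixed thresholds (two-step estimator).
// ta, tb: interior thresholds (lengths r-1, c-1).
static double polychoric_nll(const NumericMatrix &tab,
                             const std::vector<double> &ta,
                             const std::vector<double> &tb, double rho) {
  int r = tab.nrow(), c = tab.ncol();
  // cumulative CDF at threshold grid, with -inf/+inf borders
  std::vector<double> Phi((r + 1) * (c + 1));
  for (int i = 0; i <= r; i++) {
    for (int j = 0; j <= c; j++) {
      double h = (i == 0) ? R_NegInf : (i == r ? R_PosInf : ta[i - 1]);
      double k = (j == 0) ? R_NegInf : (j == c ? R_PosInf : tb[j - 1]);
      Phi[i * (c + 1) + j] = bvn_cdf(h, k, rho);
    }
  }
  double nll = 0.0;
  for (int i = 0; i < r; i++) {
    for (int j = 0; j < c; j++) {
      double nij = tab(i, j);
      if (nij <= 0) continue;
      double p = Phi[(i + 1) * (c + 1) + (j + 1)] - Phi[i * (c + 1) + (j + 1)]
               - Phi[(i + 1) * (c + 1) + j] + Phi[i * (c + 1) + j];
      if (p < 1e-14) p = 1e-14;
      nll -= nij * std::log(p);
    }
  }
  return nll;
}

// [[Rcpp::export(name = ".polychoric_fit")]]
List polychoric_fit(NumericMatrix tab, NumericVector thresh_row,
                    NumericVector thresh_col, double bound) {
  std::vector<double> ta(thresh_row.begin(), thresh_row.end());
  std::vector<double> tb(thresh_col.begin(), thresh_col.end());
  auto f = [&](double rho) { return polychoric_nll(tab, ta, tb, rho); };
  double fmin;
  double rho = brent_min(f, -bound, bound, 1e-6, &fmin);
  // observed information of the profile likelihood by central differences
  double h = 1e-4;
  double lo = std::max(rho - h, -bound), hi = std::min(rho + h, bound);
  double d2 = (f(hi) - 2.0 * fmin + f(lo)) / ((hi - rho) * (rho - lo));
  double se = (d2 > 0 && std::isfinite(d2)) ? 1.0 / std::sqrt(d2) : NA_REAL;
  bool clipped = std::fabs(rho) >= bound - 1e-4;
  return List::create(_["rho"] = rho, _["se"] = se, _["nll"] = fmin,
                      _["clipped"] = clipped);
}

// Conditional NLL of ordinal y given standardized continuous z under the
// latent bivariate-normal model; tau: interior thresholds for y, codes of y
// in 0..K-1.
static double polyserial_nll(const IntegerVector &y, const NumericVector &z,
                             const std::vector<double> &tau, double rho) {
  int n = y.size();
  double s = std::sqrt(1.0 - rho * rho);
  int K = (int)tau.size() + 1;
  double nll = 0.0;
  for (int i = 0; i < n; i++) {
    int yi = y[i];
    double up = (yi == K - 1) ? 1.0
      : 0.5 * erfc(-((tau[yi] - rho * z[i]) / s) * M_SQRT1_2);
    double lo = (yi == 0) ? 0.0
      : 0.5 * erfc(-((tau[yi - 1] - rho * z[i]) / s) * M_SQRT1_2);
    double p = up - lo;
    if (p < 1e-14) p = 1e-14;
    nll -= std::log(p);
  }
  return nll;
}

// [[Rcpp::export(name = ".polyserial_fit")]]
List polyserial_fit(IntegerVector y, NumericVector z, NumericVector tau,
                    double bound) {
  std::vector<double> tv(tau.begin(), tau.end());
  auto f = [&](double rho) { return polyserial_nll(y, z, tv, rho); };
  double fmin;
  double rho = brent_min(f, -bound, bound, 1e-6, &fmin);
  double h = 1e-4;
  double lo = std::max(rho - h, -bound), hi = std::min(rho + h, bound);
  double d2 = (f(hi) - 2.0 * fmin + f(lo)) / ((hi - rho) * (rho - lo));
  double se = (d2 > 0 && std::isfinite(d2)) ? 1.0 / std::sqrt(d2) : NA_REAL;
  bool clipped = std::fabs(rho) >= bound - 1e-4;
  return List::create(_["rho"] = rho, _["se"] = se, _["nll"] = fmin,
                      _["clipped"] = clipped);
}
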