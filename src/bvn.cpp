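#include <Rcpp.h>
#include <cmath>

// Bivariate standard-normal tail probability P(X > dh, Y > dk) for
// correlation r, after Genz (2004): Gauss-Legendre quadrature on the
// tetrachoric series integrand, switching to the complementary expansion
// for |r| > 0.925.  Absolute accuracy ~1e-15, cheap enough for the inner
// loop of polychoric likelihood evaluation.

static const double GL_X[3][10] = {
  {0.9324695142031521, 0.6612093864662645, 0.2386191860831969,
   0, 0, 0, 0, 0, 0, 0},
  {0.9815606342467192, 0.9041172563704749, 0.7699026741943047,
   0.5873179542866175, 0.3678314989981802, 0.1252334085114689,
   0, 0, 0, 0},
  {0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
   0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
   0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
   0.1132449848708745}
};
static const double GL_W[3][10] = {
  {0.1713244923791704, 0.3607615730481386, 0.4679139345726910,
   0, 0, 0, 0, 0, 0, 0},
  {0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
   0.2031674267230659, 0.2334925365383548, 0.2491470458134028,
   0, 0, 0, 0},
  {0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
   0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
   0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
   0.1527533871307259}
};
static const int GL_N[3] = {3, 6, 10};

static inline double phid(double x) {
  return 0.5 * erfc(-x * M_SQRT1_2);
}

double bvnu(double dh, double dk, double r) {
  const double TWOPI = 6.283185307179586;
  if (std::isinf(dh) || std::isinf(dk)) {
    if (dh == R_PosInf || dk == R_PosInf) return 0.0;
    if (dh == R_NegInf) return (dk == R_NegInf) ? 1.0 : phid(-dk);
    return phid(-dh);
  }
  int ng;
  double ar = std::fabs(r);
  if (ar < 0.3) ng = 0; else if (ar < 0.75) ng = 1; else ng = 2;
  int lg = GL_N[ng];

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    if (ar > 0) {
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * GL_X[ng][i] + 1.0) / 2.0);
          bvn += GL_W[ng][i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * TWOPI);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
          (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
           c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(TWOPI) * phid(-b / a) * b *
          (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a = a / 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * GL_X[ng][i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            bvn += a * GL_W[ng][i] * std::exp(asr2) *
              (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
               (1.0 + c * xs * (1.0 + d * xs)));
          }
        }
      }
      bvn = -bvn / TWOPI;
    }
    if (r > 0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// Lower CDF P(X <= h, Y <= k).
double bvn_cdf(double h, double k, double r) {
  return bvnu(-h, -k, r);
}

// [[Rcpp::export(name = ".bvn_cdf")]]
Rcpp::NumericVector bvn_cdf_r(Rcpp::NumericVector h, Rcpp::NumericVector k,
                              Rcpp::NumericVector r) {
  int n = std::max(h.size(), std::max(k.size(), r.size()));
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = bvn_cdf(h[i % h.size()], k[i % k.size()], r[i % r.size()]);
  return out;
}
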