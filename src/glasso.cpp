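// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Graphical lasso by block coordinate descent (Friedman, Hastie &
// Tibshirani 2008): maximize log det K - tr(SK) - sum_{i!=j} L_ij |K_ij|.
// Off-diagonal-only penalty, so diag(W) = diag(S).  Entry-wise penalties L
// also implement the support-constrained unpenalized refit (L = 0 on the
// support, effectively infinite elsewhere) used for BIC model scoring.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

static List glasso_core(const arma::mat &S, const arma::mat &L, double tol,
                        int maxit, const arma::mat *W0,
                        const arma::mat *B0 = nullptr) {
  int p = S.n_rows;
  arma::mat W = W0 ? *W0 : S;
  W.diag() = S.diag();
  // B(k, j): coef of var k in the regression for column j
  arma::mat B = B0 ? *B0 : arma::mat(p, p, arma::fill::zeros);
  if (B0) {
    // a warm-started coefficient is only valid where the penalty allows it
    for (int j = 0; j < p; j++)
      for (int k = 0; k < p; k++)
        if (k != j && L(k, j) >= 1e9) B(k, j) = 0.0;
  }

  double offmean = 0.0;
  for (int i = 0; i < p; i++)
    for (int j = 0; j < p; j++)
      if (i != j) offmean += std::fabs(S(i, j));
  offmean = (p > 1) ? offmean / (p * (p - 1)) : 0.0;
  double thr = tol * std::max(offmean, 1e-10);
  double inner_thr = 0.1 * thr;

  bool converged = (p == 1);
  double maxdiff = 0.0;
  for (int it = 0; it < maxit && p > 1; it++) {
    maxdiff = 0.0;
    for (int j = 0; j < p; j++) {
      // lasso: min 1/2 b'W11 b - s12'b + sum_k L_kj |b_k|
      for (int inner = 0; inner < 500; inner++) {
        double del = 0.0;
        for (int k = 0; k < p; k++) {
          if (k == j) continue;
          double r = S(k, j);
          for (int l = 0; l < p; l++) {
            if (l == j || l == k) continue;
            r -= W(k, l) * B(l, j);
          }
          double bnew = soft(r, L(k, j)) / W(k, k);
          double ch = std::fabs(bnew - B(k, j));
          if (ch > del) del = ch;
          B(k, j) = bnew;
        }
        if (del < inner_thr) break;
      }
      for (int k = 0; k < p; k++) {
        if (k == j) continue;
        double wkj = 0.0;
        for (int l = 0; l < p; l++) {
          if (l == j) continue;
          wkj += W(k, l) * B(l, j);
        }
        double ch = std::fabs(W(k, j) - wkj);
        if (ch > maxdiff) maxdiff = ch;
        W(k, j) = wkj;
        W(j, k) = wkj;
      }
    }
    if (maxdiff < thr) { converged = true; break; }
  }

  // recover K; exact zeros of B give exact zeros of K
  arma::mat K(p, p, arma::fill::zeros);
  for (int j = 0; j < p; j++) {
    double dot = 0.0;
    for (int k = 0; k < p; k++)
      if (k != j) dot += W(k, j) * B(k, j);
    double kjj = 1.0 / (W(j, j) - dot);
    K(j, j) = kjj;
    for (int k = 0; k < p; k++)
      if (k != j && B(k, j) != 0.0) K(k, j) = -B(k, j) * kjj;
  }
  // symmetrize preserving the exact-zero pattern
  for (int i = 0; i < p; i++) {
    for (int j = i + 1; j < p; j++) {
      if (K(i, j) == 0.0 || K(j, i) == 0.0) {
        K(i, j) = K(j, i) = 0.0;
      } else {
        double v = 0.5 * (K(i, j) + K(j, i));
        K(i, j) = K(j, i) = v;
      }
    }
  }
  return List::create(_["K"] = K, _["W"] = W, _["B"] = B,
                      _["converged"] = converged, _["residual"] = maxdiff);
}

// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(arma::mat S, double lambda, double tol, int maxit,
               Nullable<NumericMatrix> W0 = R_NilValue) {
  arma::mat L(S.n_rows, S.n_cols);
  L.fill(lambda);
  if (W0.isNull()) return glasso_core(S, L, tol, maxit, nullptr);
  arma::mat W = as<arma::mat>(W0.get());
  return glasso_core(S, L, tol, maxit, &W);
}

// unpenalized ML refit restricted to a given support (1 = edge allowed)
static List glasso_refit_core(const arma::mat &S, const arma::mat &support,
                              double tol, int maxit, const arma::mat *W0,
                              const arma::mat *B0 = nullptr) {
  int p = S.n_rows;
  arma::mat L(p, p, arma::fill::zeros);
  for (int i = 0; i < p; i++)
    for (int j = 0; j < p; j++)
      if (i != j && support(i, j) == 0.0) L(i, j) = 1e10;
  return glasso_core(S, L, tol, maxit, W0, B0);
}

// [[Rcpp::export(name = ".glasso_refit")]]
List glasso_refit(arma::mat S, arma::mat support, double tol, int maxit) {
  return glasso_refit_core(S, support, tol, maxit, nullptr);
}

static double bic_of(const arma::mat &K, const arma::mat &S, double n,
                     int *edges_out) {
  int p = K.n_rows;
  double ld, sign;
  arma::log_det(ld, sign, K);
  int E = 0;
  for (int a = 0; a < p; a++)
    for (int b = a + 1; b < p; b++)
      if (K(a, b) != 0.0) E++;
  *edges_out = E;
  if (sign <= 0 || !std::isfinite(ld)) return R_PosInf;
  double ll = (n / 2.0) * (ld - arma::accu(S % K));
  return -2.0 * ll + E * std::log(n);
}

// Warm-started penalty path.  Each lambda's glasso fit proposes an edge
// support; the support is refit by constrained unpenalized ML and scored
// with BIC at the refit (likelihood at the model's MLE, the classical BIC
// recipe -- scoring the shrunken estimate instead systematically favors
// denser models because large penalties bias the active edges).  Ties keep
// the earlier (larger, sparser) lambda; the winning refit is returned.
// [[Rcpp::export(name = ".glasso_path")]]
List glasso_path(arma::mat S, arma::vec lambdas, double n, double tol,
                 int maxit, bool score_refit) {
  int p = S.n_rows, m = lambdas.n_elem;
  arma::vec bic(m), edges(m);
  List best;
  double best_bic = R_PosInf;
  int best_i = -1;
  arma::mat W, B;
  arma::mat prev_support(p, p, arma::fill::zeros);
  bool have_prev = false, have_W = false;
  double prev_bic = R_PosInf;
  int prev_edges = 0;
  // refit BIC is effectively unimodal in support size: once it has risen
  // for several consecutive distinct supports past the best, the denser
  // tail of the path cannot win and the search stops (the trace is padded
  // with the last values so the grid bookkeeping stays rectangular)
  int rises_since_best = 0;
  int stop_at = -1;
  for (int i = 0; i < m; i++) {
    arma::mat Lm(p, p);
    Lm.fill(lambdas[i]);
    List fit = have_W ? glasso_core(S, Lm, tol, maxit, &W, &B)
                      : glasso_core(S, Lm, tol, maxit, nullptr);
    arma::mat K = as<arma::mat>(fit["K"]);
    W = as<arma::mat>(fit["W"]);
    B = as<arma::mat>(fit["B"]);
    have_W = true;
    int E = 0;
    double b;
    if (score_refit) {
      arma::mat support = arma::conv_to<arma::mat>::from(K != 0.0);
      if (have_prev && arma::accu(arma::abs(support - prev_support)) == 0.0) {
        bic[i] = prev_bic;
        edges[i] = prev_edges;
        continue;
      }
      // refits start cold from W = S: the coordinate descent needs a
      // feasible start, and a previous refit's covariance (e.g. diagonal,
      // from an empty support) is not one for a much denser support
      List refit = glasso_refit_core(S, support, tol, maxit, nullptr);
      arma::mat Kr = as<arma::mat>(refit["K"]);
      b = bic_of(Kr, S, n, &E);
      prev_support = support;
      prev_bic = b;
      prev_edges = E;
      have_prev = true;
      bic[i] = b;
      edges[i] = E;
      if (b < best_bic) {
        best_bic = b; best = refit; best_i = i;
        rises_since_best = 0;
      } else {
        if (++rises_since_best >= 8) { stop_at = i; break; }
      }
    } else {
      b = bic_of(K, S, n, &E);
      bic[i] = b;
      edges[i] = E;
      if (b < best_bic) { best_bic = b; best = fit; best_i = i; }
    }
  }
  if (stop_at >= 0) {
    for (int i = stop_at + 1; i < m; i++) {
      bic[i] = bic[stop_at];
      edges[i] = edges[stop_at];
    }
  }
  if (best_i < 0) stop("all penalty-path fits failed");
  return List::create(_["K"] = best["K"], _["W"] = best["W"],
                      _["converged"] = best["converged"],
                      _["lambda"] = lambdas[best_i], _["bic"] = best_bic,
                      _["bic_path"] = bic, _["edges_path"] = edges);
}
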