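// Exhaustive pairwise SNP x SNP interaction scan.
//
// For every unordered pair (i, j) the 4-parameter OLS model
//   y = b0 + b1 g_i + b2 g_j + b3 (g_i * g_j) + e
// is solved from precomputed cross-moments: all O(n k^2) work is done
// by BLAS matrix products, leaving an O(1) 4x4 solve per pair.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".pair_scan_cpp")]]
Rcpp::List pair_scan_cpp(const arma::mat& G, const arma::vec& y) {
  const uword n = G.n_rows, k = G.n_cols;
  if (n <= 4) Rcpp::stop("need more than 4 samples for the pair model");
  const mat G2 = square(G);
  const vec s1 = sum(G, 0).t();        // sum g_i
  const vec s2 = sum(G2, 0).t();       // sum g_i^2
  const mat A  = G.t() * G;            // sum g_i g_j
  const mat B  = G2.t() * G;           // B(i,j) = sum g_i^2 g_j
  const mat C  = G2.t() * G2;          // sum g_i^2 g_j^2
  const vec ty = G.t() * y;            // sum g_i y
  mat Gy = G.each_col() % y;
  const mat T  = G.t() * Gy;           // sum g_i g_j y
  const double sy = accu(y), syy = dot(y, y);
  const double df = (double)n - 4.0;

  const uword npair = k * (k - 1) / 2;
  Rcpp::IntegerVector pi(npair), pj(npair);
  Rcpp::NumericVector beta(npair), tstat(npair), pval(npair);
  Rcpp::LogicalVector flagged(npair);

  mat M(4, 4), Minv(4, 4);
  vec b(4), coef(4);
  uword q = 0;
  for (uword i = 0; i < k - 1; ++i) {
    for (uword j = i + 1; j < k; ++j, ++q) {
      pi[q] = (int)i + 1; pj[q] = (int)j + 1;
      M(0,0) = (double)n; M(0,1) = s1[i]; M(0,2) = s1[j]; M(0,3) = A(i,j);
      M(1,1) = s2[i];     M(1,2) = A(i,j); M(1,3) = B(i,j);
      M(2,2) = s2[j];     M(2,3) = B(j,i);
      M(3,3) = C(i,j);
      M = symmatu(M);
      b[0] = sy; b[1] = ty[i]; b[2] = ty[j]; b[3] = T(i,j);
      bool ok = rcond(M) > 1e-10 && inv_sympd(Minv, M);
      if (!ok || Minv(3,3) <= 0) {
        beta[q] = NA_REAL; tstat[q] = NA_REAL; pval[q] = 1.0;
        flagged[q] = true;
        continue;
      }
      coef = Minv * b;
      double rss = syy - dot(coef, b);
      if (rss < 1e-12) rss = 1e-12;
      double sigma2 = rss / df;
      double se = std::sqrt(sigma2 * Minv(3,3));
      double t = coef[3] / se;
      beta[q] = coef[3];
      tstat[q] = t;
      pval[q] = 2.0 * R::pt(-std::fabs(t), df, 1, 0);
      flagged[q] = false;
    }
  }
  return Rcpp::List::create(Rcpp::Named("i") = pi, Rcpp::Named("j") = pj,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("t") = tstat,
                            Rcpp::Named("p") = pval,
                            Rcpp::Named("flagged") = flagged);
}
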