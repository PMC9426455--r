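// Hot loops of the iterative structural aligner: window seed search and
// global sequential dynamic programming. Superposition math mirrors the
// R-level kabsch() (SVD with reflection correction).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double kabsch_rmsd_arma(const arma::mat& A, const arma::mat& B) {
  // A, B: n x 3, already in correspondence
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat A0 = A.each_row() - ca, B0 = B.each_row() - cb;
  arma::mat H = B0.t() * A0;  // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) return NA_REAL;
  double d = arma::det(V * U.t());
  arma::vec sgn = {1.0, 1.0, (d < 0) ? -1.0 : 1.0};
  // E = sum ||A0||^2 + ||B0||^2 - 2 * sum sgn*s
  double e0 = arma::accu(A0 % A0) + arma::accu(B0 % B0);
  double tr = arma::dot(sgn, s);
  double msd = (e0 - 2.0 * tr) / A.n_rows;
  return std::sqrt(std::max(msd, 0.0));
}

// Gapless seed windows: superpose every length-`wlen` window of A (stride
// `stride`) against every such window of B. Returns the window RMSD matrix
// plus the 1-based window start positions.
// [[Rcpp::export]]
List seed_search_cpp(const arma::mat& A, const arma::mat& B,
                     int wlen, int stride) {
  int na = A.n_rows, nb = B.n_rows;
  if (na < wlen || nb < wlen) stop("traces shorter than seed window");
  std::vector<int> ia, jb;
  for (int i = 0; i + wlen <= na; i += stride) ia.push_back(i);
  for (int j = 0; j + wlen <= nb; j += stride) jb.push_back(j);
  NumericMatrix rms(ia.size(), jb.size());
  bool any_finite = false;
  for (size_t wi = 0; wi < ia.size(); ++wi) {
    arma::mat Aw = A.rows(ia[wi], ia[wi] + wlen - 1);
    for (size_t wj = 0; wj < jb.size(); ++wj) {
      arma::mat Bw = B.rows(jb[wj], jb[wj] + wlen - 1);
      double r = kabsch_rmsd_arma(Aw, Bw);
      rms(wi, wj) = R_finite(r) ? r : R_PosInf;
      if (R_finite(r)) any_finite = true;
    }
  }
  if (!any_finite) stop("alignment failed: no seed window with finite score");
  IntegerVector starts_a(ia.begin(), ia.end()), starts_b(jb.begin(), jb.end());
  return List::create(_["rmsd"] = rms,
                      _["starts_a"] = starts_a + 1,
                      _["starts_b"] = starts_b + 1);
}

// Global sequential alignment on a precomputed similarity matrix S
// (na x nb) with linear gap penalty `gap` per skipped interior position;
// end gaps are free (semi-global), as is standard when superposable cores
// sit at different offsets within their chains. Returns the matched index
// pairs (1-based, strictly increasing in both coordinates).
// [[Rcpp::export]]
IntegerMatrix nw_align_cpp(const NumericMatrix& S, double gap) {
  int na = S.nrow(), nb = S.ncol();
  NumericMatrix F(na + 1, nb + 1);
  IntegerMatrix P(na + 1, nb + 1);  // 0 diag, 1 up (gap in B), 2 left
  for (int i = 1; i <= na; ++i) { F(i, 0) = 0; P(i, 0) = 1; }
  for (int j = 1; j <= nb; ++j) { F(0, j) = 0; P(0, j) = 2; }
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double gi = (j == nb) ? 0.0 : gap;  // trailing gaps free
      double gj = (i == na) ? 0.0 : gap;
      double diag = F(i - 1, j - 1) + S(i - 1, j - 1);
      double up = F(i - 1, j) - gi;
      double left = F(i, j - 1) - gj;
      if (diag >= up && diag >= left) {
        F(i, j) = diag; P(i, j) = 0;
      } else if (up >= left) {
        F(i, j) = up; P(i, j) = 1;
      } else {
        F(i, j) = left; P(i, j) = 2;
      }
    }
  }
  std::vector<int> ai, bj;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    int p = P(i, j);
    if (i > 0 && j > 0 && p == 0) {
      ai.push_back(i); bj.push_back(j); --i; --j;
    } else if (i > 0 && (p == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
  }
  int m = ai.size();
  IntegerMatrix out(m, 2);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = ai[m - 1 - k];
    out(k, 1) = bj[m - 1 - k];
  }
  return out;
}
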