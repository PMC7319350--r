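#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// All-pairs least-squares (Kabsch) RMSD over an atoms x 3 x n coordinate
// array. Each slice is one conformer restricted to the shared atom subset.
// Centring and per-conformer sums of squares are precomputed; each pair
// then needs only one 3x3 SVD:
//   rmsd_ij^2 = (|Xi|^2 + |Xj|^2 - 2 * (s1 + s2 +/- s3)) / m
// with the sign of s3 flipped when the optimal orthogonal map is a
// reflection (proper-rotation constraint).
// [[Rcpp::export]]
arma::mat pairwise_rmsd_cpp(const arma::cube& coords) {
  const arma::uword n = coords.n_slices;
  const arma::uword m = coords.n_rows;
  if (n == 0 || m == 0) Rcpp::stop("Empty coordinate array.");

  std::vector<arma::mat> centred(n);
  arma::vec ssq(n);
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat X = coords.slice(i);
    X.each_row() -= arma::mean(X, 0);
    centred[i] = X;
    ssq(i) = arma::accu(X % X);
  }

  arma::mat out(n, n, arma::fill::zeros);
  arma::mat U, V;
  arma::vec s;
  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      arma::mat H = centred[i].t() * centred[j];
      if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in pairwise RMSD.");
      double sign3 = (arma::det(U) * arma::det(V) < 0.0) ? -1.0 : 1.0;
      double tr = s(0) + s(1) + sign3 * s(2);
      double msd = (ssq(i) + ssq(j) - 2.0 * tr) / static_cast<double>(m);
      double r = msd > 0.0 ? std::sqrt(msd) : 0.0;
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}
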