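#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Batch eigendecomposition of symmetric 3x3 tensors stored compactly as
// n x 6 rows (xx, yy, zz, xy, xz, yz). Returns eigenvalues sorted
// descending and the matching unit eigenvectors (rows of 9: v1, v2, v3).
// [[Rcpp::export(name = ".eig3_batch_cpp")]]
Rcpp::List eig3_batch_cpp(const arma::mat& comp) {
  const arma::uword n = comp.n_rows;
  arma::mat values(n, 3);
  arma::mat vectors(n, 9);
  arma::mat33 D;
  arma::vec3 ev;
  arma::mat33 V;
  for (arma::uword i = 0; i < n; ++i) {
    D(0, 0) = comp(i, 0); D(1, 1) = comp(i, 1); D(2, 2) = comp(i, 2);
    D(0, 1) = D(1, 0) = comp(i, 3);
    D(0, 2) = D(2, 0) = comp(i, 4);
    D(1, 2) = D(2, 1) = comp(i, 5);
    arma::eig_sym(ev, V, D);  // ascending
    for (int j = 0; j < 3; ++j) {
      values(i, j) = ev(2 - j);
      for (int k = 0; k < 3; ++k) vectors(i, 3 * j + k) = V(k, 2 - j);
    }
  }
  return Rcpp::List::create(Rcpp::Named("values") = values,
                            Rcpp::Named("vectors") = vectors);
}
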