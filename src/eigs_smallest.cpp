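// Partial symmetric eigensolver for sparse PSD matrices.
//
// Lanczos iteration (Armadillo's built-in NEWARP backend) applied to the
// shifted operator B = shift*I - A: the largest eigenpairs of B are the
// smallest eigenpairs of A. `shift` must be an upper bound on the spectrum
// of A (a Gershgorin bound works); the R wrapper supplies it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List eigs_sym_smallest_cpp(const arma::sp_mat& A, int k, double shift,
                                 int subdim, int maxiter) {
  if (k < 1 || (arma::uword)k >= A.n_rows)
    Rcpp::stop("k must satisfy 1 <= k < nrow(A)");
  arma::sp_mat B = -A;
  B.diag() += shift;

  arma::eigs_opts opts;
  opts.maxiter = maxiter;
  arma::uword sd = (arma::uword)subdim;
  if (sd > A.n_rows - 1) sd = A.n_rows - 1;
  if (sd < (arma::uword)(2 * k + 1)) sd = 2 * k + 1;
  opts.subdim = sd;

  arma::vec vals;
  arma::mat vecs;
  bool ok = arma::eigs_sym(vals, vecs, B, k, "la", opts);
  if (!ok) Rcpp::stop("Lanczos iteration failed to converge");

  // map back: lambda_A = shift - lambda_B, ascending order
  arma::vec lam = shift - vals;
  arma::uvec ord = arma::sort_index(lam);
  arma::vec lam_s(lam.n_elem);
  arma::mat vec_s(vecs.n_rows, vecs.n_cols);
  for (arma::uword i = 0; i < ord.n_elem; ++i) {
    lam_s(i) = lam(ord(i));
    vec_s.col(i) = vecs.col(ord(i));
  }
  return Rcpp::List::create(Rcpp::Named("values") = lam_s,
                            Rcpp::Named("vectors") = vec_s);
}
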