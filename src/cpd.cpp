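// Rotation-only rigid Coherent Point Drift.
//
// The moving cloud Y (M x 3) provides the Gaussian mixture centroids; the
// reference cloud X (N x 3) is the data the mixture is fitted to. Scale is
// fixed at 1 and translation at 0, so the M-step reduces to an SVD of the
// uncentered posterior-weighted cross-covariance with a determinant
// correction that forbids reflections.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double TWO_PI = 6.283185307179586476925286766559;

// Squared distances ||x_n - y_m||^2, M x N.
static mat sqdist(const mat& Yr, const mat& X) {
  mat D2 = repmat(sum(square(Yr), 1), 1, X.n_rows) +
           repmat(sum(square(X), 1).t(), Yr.n_rows, 1) -
           2.0 * Yr * X.t();
  D2.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return D2;
}

// E-step posteriors P (M x N): P(m, n) = responsibility of centroid m for
// data point x_n, with the uniform outlier component weighted by w.
// Returns P and, via nll, the negative log-likelihood of X under the mixture.
static mat estep(const mat& X, const mat& Yrot, double sigma2, double w,
                 double* nll) {
  const uword M = Yrot.n_rows, N = X.n_rows;
  mat P = exp(-sqdist(Yrot, X) / (2.0 * sigma2));
  double c = std::pow(TWO_PI * sigma2, 1.5) * (w / (1.0 - w)) *
             (double)M / (double)N;
  rowvec den = sum(P, 0) + c;
  den.transform([](double v) { return v < 1e-300 ? 1e-300 : v; });
  if (nll != nullptr) {
    // p(x_n) = w/N + (1-w)/M (2*pi*sigma2)^{-3/2} sum_m exp(...)
    double lognorm = std::log((1.0 - w) / (double)M) -
                     1.5 * std::log(TWO_PI * sigma2);
    *nll = -(accu(log(den)) + (double)N * lognorm);
  }
  P.each_row() /= den;
  return P;
}

// [[Rcpp::export(name = ".cpd_estep_core")]]
arma::mat cpd_estep_core(const arma::mat& X, const arma::mat& Yrot,
                         double sigma2, double w) {
  return estep(X, Yrot, sigma2, w, nullptr);
}

// [[Rcpp::export(name = ".cpd_core")]]
Rcpp::List cpd_core(const arma::mat& X, const arma::mat& Y, int max_iter,
                    double tol, double w) {
  const uword M = Y.n_rows, N = X.n_rows;
  mat R = eye<mat>(3, 3);

  // Standard initialization: mean squared cross-pair distance / D.
  double sigma2 = accu(sqdist(Y, X)) / (3.0 * (double)M * (double)N);
  if (sigma2 <= 0.0) sigma2 = 1e-8;

  std::vector<double> nll_trace;
  double nll_prev = datum::inf;
  int iter = 0;
  std::string converged_by = "max_iter";

  mat P;
  for (iter = 1; iter <= max_iter; ++iter) {
    double nll;
    P = estep(X, Y * R.t(), sigma2, w, &nll);
    nll_trace.push_back(nll);

    // M-step: rotation from SVD of A = sum_{m,n} P(m,n) x_n y_m^T.
    mat A = X.t() * P.t() * Y;  // 3 x 3
    mat U, V;
    vec s;
    svd(U, s, V, A);
    vec cdiag = ones<vec>(3);
    cdiag(2) = det(U * V.t()) < 0.0 ? -1.0 : 1.0;
    R = U * diagmat(cdiag) * V.t();

    double Np = accu(P);
    vec d = sum(P, 0).t();   // per data point
    vec q = sum(P, 1);       // per centroid
    double e = dot(d, sum(square(X), 1)) -
               2.0 * trace(R * A.t()) +
               dot(q, sum(square(Y), 1));
    sigma2 = e / (3.0 * Np);
    if (sigma2 < 1e-10) sigma2 = 1e-10;

    if (std::abs(nll_prev - nll) < tol) {
      converged_by = "tol";
      break;
    }
    nll_prev = nll;
  }
  if (iter > max_iter) iter = max_iter;

  // Hard correspondences and MSE on the final rotation.
  mat Yrot = Y * R.t();
  P = estep(X, Yrot, sigma2, w, nullptr);
  Rcpp::IntegerVector corr(M);
  double mse = 0.0;
  for (uword m = 0; m < M; ++m) {
    uword n = index_max(P.row(m));
    corr[m] = (int)n + 1;  // 1-based for R
    mse += accu(square(Yrot.row(m) - X.row(n)));
  }
  mse /= (double)M;

  return Rcpp::List::create(
      Rcpp::Named("rotation") = R, Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("n_iter") = iter, Rcpp::Named("converged_by") = converged_by,
      Rcpp::Named("nll") = nll_trace, Rcpp::Named("correspondence") = corr,
      Rcpp::Named("mse") = mse);
}
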