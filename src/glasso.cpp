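#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Graphical lasso by block coordinate descent on the covariance estimate W
// (Friedman-style): each column of W is updated by solving a lasso problem
//   min_b 1/2 b' W11 b - s12' b + lam ||b||_1
// over the remaining coordinates. The l1 penalty applies to off-diagonal
// entries of Theta only, so diag(W) = diag(S) throughout.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Coordinate descent for one column. b is a full p-vector with b(j) fixed at
// 0, so the full W stands in for W11. The product m = W * b is maintained
// incrementally: reading the partial residual is O(1) and only coordinates
// that actually move cost O(p). After the first full sweep, iteration is
// restricted to the active (nonzero) set until it stabilizes, then one full
// sweep verifies optimality over all coordinates.
static void lasso_col(const arma::mat& W, const arma::mat& S, int j, double lam,
                      arma::vec& b, arma::vec& m, double tol, int maxit) {
  const int p = W.n_rows;
  bool full = true;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      const double old = b(k);
      if (!full && old == 0.0) continue;
      const double x = S(k, j) - (m(k) - W(k, k) * old);
      const double bk = soft(x, lam) / W(k, k);
      if (bk != old) {
        const double d = bk - old;
        m += W.col(k) * d;
        b(k) = bk;
        const double ad = std::fabs(d);
        if (ad > dmax) dmax = ad;
      }
    }
    if (dmax < tol) {
      if (full) break;   // optimal over all coordinates
      full = true;       // active set stable; verify with a full sweep
    } else {
      full = false;
    }
  }
}

// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double lam, double tol, int maxit,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const int p = S.n_rows;
  arma::mat W(p, p), B(p, p, arma::fill::zeros);
  if (W_init.isNotNull()) {
    W = Rcpp::as<arma::mat>(W_init.get());
    W.diag() = S.diag();  // diagonal is never penalized
  } else {
    W = S;
  }
  if (B_init.isNotNull()) B = Rcpp::as<arma::mat>(B_init.get());

  // scale for the convergence criterion: average absolute off-diagonal of S
  double soff = 0.0;
  for (int j = 0; j < p; ++j)
    for (int k = 0; k < p; ++k)
      if (k != j) soff += std::fabs(S(k, j));
  soff /= std::max(1, p * (p - 1));
  const double thr = tol * std::max(soff, 1e-12);

  bool converged = false;
  int iter = 0;
  const double inner_tol = 0.1 * thr;
  for (iter = 1; iter <= maxit; ++iter) {
    double dW = 0.0;
    for (int j = 0; j < p; ++j) {
      arma::vec b = B.col(j);
      b(j) = 0.0;
      arma::vec m = W * b;
      lasso_col(W, S, j, lam, b, m, inner_tol, 500);
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        const double d = std::fabs(m(k) - W(k, j));
        if (d > dW) dW = d;
        W(k, j) = m(k);
        W(j, k) = m(k);
      }
      B.col(j) = b;
      B(j, j) = 0.0;
    }
    if (dW < thr) { converged = true; break; }
  }

  // Recover Theta from W and the regression coefficients.
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    const double denom = W(j, j) - arma::dot(W.col(j), B.col(j));
    const double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  // Symmetrize, keeping the sparsity pattern symmetric (an entry is zero only
  // if both regressions excluded it).
  for (int j = 0; j < p; ++j) {
    for (int k = j + 1; k < p; ++k) {
      if (B(k, j) == 0.0 && B(j, k) == 0.0) {
        Theta(k, j) = Theta(j, k) = 0.0;
      } else {
        const double m2 = 0.5 * (Theta(k, j) + Theta(j, k));
        Theta(k, j) = Theta(j, k) = m2;
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta,
      Rcpp::Named("w") = W,
      Rcpp::Named("B") = B,
      Rcpp::Named("iterations") = iter > maxit ? maxit : iter,
      Rcpp::Named("converged") = converged);
}
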