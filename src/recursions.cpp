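// Quasi-likelihood recursions for the linear (MACI/INGARCH) and log-linear
// conditional-intensity models. Parameter packing everywhere is
// theta = (omega, vec(A), vec(B)), column-major vec, d = n(1 + 2n).
//
// The intensity recursion lambda_t = omega + A lambda_{t-1} + B X_{t-1}
// (resp. nu_t = omega + A nu_{t-1} + B log(X_{t-1} + 1)) is differentiated
// analytically:
//   d lambda_t / d omega'   = I_n            + A d lambda_{t-1} / d omega'
//   d lambda_t / d vec(A)'  = (l'_{t-1} x I) + A d lambda_{t-1} / d vec(A)'
//   d lambda_t / d vec(B)'  = (X'_{t-1} x I) + A d lambda_{t-1} / d vec(B)'
// with all derivative states zero at t = 1 (lambda_1 is a fixed initializer).
// Second derivatives follow the same one-lag structure: the only curvature
// source is the bilinear A * lambda_{t-1}(theta) term.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Shared second-derivative update. K is a (d x d x n) cube holding the
// Hessian of each intensity component; J is the (n x d) Jacobian at t-1.
static void update_second_deriv(cube& K, const cube& Kold, const mat& J,
                                const mat& A, int n, int d) {
  for (int i = 0; i < n; ++i) {
    K.slice(i).zeros();
    for (int m = 0; m < n; ++m) {
      double a = A(i, m);
      if (a != 0.0) K.slice(i) += a * Kold.slice(m);
    }
  }
  // cross terms from differentiating A * lambda_{t-1}(theta) w.r.t. A
  for (int c = 0; c < n; ++c) {
    for (int r = 0; r < n; ++r) {
      int pj = n + c * n + r;  // position of A_{rc} in theta
      K.slice(r).row(pj) += J.row(c);
      K.slice(r).col(pj) += J.row(c).t();
    }
  }
}

// [[Rcpp::export]]
Rcpp::List maci_qml_cpp(const arma::vec& omega, const arma::mat& A,
                        const arma::mat& B, const arma::mat& X,
                        const arma::vec& lambda1, bool derivs, bool hessian) {
  const int T = X.n_rows, n = X.n_cols;
  const int d = n * (1 + 2 * n);

  mat lam(T, n);
  vec lt = lambda1;
  double ll = 0.0;
  vec score(d, fill::zeros);
  mat G(d, d, fill::zeros), H(d, d, fill::zeros);
  mat J(n, d, fill::zeros), Jold(n, d, fill::zeros);
  cube K, Kold;
  if (hessian) {
    K.set_size(d, d, n);
    Kold.set_size(d, d, n);
    K.zeros();
    Kold.zeros();
  }

  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      lt = omega + A * lt + B * X.row(t - 1).t();
      if (derivs) {
        J = A * Jold;
        for (int i = 0; i < n; ++i) J(i, i) += 1.0;
        for (int c = 0; c < n; ++c) {
          double lv = lam(t - 1, c);
          double xv = X(t - 1, c);
          for (int r = 0; r < n; ++r) {
            J(r, n + c * n + r) += lv;
            J(r, n + n * n + c * n + r) += xv;
          }
        }
        if (hessian) update_second_deriv(K, Kold, Jold, A, n, d);
      }
    }
    if (lt.min() <= 0.0 || !lt.is_finite())
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("t_fail") = t + 1);
    lam.row(t) = lt.t();
    for (int i = 0; i < n; ++i) {
      double x = X(t, i), l = lt(i);
      ll += x * std::log(l) - l;
      if (derivs) {
        rowvec Ji = J.row(i);
        score += Ji.t() * (x / l - 1.0);
        G += (Ji.t() * Ji) / l;
        if (hessian) {
          H += (x / (l * l)) * (Ji.t() * Ji) - (x / l - 1.0) * K.slice(i);
        }
      }
    }
    if (derivs) {
      Jold = J;
      if (hessian) Kold = K;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("loglik") = ll,
      Rcpp::Named("lambda") = lam, Rcpp::Named("score") = score,
      Rcpp::Named("G") = G, Rcpp::Named("H") = H);
}

// [[Rcpp::export]]
Rcpp::List loglin_qml_cpp(const arma::vec& omega, const arma::mat& A,
                          const arma::mat& B, const arma::mat& X,
                          const arma::vec& nu1, bool derivs, bool hessian,
                          double nu_max) {
  const int T = X.n_rows, n = X.n_cols;
  const int d = n * (1 + 2 * n);

  mat nu(T, n);
  vec nt = nu1;
  double ll = 0.0;
  vec score(d, fill::zeros);
  mat G(d, d, fill::zeros), H(d, d, fill::zeros);
  mat J(n, d, fill::zeros), Jold(n, d, fill::zeros);
  cube K, Kold;
  if (hessian) {
    K.set_size(d, d, n);
    Kold.set_size(d, d, n);
    K.zeros();
    Kold.zeros();
  }

  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      vec z = log(X.row(t - 1).t() + 1.0);
      nt = omega + A * nu.row(t - 1).t() + B * z;
      if (derivs) {
        J = A * Jold;
        for (int i = 0; i < n; ++i) J(i, i) += 1.0;
        for (int c = 0; c < n; ++c) {
          double nv = nu(t - 1, c);
          double zv = z(c);
          for (int r = 0; r < n; ++r) {
            J(r, n + c * n + r) += nv;
            J(r, n + n * n + c * n + r) += zv;
          }
        }
        if (hessian) update_second_deriv(K, Kold, Jold, A, n, d);
      }
    }
    if (!nt.is_finite() || abs(nt).max() > nu_max)
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("t_fail") = t + 1);
    nu.row(t) = nt.t();
    for (int i = 0; i < n; ++i) {
      double x = X(t, i), v = nt(i), el = std::exp(v);
      ll += x * v - el;
      if (derivs) {
        rowvec Ji = J.row(i);
        score += Ji.t() * (x - el);
        G += el * (Ji.t() * Ji);
        if (hessian) {
          H += el * (Ji.t() * Ji) - (x - el) * K.slice(i);
        }
      }
    }
    if (derivs) {
      Jold = J;
      if (hessian) Kold = K;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("loglik") = ll,
      Rcpp::Named("nu") = nu, Rcpp::Named("score") = score,
      Rcpp::Named("G") = G, Rcpp::Named("H") = H);
}
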