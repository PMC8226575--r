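// Bootstrap particle filter for the Poisson state-space model
//   X_t | h_t ~ Poisson(beta * exp(h_t)),  h_t = Phi h_{t-1} + eta_t,
// in (possibly companion-stacked) state dimension m >= n. The first n state
// coordinates are observed through the intensity; eta_t = L z_t with z_t
// standard normal of dimension ncol(L). Per-step likelihood increment is
// log of the mean unnormalized weight, accumulated by log-sum-exp.
//
// A Gaussian measurement variant (X_t = h_t + N(0, sd^2 I)) is exposed for
// validation against the exact Kalman filter on the linear-Gaussian analogue.

#include <RcppArmadillo.h>
#include "rng.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline uint64_t make_seed(double s1, double s2) {
  return (static_cast<uint64_t>(s1) << 31) ^ static_cast<uint64_t>(s2);
}

static void systematic_indices(const vec& W, int N, double u0, uvec& idx) {
  double cum = W(0);
  int i = 0;
  for (int j = 0; j < N; ++j) {
    double u = (j + u0) / N;
    while (u > cum && i < N - 1) cum += W(++i);
    idx(j) = i;
  }
}

static void multinomial_indices(const vec& W, int N, Xoshiro& rng, uvec& idx) {
  vec cum = cumsum(W);
  for (int j = 0; j < N; ++j) {
    double u = rng.unif();
    // binary search on the cumulative weights
    int lo = 0, hi = N - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (u <= cum(mid)) hi = mid; else lo = mid + 1;
    }
    idx(j) = lo;
  }
}

// [[Rcpp::export]]
Rcpp::IntegerVector resample_cpp(const arma::vec& w, int scheme, double s1,
                                 double s2) {
  int N = w.n_elem;
  Xoshiro rng(make_seed(s1, s2));
  uvec idx(N);
  vec W = w / accu(w);
  if (scheme == 0)
    systematic_indices(W, N, rng.unif(), idx);
  else
    multinomial_indices(W, N, rng, idx);
  Rcpp::IntegerVector out(N);
  for (int j = 0; j < N; ++j) out[j] = idx(j) + 1;
  return out;
}

// [[Rcpp::export]]
Rcpp::List pf_cpp(const arma::mat& X, const arma::vec& beta,
                  const arma::mat& Phi, const arma::mat& L,
                  const arma::vec& h1_mean, const arma::mat& h1_L, int N,
                  int obs_model, double obs_sd, int resample_scheme,
                  bool store, double s1, double s2) {
  const int T = X.n_rows, n = X.n_cols;
  const int m = Phi.n_rows, q = L.n_cols, q1 = h1_L.n_cols;
  Xoshiro rng(make_seed(s1, s2));

  mat H(m, N), Hres(m, N);
  vec logw(N), W(N);
  vec logbeta = log(beta);
  cube P;
  mat Wmat;
  imat Anc;
  if (store) {
    P.set_size(m, N, T);
    Wmat.set_size(N, T);
    Anc.set_size(N, T);
    Anc.zeros();
  }
  uvec idx(N);
  vec ess(T);
  double loglik = 0.0;
  const double ln2pi = 1.837877066409345483560659;

  mat Z1(q1, N), Zq(q, N);
  for (int t = 0; t < T; ++t) {
    // propagate (single matrix products over the particle cloud)
    if (t == 0) {
      double* zp = Z1.memptr();
      for (int k = 0; k < q1 * N; ++k) zp[k] = rng.norm();
      H = h1_L * Z1;
      H.each_col() += h1_mean;
    } else {
      double* zp = Zq.memptr();
      for (int k = 0; k < q * N; ++k) zp[k] = rng.norm();
      H = Phi * Hres + L * Zq;
    }
    // weight
    double cst = 0.0;
    if (obs_model == 0) {
      for (int i = 0; i < n; ++i) cst -= std::lgamma(X(t, i) + 1.0);
    } else {
      cst = -0.5 * n * (ln2pi + 2.0 * std::log(obs_sd));
    }
    for (int j = 0; j < N; ++j) {
      double lw = 0.0;
      if (obs_model == 0) {
        for (int i = 0; i < n; ++i) {
          double h = H(i, j);
          lw += X(t, i) * (logbeta(i) + h) - beta(i) * std::exp(h);
        }
      } else {
        for (int i = 0; i < n; ++i) {
          double r = X(t, i) - H(i, j);
          lw -= 0.5 * r * r / (obs_sd * obs_sd);
        }
      }
      logw(j) = lw;
    }
    double Mx = logw.max();
    if (!std::isfinite(Mx))
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("t_fail") = t + 1);
    double S = 0.0;
    for (int j = 0; j < N; ++j) {
      W(j) = std::exp(logw(j) - Mx);
      S += W(j);
    }
    if (S <= 0.0 || !std::isfinite(S))
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("t_fail") = t + 1);
    loglik += Mx + std::log(S / N) + cst;
    W /= S;
    ess(t) = 1.0 / accu(square(W));
    if (store) {
      P.slice(t) = H;
      Wmat.col(t) = W;
    }
    // resample
    if (resample_scheme == 0)
      systematic_indices(W, N, rng.unif(), idx);
    else
      multinomial_indices(W, N, rng, idx);
    if (store)
      for (int j = 0; j < N; ++j) Anc(j, t) = idx(j) + 1;
    Hres = H.cols(idx);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("loglik") = loglik,
      Rcpp::Named("ess") = ess, Rcpp::Named("last_particles") = H,
      Rcpp::Named("last_weights") = W);
  if (store) {
    out["particles"] = P;
    out["weights"] = Wmat;
    out["ancestors"] = Anc;
  }
  return out;
}

// Backward sampling of latent trajectories from stored filter output.
// P: m x N x T particle cube (pre-resampling), W: N x T normalized weights.
// [[Rcpp::export]]
arma::cube ffbs_sample_cpp(const arma::cube& P, const arma::mat& W,
                           const arma::mat& Phi, const arma::mat& SigInv,
                           int n_paths, double s1, double s2) {
  const int m = P.n_rows, N = P.n_cols, T = P.n_slices;
  Xoshiro rng(make_seed(s1, s2));
  cube paths(m, T, n_paths);

  // terminal draws
  vec cumT = cumsum(W.col(T - 1));
  ivec cur(n_paths);
  for (int p = 0; p < n_paths; ++p) {
    double u = rng.unif();
    int i = 0;
    while (cumT(i) < u && i < N - 1) ++i;
    cur(p) = i;
    paths.slice(p).col(T - 1) = P.slice(T - 1).col(i);
  }

  vec lw(N), w(N);
  for (int k = T - 2; k >= 0; --k) {
    mat PhiP = Phi * P.slice(k);  // m x N, shared across paths
    for (int p = 0; p < n_paths; ++p) {
      vec hnext = paths.slice(p).col(k + 1);
      for (int i = 0; i < N; ++i) {
        vec d = hnext - PhiP.col(i);
        lw(i) = std::log(W(i, k)) - 0.5 * as_scalar(d.t() * SigInv * d);
      }
      double Mx = lw.max();
      double S = 0.0;
      for (int i = 0; i < N; ++i) {
        w(i) = std::exp(lw(i) - Mx);
        S += w(i);
      }
      double u = rng.unif() * S, cum = 0.0;
      int pick = N - 1;
      for (int i = 0; i < N; ++i) {
        cum += w(i);
        if (cum >= u) {
          pick = i;
          break;
        }
      }
      paths.slice(p).col(k) = P.slice(k).col(pick);
    }
  }
  return paths;
}

// Marginal smoothing weights W_{k|T} by the backward recursion.
// [[Rcpp::export]]
arma::mat ffbs_marginal_cpp(const arma::cube& P, const arma::mat& W,
                            const arma::mat& Phi, const arma::mat& SigInv) {
  const int N = P.n_cols, T = P.n_slices;
  mat Wsm(N, T);
  Wsm.col(T - 1) = W.col(T - 1);
  mat logf(N, N);
  for (int k = T - 2; k >= 0; --k) {
    mat PhiP = Phi * P.slice(k);
    // logf(i, j) = log kernel of f(h_{k+1}^j | h_k^i)
    for (int j = 0; j < N; ++j) {
      vec hj = P.slice(k + 1).col(j);
      for (int i = 0; i < N; ++i) {
        vec d = hj - PhiP.col(i);
        logf(i, j) = -0.5 * as_scalar(d.t() * SigInv * d);
      }
    }
    vec num(N, fill::zeros);
    for (int j = 0; j < N; ++j) {
      double Mx = logf.col(j).max();
      double D = 0.0;
      for (int l = 0; l < N; ++l) D += W(l, k) * std::exp(logf(l, j) - Mx);
      double ratio = Wsm(j, k + 1) / D;
      for (int i = 0; i < N; ++i)
        num(i) += ratio * std::exp(logf(i, j) - Mx);
    }
    Wsm.col(k) = W.col(k) % num;
    Wsm.col(k) /= accu(Wsm.col(k));
  }
  return Wsm;
}
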