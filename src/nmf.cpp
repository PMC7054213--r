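#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-16;

// Generalized Kullback-Leibler divergence D(V || R); terms with V==0
// contribute R (the limit of v*log(v/r) - v + r as v -> 0).
static double kl_div(const mat& V, const mat& R) {
  double d = 0.0;
  const double* v = V.memptr();
  const double* r = R.memptr();
  for (uword i = 0; i < V.n_elem; ++i) {
    double ri = std::max(r[i], EPS);
    if (v[i] > 0.0)
      d += v[i] * std::log(v[i] / ri) - v[i] + ri;
    else
      d += ri;
  }
  return d;
}

// Multiplicative-update NMF under generalized KL divergence.
// W, H are the (already random, strictly positive) initial factors.
// Convergence is declared when the relative drop of the objective over
// `check_every` iterations falls below `tol`.
// [[Rcpp::export]]
Rcpp::List cpp_nmf_kl(const arma::mat& V, arma::mat W, arma::mat H,
                      double tol, int max_iter, int check_every) {
  std::vector<double> trace;
  mat R = W * H;
  double obj = kl_div(V, R);
  double prev = obj;
  trace.push_back(obj);
  int it;
  for (it = 1; it <= max_iter; ++it) {
    mat Q = V / (R + EPS);
    H %= (W.t() * Q) / (repmat(sum(W, 0).t(), 1, H.n_cols) + EPS);
    R = W * H;
    Q = V / (R + EPS);
    W %= (Q * H.t()) / (repmat(sum(H, 1).t(), W.n_rows, 1) + EPS);
    R = W * H;
    if (it % check_every == 0) {
      obj = kl_div(V, R);
      trace.push_back(obj);
      if (prev - obj <= tol * std::max(prev, EPS) && prev >= obj - 1e-12)
        break;
      prev = obj;
    }
  }
  obj = kl_div(V, W * H);
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = std::min(it, max_iter));
}

// Bayesian NMF with automatic relevance determination (ARD).
// KL (Poisson) likelihood; per-component scale hyperparameters lambda_k
// with inverse-gamma(a, b) hyperprior, updated in closed form.
// prior = 1: exponential (L1) component priors; prior = 2: half-normal (L2).
// The first `n_fixed` columns of W are never updated (two-step extraction /
// fixed-signature attribution). If `use_mask`, H is multiplied elementwise
// by the binary indicator Z after every update of H.
// update_w = false freezes all of W and bases lambda on H alone.
// [[Rcpp::export]]
Rcpp::List cpp_ard_nmf(const arma::mat& V, arma::mat W, arma::mat H,
                       double a, double b, int prior,
                       double tol, int max_iter, int check_every,
                       int n_fixed, bool update_w,
                       const arma::mat& Z, bool use_mask) {
  const uword M = V.n_rows, N = V.n_cols, K = W.n_cols;
  vec lambda(K, fill::ones);
  mat R = W * H;
  double prev_obj = datum::inf;
  double obj = 0.0;
  int it;

  for (it = 1; it <= max_iter; ++it) {
    // closed-form lambda update
    rowvec sW = sum(W, 0);
    vec sH = sum(H, 1);
    if (prior == 1) {
      double denom = update_w ? (double)(M + N) + a + 1.0
                              : (double)N + a + 1.0;
      for (uword k = 0; k < K; ++k) {
        double num = sH(k) + b + (update_w ? sW(k) : 0.0);
        lambda(k) = num / denom;
      }
    } else {
      double denom = update_w ? 0.5 * (double)(M + N) + a + 1.0
                              : 0.5 * (double)N + a + 1.0;
      for (uword k = 0; k < K; ++k) {
        double num = 0.5 * accu(square(H.row(k))) + b +
                     (update_w ? 0.5 * accu(square(W.col(k))) : 0.0);
        lambda(k) = num / denom;
      }
    }

    // H update
    mat Q = V / (R + EPS);
    mat numH = W.t() * Q;
    mat denH(K, N);
    for (uword k = 0; k < K; ++k) denH.row(k).fill(sW(k));
    if (prior == 1) {
      for (uword k = 0; k < K; ++k) denH.row(k) += 1.0 / (lambda(k) + EPS);
    } else {
      for (uword k = 0; k < K; ++k)
        denH.row(k) += H.row(k) / (lambda(k) + EPS);
    }
    H %= numH / (denH + EPS);
    if (use_mask) H %= Z;
    R = W * H;

    // W update (free columns only)
    if (update_w && (uword)n_fixed < K) {
      Q = V / (R + EPS);
      mat numW = Q * H.t();
      vec sH2 = sum(H, 1);
      for (uword k = (uword)n_fixed; k < K; ++k) {
        vec den(M);
        den.fill(sH2(k));
        if (prior == 1)
          den += 1.0 / (lambda(k) + EPS);
        else
          den += W.col(k) / (lambda(k) + EPS);
        W.col(k) %= numW.col(k) / (den + EPS);
      }
      R = W * H;
    }

    if (it % check_every == 0) {
      // negative log-posterior up to constants
      double pen = 0.0;
      rowvec sW2 = sum(W, 0);
      vec sH3 = sum(H, 1);
      for (uword k = 0; k < K; ++k) {
        double lam = std::max(lambda(k), EPS);
        if (prior == 1) {
          double mass = sH3(k) + b + (update_w ? sW2(k) : 0.0);
          double cnt = (update_w ? (double)(M + N) : (double)N) + a + 1.0;
          pen += mass / lam + cnt * std::log(lam);
        } else {
          double mass = 0.5 * accu(square(H.row(k))) + b +
                        (update_w ? 0.5 * accu(square(W.col(k))) : 0.0);
          double cnt = (update_w ? 0.5 * (double)(M + N) : 0.5 * (double)N) +
                       a + 1.0;
          pen += mass / lam + cnt * std::log(lam);
        }
      }
      obj = kl_div(V, R) + pen;
      if (std::isfinite(prev_obj) &&
          std::abs(prev_obj - obj) <=
              tol * std::max(std::abs(prev_obj), EPS))
        break;
      prev_obj = obj;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("lambda") = lambda,
      Rcpp::Named("neg_log_posterior") = obj,
      Rcpp::Named("kl") = kl_div(V, W * H),
      Rcpp::Named("iterations") = std::min(it, max_iter));
}
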