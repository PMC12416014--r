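// EM engine for the K-component normal mixture of linear regressions with
// subject-level membership. Mirrors the reference R implementation
// (e_step / m_step) exactly; the loop lives here because the replicated
// simulation harnesses run it hundreds of thousands of times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// per-subject log component densities, n x K
static mat logdens_matrix(const vec &y, const mat &X, const uvec &sidx,
                          const vec &p, const mat &theta, const vec &sigma2) {
  const uword n = p.n_elem, K = sigma2.n_elem, N = y.n_elem;
  mat rss(n, K, fill::zeros);
  mat fitted = X * theta; // N x K
  for (uword k = 0; k < K; ++k) {
    for (uword r = 0; r < N; ++r) {
      double d = y[r] - fitted(r, k);
      rss(sidx[r], k) += d * d;
    }
  }
  mat L(n, K);
  for (uword k = 0; k < K; ++k) {
    double c = std::log(2.0 * M_PI * sigma2[k]);
    L.col(k) = -0.5 * rss.col(k) / sigma2[k] - 0.5 * p * c;
  }
  return L;
}

struct EStep {
  mat resp;
  mat logdens;
  double loglik;
  bool ok;
};

static EStep e_step_cpp(const vec &y, const mat &X, const uvec &sidx,
                        const vec &p, const mat &theta, const vec &sigma2,
                        const vec &pi) {
  EStep out;
  out.logdens = logdens_matrix(y, X, sidx, p, theta, sigma2);
  mat A = out.logdens;
  A.each_row() += log(pi).t();
  vec m = max(A, 1);
  vec lse = m + log(sum(exp(A.each_col() - m), 1));
  out.ok = lse.is_finite();
  out.resp = exp(A.each_col() - lse);
  out.loglik = accu(lse);
  return out;
}

// weighted least-squares M-step; returns false on singular normal equations
static bool m_step_cpp(const vec &y, const mat &X, const uvec &sidx,
                       const mat &resp, mat &theta, vec &sigma2, vec &pi,
                       int &bad_k) {
  const uword K = resp.n_cols, N = y.n_elem, q = X.n_cols;
  theta.set_size(q, K);
  sigma2.set_size(K);
  pi = mean(resp, 0).t();
  vec w(N);
  for (uword k = 0; k < K; ++k) {
    for (uword r = 0; r < N; ++r) w[r] = resp(sidx[r], k);
    mat Xw = X.each_col() % w;
    mat A = X.t() * Xw;
    vec b = X.t() * (w % y);
    vec th;
    if (!solve(th, A, b, solve_opts::no_approx)) {
      bad_k = (int)k + 1;
      return false;
    }
    vec res = y - X * th;
    theta.col(k) = th;
    sigma2[k] = dot(w, square(res)) / accu(w);
  }
  return true;
}

// [[Rcpp::export(name = ".em_engine")]]
Rcpp::List em_engine(const arma::vec &y, const arma::mat &X,
                     const arma::uvec &sidx0, const arma::vec &p,
                     const arma::mat &resp0, double tol, int max_iter,
                     double min_prior, double var_floor) {
  uvec sidx = sidx0 - 1; // R passes 1-based subject indices
  mat theta;
  vec sigma2, pi;
  int bad_k = 0;
  if (!m_step_cpp(y, X, sidx, resp0, theta, sigma2, pi, bad_k))
    Rcpp::stop("singular weighted normal equations in component %d", bad_k);

  std::vector<double> trace;
  double ll_prev = -datum::inf;
  bool converged = false, degenerate = false;
  int iter = 0;
  EStep es;
  for (;;) {
    // clamp collapsed variances so the final E-step stays finite; the fit
    // is flagged degenerate and excluded from model selection
    if (sigma2.min() < var_floor) {
      degenerate = true;
      sigma2 = arma::clamp(sigma2, var_floor, datum::inf);
    }
    es = e_step_cpp(y, X, sidx, p, theta, sigma2, pi);
    if (!es.ok)
      Rcpp::stop("all components underflow for some subject; try another start");
    trace.push_back(es.loglik);
    if (degenerate) break;
    if (std::isfinite(ll_prev) &&
        std::abs(es.loglik - ll_prev) < tol * (std::abs(ll_prev) + tol)) {
      converged = true;
      break;
    }
    if (iter >= max_iter) break;
    ll_prev = es.loglik;
    if (!m_step_cpp(y, X, sidx, es.resp, theta, sigma2, pi, bad_k))
      Rcpp::stop("singular weighted normal equations in component %d", bad_k);
    ++iter;
    if (min_prior > 0 && pi.n_elem > 1 && pi.min() < min_prior) {
      uvec keep = find(pi >= min_prior);
      if (keep.n_elem == 0) keep = uvec{pi.index_max()};
      theta = theta.cols(keep);
      sigma2 = sigma2(keep);
      pi = pi(keep) / accu(pi(keep));
      ll_prev = -datum::inf; // likelihood not comparable across K
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("theta") = theta, Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("pi") = pi, Rcpp::Named("resp") = es.resp,
      Rcpp::Named("logdens") = es.logdens,
      Rcpp::Named("loglik") = es.loglik, Rcpp::Named("trace") = trace,
      Rcpp::Named("n_iter") = iter, Rcpp::Named("converged") = converged,
      Rcpp::Named("degenerate") = degenerate);
}
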