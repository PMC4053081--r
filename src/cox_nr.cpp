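// Newton-Raphson maximisation of the Cox partial likelihood with Breslow or
// Efron handling of tied event times.  The observed information matrix is
// accumulated alongside the gradient, so the inverse information (coefficient
// covariance) and the global Wald statistic fall out of the same pass.
//
// All entry points accept unsorted data; observations are ordered by follow-up
// time internally and risk-set sums are maintained as running totals from the
// largest time downward, giving O(n p^2) work per likelihood evaluation.  The
// inner accumulation works on a transposed (p x n) covariate copy so each
// observation's covariates are contiguous, and only the upper triangle of the
// information matrix is updated per observation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct TieGroups {
  uvec ord;                       // ascending-time permutation
  std::vector<uword> start;       // block starts into the sorted arrays
  std::vector<uword> end;         // block ends (inclusive)
};

TieGroups make_groups(const vec& time) {
  TieGroups g;
  g.ord = stable_sort_index(time, "ascend");
  const uword n = time.n_elem;
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && time(g.ord(j + 1)) == time(g.ord(i))) ++j;
    g.start.push_back(i);
    g.end.push_back(j);
    i = j + 1;
  }
  return g;
}

inline void symmetrise(mat& m) {
  for (uword a = 0; a < m.n_rows; ++a)
    for (uword b = a + 1; b < m.n_cols; ++b)
      m(b, a) = m(a, b);
}

// log partial likelihood, score vector and observed information at beta.
// Xt is p x n, already sorted ascending in time along columns.
void cox_eval(const mat& Xt, const ivec& status_s, const TieGroups& g,
              const vec& beta, bool efron,
              double& ll, vec& grad, mat& info) {
  const uword n = Xt.n_cols, p = Xt.n_rows;
  vec eta = Xt.t() * beta;
  eta -= eta.max();               // shift-invariant; guards exp overflow
  vec w = exp(eta);

  double S0 = 0.0;
  vec S1(p, fill::zeros);
  mat S2(p, p, fill::zeros);      // upper triangle maintained
  vec s1d(p);
  mat s2d(p, p);
  vec x_d(p), mu(p);
  ll = 0.0;
  grad.zeros(p);
  info.zeros(p, p);

  for (uword b = g.start.size(); b-- > 0;) {
    double s0d = 0.0;
    uword d = 0;
    double eta_d = 0.0;
    bool have_block_d = false;

    for (uword i = g.start[b]; i <= g.end[b]; ++i) {
      const double wi = w(i);
      const double* xi = Xt.colptr(i);
      S0 += wi;
      const bool ev = status_s(i) == 1;
      if (ev && !have_block_d) {
        s1d.zeros();
        s2d.zeros();
        x_d.zeros();
        have_block_d = true;
      }
      for (uword a = 0; a < p; ++a) {
        const double wxa = wi * xi[a];
        S1(a) += wxa;
        double* S2col = S2.colptr(a);
        for (uword c = 0; c <= a; ++c) S2col[c] += wxa * xi[c];
      }
      if (ev) {
        ++d;
        eta_d += eta(i);
        s0d += wi;
        for (uword a = 0; a < p; ++a) {
          const double wxa = wi * xi[a];
          x_d(a) += xi[a];
          s1d(a) += wxa;
          double* s2col = s2d.colptr(a);
          for (uword c = 0; c <= a; ++c) s2col[c] += wxa * xi[c];
        }
      }
    }
    if (d == 0) continue;
    ll += eta_d;
    grad += x_d;
    if (!efron || d == 1) {
      ll -= d * std::log(S0);
      mu = S1 / S0;
      grad -= d * mu;
      for (uword a = 0; a < p; ++a) {
        const double* S2col = S2.colptr(a);
        for (uword c = 0; c <= a; ++c)
          info(c, a) += d * (S2col[c] / S0 - mu(a) * mu(c));
      }
    } else {
      for (uword l = 0; l < d; ++l) {
        const double f = static_cast<double>(l) / d;
        const double S0l = S0 - f * s0d;
        ll -= std::log(S0l);
        for (uword a = 0; a < p; ++a) mu(a) = (S1(a) - f * s1d(a)) / S0l;
        grad -= mu;
        for (uword a = 0; a < p; ++a) {
          const double* S2col = S2.colptr(a);
          const double* s2col = s2d.colptr(a);
          for (uword c = 0; c <= a; ++c)
            info(c, a) += (S2col[c] - f * s2col[c]) / S0l - mu(a) * mu(c);
        }
      }
    }
  }
  symmetrise(info);
  (void)n;
}

struct FitResult {
  vec beta;
  mat info;
  double loglik;
  double loglik0;
  int iter;
  bool converged;
};

FitResult cox_newton(const mat& Xt, const ivec& status_s, const TieGroups& g,
                     bool efron, int maxit, double tol,
                     const vec* beta_init = nullptr,
                     const double* ll0_known = nullptr) {
  const uword p = Xt.n_rows;
  FitResult r;
  r.beta = (beta_init != nullptr) ? *beta_init : vec(p, fill::zeros);
  r.iter = 0;
  r.converged = false;

  double ll;
  vec grad(p);
  mat info(p, p);
  if (beta_init != nullptr && any(r.beta != 0)) {
    // ll at beta = 0 involves no covariates, so a caller evaluating many
    // models on the same survival data can supply it once
    if (ll0_known != nullptr) {
      r.loglik0 = *ll0_known;
    } else {
      vec zero(p, fill::zeros);
      vec g0(p);
      mat i0(p, p);
      cox_eval(Xt, status_s, g, zero, efron, r.loglik0, g0, i0);
    }
    cox_eval(Xt, status_s, g, r.beta, efron, ll, grad, info);
    if (!std::isfinite(ll) || ll < r.loglik0) {  // bad warm start: restart
      r.beta.zeros();
      cox_eval(Xt, status_s, g, r.beta, efron, ll, grad, info);
    }
  } else {
    cox_eval(Xt, status_s, g, r.beta, efron, ll, grad, info);
    r.loglik0 = ll;
  }
  r.loglik = ll;
  r.info = info;

  const double ll_eps = 1e-9;  // relative log-likelihood stall criterion
  auto info_ok = [&]() { return info.is_finite() && rcond(info) > 1e-10; };

  for (int it = 1; it <= maxit; ++it) {
    r.iter = it;
    if (grad.is_finite() && abs(grad).max() <= tol) {
      // information must be usable for covariance / Wald
      r.converged = info_ok();
      break;
    }
    vec step;
    bool ok = grad.is_finite() && info_ok() &&
              solve(step, info, grad, solve_opts::no_approx);
    if (!ok) { r.converged = false; break; }

    double ll_new;
    vec grad_new(p);
    mat info_new(p, p);
    vec beta_new = r.beta + step;
    cox_eval(Xt, status_s, g, beta_new, efron, ll_new, grad_new, info_new);
    int halves = 0;
    while ((!std::isfinite(ll_new) || ll_new < r.loglik) && halves < 30) {
      step *= 0.5;
      beta_new = r.beta + step;
      cox_eval(Xt, status_s, g, beta_new, efron, ll_new, grad_new, info_new);
      ++halves;
    }
    if (!std::isfinite(ll_new) || ll_new < r.loglik) {
      // no direction of ascent at floating-point resolution: we are at the
      // numerical optimum even though the gradient norm sits above `tol`
      r.converged = info_ok();
      break;
    }
    const double ll_old = r.loglik;
    r.beta = beta_new;
    r.loglik = ll_new;
    grad = grad_new;
    info = info_new;
    r.info = info;
    if (std::abs(1.0 - ll_new / ll_old) <= ll_eps ||
        (grad.is_finite() && abs(grad).max() <= tol)) {
      r.converged = info_ok();
      break;
    }
    if (it == maxit) r.converged = false;
  }
  return r;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cox_nr_fit_cpp(const arma::mat& X, const arma::vec& time,
                          const arma::ivec& status, bool efron,
                          int maxit, double tol) {
  TieGroups g = make_groups(time);
  mat Xt = X.rows(g.ord).t();
  ivec status_s = status.elem(g.ord);
  FitResult r = cox_newton(Xt, status_s, g, efron, maxit, tol);

  double wald = NA_REAL;
  mat vcov(X.n_cols, X.n_cols, fill::value(datum::nan));
  if (r.converged) {
    wald = as_scalar(r.beta.t() * r.info * r.beta);
    vcov = inv(r.info);
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = r.beta,
      Rcpp::Named("information") = r.info,
      Rcpp::Named("vcov") = vcov,
      Rcpp::Named("loglik") = r.loglik,
      Rcpp::Named("loglik0") = r.loglik0,
      Rcpp::Named("wald") = wald,
      Rcpp::Named("iter") = r.iter,
      Rcpp::Named("converged") = r.converged);
}

// [[Rcpp::export]]
double cox_loglik_cpp(const arma::mat& X, const arma::vec& time,
                      const arma::ivec& status, const arma::vec& beta,
                      bool efron) {
  TieGroups g = make_groups(time);
  mat Xt = X.rows(g.ord).t();
  ivec status_s = status.elem(g.ord);
  double ll;
  vec grad(X.n_cols);
  mat info(X.n_cols, X.n_cols);
  cox_eval(Xt, status_s, g, beta, efron, ll, grad, info);
  return ll;
}

// Evaluate, for every candidate column, the model [Xbase, candidate]:
// returns an m x 3 matrix with columns (wald statistic, converged flag,
// candidate coefficient).  Shared sorting, tie bookkeeping and a warm start
// at the base model's coefficients make this the fast path of the greedy
// subnetwork growth.
// [[Rcpp::export]]
arma::mat cox_batch_wald_cpp(const arma::mat& Xbase, const arma::mat& Xcand,
                             const arma::vec& time, const arma::ivec& status,
                             bool efron, int maxit, double tol) {
  TieGroups g = make_groups(time);
  ivec status_s = status.elem(g.ord);
  const uword m = Xcand.n_cols, p0 = Xbase.n_cols, p = p0 + 1;

  vec warm(p, fill::zeros);
  double ll0 = 0.0;
  bool have_ll0 = false;
  if (p0 > 0) {
    mat Xbt = Xbase.rows(g.ord).t();
    FitResult base = cox_newton(Xbt, status_s, g, efron, maxit, tol);
    if (base.converged) warm.head(p0) = base.beta;
    ll0 = base.loglik0;
    have_ll0 = true;
  }

  mat out(m, 3);
  mat Xt(p, time.n_elem);
  if (p0 > 0) Xt.head_rows(p0) = Xbase.rows(g.ord).t();
  for (uword j = 0; j < m; ++j) {
    vec cand = Xcand.col(j);
    Xt.row(p - 1) = cand.elem(g.ord).t();
    FitResult r = cox_newton(Xt, status_s, g, efron, maxit, tol, &warm,
                             have_ll0 ? &ll0 : nullptr);
    out(j, 0) = r.converged ? as_scalar(r.beta.t() * r.info * r.beta) : NA_REAL;
    out(j, 1) = r.converged ? 1.0 : 0.0;
    out(j, 2) = r.beta(p - 1);
  }
  return out;
}
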