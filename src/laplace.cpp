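// Laplace-approximated log-likelihood for the binomial logistic mixed model
//
//   y_jk ~ Binomial(n_jk, p_jk),  logit p_jk = beta + S_j + R_k,
//   S_j ~ N(0, s2s),  R_k ~ N(0, s2r),
//
// integrating the random-effect vector b = (S, R) by a single Laplace
// approximation around the mode of the joint log-density of (y, b).  The
// complete-data log-density is strictly concave in b, so a damped Newton
// iteration converges globally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double softplus(double x) {
  // numerically stable log(1 + e^x)
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double inv_logit(double x) {
  if (x >= 0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// complete-data log density: binomial log-likelihood (with normalizing
// constants) plus the Gaussian log-densities of the active random effects.
static double joint_logdens(const arma::vec& y, const arma::vec& n,
                            const arma::ivec& snp, const arma::ivec& rep,
                            double beta, double s2s, double s2r,
                            int J, int K, bool use_s, bool use_r,
                            const arma::vec& u, const arma::vec& lchoose_yn) {
  const int C = y.n_elem;
  double f = 0.0;
  for (int c = 0; c < C; ++c) {
    double eta = beta;
    if (use_s) eta += u[snp[c]];
    if (use_r) eta += u[(use_s ? J : 0) + rep[c]];
    f += lchoose_yn[c] + y[c] * eta - n[c] * softplus(eta);
  }
  if (use_s) {
    for (int j = 0; j < J; ++j) f += -0.5 * u[j] * u[j] / s2s;
    f += -0.5 * J * std::log(2.0 * M_PI * s2s);
  }
  if (use_r) {
    int off = use_s ? J : 0;
    for (int k = 0; k < K; ++k) f += -0.5 * u[off + k] * u[off + k] / s2r;
    f += -0.5 * K * std::log(2.0 * M_PI * s2r);
  }
  return f;
}

// [[Rcpp::export]]
List cpp_laplace_loglik(NumericVector y_, NumericVector n_,
                        IntegerVector snp_, IntegerVector rep_,
                        double beta, double s2s, double s2r,
                        int J, int K, double tol, int maxit) {
  const arma::vec y(y_.begin(), y_.size(), false);
  const arma::vec n(n_.begin(), n_.size(), false);
  const arma::ivec snp(snp_.begin(), snp_.size());  // 0-based
  const arma::ivec rep(rep_.begin(), rep_.size());
  const int C = y.n_elem;

  arma::vec lchoose_yn(C);
  for (int c = 0; c < C; ++c) lchoose_yn[c] = R::lchoose(n[c], y[c]);

  const bool use_s = s2s > 0.0;
  const bool use_r = s2r > 0.0;
  const int d = (use_s ? J : 0) + (use_r ? K : 0);

  if (d == 0) {
    // no random effects: exact binomial log-likelihood at logit p = beta
    double ll = 0.0;
    for (int c = 0; c < C; ++c)
      ll += lchoose_yn[c] + y[c] * beta - n[c] * softplus(beta);
    return List::create(_["loglik"] = ll, _["converged"] = true,
                        _["iter"] = 0, _["mode"] = NumericVector(0));
  }

  arma::vec u(d, arma::fill::zeros);
  double f = joint_logdens(y, n, snp, rep, beta, s2s, s2r, J, K,
                           use_s, use_r, u, lchoose_yn);

  arma::vec g(d);
  arma::mat H(d, d);
  bool converged = false;
  int it = 0;
  const int offR = use_s ? J : 0;

  for (it = 0; it < maxit; ++it) {
    // gradient and negative Hessian of joint log-density in u
    g.zeros();
    H.zeros();
    for (int c = 0; c < C; ++c) {
      double eta = beta;
      if (use_s) eta += u[snp[c]];
      if (use_r) eta += u[offR + rep[c]];
      double p = inv_logit(eta);
      double r = y[c] - n[c] * p;
      double w = n[c] * p * (1.0 - p);
      if (use_s) {
        g[snp[c]] += r;
        H(snp[c], snp[c]) += w;
      }
      if (use_r) {
        g[offR + rep[c]] += r;
        H(offR + rep[c], offR + rep[c]) += w;
        if (use_s) {
          H(snp[c], offR + rep[c]) += w;
          H(offR + rep[c], snp[c]) += w;
        }
      }
    }
    if (use_s)
      for (int j = 0; j < J; ++j) {
        g[j] -= u[j] / s2s;
        H(j, j) += 1.0 / s2s;
      }
    if (use_r)
      for (int k = 0; k < K; ++k) {
        g[offR + k] -= u[offR + k] / s2r;
        H(offR + k, offR + k) += 1.0 / s2r;
      }

    if (arma::norm(g, "inf") < tol) {
      converged = true;
      break;
    }

    arma::vec step;
    bool ok = arma::solve(step, H, g, arma::solve_opts::likely_sympd);
    if (!ok) {
      arma::mat Hr = H + 1e-8 * arma::eye(d, d);
      step = arma::solve(Hr, g);
    }

    // damped Newton: halve until the joint log-density does not decrease
    double t = 1.0;
    arma::vec u_new = u + step;
    double f_new = joint_logdens(y, n, snp, rep, beta, s2s, s2r, J, K,
                                 use_s, use_r, u_new, lchoose_yn);
    int halvings = 0;
    while (f_new < f - 1e-12 && halvings < 50) {
      t *= 0.5;
      u_new = u + t * step;
      f_new = joint_logdens(y, n, snp, rep, beta, s2s, s2r, J, K,
                            use_s, use_r, u_new, lchoose_yn);
      ++halvings;
    }
    u = u_new;
    f = f_new;
  }

  // recompute negative Hessian at the final iterate for the Laplace term
  H.zeros();
  for (int c = 0; c < C; ++c) {
    double eta = beta;
    if (use_s) eta += u[snp[c]];
    if (use_r) eta += u[offR + rep[c]];
    double p = inv_logit(eta);
    double w = n[c] * p * (1.0 - p);
    if (use_s) H(snp[c], snp[c]) += w;
    if (use_r) {
      H(offR + rep[c], offR + rep[c]) += w;
      if (use_s) {
        H(snp[c], offR + rep[c]) += w;
        H(offR + rep[c], snp[c]) += w;
      }
    }
  }
  if (use_s) for (int j = 0; j < J; ++j) H(j, j) += 1.0 / s2s;
  if (use_r) for (int k = 0; k < K; ++k) H(offR + k, offR + k) += 1.0 / s2r;

  double ldet, sign;
  bool ok = arma::log_det(ldet, sign, H);
  if (!ok || sign <= 0.0) {
    arma::mat Hr = H + 1e-8 * arma::eye(d, d);
    arma::log_det(ldet, sign, Hr);
  }

  double ll = f + 0.5 * d * std::log(2.0 * M_PI) - 0.5 * ldet;
  return List::create(_["loglik"] = ll, _["converged"] = converged,
                      _["iter"] = it,
                      _["mode"] = NumericVector(u.begin(), u.end()));
}
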