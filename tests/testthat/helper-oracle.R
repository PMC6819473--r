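# independent quadrature oracle for the random-effect integral
#
#   \int P(y | beta, b) N(b; 0, diag) db
#
# evaluated by adaptive tensor Gauss-Hermite quadrature: the integrand's own
# mode and curvature are found here with generic numerical optimization
# (stats::optim), entirely separate from the package's Newton/Laplace code
# path, and the GH rule is centered and scaled accordingly.

gh_nodes_cache <- new.env(parent = emptyenv())
gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gh_nodes_cache[[key]]))
    gh_nodes_cache[[key]] <- pracma::gaussHermite(n)
  gh_nodes_cache[[key]]
}

oracle_loglik <- function(gene, beta, s2s, s2r, n_nodes = 15) {
  obs <- which(gene$observed, arr.ind = TRUE)
  y <- gene$y[obs]
  n <- gene$n[obs]
  J <- nrow(gene$n)
  K <- ncol(gene$n)
  sds <- c(if (s2s > 0) rep(sqrt(s2s), J), if (s2r > 0) rep(sqrt(s2r), K))
  d <- length(sds)
  if (d == 0)
    return(sum(dbinom(y, n, plogis(beta), log = TRUE)))

  snp_col <- if (s2s > 0) obs[, 1L] else NULL
  rep_col <- if (s2r > 0) (if (s2s > 0) J else 0) + obs[, 2L] else NULL
  logf <- function(b) {
    eta <- beta +
      (if (!is.null(snp_col)) b[snp_col] else 0) +
      (if (!is.null(rep_col)) b[rep_col] else 0)
    sum(dbinom(y, n, plogis(eta), log = TRUE)) +
      sum(dnorm(b, 0, sds, log = TRUE))
  }

  opt <- stats::optim(rep(0, d), function(b) -logf(b), method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  H <- stats::optimHess(opt$par, function(b) -logf(b))
  R <- chol(solve((H + t(H)) / 2))            # Sigma = t(R) %*% R, R upper

  nodes <- gh_nodes(n_nodes)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(n_nodes)), d)))
  X <- matrix(nodes$x[idx], nrow(idx), d)
  lw <- rowSums(matrix(log(nodes$w[idx]), nrow(idx), d)) + rowSums(X^2)
  B <- sweep(sqrt(2) * X %*% R, 2, opt$par, `+`)

  # vectorized integrand over all grid points
  Sj <- if (!is.null(snp_col)) B[, snp_col, drop = FALSE] else 0
  Rk <- if (!is.null(rep_col)) B[, rep_col, drop = FALSE] else 0
  eta <- beta + Sj + Rk
  ll_data <- rowSums(matrix(
    dbinom(rep(y, each = nrow(B)), rep(n, each = nrow(B)), plogis(eta),
           log = TRUE), nrow(B)))
  ll_prior <- rowSums(matrix(
    dnorm(B, 0, rep(sds, each = nrow(B)), log = TRUE), nrow(B)))
  tot <- ll_data + ll_prior + lw
  mx <- max(tot)
  mx + log(sum(exp(tot - mx))) + 0.5 * d * log(2) +
    sum(log(diag(R)))
}

# oracle marginal with the same plug-in convention as marginal_loglik()
oracle_marginal <- function(gene, model, eb, include_prior = TRUE,
                            n_nodes = 15) {
  beta <- if (model %in% c(2, 4)) eb$beta_tilde else 0
  s2s <- if (model %in% c(3, 4)) eb$sigma2_s_tilde else 0
  ll <- oracle_loglik(gene, beta, s2s, eb$sigma2_r_tilde, n_nodes)
  if (include_prior) {
    ll <- ll + eb$log_prior_s2r
    if (model %in% c(2, 4)) ll <- ll + eb$log_prior_beta
    if (model %in% c(3, 4)) ll <- ll + eb$log_prior_s2s
  }
  ll
}

# plausible random EB plug-ins for oracle comparisons
random_eb <- function() {
  structure(
    list(beta_tilde = runif(1, -2, 2),
         sigma2_s_tilde = runif(1, 0.05, 1.5),
         sigma2_r_tilde = runif(1, 0.02, 0.8),
         d_sg = 1L, d_rg = 1L,
         log_prior_beta = 0, log_prior_s2s = 0, log_prior_s2r = 0),
    class = "eb_estimates")
}
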