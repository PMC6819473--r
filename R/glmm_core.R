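#' Numerical control parameters
#'
#' All tolerances used by the likelihood machinery, in one place.
#'
#' @param newton_tol gradient sup-norm tolerance of the inner Newton search
#'   for the random-effect mode.
#' @param newton_maxit iteration cap of the inner Newton search.
#' @param var_floor variance components whose optimum falls below this are
#'   treated as on the zero boundary: the component is removed and the
#'   reduced model refit.
#' @param var_upper upper bound for variance components during optimization.
#' @param beta_bound symmetric box bound for the gene effect (log-odds).
#' @return a named list of class `"blmrm_control"`.
#' @export
blmrm_control <- function(newton_tol = 1e-8, newton_maxit = 100L,
                          var_floor = 1e-8, var_upper = 50,
                          beta_bound = 25) {
  stopifnot(newton_tol > 0, var_floor > 0, var_upper > var_floor,
            beta_bound > 0)
  structure(list(newton_tol = newton_tol, newton_maxit = newton_maxit,
                 var_floor = var_floor, var_upper = var_upper,
                 beta_bound = beta_bound),
            class = "blmrm_control")
}

# flatten a gene's observed cells into the vector form the C++ kernel takes,
# dropping SNP/replicate levels with no observed cell (their random effects
# integrate to one and must not enter the Laplace dimension)
gene_cells <- function(gene) {
  idx <- which(gene$observed, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("gene ", gene$gene_id, " has no observed cells")
  snp_lev <- sort(unique(idx[, 1L]))
  rep_lev <- sort(unique(idx[, 2L]))
  list(y = gene$y[idx], n = gene$n[idx],
       snp0 = match(idx[, 1L], snp_lev) - 1L,
       rep0 = match(idx[, 2L], rep_lev) - 1L,
       J = length(snp_lev), K = length(rep_lev))
}

laplace_loglik_cells <- function(cells, beta, sigma2_s, sigma2_r, control) {
  cpp_laplace_loglik(cells$y, cells$n, cells$snp0, cells$rep0,
                     beta, sigma2_s, sigma2_r, cells$J, cells$K,
                     control$newton_tol, control$newton_maxit)
}

#' Laplace-approximated log-likelihood of one gene
#'
#' Evaluates \eqn{\log \int P(y \mid \beta, b)\, P(b \mid \sigma^2_s,
#' \sigma^2_r)\, db} for the binomial logistic mixed model
#' \eqn{\mathrm{logit}\, p_{jk} = \beta + S_j + R_k} by a single Laplace
#' approximation around the mode of the joint log-density of \eqn{(y, b)},
#' found by damped Newton iteration (the complete-data log-density is
#' strictly concave in \eqn{b}).  Components with zero variance are removed
#' from \eqn{b}; with both variances zero the value is the exact binomial
#' log-likelihood.
#'
#' @param gene an [ase_counts()] object.
#' @param beta fixed gene effect (log-odds of maternal expression).
#' @param sigma2_s,sigma2_r SNP and replicate variance components
#'   (non-negative).
#' @param control a [blmrm_control()] list.
#' @return the log-likelihood value, with attributes `converged` and `iter`
#'   describing the inner Newton search.
#' @export
laplace_loglik <- function(gene, beta, sigma2_s, sigma2_r,
                           control = blmrm_control()) {
  stopifnot(sigma2_s >= 0, sigma2_r >= 0, is.finite(beta))
  res <- laplace_loglik_cells(gene_cells(gene), beta, sigma2_s, sigma2_r,
                              control)
  if (!res$converged && res$iter > 0L)
    warning("inner Newton search did not converge for gene ", gene$gene_id,
            "; value from best iterate")
  structure(res$loglik, converged = res$converged, iter = res$iter)
}

pooled_logit <- function(cells) {
  stats::qlogis((sum(cells$y) + 0.5) / (sum(cells$n) + 1))
}

# crude moment starts for the variance components from empirical logits
start_variances <- function(cells) {
  el <- log((cells$y + 0.5) / (cells$n - cells$y + 0.5))
  snp_means <- tapply(el, cells$snp0, mean)
  rep_means <- tapply(el, cells$rep0, mean)
  s2s0 <- if (length(snp_means) > 1L) stats::var(snp_means) else 0
  s2r0 <- if (length(rep_means) > 1L) stats::var(rep_means) else 0
  c(s2s = min(max(s2s0, 0.05), 5), s2r = min(max(s2r0, 0.05), 5))
}

# maximize the Laplace log-likelihood over the free parameters given by the
# inclusion mask; variances optimized on the log scale
fit_mask <- function(cells, use_beta, use_s, use_r, control) {
  sv <- start_variances(cells)
  lower <- c(if (use_beta) -control$beta_bound,
             if (use_s) log(control$var_floor / 100),
             if (use_r) log(control$var_floor / 100))
  upper <- c(if (use_beta) control$beta_bound,
             if (use_s) log(control$var_upper),
             if (use_r) log(control$var_upper))

  unpack <- function(par) {
    i <- 1L
    beta <- 0
    s2s <- 0
    s2r <- 0
    if (use_beta) { beta <- par[[i]]; i <- i + 1L }
    if (use_s) { s2s <- exp(par[[i]]); i <- i + 1L }
    if (use_r) { s2r <- exp(par[[i]]) }
    list(beta = beta, s2s = s2s, s2r = s2r)
  }
  negll <- function(par) {
    p <- unpack(par)
    -laplace_loglik_cells(cells, p$beta, p$s2s, p$s2r, control)$loglik
  }

  if (!use_beta && !use_s && !use_r) {
    ll <- laplace_loglik_cells(cells, 0, 0, 0, control)$loglik
    return(list(beta = 0, s2s = 0, s2r = 0, loglik = ll, hessian = NULL,
                converged = TRUE, n_iter = 0L,
                use = c(beta = use_beta, s = use_s, r = use_r)))
  }

  beta_starts <- if (use_beta) c(0, pooled_logit(cells)) else 0
  best <- NULL
  for (b0 in unique(beta_starts)) {
    par0 <- c(if (use_beta) b0,
              if (use_s) log(sv[["s2s"]]),
              if (use_r) log(sv[["s2r"]]))
    opt <- tryCatch(
      stats::optim(par0, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("ML optimization failed")

  p <- unpack(best$par)
  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  list(beta = p$beta, s2s = p$s2s, s2r = p$s2r, loglik = -best$value,
       hessian = H, converged = best$convergence == 0L,
       n_iter = as.integer(best$counts[[1L]]),
       use = c(beta = use_beta, s = use_s, r = use_r))
}

var_beta_from_fit <- function(fit) {
  if (!fit$use[["beta"]]) return(NA_real_)
  H <- fit$hessian
  v <- NA_real_
  if (!is.null(H)) {
    v <- tryCatch(solve(H)[1L, 1L], error = function(e) NA_real_)
    if (!is.finite(v) || v <= 0) v <- 1 / max(H[1L, 1L], 1e-10)
  }
  if (!is.finite(v) || v <= 0) v <- NA_real_
  v
}

#' Maximum-likelihood fit of one model configuration
#'
#' Maximizes the Laplace log-likelihood of [laplace_loglik()] over the free
#' parameters of model `m`:
#' `m = 1`: \eqn{\beta = 0,\ \sigma^2_s = 0};
#' `m = 2`: \eqn{\beta} free, \eqn{\sigma^2_s = 0};
#' `m = 3`: \eqn{\beta = 0}, \eqn{\sigma^2_s} free;
#' `m = 4`: both free.  The replicate variance \eqn{\sigma^2_r} is free in
#' all four.  Variances are optimized on the log scale; a component whose
#' optimum falls below `control$var_floor` is set to exactly zero and the
#' reduced model refit.  When the gene effect is free, optimization is
#' multi-started from \eqn{\beta_0 = 0} and the pooled empirical logit.
#'
#' @inheritParams laplace_loglik
#' @param model integer in 1..4.
#' @return an object of class `"ml_fit"`: list with `model`, `beta_hat`,
#'   `var_beta_hat` (inverse observed information; `NA` when \eqn{\beta} is
#'   excluded), `sigma2_s_hat`, `sigma2_r_hat`, `loglik`, `converged`,
#'   `n_iter`, and the per-gene dimensions `J`, `K`.
#' @export
fit_ml <- function(gene, model, control = blmrm_control()) {
  stopifnot(model %in% 1:4)
  cells <- gene_cells(gene)
  fit_ml_cells(cells, model, control, gene_id = gene$gene_id)
}

fit_ml_cells <- function(cells, model, control, gene_id = NA_character_) {
  use_beta <- model %in% c(2L, 4L)
  use_s <- model %in% c(3L, 4L)
  fit <- fit_mask(cells, use_beta, use_s, TRUE, control)
  # zero-boundary handling: drop components that collapsed and refit
  repeat {
    drop_s <- fit$use[["s"]] && fit$s2s < control$var_floor
    drop_r <- fit$use[["r"]] && fit$s2r < control$var_floor
    if (!drop_s && !drop_r) break
    fit <- fit_mask(cells, use_beta, fit$use[["s"]] && !drop_s,
                    fit$use[["r"]] && !drop_r, control)
  }
  structure(
    list(model = as.integer(model),
         beta_hat = fit$beta,
         var_beta_hat = var_beta_from_fit(fit),
         sigma2_s_hat = fit$s2s,
         sigma2_r_hat = fit$s2r,
         loglik = fit$loglik,
         converged = isTRUE(fit$converged),
         n_iter = fit$n_iter,
         J = cells$J, K = cells$K, gene_id = gene_id),
    class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf(
    "<ml_fit> model %d: beta=%.4f s2s=%.4g s2r=%.4g loglik=%.4f%s\n",
    x$model, x$beta_hat, x$sigma2_s_hat, x$sigma2_r_hat, x$loglik,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

lrt_pvalue <- function(ll_full, ll_null, df, boundary = FALSE) {
  if (!is.finite(ll_full) || !is.finite(ll_null)) {
    warning("degenerate fit in likelihood ratio test; p = 1")
    return(1)
  }
  stat <- max(2 * (ll_full - ll_null), 0)
  if (stat == 0) return(1)
  if (boundary) {
    # 50:50 mixture of chi^2_{df-1} and chi^2_{df} (null on the boundary)
    0.5 * (if (df >= 2L) stats::pchisq(stat, df - 1L, lower.tail = FALSE)
           else as.numeric(stat <= 0)) +
      0.5 * stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
}

#' Likelihood-ratio tests for the gene effect and SNP-level variation
#'
#' `lrt_gene()` tests \eqn{H_0: \beta_g = 0} by comparing model 4 against
#' model 3 on a \eqn{\chi^2_1} reference.  `lrt_snp()` tests
#' \eqn{H_0: \sigma^2_{sg} = 0} by comparing model 4 against model 2; the
#' null value lies on the boundary of the parameter space, so the reference
#' is the 50:50 mixture \eqn{\chi^2_0 : \chi^2_1}.
#'
#' @inheritParams laplace_loglik
#' @param fit_full,fit_null optional precomputed [fit_ml()] results (model 4
#'   and the respective null model) to avoid refitting.
#' @return a p-value.
#' @export
lrt_gene <- function(gene, fit_full = NULL, fit_null = NULL,
                     control = blmrm_control()) {
  if (is.null(fit_full)) fit_full <- fit_ml(gene, 4L, control)
  if (is.null(fit_null)) fit_null <- fit_ml(gene, 3L, control)
  lrt_pvalue(fit_full$loglik, fit_null$loglik, df = 1L)
}

#' @rdname lrt_gene
#' @export
lrt_snp <- function(gene, fit_full = NULL, fit_null = NULL,
                    control = blmrm_control()) {
  if (is.null(fit_full)) fit_full <- fit_ml(gene, 4L, control)
  if (is.null(fit_null)) fit_null <- fit_ml(gene, 2L, control)
  lrt_pvalue(fit_full$loglik, fit_null$loglik, df = 1L, boundary = TRUE)
}
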