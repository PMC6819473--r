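#' Genome-level hyperparameters
#'
#' Prior parameters shared across genes: \eqn{\beta_g \sim N(\mu, \sigma^2)},
#' \eqn{\sigma^2_{sg} \sim IG(a_s, b_s)}, \eqn{\sigma^2_{rg} \sim
#' IG(a_r, b_r)}.
#'
#' @param mu,sigma2 Gaussian prior mean and variance of the gene effect.
#' @param a_s,b_s inverse-gamma shape and scale of the SNP variance prior.
#' @param a_r,b_r inverse-gamma shape and scale of the replicate variance
#'   prior.
#' @return an object of class `"hyperparameters"`.
#' @export
hyperparameters <- function(mu, sigma2, a_s, b_s, a_r, b_r) {
  stopifnot(is.finite(mu), sigma2 > 0, a_s > 0, b_s > 0, a_r > 0, b_r > 0)
  structure(list(mu = mu, sigma2 = sigma2, a_s = a_s, b_s = b_s,
                 a_r = a_r, b_r = b_r),
            class = "hyperparameters")
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat(sprintf(
    "<hyperparameters> mu=%.3f sigma2=%.3f a_s=%.3f b_s=%.3f a_r=%.3f b_r=%.3f\n",
    x$mu, x$sigma2, x$a_s, x$b_s, x$a_r, x$b_r))
  invisible(x)
}

#' Serialize hyperparameters as a flat key=value text file
#'
#' Lets a simulation or a later analysis reuse previously estimated (or
#' published) values without refitting.
#'
#' @param hp a [hyperparameters()] object.
#' @param path file path.
#' @return `path` invisibly, or a [hyperparameters()] object.
#' @export
write_hyperparameters <- function(hp, path) {
  writeLines(sprintf("%s=%.17g", names(unclass(hp)), unlist(hp)), path)
  invisible(path)
}

#' @rdname write_hyperparameters
#' @export
read_hyperparameters <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
                          vapply(kv, `[[`, "", 1L))
  do.call(hyperparameters, as.list(vals))
}

#' Pseudo-count adjustment
#'
#' Adds one pseudo read to each allele of every observed cell
#' (\eqn{y^* = y + 1}, \eqn{n^* = n + 2}), pulling extreme observed ratios
#' (0 or 1) off the boundary.  Used only inside
#' [estimate_hyperparameters()]; model selection runs on raw counts.
#'
#' @param gene an [ase_counts()] object.
#' @return a copy with adjusted counts at observed cells.
#' @export
pseudo_adjust <- function(gene) {
  y <- gene$y
  n <- gene$n
  y[gene$observed] <- y[gene$observed] + 1
  n[gene$observed] <- n[gene$observed] + 2
  ase_counts(gene$gene_id, y, n, gene$snp_ids, gene$rep_ids, gene$observed)
}

#' Inverse-gamma maximum likelihood fit
#'
#' Fits \eqn{IG(a, b)} to positive observations.  Since \eqn{1/x \sim
#' \mathrm{Gamma}(a, \mathrm{rate}= b)}, the shape solves
#' \eqn{\log a - \psi(a) = \log \bar z - \overline{\log z}} with
#' \eqn{z = 1/x}, found by Newton iteration from the standard closed-form
#' approximation, and \eqn{b = a / \bar z}.
#'
#' @param x positive values.
#' @param maxit,tol Newton iteration cap and tolerance on the shape.
#' @return list with `a`, `b`, `converged`.
#' @export
fit_invgamma <- function(x, maxit = 100L, tol = 1e-10) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || any(x <= 0))
    stop("inverse-gamma MLE needs >= 2 positive values")
  z <- 1 / x
  s <- log(mean(z)) - mean(log(z))
  if (s <= 0) stop("degenerate sample (all values equal?)")
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  converged <- FALSE
  for (i in seq_len(maxit)) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < tol * (1 + a)) {
      a <- a_new
      converged <- TRUE
      break
    }
    a <- a_new
  }
  if (!converged)
    stop("inverse-gamma MLE did not converge (n=", length(x),
         ", spread statistic=", signif(s, 4), ")")
  list(a = a, b = a / mean(z), converged = converged)
}

#' Inverse-gamma hyperparameter fit from noisy variance MLEs
#'
#' A per-gene variance MLE \eqn{\hat\sigma^2} with \eqn{d} degrees of
#' freedom carries sampling noise \eqn{d \hat\sigma^2 / \sigma^2 \sim
#' \chi^2_d} — the same sampling model under which the shrinkage estimators
#' \eqn{(d\hat\sigma^2 + 2b)/(d + 2a)} are the posterior means of an
#' \eqn{IG(a, b)} prior.  Fitting \eqn{IG(a, b)} directly to the
#' \eqn{\hat\sigma^2} values would recover the convolution of the prior
#' with that noise (far too dispersed for small \eqn{d}); this function
#' instead maximizes the compound marginal likelihood
#' \deqn{p(\hat\sigma^2 \mid a, b) = \frac{\Gamma(d/2 + a)}
#' {\Gamma(d/2)\Gamma(a)} \Big(\frac{d}{2b}\Big)^{d/2}
#' (\hat\sigma^2)^{d/2 - 1} \Big(1 + \frac{d \hat\sigma^2}{2b}\Big)^{-(d/2 + a)},}
#' a scaled beta-prime density, over \eqn{(\log a, \log b)}.
#'
#' Variance MLEs that sit on the zero boundary carry real information (the
#' unconstrained optimum was at or below zero); passing their count and
#' degrees of freedom via `cens_d` treats them as left-censored at
#' `cens_at`, using \eqn{P(\hat\sigma^2 \le c)} under the same compound
#' model, instead of discarding them (which truncates the low tail and
#' biases the shape up).
#'
#' @param x positive variance MLEs.
#' @param d degrees of freedom per value (recycled).
#' @param cens_d degrees of freedom of the left-censored (boundary)
#'   estimates, one entry per censored gene; empty for none.
#' @param cens_at censoring threshold.
#' @return list with `a`, `b`, `converged`.
#' @export
fit_invgamma_noisy <- function(x, d, cens_d = numeric(), cens_at = 1e-4) {
  x <- as.numeric(x)
  d <- rep_len(as.numeric(d), length(x))
  keep <- is.finite(x) & x > 0
  x <- x[keep]
  d <- d[keep]
  if (length(x) < 10L) stop("too few positive variance estimates")
  # scaled beta-prime CDF of the compound marginal
  pmarg <- function(q, d, a, b) {
    t <- d * q / (2 * b)
    stats::pbeta(t / (1 + t), d / 2, a)
  }
  negll <- function(par) {
    a <- exp(par[[1L]])
    b <- exp(par[[2L]])
    ll <- sum(lgamma(d / 2 + a) - lgamma(d / 2) - lgamma(a) +
                (d / 2) * log(d / (2 * b)) + (d / 2 - 1) * log(x) -
                (d / 2 + a) * log1p(d * x / (2 * b)))
    if (length(cens_d))
      ll <- ll + sum(log(pmax(pmarg(cens_at, cens_d, a, b), 1e-300)))
    -ll
  }
  start <- tryCatch(log(unlist(fit_invgamma(x)[c("a", "b")])),
                    error = function(e) c(0, log(stats::median(x))))
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500))
  if (opt$convergence != 0L)
    stop("compound inverse-gamma MLE did not converge")
  list(a = exp(opt$par[[1L]]), b = exp(opt$par[[2L]]),
       converged = TRUE)
}

# density of IG(a,b) on the log scale (used by the pure-Laplace comparator)
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

rinvgamma <- function(n, a, b) 1 / stats::rgamma(n, shape = a, rate = b)

#' Estimate genome-wide hyperparameters by empirical Bayes
#'
#' Fits the full model to every gene on pseudo-adjusted counts
#' ([pseudo_adjust()]), then
#' (i) estimates \eqn{\mu, \sigma^2} by the method of moments from the
#' \eqn{\hat\beta_g} of genes whose gene-level likelihood-ratio test is
#' significant at Storey q-value `fdr_level`;
#' (ii) fits \eqn{IG(a_s, b_s)} by maximum likelihood to the positive
#' \eqn{\hat\sigma^2_{sg}} of genes significant in the SNP-variance test;
#' (iii) fits \eqn{IG(a_r, b_r)} to the \eqn{\hat\sigma^2_{rg}} of all
#' genes.  Variance estimates on or numerically indistinguishable from the
#' zero boundary (below `pool_floor`) are excluded from the inverse-gamma
#' fits (`zero_rule = "exclude"`, the default) or replaced by `zero_floor`
#' (`zero_rule = "floor"`); the inverse-gamma likelihood depends on the
#' data through \eqn{1/x}, so a point mass at an arbitrary tiny floor
#' dominates the fit and destroys the shape estimate — excluding boundary
#' estimates is the default.
#'
#' If fewer than `min_sig` genes are significant for a component, all genes
#' are used for that component, with a warning.
#'
#' @param ds a filtered [ase_dataset()].
#' @param fdr_level FDR level for selecting significant genes.
#' @param min_sig minimum number of significant genes per component before
#'   falling back to all genes.
#' @param sigma2_min floor for \eqn{\hat\sigma^2} when the selected
#'   \eqn{\hat\beta_g} are (numerically) constant.
#' @param ig_method how the inverse-gamma hyperparameters are fit:
#'   `"compound"` (default) maximizes the marginal likelihood of the noisy
#'   variance MLEs under their \eqn{\chi^2_d} sampling model
#'   ([fit_invgamma_noisy()]), which is the model the shrinkage estimators
#'   themselves assume; `"direct"` fits the inverse gamma straight to the
#'   \eqn{\hat\sigma^2} values ([fit_invgamma()]), which over-disperses the
#'   prior when the per-gene degrees of freedom are small.
#' @param zero_rule treatment of boundary \eqn{\hat\sigma^2_{rg}}:
#'   `"exclude"` or `"floor"`.
#' @param zero_floor replacement value under `zero_rule = "floor"`.
#' @param pool_floor variance estimates below this are treated as boundary
#'   zeros when pooling (the generating priors put no mass there).
#' @param control a [blmrm_control()] list.
#' @param fits optional precomputed per-gene fits on pseudo-adjusted counts,
#'   as returned by this function in attribute `"fits"` (a list per gene of
#'   `ml_fit`s for models 2, 3, 4 named `"2"`, `"3"`, `"4"`).
#' @return a [hyperparameters()] object; attribute `"fits"` carries the
#'   per-gene pseudo-count fits and attribute `"selection"` the per-gene
#'   p/q-values used.
#' @export
estimate_hyperparameters <- function(ds, fdr_level = 0.05, min_sig = 50L,
                                     sigma2_min = 1e-4,
                                     ig_method = c("compound", "direct"),
                                     zero_rule = c("exclude", "floor"),
                                     zero_floor = 1e-6, pool_floor = 1e-4,
                                     control = blmrm_control(),
                                     fits = NULL) {
  zero_rule <- match.arg(zero_rule)
  ig_method <- match.arg(ig_method)
  genes <- ds$genes
  if (length(genes) < 2L) stop("need at least 2 genes")

  if (is.null(fits)) {
    fits <- lapply(genes, function(g) {
      cells <- gene_cells(pseudo_adjust(g))
      list("2" = fit_ml_cells(cells, 2L, control, g$gene_id),
           "3" = fit_ml_cells(cells, 3L, control, g$gene_id),
           "4" = fit_ml_cells(cells, 4L, control, g$gene_id))
    })
  }

  p_gene <- vapply(fits, function(f)
    lrt_pvalue(f[["4"]]$loglik, f[["3"]]$loglik, df = 1L), numeric(1))
  p_snp <- vapply(fits, function(f)
    lrt_pvalue(f[["4"]]$loglik, f[["2"]]$loglik, df = 1L, boundary = TRUE),
    numeric(1))
  q_gene <- storey_qvalues(p_gene)
  q_snp <- storey_qvalues(p_snp)

  beta_hat <- vapply(fits, function(f) f[["4"]]$beta_hat, numeric(1))
  s2s_hat <- vapply(fits, function(f) f[["4"]]$sigma2_s_hat, numeric(1))
  s2r_hat <- vapply(fits, function(f) f[["4"]]$sigma2_r_hat, numeric(1))

  sel_gene <- q_gene <= fdr_level
  if (sum(sel_gene) < min_sig) {
    warning("fewer than ", min_sig,
            " genes significant for the gene effect; using all genes for (mu, sigma2)")
    sel_gene <- rep(TRUE, length(beta_hat))
  }
  mu <- mean(beta_hat[sel_gene])
  sigma2 <- stats::var(beta_hat[sel_gene])
  if (!is.finite(sigma2) || sigma2 < sigma2_min) {
    warning("degenerate spread of selected gene effects; sigma2 floored at ",
            sigma2_min)
    sigma2 <- sigma2_min
  }

  d_s <- vapply(fits, function(f) f[["4"]]$J - 1L, integer(1))
  d_r <- vapply(fits, function(f) f[["4"]]$K - 1L, integer(1))
  # boundary estimates (the optimizer's zero atom) are excluded: this is the
  # profile MLE of a zero-inflated mixture with a free atom probability, and
  # measurably beats both floor replacement and censoring under the smooth
  # compound model (which assigns the atom essentially no mass)
  fit_ig <- function(pos, d_pos) {
    if (ig_method == "compound") fit_invgamma_noisy(pos, d_pos)
    else fit_invgamma(pos)
  }

  sel_s <- q_snp <= fdr_level & s2s_hat >= pool_floor
  if (sum(sel_s) < min_sig) {
    warning("fewer than ", min_sig,
            " genes significant for SNP variance; using all positive estimates for (a_s, b_s)")
    sel_s <- s2s_hat >= pool_floor
  }
  ig_s <- fit_ig(s2s_hat[sel_s], d_s[sel_s])

  if (zero_rule == "floor") s2r_hat <- pmax(s2r_hat, zero_floor)
  pos_r <- s2r_hat >= pool_floor
  if (sum(pos_r) < 2L)
    stop("too few positive replicate-variance estimates")
  ig_r <- fit_ig(s2r_hat[pos_r], d_r[pos_r])

  hp <- hyperparameters(mu = mu, sigma2 = sigma2,
                        a_s = ig_s$a, b_s = ig_s$b,
                        a_r = ig_r$a, b_r = ig_r$b)
  attr(hp, "fits") <- fits
  attr(hp, "selection") <- data.frame(
    gene = names(genes), p_gene = p_gene, q_gene = q_gene,
    p_snp = p_snp, q_snp = q_snp, row.names = NULL,
    stringsAsFactors = FALSE)
  hp
}

#' Empirical-Bayes plug-in estimates for one gene
#'
#' Shrinks the full-model maximum-likelihood estimates toward the
#' genome-wide prior:
#' \deqn{\tilde\beta_g = \frac{\widehat{Var}(\hat\beta_g)\,\mu +
#'   \sigma^2 \hat\beta_g}{\widehat{Var}(\hat\beta_g) + \sigma^2}, \quad
#' \tilde\sigma^2_{sg} = \frac{d_{sg}\hat\sigma^2_{sg} + 2 b_s}
#'   {d_{sg} + 2 a_s}, \quad
#' \tilde\sigma^2_{rg} = \frac{d_{rg}\hat\sigma^2_{rg} + 2 b_r}
#'   {d_{rg} + 2 a_r},}
#' with degrees of freedom \eqn{d_{sg} = J_g - 1}, \eqn{d_{rg} = K - 1}.
#' The variance plug-ins are strictly positive even when the MLE sits on
#' the zero boundary.
#'
#' @param fit a model-4 [fit_ml()] result (the gene effect must be free so
#'   that \eqn{\widehat{Var}(\hat\beta_g)} exists).
#' @param hp a [hyperparameters()] object.
#' @param J_g,K number of SNPs and replicates of the gene; defaults taken
#'   from the fit.
#' @return an object of class `"eb_estimates"`: list with `beta_tilde`,
#'   `sigma2_s_tilde`, `sigma2_r_tilde`, `d_sg`, `d_rg`.
#' @export
eb_estimates <- function(fit, hp, J_g = fit$J, K = fit$K) {
  if (!fit$model %in% c(2L, 4L) || is.null(fit$var_beta_hat))
    stop("eb_estimates requires the model-4 fit (free gene effect)")
  v <- fit$var_beta_hat
  if (!is.finite(v)) stop("var_beta_hat unavailable for gene ", fit$gene_id)
  stopifnot(J_g >= 2L, K >= 2L)
  d_sg <- J_g - 1L
  d_rg <- K - 1L
  beta_tilde <- (v * hp$mu + hp$sigma2 * fit$beta_hat) / (v + hp$sigma2)
  sigma2_s_tilde <- (d_sg * fit$sigma2_s_hat + 2 * hp$b_s) /
    (d_sg + 2 * hp$a_s)
  sigma2_r_tilde <- (d_rg * fit$sigma2_r_hat + 2 * hp$b_r) /
    (d_rg + 2 * hp$a_r)
  structure(
    list(beta_tilde = beta_tilde,
         sigma2_s_tilde = sigma2_s_tilde,
         sigma2_r_tilde = sigma2_r_tilde,
         d_sg = d_sg, d_rg = d_rg,
         # prior log-densities at the plug-ins: the marginal likelihood of a
         # model is the full integrand of the Bayesian model average with the
         # plug-ins entered, so each model picks up the prior density of the
         # parameters it includes (the Occam penalty of the richer models)
         log_prior_beta = stats::dnorm(beta_tilde, hp$mu, sqrt(hp$sigma2),
                                       log = TRUE),
         log_prior_s2s = dinvgamma_log(sigma2_s_tilde, hp$a_s, hp$b_s),
         log_prior_s2r = dinvgamma_log(sigma2_r_tilde, hp$a_r, hp$b_r)),
    class = "eb_estimates")
}
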