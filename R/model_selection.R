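#' Approximate marginal likelihood of one candidate model
#'
#' The four candidate models are indexed by the presence of the gene effect
#' and of SNP-level variation: model 1 has \eqn{\beta_g = 0,
#' \sigma^2_{sg} = 0}; model 2 has \eqn{\beta_g \neq 0}; model 3 has
#' \eqn{\sigma^2_{sg} \neq 0}; model 4 has both.  The replicate variance is
#' present in all four.  The empirical-Bayes plug-ins \eqn{(\tilde\beta_g,
#' \tilde\sigma^2_{sg}, \tilde\sigma^2_{rg})} replace the components the
#' model includes (zero where excluded), and the remaining random-effect
#' integral is evaluated by a single Laplace approximation — the parameters
#' are fixed, not optimized.
#'
#' With `include_prior = TRUE` (the default) the value is the full
#' model-averaging integrand at the plug-ins: the Laplace random-effect
#' integral times the prior density of the parameters the model includes
#' (\eqn{N(\mu, \sigma^2)} for the gene effect, the inverse-gamma densities
#' for the variance components).  These factors carry the Occam penalty of
#' the richer models; without them the point-estimate plug-in systematically
#' favours the models with more free parameters and the posterior
#' probabilities lose their frequentist calibration.
#' `include_prior = FALSE` gives the bare random-effect integral.
#'
#' @inheritParams laplace_loglik
#' @param model integer in 1..4.
#' @param eb an [eb_estimates()] object for the gene.
#' @param include_prior include the prior density factors of the plugged-in
#'   parameters.
#' @return log marginal likelihood.
#' @export
marginal_loglik <- function(gene, model, eb, control = blmrm_control(),
                            include_prior = TRUE) {
  marginal_loglik_cells(gene_cells(gene), model, eb, control, include_prior)
}

marginal_loglik_cells <- function(cells, model, eb, control,
                                  include_prior = TRUE) {
  stopifnot(model %in% 1:4)
  use_beta <- model %in% c(2L, 4L)
  use_s <- model %in% c(3L, 4L)
  beta <- if (use_beta) eb$beta_tilde else 0
  s2s <- if (use_s) eb$sigma2_s_tilde else 0
  ll <- laplace_loglik_cells(cells, beta, s2s, eb$sigma2_r_tilde,
                             control)$loglik
  if (include_prior) {
    ll <- ll + eb$log_prior_s2r
    if (use_beta) ll <- ll + eb$log_prior_beta
    if (use_s) ll <- ll + eb$log_prior_s2s
  }
  ll
}

# nested-Laplace marginal likelihood: integrates the parameters the model
# includes against their genome-level priors (beta ~ N(mu, sigma2),
# variances ~ IG) with an inner Laplace over the random effects and an outer
# Laplace over the parameters, on the original parameter scale
marginal_pure_laplace_cells <- function(cells, model, hp, control) {
  use_beta <- model %in% c(2L, 4L)
  use_s <- model %in% c(3L, 4L)

  logpost <- function(theta) {
    i <- 1L
    beta <- 0
    s2s <- 0
    if (use_beta) { beta <- theta[[i]]; i <- i + 1L }
    if (use_s) { s2s <- theta[[i]]; i <- i + 1L }
    s2r <- theta[[i]]
    if (s2r <= 0 || (use_s && s2s <= 0)) return(-Inf)
    ll <- laplace_loglik_cells(cells, beta, s2s, s2r, control)$loglik
    lp <- dinvgamma_log(s2r, hp$a_r, hp$b_r)
    if (use_beta) lp <- lp + stats::dnorm(beta, hp$mu, sqrt(hp$sigma2),
                                          log = TRUE)
    if (use_s) lp <- lp + dinvgamma_log(s2s, hp$a_s, hp$b_s)
    ll + lp
  }

  # optimize on a transformed scale for stability, Hessian on original scale
  to_theta <- function(par) {
    i <- 1L
    out <- numeric(length(par))
    if (use_beta) { out[i] <- par[i]; i <- i + 1L }
    if (use_s) { out[i] <- exp(par[i]); i <- i + 1L }
    out[i] <- exp(par[i])
    out
  }
  neg <- function(par) -logpost(to_theta(par))
  par0 <- c(if (use_beta) hp$mu,
            if (use_s) log(hp$b_s / (hp$a_s + 1)),
            log(hp$b_r / (hp$a_r + 1)))
  opt <- stats::optim(par0, neg, method = "BFGS",
                      control = list(maxit = 200))
  theta_hat <- to_theta(opt$par)
  d <- length(theta_hat)
  H <- tryCatch(stats::optimHess(theta_hat, function(th) -logpost(th)),
                error = function(e) NULL)
  if (is.null(H)) H <- diag(1e6, d)
  ldet <- determinant(H, logarithm = TRUE)
  if (ldet$sign <= 0) {
    # near-singular curvature at the mode: regularize
    ldet <- determinant(H + diag(1e-6, d), logarithm = TRUE)
  }
  -opt$value + 0.5 * d * log(2 * pi) - 0.5 * as.numeric(ldet$modulus)
}

#' Posterior model probabilities for one gene
#'
#' Combines the four approximate marginal likelihoods with a model prior
#' (uniform by default) via log-sum-exp normalization, and derives the
#' probabilities of the three scientific hypotheses: gene-level ASE
#' (models 2 or 4), SNP-level variation of ASE (models 3 or 4), and both
#' simultaneously (model 4).
#'
#' @inheritParams marginal_loglik
#' @param prior prior probabilities over the four models; strictly positive,
#'   normalized internally (entries below `1e-12` are floored).
#' @return an object of class `"model_posterior"`: list with `gene_id`,
#'   `log_marginals`, `posteriors`, `p_gene_ase`, `p_snp_var`, `p_both`,
#'   `selected_model`.
#' @export
model_posteriors <- function(gene, eb, prior = rep(0.25, 4),
                             control = blmrm_control()) {
  cells <- gene_cells(gene)
  logm <- vapply(1:4, function(m)
    marginal_loglik_cells(cells, m, eb, control), numeric(1))
  posterior_from_logm(gene$gene_id, logm, prior)
}

posterior_from_logm <- function(gene_id, logm, prior = rep(0.25, 4)) {
  stopifnot(length(logm) == 4L, length(prior) == 4L, all(prior >= 0))
  prior <- pmax(prior, 1e-12)
  prior <- prior / sum(prior)
  if (all(!is.finite(logm)))
    stop("all marginal likelihoods are -Inf for gene ", gene_id)
  lw <- logm + log(prior)
  m <- max(lw)
  post <- exp(lw - m)
  post <- post / sum(post)
  prob1 <- function(x) min(max(x, 0), 1)
  structure(
    list(gene_id = gene_id, log_marginals = logm, posteriors = post,
         p_gene_ase = prob1(post[[2L]] + post[[4L]]),
         p_snp_var = prob1(post[[3L]] + post[[4L]]),
         p_both = prob1(post[[4L]]),
         selected_model = which.max(post)),
    class = "model_posterior")
}

#' Bayesian FDR selection from posterior probabilities
#'
#' Orders genes by decreasing posterior probability of the tested hypothesis
#' and finds the largest prefix whose mean posterior error probability
#' \eqn{\sum_{i \le l} (1 - P_{(i)}) / l} does not exceed `alpha`; the first
#' \eqn{l} genes are declared significant.  Ties are broken by stable input
#' order.
#'
#' @param posteriors posterior probabilities in `[0, 1]`, one per gene.
#' @param alpha target FDR level in (0, 1).
#' @return list with `l` (number of significant genes) and `significant`
#'   (logical flags in input order).
#' @export
bayes_fdr_select <- function(posteriors, alpha) {
  stopifnot(alpha > 0, alpha < 1,
            all(posteriors >= -1e-9 & posteriors <= 1 + 1e-9, na.rm = TRUE))
  posteriors <- pmin(pmax(posteriors, 0), 1)
  ok <- !is.na(posteriors)
  ord <- order(posteriors[ok], decreasing = TRUE)  # stable
  cm <- cumsum(1 - posteriors[ok][ord]) / seq_along(ord)
  l <- if (any(cm <= alpha)) max(which(cm <= alpha)) else 0L
  sig <- rep(NA, length(posteriors))
  sig_ok <- rep(FALSE, sum(ok))
  if (l > 0L) sig_ok[ord[seq_len(l)]] <- TRUE
  sig[ok] <- sig_ok
  list(l = as.integer(l), significant = sig)
}

#' Run the full Bayesian model-selection pipeline on a genome
#'
#' For every gene: fit the full model by maximum likelihood, shrink the
#' estimates toward the genome-wide empirical-Bayes prior
#' ([eb_estimates()]), evaluate the four marginal likelihoods, convert them
#' to posterior model probabilities, and flag significance for the three
#' hypotheses (gene ASE, SNP variation, both) by [bayes_fdr_select()] at
#' level `alpha`.  With `laplace_only = TRUE` the marginal likelihoods are
#' instead computed by nested Laplace integration of the model parameters
#' against their priors (a comparator that avoids the plug-in step at the
#' cost of stacked approximations).
#'
#' @param ds a filtered [ase_dataset()].
#' @param alpha FDR level.
#' @param hp optional [hyperparameters()]; estimated from `ds` by
#'   [estimate_hyperparameters()] when `NULL`.
#' @param laplace_only use the nested-Laplace comparator instead of the
#'   empirical-Bayes plug-ins.
#' @param prior model prior over the four candidate models.
#' @param control a [blmrm_control()] list.
#' @param fits optional named list of precomputed raw-count model-4
#'   [fit_ml()] results keyed by gene id (reused when available).
#' @return data frame with one row per gene: `gene`, `logM1..logM4`,
#'   `P1..P4`, `p_gene_ase`, `p_snp_var`, `p_both`, `selected_model`,
#'   `sig_gene`, `sig_snp`, `sig_both`, `beta_tilde`, `sigma2_s_tilde`,
#'   `sigma2_r_tilde`, `converged`.  Genes whose fits failed carry `NA`
#'   rows and are excluded from the FDR ordering.  The estimated
#'   hyperparameters are attached as attribute `"hyperparameters"`.
#' @export
run_blmrm <- function(ds, alpha = 0.05, hp = NULL, laplace_only = FALSE,
                      prior = rep(0.25, 4), control = blmrm_control(),
                      fits = NULL) {
  if (is.null(hp)) hp <- estimate_hyperparameters(ds, fdr_level = alpha,
                                                  control = control)
  genes <- ds$genes
  rows <- lapply(genes, function(g) {
    cells <- gene_cells(g)
    res <- tryCatch({
      if (laplace_only) {
        logm <- vapply(1:4, function(m)
          marginal_pure_laplace_cells(cells, m, hp, control), numeric(1))
        pos <- posterior_from_logm(g$gene_id, logm, prior)
        list(pos = pos, eb = NULL, converged = TRUE)
      } else {
        fit4 <- fits[[g$gene_id]]
        if (is.null(fit4))
          fit4 <- fit_ml_cells(cells, 4L, control, g$gene_id)
        if (!is.finite(fit4$var_beta_hat)) {
          # fall back to the richest reduced model with a free gene effect
          fit4 <- fit_ml_cells(cells, 2L, control, g$gene_id)
        }
        eb <- eb_estimates(fit4, hp, J_g = cells$J, K = cells$K)
        logm <- vapply(1:4, function(m)
          marginal_loglik_cells(cells, m, eb, control), numeric(1))
        pos <- posterior_from_logm(g$gene_id, logm, prior)
        list(pos = pos, eb = eb, converged = fit4$converged)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(gene = g$gene_id, logM1 = NA_real_, logM2 = NA_real_,
                        logM3 = NA_real_, logM4 = NA_real_, P1 = NA_real_,
                        P2 = NA_real_, P3 = NA_real_, P4 = NA_real_,
                        p_gene_ase = NA_real_, p_snp_var = NA_real_,
                        p_both = NA_real_, selected_model = NA_integer_,
                        beta_tilde = NA_real_, sigma2_s_tilde = NA_real_,
                        sigma2_r_tilde = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    pos <- res$pos
    data.frame(gene = g$gene_id,
               logM1 = pos$log_marginals[[1L]],
               logM2 = pos$log_marginals[[2L]],
               logM3 = pos$log_marginals[[3L]],
               logM4 = pos$log_marginals[[4L]],
               P1 = pos$posteriors[[1L]], P2 = pos$posteriors[[2L]],
               P3 = pos$posteriors[[3L]], P4 = pos$posteriors[[4L]],
               p_gene_ase = pos$p_gene_ase, p_snp_var = pos$p_snp_var,
               p_both = pos$p_both,
               selected_model = pos$selected_model,
               beta_tilde = if (is.null(res$eb)) NA_real_ else
                 res$eb$beta_tilde,
               sigma2_s_tilde = if (is.null(res$eb)) NA_real_ else
                 res$eb$sigma2_s_tilde,
               sigma2_r_tilde = if (is.null(res$eb)) NA_real_ else
                 res$eb$sigma2_r_tilde,
               converged = res$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  out$sig_gene <- bayes_fdr_select(out$p_gene_ase, alpha)$significant
  out$sig_snp <- bayes_fdr_select(out$p_snp_var, alpha)$significant
  out$sig_both <- bayes_fdr_select(out$p_both, alpha)$significant
  out <- out[, c("gene", paste0("logM", 1:4), paste0("P", 1:4),
                 "p_gene_ase", "p_snp_var", "p_both", "selected_model",
                 "sig_gene", "sig_snp", "sig_both", "beta_tilde",
                 "sigma2_s_tilde", "sigma2_r_tilde", "converged")]
  attr(out, "hyperparameters") <- hp
  out
}
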