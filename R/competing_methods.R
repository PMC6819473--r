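#' Pooled exact binomial test for gene-level ASE
#'
#' Pools maternal and total counts over all observed cells of the gene and
#' applies the two-sided exact binomial test of \eqn{p = 0.5}.  The simplest
#' and most widely used ASE test; it ignores SNP-level and replicate-level
#' variation entirely, which is what inflates its false discovery rate when
#' those variance components are present.
#'
#' @param gene an [ase_counts()] object.
#' @return a p-value.
#' @export
binomial_ase_test <- function(gene) {
  y <- sum(gene$y[gene$observed])
  n <- sum(gene$n[gene$observed])
  if (n == 0) {
    warning("no reads for gene ", gene$gene_id, "; p = 1")
    return(1)
  }
  stats::binom.test(y, n, p = 0.5)$p.value
}

#' Empirical-logit location test for gene-level ASE
#'
#' Tests whether the mean of the empirical logits
#' \eqn{\log\{(y + 0.5) / (n - y + 0.5)\}} across observed cells is zero,
#' via the F statistic of the intercept-only linear model (equivalently a
#' one-sample t-test) — the gene-effect analogue of the ANOVA-style
#' pipelines.
#'
#' @param gene an [ase_counts()] object with at least two observed cells.
#' @return a p-value, with attribute `degenerate = TRUE` when the logits
#'   have zero variance (then `p = 1` if the common logit is zero, else
#'   `p = 0`).
#' @export
anova_ase_test <- function(gene) {
  y <- gene$y[gene$observed]
  n <- gene$n[gene$observed]
  if (length(y) < 2L) stop("need >= 2 observed cells")
  logit <- log((y + 0.5) / (n - y + 0.5))
  if (stats::var(logit) == 0) {
    p <- if (mean(logit) == 0) 1 else 0
    return(structure(p, degenerate = TRUE))
  }
  stats::t.test(logit, mu = 0)$p.value
}

#' Plain GLMM likelihood-ratio tests
#'
#' The no-prior baseline: likelihood-ratio tests from the maximum-likelihood
#' fits of the four model configurations on raw counts.  `p_gene` compares
#' model 4 vs 3 (\eqn{\chi^2_1}); `p_snp` compares model 4 vs 2 (50:50
#' \eqn{\chi^2_0 : \chi^2_1} boundary mixture); `p_both` compares model 4
#' vs 1 (50:50 \eqn{\chi^2_1 : \chi^2_2} mixture, one parameter interior
#' and one on the boundary under the joint null).
#'
#' @inheritParams laplace_loglik
#' @param fits optional precomputed list of [fit_ml()] results for models
#'   1..4 named `"1"`..`"4"`.
#' @return list with `p_gene`, `p_snp`, `p_both`.
#' @export
glmm_tests <- function(gene, fits = NULL, control = blmrm_control()) {
  if (is.null(fits)) {
    cells <- gene_cells(gene)
    fits <- lapply(stats::setNames(1:4, 1:4), function(m)
      fit_ml_cells(cells, m, control, gene$gene_id))
  }
  ll <- vapply(as.character(1:4), function(m) fits[[m]]$loglik, numeric(1))
  list(p_gene = lrt_pvalue(ll[["4"]], ll[["3"]], df = 1L),
       p_snp = lrt_pvalue(ll[["4"]], ll[["2"]], df = 1L, boundary = TRUE),
       p_both = lrt_pvalue(ll[["4"]], ll[["1"]], df = 2L, boundary = TRUE))
}

#' Storey q-values
#'
#' Estimates the null proportion \eqn{\pi_0} by the smoother method on the
#' grid \eqn{\lambda = 0.05, 0.10, \dots, 0.95} (a df-3 smoothing spline of
#' \eqn{\hat\pi_0(\lambda)} evaluated at the largest \eqn{\lambda}), then
#' computes \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j},
#' clipped to `[0, 1]`.  Monotonicity in the p-values is enforced by
#' construction.
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda grid for the \eqn{\pi_0} smoother.
#' @param pi0 optional fixed \eqn{\pi_0} overriding the smoother.
#' @return q-values in the input order, with attribute `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20L || max(p, na.rm = TRUE) < max(lambda)) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  attr(out, "pi0") <- pi0
  out
}
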