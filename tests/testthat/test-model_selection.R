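test_that("posterior normalization and hand-computed example", {
  # four equal marginals -> uniform posteriors
  p <- posterior_from_logm("g", rep(-5, 4))
  expect_equal(p$posteriors, rep(0.25, 4))

  # log marginals (0, log 3, 0, 0) -> (1/6, 1/2, 1/6, 1/6)
  p <- posterior_from_logm("g", c(0, log(3), 0, 0))
  expect_equal(p$posteriors, c(1, 3, 1, 1) / 6)
  expect_equal(p$p_gene_ase, 2 / 3)
  expect_equal(p$p_snp_var, 1 / 3)
  expect_equal(p$p_both, 1 / 6)
  expect_equal(p$selected_model, 2L)

  # a zero prior entry is floored, not fatal
  p <- posterior_from_logm("g", rep(0, 4), prior = c(1, 0, 0, 0))
  expect_true(all(is.finite(p$posteriors)))
  expect_equal(sum(p$posteriors), 1, tolerance = 1e-10)

  expect_error(posterior_from_logm("g", rep(-Inf, 4)), "-Inf")

  set.seed(2)
  for (i in 1:25) {
    p <- posterior_from_logm("g", rnorm(4, sd = 10))
    expect_equal(sum(p$posteriors), 1, tolerance = 1e-10)
    expect_equal(p$p_gene_ase + p$posteriors[[1L]] + p$posteriors[[3L]], 1,
                 tolerance = 1e-10)
    expect_equal(p$selected_model, which.max(p$posteriors))
  }
})

test_that("plug-in marginals match the quadrature oracle and favour the right model", {
  set.seed(13)
  g <- random_gene(J = 2, K = 2, nmax = 40, beta = 0.5, s2s = 0.3,
                   s2r = 0.2)
  eb <- random_eb()
  for (m in 1:4) {
    expect_equal(marginal_loglik(g, m, eb),
                 oracle_marginal(g, m, eb), tolerance = 0.05)
  }

  # full maternal expression: the gene-effect model dominates the null
  gsk <- flat_gene(J = 2, K = 2, n = 30, y = matrix(30, 2, 2))
  ebs <- random_eb()
  ebs$beta_tilde <- 2.5
  expect_gt(marginal_loglik(gsk, 2, ebs), marginal_loglik(gsk, 1, ebs))
  expect_gt(oracle_marginal(gsk, 2, ebs), oracle_marginal(gsk, 1, ebs))
})

test_that("coincident plug-ins give coincident marginals", {
  set.seed(17)
  g <- random_gene(J = 2, K = 3, nmax = 30, beta = 0, s2r = 0.1)
  eb <- random_eb()
  eb$beta_tilde <- 0
  # with beta_tilde = 0 models 1 and 2 differ only by the prior factor
  expect_equal(marginal_loglik(g, 1, eb, include_prior = FALSE),
               marginal_loglik(g, 2, eb, include_prior = FALSE))
})

test_that("Bayesian FDR selection reproduces the hand-computed prefix", {
  sel <- bayes_fdr_select(c(0.99, 0.98, 0.90, 0.60), alpha = 0.05)
  expect_equal(sel$l, 3L)
  expect_equal(sel$significant, c(TRUE, TRUE, TRUE, FALSE))

  expect_equal(bayes_fdr_select(rep(1, 5), 0.05)$l, 5L)
  expect_equal(bayes_fdr_select(rep(0.9, 5), 0.05)$l, 0L)

  # monotone in alpha
  set.seed(5)
  p <- runif(50)
  ls <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
               function(a) bayes_fdr_select(p, a)$l, integer(1))
  expect_true(all(diff(ls) >= 0))

  # ties keep input order
  sel <- bayes_fdr_select(c(0.99, 0.99, 0.99), 0.05)
  expect_equal(sel$significant, rep(TRUE, 3))
})

test_that("allele swap preserves the null/alternative split when mu = 0", {
  set.seed(43)
  g <- random_gene(J = 3, K = 3, nmax = 50, beta = 0.9, s2s = 0.2,
                   s2r = 0.1)
  hp <- hyperparameters(mu = 0, sigma2 = 4, a_s = 2.35, b_s = 1.37,
                        a_r = 2.03, b_r = 0.09)
  eb <- eb_estimates(fit_ml(g, 4), hp)
  ebs <- eb_estimates(fit_ml(swap_alleles(g), 4), hp)
  expect_equal(ebs$beta_tilde, -eb$beta_tilde, tolerance = 1e-3)
  logm <- vapply(1:4, function(m) marginal_loglik(g, m, eb), numeric(1))
  logms <- vapply(1:4, function(m)
    marginal_loglik(swap_alleles(g), m, ebs), numeric(1))
  expect_equal(logms, logm, tolerance = 0.02)
})

test_that("a one-gene genome is flagged iff its posterior clears the threshold", {
  set.seed(47)
  genes <- list(random_gene(3, 4, nmax = 60, beta = 2, s2r = 0.05,
                            gene_id = "gA"),
                random_gene(3, 4, nmax = 60, beta = 0, s2r = 0.05,
                            gene_id = "gB"))
  ds <- ase_dataset(genes)
  hp <- hyperparameters(0, 4, 2.35, 1.37, 2.03, 0.09)
  res <- run_blmrm(ds, alpha = 0.05, hp = hp)
  expect_equal(nrow(res), 2L)
  expect_equal(res$sig_gene, bayes_fdr_select(res$p_gene_ase, 0.05)$significant)
  expect_equal(sum(res$P1 + res$P2 + res$P3 + res$P4), 2, tolerance = 1e-9)

  one <- run_blmrm(ase_dataset(genes[1]), alpha = 0.05, hp = hp)
  expect_equal(one$sig_gene, 1 - one$p_gene_ase <= 0.05)
})

test_that("the nested-Laplace comparator agrees with plug-in selection on clear genes", {
  set.seed(53)
  hp <- hyperparameters(0, 4, 2.35, 1.37, 2.03, 0.09)
  g <- random_gene(J = 3, K = 4, nmax = 300, beta = 2.5, s2r = 0.02)
  ds <- ase_dataset(list(g))
  res_eb <- run_blmrm(ds, hp = hp)
  res_pl <- run_blmrm(ds, hp = hp, laplace_only = TRUE)
  expect_gt(res_eb$p_gene_ase, 0.95)
  expect_gt(res_pl$p_gene_ase, 0.95)
})
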