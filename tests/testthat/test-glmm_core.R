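test_that("with no random effects the Laplace value is the exact binomial log-likelihood", {
  g <- flat_gene(J = 2, K = 2, n = 20, y = matrix(c(12, 8, 15, 5), 2, 2))
  for (b in c(-1, 0, 0.7)) {
    expect_equal(as.numeric(laplace_loglik(g, b, 0, 0)),
                 sum(dbinom(g$y, g$n, plogis(b), log = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("Laplace log-likelihood matches Gauss-Hermite quadrature on small genes", {
  g <- flat_gene(J = 2, K = 2, n = 20, y = matrix(c(12, 8, 15, 5), 2, 2))
  expect_equal(as.numeric(laplace_loglik(g, 0, 0.5, 0.25)),
               oracle_loglik(g, 0, 0.5, 0.25, n_nodes = 25),
               tolerance = 0.05)
  set.seed(11)
  for (i in 1:20) {
    gene <- random_gene(J = sample(2:3, 1), K = 2, nmax = 50,
                        beta = runif(1, -1.5, 1.5),
                        s2s = runif(1, 0, 1), s2r = runif(1, 0, 1))
    b <- runif(1, -1, 1)
    s2s <- runif(1, 0.05, 1.5)
    s2r <- runif(1, 0.05, 1)
    expect_equal(as.numeric(laplace_loglik(gene, b, s2s, s2r)),
                 oracle_loglik(gene, b, s2s, s2r),
                 tolerance = 0.05)
  }
})

test_that("all-zero maternal counts saturate monotonically as beta decreases", {
  g <- flat_gene(J = 2, K = 2, n = 10, y = matrix(0, 2, 2))
  lls <- vapply(c(-2, -5, -10, -20), function(b)
    as.numeric(laplace_loglik(g, b, 0, 0)), numeric(1))
  expect_true(all(diff(lls) > 0))
  expect_lt(abs(lls[[4L]]), 1e-6)
})

test_that("model-2 fit recovers the pooled binomial MLE on dispersion-free data", {
  g <- flat_gene(J = 2, K = 2, n = 50, y = matrix(40, 2, 2))
  fit <- fit_ml(g, 2)
  expect_equal(fit$beta_hat, qlogis(0.8), tolerance = 0.01)
  expect_lt(fit$sigma2_r_hat, 1e-6)
  expect_true(fit$converged)

  # identical replicate ratios: model 1's free replicate variance collapses
  g1 <- flat_gene(J = 2, K = 3, n = 40, y = matrix(20, 2, 3))
  expect_lt(fit_ml(g1, 1)$sigma2_r_hat, 1e-6)
})

test_that("maximized log-likelihoods respect model nesting", {
  set.seed(23)
  for (i in 1:5) {
    gene <- random_gene(J = 3, K = 3, nmax = 60,
                        beta = runif(1, -2, 2), s2s = runif(1, 0, 0.8),
                        s2r = runif(1, 0, 0.4))
    ll <- vapply(1:4, function(m) fit_ml(gene, m)$loglik, numeric(1))
    expect_true(all(ll[4] >= ll[1:3] - 1e-4))
    expect_true(all(ll[2:3] >= ll[1] - 1e-4))
  }
})

test_that("fits agree with an independent Laplace GLMM implementation", {
  skip_if_not_installed("lme4")
  set.seed(31)
  for (i in 1:4) {
    gene <- random_gene(J = 4, K = 4, nmax = 80, beta = runif(1, -1, 1),
                        s2s = 0.4, s2r = 0.2)
    fit <- fit_ml(gene, 4)
    obs <- which(gene$observed, arr.ind = TRUE)
    df <- data.frame(y = gene$y[obs], n = gene$n[obs],
                     snp = factor(obs[, 1]), rep = factor(obs[, 2]))
    gm <- suppressMessages(suppressWarnings(
      lme4::glmer(cbind(y, n - y) ~ 1 + (1 | snp) + (1 | rep),
                  data = df, family = binomial)))
    expect_equal(fit$loglik, as.numeric(stats::logLik(gm)), tolerance = 1e-3)
    expect_equal(fit$beta_hat, unname(lme4::fixef(gm)[[1L]]),
                 tolerance = 0.01)
  }
})

test_that("allele swap negates the gene effect and preserves variances and tests", {
  set.seed(57)
  gene <- random_gene(J = 3, K = 3, nmax = 60, beta = 0.8, s2s = 0.3,
                      s2r = 0.2)
  sw <- swap_alleles(gene)
  f <- fit_ml(gene, 4)
  fs <- fit_ml(sw, 4)
  expect_equal(fs$beta_hat, -f$beta_hat, tolerance = 1e-3)
  expect_equal(fs$sigma2_s_hat, f$sigma2_s_hat, tolerance = 1e-3)
  expect_equal(fs$sigma2_r_hat, f$sigma2_r_hat, tolerance = 1e-3)
  expect_equal(lrt_gene(sw), lrt_gene(gene), tolerance = 1e-3)
  expect_equal(lrt_snp(sw), lrt_snp(gene), tolerance = 1e-3)
})

test_that("likelihood-ratio p-values follow their reference distributions", {
  # identical fits -> p = 1
  f <- structure(list(loglik = -10), class = "ml_fit")
  expect_equal(lrt_gene(NULL, fit_full = f, fit_null = f), 1)
  # Delta 2*loglik = 3.84 on chi^2_1 -> p ~ 0.05
  f0 <- structure(list(loglik = -10), class = "ml_fit")
  f1 <- structure(list(loglik = -10 + 3.84 / 2), class = "ml_fit")
  p_gene <- lrt_gene(NULL, fit_full = f1, fit_null = f0)
  expect_equal(p_gene, 0.05, tolerance = 2e-3)
  expect_equal(p_gene, pchisq(3.84, 1, lower.tail = FALSE))
  # boundary mixture halves the tail probability
  expect_equal(lrt_snp(NULL, fit_full = f1, fit_null = f0), p_gene / 2)
})

test_that("gene-level LRT holds its type-I error on null genes", {
  set.seed(73)
  G <- 400
  p <- vapply(seq_len(G), function(i) {
    gene <- random_gene(J = 3, K = 4, nmax = 60, beta = 0, s2s = 0,
                        s2r = 0.05)
    lrt_gene(gene)
  }, numeric(1))
  rate <- mean(p <= 0.05)
  se <- sqrt(0.05 * 0.95 / G)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-9)
})

test_that("parameter recovery at large counts", {
  set.seed(91)
  gene <- random_gene(J = 12, K = 8, nmax = 2000, beta = 1.0, s2s = 0.4,
                      s2r = 0.2)
  gene$n[] <- 2000
  gene$y <- matrix(rbinom(96, 2000,
                          plogis(1.0 + outer(rnorm(12, 0, sqrt(0.4)),
                                             rnorm(8, 0, sqrt(0.2)), `+`))),
                   12, 8, dimnames = dimnames(gene$n))
  fit <- fit_ml(gene, 4)
  expect_lt(abs(fit$beta_hat - 1.0), 3 * sqrt(0.4 / 12 + 0.2 / 8))
})
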