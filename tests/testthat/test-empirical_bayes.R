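test_that("pseudo-count adjustment adds one read per allele in observed cells", {
  g <- toy_gene(matrix(c(0, 10, 5, 3), 2, 2), matrix(c(10, 10, 10, 7), 2, 2))
  a <- pseudo_adjust(g)
  expect_equal(unname(a$y), matrix(c(1, 11, 6, 4), 2, 2))
  expect_equal(unname(a$n), matrix(c(12, 12, 12, 9), 2, 2))
  # midpoint ratio is a fixed point
  expect_equal(a$y[[1, 2]] / a$n[[1, 2]], 0.5)
  # unobserved cells stay unobserved
  n <- matrix(c(10, NA, 8, 12), 2, 2)
  g2 <- toy_gene(matrix(c(4, NA, 3, 6), 2, 2), n)
  a2 <- pseudo_adjust(g2)
  expect_equal(a2$observed, g2$observed)
  expect_true(is.na(a2$y[[2, 1]]))
})

test_that("shrinkage estimators follow the closed forms and their limits", {
  hp <- hyperparameters(mu = 0.43, sigma2 = 4.62, a_s = 2.35, b_s = 1.37,
                        a_r = 2.03, b_r = 0.09)
  mkfit <- function(beta, v, s2s, s2r, J = 3L, K = 4L)
    structure(list(model = 4L, beta_hat = beta, var_beta_hat = v,
                   sigma2_s_hat = s2s, sigma2_r_hat = s2r, J = J, K = K,
                   gene_id = "g"), class = "ml_fit")

  # exact arithmetic
  eb <- eb_estimates(mkfit(2, 0.5, 0.8, 0.1), hp)
  expect_equal(eb$beta_tilde, (0.5 * 0.43 + 4.62 * 2) / (0.5 + 4.62))
  expect_equal(eb$sigma2_s_tilde, (2 * 0.8 + 2 * 1.37) / (2 + 2 * 2.35))
  expect_equal(eb$sigma2_r_tilde, (3 * 0.1 + 2 * 0.09) / (3 + 2 * 2.03))

  # Var(beta_hat) -> 0: no shrinkage of the gene effect
  expect_equal(eb_estimates(mkfit(1.7, 0, 0.3, 0.1), hp)$beta_tilde, 1.7)

  # zero SNP variance with d_sg = 2: value fixed by the prior alone
  eb0 <- eb_estimates(mkfit(0, 0.1, 0, 0.1), hp)
  expect_equal(eb0$sigma2_s_tilde, 2 * 1.37 / (2 + 2 * 2.35))
  expect_equal(round(eb0$sigma2_s_tilde, 3), 0.409)
  expect_gt(eb0$sigma2_s_tilde, 0)

  # d -> infinity: shrinkage vanishes
  ebL <- eb_estimates(mkfit(0, 0.1, 0.5, 0.33, J = 20001L, K = 10001L), hp)
  expect_equal(ebL$sigma2_s_tilde, 0.5, tolerance = 1e-3)
  expect_equal(ebL$sigma2_r_tilde, 0.33, tolerance = 1e-3)

  # shrinkage always lands strictly between the MLE and the prior mean
  set.seed(3)
  for (i in 1:20) {
    b <- rnorm(1, 0, 3)
    v <- runif(1, 0.01, 2)
    eb <- eb_estimates(mkfit(b, v, runif(1, 0, 2), runif(1, 0, 1)), hp)
    expect_true(eb$beta_tilde >= min(b, hp$mu) - 1e-12 &&
                  eb$beta_tilde <= max(b, hp$mu) + 1e-12)
  }

  # a model fit without a free gene effect cannot be shrunk
  f3 <- structure(list(model = 3L, beta_hat = 0, var_beta_hat = NA_real_,
                       sigma2_s_hat = 0.1, sigma2_r_hat = 0.1, J = 3L,
                       K = 4L, gene_id = "g"), class = "ml_fit")
  expect_error(eb_estimates(f3, hp), "model-4")
})

test_that("sigma2_s_tilde increases strictly with the MLE", {
  hp <- hyperparameters(0, 1, 2.35, 1.37, 2.03, 0.09)
  vals <- seq(0, 3, by = 0.25)
  sh <- (2 * vals + 2 * hp$b_s) / (2 + 2 * hp$a_s)
  expect_true(all(diff(sh) > 0))
})

test_that("inverse-gamma MLE recovers parameters from direct IG samples", {
  set.seed(19)
  x <- 1 / rgamma(5000, shape = 3, rate = 2)
  fit <- fit_invgamma(x)
  expect_lt(abs(fit$a - 3) / 3, 0.1)
  expect_lt(abs(fit$b - 2) / 2, 0.1)
})

test_that("compound MLE deconvolves chi-square noise that the direct fit cannot", {
  set.seed(29)
  d <- 3
  s2 <- 1 / rgamma(3000, shape = 2.03, rate = 0.09)
  s2hat <- s2 * rchisq(3000, d) / d
  noisy <- fit_invgamma_noisy(s2hat, d)
  expect_lt(abs(noisy$a - 2.03), 0.35)
  expect_lt(abs(noisy$b - 0.09), 0.02)
  direct <- fit_invgamma(s2hat)
  expect_gt(abs(direct$a - 2.03), abs(noisy$a - 2.03))
})

test_that("hyperparameter estimation floors a degenerate gene-effect spread", {
  set.seed(37)
  # fabricated per-gene fits: every gene has the identical, clearly
  # significant gene effect (zero spread -> sigma2 must be floored), with
  # ordinary positive variance-component estimates for the IG pools
  G <- 60
  genes <- lapply(seq_len(G), function(i)
    flat_gene(2, 2, n = 10, y = matrix(c(5, 6, 4, 7), 2, 2),
              gene_id = sprintf("g%02d", i)))
  ds <- ase_dataset(genes)
  mk <- function(loglik, beta = 0, s2s = 0, s2r = 0)
    structure(list(model = 4L, beta_hat = beta, var_beta_hat = 0.05,
                   sigma2_s_hat = s2s, sigma2_r_hat = s2r, loglik = loglik,
                   converged = TRUE, n_iter = 1L, J = 4L, K = 4L,
                   gene_id = "g"), class = "ml_fit")
  fits <- lapply(seq_len(G), function(i) {
    s2s <- 1 / rgamma(1, 2.35, rate = 1.37)
    s2r <- 1 / rgamma(1, 2.03, rate = 0.09)
    list("2" = mk(-60), "3" = mk(-80),
         "4" = mk(-40, beta = 2, s2s = s2s, s2r = s2r))
  })
  expect_warning(
    hp <- estimate_hyperparameters(ds, min_sig = 5L, fits = fits),
    "sigma2 floored")
  expect_equal(hp$sigma2, 1e-4)
  expect_equal(hp$mu, 2)
  expect_gt(hp$a_s, 0)
  expect_gt(hp$b_r, 0)
})

test_that("hyperparameters survive a key=value round trip", {
  hp <- hyperparameters(0.43, 4.62, 2.35, 1.37, 2.03, 0.09)
  f <- tempfile()
  write_hyperparameters(hp, f)
  expect_equal(read_hyperparameters(f), hp)
})
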