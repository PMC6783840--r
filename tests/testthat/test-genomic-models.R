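make_regression_data <- function(seed = 1, n = 150, p = 40, h2 = 0.5) {
  set.seed(seed)
  Z <- matrix(rbinom(n * p, 2, 0.3), n, p)
  b <- rnorm(p, 0, 0.3)
  g <- as.vector(Z %*% b)
  e <- rnorm(n, 0, sd(g) * sqrt((1 - h2) / h2))
  list(y = g + e, Z = Z, b = b, g = g, X = matrix(1, n, 1))
}

test_that("BRR with fixed variances matches the closed-form ridge posterior", {
  d <- make_regression_data(seed = 71)
  sm <- 0.09; se <- 1
  spec <- model_spec("BRR", nu_m = 1e9, S_m = sm, nu_e = 1e9, S_e = se,
                     mcmc = mcmc_settings(8000, 1000, 5))
  fit <- fit_whole_regression(d$y, d$X, d$Z, spec, seed = 11)
  # exact conditional posterior mean given the variances, with the flat
  # intercept absorbed by centering
  n <- length(d$y)
  M <- diag(n) - matrix(1 / n, n, n)
  ridge <- solve(crossprod(d$Z, M %*% d$Z) + diag(ncol(d$Z)) * se / sm,
                 crossprod(d$Z, M %*% d$y))
  nret <- nrow(fit$samples$m)
  mcse <- apply(fit$samples$m, 2, sd) / sqrt(nret / 10)  # conservative ESS
  expect_true(all(abs(fit$m_hat - ridge) <= 3 * pmax(mcse, 1e-3)))
})

test_that("Bayes A approaches BRR in the large-df limit", {
  d <- make_regression_data(seed = 73)
  sm <- 0.05
  mc <- mcmc_settings(6000, 1000, 5)
  brr <- fit_whole_regression(d$y, d$X, d$Z,
                              model_spec("BRR", nu_m = 1e9, S_m = sm, mcmc = mc),
                              seed = 3)
  ba <- fit_whole_regression(d$y, d$X, d$Z,
                             model_spec("BA", nu_m = 1e9, S_m = sm, mcmc = mc),
                             seed = 3)
  expect_lt(max(abs(brr$m_hat - ba$m_hat)), 0.05)
  expect_gt(cor(brr$m_hat, ba$m_hat), 0.99)
})

test_that("null data leave Bayes C inclusion at the prior mass", {
  set.seed(79)
  n <- 400; p <- 60
  Z <- matrix(rbinom(n * p, 2, 0.4), n, p)
  y <- rnorm(n)  # independent of all markers
  spec <- model_spec("BC", pi = 0.5, pi_fixed = TRUE,
                     mcmc = mcmc_settings(4000, 1000, 5))
  fit <- fit_whole_regression(y, matrix(1, n, 1), Z, spec, seed = 31)
  incl <- colMeans(fit$samples$delta)
  expect_lt(abs(mean(incl) - 0.5), 0.1)
})

test_that("genomic variance evaluates each model formula directly", {
  # common-variance form: 2 sigma_m2 sum p(1-p)
  s_common <- list(sigma_m2 = c(0.3, 0.3))
  expect_equal(genomic_variance(s_common, c(0.5, 0.2), "BRR"),
               c(0.246, 0.246))
  # per-marker form with inclusion masking for Bayes B
  s_bb <- list(sigma_mi2 = rbind(c(0.4, 0.2)), delta = rbind(c(1L, 0L)))
  expect_equal(genomic_variance(s_bb, c(0.5, 0.5), "BB"),
               2 * (0.25 * 0.4))
  s_ba <- list(sigma_mi2 = rbind(c(0.4, 0.2)))
  expect_equal(genomic_variance(s_ba, c(0.5, 0.5), "BA"),
               2 * (0.25 * 0.4 + 0.25 * 0.2))
  # LASSO form: 2 sum tau2 sigma_e2 p(1-p)
  s_bl <- list(tau2 = rbind(c(0.5, 0.2)), sigma_e2 = 1)
  expect_equal(genomic_variance(s_bl, c(0.5, 0.5), "BL"), 0.35)
  # monomorphic columns contribute nothing
  expect_equal(genomic_variance(s_common, c(1e-12, 0.5), "BRR"),
               2 * s_common$sigma_m2 * 0.25, tolerance = 1e-6)
  expect_error(genomic_variance(s_common, c(0.5, 0.5), "BL"), "mismatch")
})

test_that("heritability posterior is the per-draw variance ratio", {
  h <- heritability_posterior(rep(1, 10), rep(3, 10))
  expect_equal(h$mean, 0.25)
  expect_equal(unname(h$ci90), c(0.25, 0.25))
  h0 <- heritability_posterior(rep(0, 10), rep(3, 10))
  expect_equal(h0$mean, 0)
  expect_error(heritability_posterior(c(1, -1), c(1, 1)), "positive")
  expect_error(heritability_posterior(1:3, 1:2), "equal length")
})

test_that("genetic gain follows the truncation-selection formula", {
  gg <- genetic_gain(rnorm(646), 0.1006, 10)
  expect_equal(gg$n_selected, 65)
  gg2 <- genetic_gain(c(1, 2, 3, 4), 0.5, 10)
  expect_equal(gg2$gg_percent, 10)
  gg3 <- genetic_gain(rep(2, 50), 0.1, 5)
  expect_equal(gg3$gg_percent, 0)
  expect_error(genetic_gain(1:10, 0.5, 0), "non-zero")
  expect_error(genetic_gain(1:10, 0, 1), "selection_fraction")
})

test_that("variable-selection models shrink null markers harder than ridge", {
  set.seed(83)
  n <- 300; p <- 200; n_qtl <- 10
  Z <- matrix(rbinom(n * p, 2, 0.3), n, p)
  qtl <- sample.int(p, n_qtl)
  b <- rep(0, p); b[qtl] <- rnorm(n_qtl, 0, 1)
  g <- as.vector(Z %*% b)
  y <- g + rnorm(n, 0, sd(g))
  mc <- mcmc_settings(3000, 1000, 5)
  X <- matrix(1, n, 1)
  null_idx <- setdiff(seq_len(p), qtl)
  m_brr <- abs(fit_whole_regression(y, X, Z, model_spec("BRR", mcmc = mc),
                                    seed = 5)$m_hat)
  for (mod in c("BB", "BC")) {
    m_sel <- abs(fit_whole_regression(y, X, Z, model_spec(mod, mcmc = mc),
                                      seed = 5)$m_hat)
    expect_lt(mean(m_sel[null_idx]), mean(m_brr[null_idx]))
  }
})

test_that("chains are bit-identical under identical seeds and specs", {
  d <- make_regression_data(seed = 89, n = 80, p = 20)
  for (mod in c("BRR", "BA", "BB", "BC", "BL")) {
    spec <- model_spec(mod, mcmc = mcmc_settings(600, 200, 2))
    f1 <- fit_whole_regression(d$y, d$X, d$Z, spec, seed = 17)
    f2 <- fit_whole_regression(d$y, d$X, d$Z, spec, seed = 17)
    expect_identical(f1$samples$m, f2$samples$m)
    expect_identical(f1$sigma_g2, f2$sigma_g2)
  }
})

test_that("genomic variance is invariant under column permutation of chains", {
  d <- make_regression_data(seed = 97, n = 100, p = 30)
  spec <- model_spec("BA", mcmc = mcmc_settings(1000, 400, 2))
  fit <- fit_whole_regression(d$y, d$X, d$Z, spec, seed = 19)
  perm <- sample(ncol(d$Z))
  permuted <- list(sigma_mi2 = fit$samples$sigma_mi2[, perm, drop = FALSE])
  expect_equal(genomic_variance(permuted, fit$freq[perm], "BA"),
               fit$sigma_g2)
})

test_that("GEBVs track true breeding values on the standard scenario", {
  pop <- tiny_population(seed = 101, n_families = 65, n_markers = 200,
                         traits = list(t = list(n_qtl = 50, h2 = 0.4)))
  X <- block_indicators(pop$phenotypes$design_block)
  fit <- fit_whole_regression(pop$phenotypes$t, X, pop$genotypes,
                              model_spec("BRR", mcmc = mcmc_settings(2500, 500, 5)),
                              seed = 23)
  expect_gt(cor(fit$gebv, pop$truth$t$true_breeding_values), 0.5)
})
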