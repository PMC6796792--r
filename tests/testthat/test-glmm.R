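test_that("with identity relatedness the PQL fit matches plain logistic", {
  for (s in 1:3) {
    set.seed(s)
    n <- 600
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, plogis(drop(X %*% c(-0.4, 0.5, 0.3))))
    fit <- fit_logistic_mixed(y, X, diag(n), blocks = seq_len(n))
    ref <- glm.fit(X, y, family = binomial())
    expect_lt(max(abs(fit$coefficients$estimate - ref$coefficients)), 1e-3)
    expect_lt(fit$sigma2g, 0.05)
    expect_true(fit$converged)
  }
})

test_that("degenerate and malformed inputs are rejected", {
  n <- 50
  X <- cbind(1, rnorm(n))
  expect_error(fit_logistic_mixed(rep(0, n), X, diag(n)), "single class")
  expect_error(fit_logistic_mixed(rep(1, n), X, diag(n)), "single class")
  expect_error(fit_logistic_mixed(c(rep(0:1, 25)), cbind(X, X[, 2]),
                                  diag(n)), "full column rank")
  expect_error(fit_logistic_mixed(rbinom(n, 1, .5), X, diag(n - 1)), "n x n")
})

test_that("perfect separation raises a warning but returns estimates", {
  set.seed(4)
  n <- 80
  x <- rnorm(n)
  y <- as.numeric(x > 0)
  expect_warning(
    fit <- fit_logistic_mixed(y, cbind(1, x), diag(n), blocks = seq_len(n)),
    "separation")
  expect_true(fit$separation)
  expect_true(is.finite(fit$coefficients$estimate[2]))
})

test_that("rescaling a covariate rescales its coefficient exactly", {
  set.seed(7)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.6 * x))
  f1 <- fit_logistic_mixed(y, cbind(1, x), diag(n), blocks = seq_len(n))
  f2 <- fit_logistic_mixed(y, cbind(1, 2 * x), diag(n), blocks = seq_len(n))
  expect_equal(f2$coefficients$estimate[2], f1$coefficients$estimate[2] / 2,
               tolerance = 1e-5)
})

test_that("relabelling the counted allele flips the SNP coefficient", {
  sim <- sim_glmm_families(11, n_fam = 50)
  X1 <- sim$X
  X2 <- X1; X2[, "snp"] <- 2 - X2[, "snp"]
  f1 <- fit_logistic_mixed(sim$y, X1, sim$G, blocks = sim$fam)
  f2 <- fit_logistic_mixed(sim$y, X2, sim$G, blocks = sim$fam)
  expect_equal(f2$coefficients$estimate[4], -f1$coefficients$estimate[4],
               tolerance = 1e-5)
  expect_equal(f2$coefficients$se[4], f1$coefficients$se[4],
               tolerance = 1e-5)
})

test_that("a known family SNP effect is recovered on average", {
  est <- vapply(1:40, function(s) {
    sim <- sim_glmm_families(s, n_fam = 60, beta_snp = 0.3, s2g = 0.5)
    fit <- fit_logistic_mixed(sim$y, sim$X, sim$G, blocks = sim$fam)
    fit$coefficients$estimate[4]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.1)
})

test_that("the scan handles monomorphic SNPs, missingness and ordering", {
  sim <- sim_glmm_families(23, n_fam = 70, beta_snp = 0.8, maf = 0.3)
  co <- sim$cohort
  n <- nrow(co$genotypes)
  co$genotypes <- cbind(co$genotypes,
                        snp_mono = rep(0L, n),
                        snp_miss = {g <- co$genotypes[, 1]
                                    g[seq(1, n, by = 7)] <- NA
                                    g})
  co$snp_meta <- data.frame(snp_id = colnames(co$genotypes),
                            counted_allele = "G", other_allele = "A",
                            imputation_r2 = NA_real_)
  res <- single_snp_scan(co)
  expect_identical(res$snp_id, colnames(co$genotypes))
  expect_equal(res$skipped[2], "monomorphic")
  expect_true(is.na(res$or[2]))
  expect_false(is.na(res$or[3]))   # mean imputation lets the fit proceed
  expect_true(res$p[1] < 0.05)     # strong simulated effect is detected
  expect_true("snp001" %in% attr(res, "significant"))
  # case/control counted-allele frequencies bracket the overall frequency
  expect_true(res$freq_case[1] > res$freq_control[1])
})

test_that("null_fixed scan mode approximates the per-SNP mode", {
  sim <- sim_glmm_families(29, n_fam = 60, beta_snp = 0.4)
  r1 <- single_snp_scan(sim$cohort, sigma2g_mode = "per_snp")
  r2 <- single_snp_scan(sim$cohort, sigma2g_mode = "null_fixed")
  expect_lt(abs(r1$beta[1] - r2$beta[1]), 0.05)
})

test_that("linear mixed model recovers variance components", {
  set.seed(41)
  # unrelated: REML variance estimates near the truth
  n <- 1500
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n, 0, 2)
  fit <- fit_linear_mixed(y, cbind(1, x), diag(n), blocks = seq_len(n))
  expect_lt(abs(fit$coefficients$estimate[2] - 0.5), 0.15)
  expect_lt(abs(fit$sigma2g + fit$sigma2e - 4), 0.5)
  # family data with a real polygenic component
  sim <- sim_glmm_families(42, n_fam = 150, beta_snp = 0, s2g = 0)
  b <- unlist(lapply(sim$G, function(m)
    drop(crossprod(chol(m + diag(1e-8, nrow(m))), rnorm(nrow(m)))) * 2))
  yq <- 25 + b + rnorm(length(b), 0, 2)        # sigma2g = 4, sigma2e = 4
  fl <- fit_linear_mixed(yq, cbind(rep(1, length(yq))), sim$G,
                         blocks = sim$fam)
  expect_lt(abs(fl$sigma2g - 4), 1.6)
  expect_lt(abs(fl$sigma2e - 4), 1.6)
})
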