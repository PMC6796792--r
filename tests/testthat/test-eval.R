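# small unrelated data set with a configurable score effect on obesity
sim_eval_data <- function(n, beta_prs = 0, seed = 1) {
  set.seed(seed)
  prs <- rnorm(n)
  sex <- rbinom(n, 1, 0.5) + 1
  age <- runif(n, 20, 60)
  y <- rbinom(n, 1, plogis(-1 + 0.2 * (sex - 1) + 0.005 * age +
                             beta_prs * prs))
  list(prs = prs, sex = sex, age = age, y = y,
       G = diag(n), blocks = seq_len(n))
}

test_that("per-SD and per-unit trend tests are algebraically linked", {
  d <- sim_eval_data(500, beta_prs = 0.4, seed = 2)
  t_unit <- trend_test(d$prs, d$y, d$sex, d$age, d$G, d$blocks)
  t_sd <- trend_test(d$prs, d$y, d$sex, d$age, d$G, d$blocks, per_sd = TRUE)
  expect_equal(t_sd$beta, t_unit$beta * sd(d$prs), tolerance = 1e-4)
  expect_equal(t_sd$or_trend, t_unit$or_trend^sd(d$prs), tolerance = 1e-4)
})

test_that("a positive score effect yields OR_trend > 1 with CI excluding 1", {
  d <- sim_eval_data(2000, beta_prs = 0.35, seed = 3)
  tt <- trend_test(d$prs, d$y, d$sex, d$age, d$G, d$blocks)
  expect_gt(tt$or_trend, 1)
  expect_gt(tt$ci[1], 1)
  expect_lt(tt$p, 0.01)
  expect_true(tt$ci[1] <= tt$or_trend && tt$or_trend <= tt$ci[2])
})

test_that("permutation null: trend CI covers 1 at the nominal rate", {
  sim <- sim_glmm_families(5, n_fam = 30, beta_snp = 0, s2g = 0.3)
  n <- length(sim$y)
  prs0 <- rnorm(n)
  cover <- vapply(1:500, function(r) {
    set.seed(r + 6000)
    tt <- trend_test(sample(prs0), sim$y, sim$X[, "sex"] + 1,
                     sim$X[, "age"], sim$G, sim$fam)
    tt$ci[1] <= 1 && 1 <= tt$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("quintile odds ratios: reference, null behaviour, separation", {
  # Q1 is the reference
  d <- sim_eval_data(600, beta_prs = 0.5, seed = 4)
  q <- assign_quintiles(d$prs)
  res <- quintile_or_test(q, d$y, d$sex, d$age, d$G, d$blocks)
  expect_equal(res$or[1], 1)
  expect_equal(res$quintile, paste0("Q", 1:5))
  # equal prevalence across quintiles: small effects, CIs cover 1
  d0 <- sim_eval_data(5000, beta_prs = 0, seed = 5)
  res0 <- quintile_or_test(assign_quintiles(d0$prs), d0$y, d0$sex, d0$age,
                           d0$G, d0$blocks)
  expect_true(all(abs(log(res0$or[2:5])) < 0.3))
  expect_true(all(res0$ci_lower[2:5] < 1 & 1 < res0$ci_upper[2:5]))
  # only the top quintile obese: flagged separation
  n <- 100
  prs <- seq_len(n)
  y <- as.integer(prs > 80)
  set.seed(99)
  ages <- runif(n, 20, 60)
  res_sep <- quintile_or_test(assign_quintiles(prs), y,
                              rep(1:2, 50), ages,
                              diag(n), seq_len(n))
  expect_true(attr(res_sep, "separation") || !all(res_sep$estimable))
  expect_error(quintile_or_test(assign_quintiles(prs), rep(0, n),
                                rep(1:2, 50), ages, diag(n)),
               "case")
})

test_that("AUC equals the pair-counting oracle and handles ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(1, 10), rep(0:1, 5)), 0.5)
  expect_error(auc(1:5, rep(1, 5)), "both classes")
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    pred <- sample(round(rnorm(n), 1))   # induce ties
    pairs <- outer(pred[y == 1], pred[y == 0],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(pred, y), mean(pairs), tolerance = 1e-12)
  }
})

test_that("optimism bootstrap corrects null-model AUC toward 0.5", {
  set.seed(7)
  dat <- data.frame(obesity = rbinom(400, 1, 0.3), x1 = rnorm(400),
                    x2 = rnorm(400))
  res <- auc_optimism(dat, "obesity", c("x1", "x2"), B = 200, seed = 9)
  expect_gt(res$apparent, res$auc_adj)
  expect_lt(abs(res$auc_adj - 0.5), 0.03)
  # B = 0 leaves the apparent AUC untouched
  res0 <- auc_optimism(dat, "obesity", c("x1", "x2"), B = 0)
  expect_equal(res0$optimism, 0)
  expect_equal(res0$auc_adj, res0$apparent)
  # fixed seed: identical report on rerun
  res2 <- auc_optimism(dat, "obesity", c("x1", "x2"), B = 200, seed = 9)
  expect_identical(res, res2)
})

test_that("optimism is non-negative in expectation under the null", {
  opt <- vapply(1:30, function(s) {
    set.seed(s + 100)
    dat <- data.frame(obesity = rbinom(150, 1, 0.3), x = rnorm(150))
    auc_optimism(dat, "obesity", "x", B = 40, seed = s)$optimism
  }, numeric(1))
  expect_gt(mean(opt), -0.005)
})

test_that("adding an informative score raises the corrected AUC", {
  deltas <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 150
    prs <- rnorm(n)
    dat <- data.frame(obesity = rbinom(n, 1, plogis(-0.8 + 0.9 * prs)),
                      age = runif(n, 20, 60), prs = prs)
    if (length(unique(dat$obesity)) < 2) return(NA_real_)
    compare_auc_adj(dat, "obesity", "age", c("age", "prs"),
                    B = 60, seed = s)$delta_auc_adj
  }, numeric(1))
  deltas <- deltas[!is.na(deltas)]
  expect_lt(binom.test(sum(deltas > 0), length(deltas),
                       alternative = "greater")$p.value, 0.05)
  # a clearly informative model comparison is flagged significant
  set.seed(77)
  n <- 500
  prs <- rnorm(n)
  dat <- data.frame(obesity = rbinom(n, 1, plogis(-0.8 + 1.2 * prs)),
                    age = runif(n, 20, 60), prs = prs)
  cmp <- compare_auc_adj(dat, "obesity", "age", c("age", "prs"),
                         B = 150, seed = 8)
  expect_gt(cmp$delta_auc_adj, 0.1)
  expect_true(cmp$significant)
  expect_true(cmp$ci_diff[1] > 0)
})

test_that("NRI and IDI match direct enumeration", {
  # identical risk vectors: both zero
  y <- c(1, 1, 0, 0)
  p <- c(0.6, 0.4, 0.3, 0.2)
  r0 <- nri_idi(p, p, y, B = 0)
  expect_equal(r0$nri, 0)
  expect_equal(r0$idi, 0)
  # events: 3/4 up, 1/4 down; nonevents: 2/3 down, 1/3 up
  y1 <- c(1, 1, 1, 1, 0, 0, 0)
  p_old <- c(.5, .5, .5, .5, .5, .5, .5)
  p_new <- c(.6, .6, .6, .4, .4, .4, .6)
  r1 <- nri_idi(p_old, p_new, y1, B = 0)
  expect_equal(r1$nri, 0.5 + 1 / 3, tolerance = 1e-12)
  # IDI from enumerated means: (0.6-0.5) - (0.30-0.35) = 0.15
  y2 <- c(1, 1, 0, 0)
  r2 <- nri_idi(c(.5, .5, .35, .35), c(.55, .65, .3, .3), y2, B = 0)
  expect_equal(r2$idi, 0.15, tolerance = 1e-12)
  # bounds and errors
  expect_error(nri_idi(c(.5, 1.2), c(.5, .5), c(0, 1)), "risks")
  expect_error(nri_idi(c(.5, .5), c(.5, .5), c(1, 1)), "both classes")
  # bootstrap intervals are reproducible and contain the point estimate
  set.seed(10)
  n <- 200
  yb <- rbinom(n, 1, 0.4)
  po <- plogis(rnorm(n))
  pn <- plogis(rnorm(n) + 0.8 * yb)
  rb <- nri_idi(po, pn, yb, B = 200, seed = 3)
  expect_true(rb$nri_ci[1] <= rb$nri && rb$nri <= rb$nri_ci[2])
  expect_true(abs(rb$nri) <= 2 && abs(rb$idi) <= 1)
})

test_that("a pure-noise score explains almost no BMI variance", {
  set.seed(11)
  n <- 3000
  sex <- rbinom(n, 1, .5) + 1
  age <- runif(n, 20, 60)
  bmi <- 24 + 0.5 * (sex - 1) + 0.05 * age + rnorm(n, 0, 6)
  ve <- variance_explained(bmi, rnorm(n), sex, age, diag(n),
                           blocks = seq_len(n))
  expect_lt(ve$r2, 0.005)
  expect_lt(ve$r2_partial, 0.005)
})
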