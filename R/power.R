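#' Design parameters of a training/target polygenic score power analysis
#'
#' The polygenic score is built from per-SNP effects estimated in a
#' training sample and tested for association with the trait in an
#' independent target sample. Power depends on the training and target
#' sizes, the trait prevalences (binary traits, via the liability
#' threshold model), the number of score SNPs (each estimated weight
#' carries sampling noise), and the variance the true score explains in
#' the training population.
#'
#' @param n_train,n_target Training and target sample sizes.
#' @param prevalence_train,prevalence_target Trait prevalences in each
#'   sample (used only for binary traits).
#' @param n_snps Number of SNPs in the score.
#' @param score_r2_train Proportion of the training phenotypic variance
#'   explained by the true score — on the liability scale for binary
#'   traits, in `[0, 1)`.
#' @param pi_null Proportion of effect-free SNPs among the score SNPs.
#'   With every SNP entering the score (no p-value selection) and the
#'   total score variance fixed, this does not alter power; it is exposed
#'   for sensitivity analyses around the effect distribution.
#' @param alpha Two-sided significance level of the score-trait test in
#'   the target.
#' @param trait `"binary"` (liability threshold) or `"quantitative"`.
#' @export
power_inputs <- function(n_train, n_target, prevalence_train = NA,
                         prevalence_target = NA, n_snps,
                         score_r2_train, pi_null = 0, alpha = 0.05,
                         trait = c("binary", "quantitative")) {
  trait <- match.arg(trait)
  x <- list(n_train = as.integer(n_train), n_target = as.integer(n_target),
            prevalence_train = prevalence_train,
            prevalence_target = prevalence_target,
            n_snps = as.integer(n_snps), score_r2_train = score_r2_train,
            pi_null = pi_null, alpha = alpha, trait = trait)
  if (x$n_train < 1L || x$n_target < 1L || x$n_snps < 1L)
    stop("sample sizes and SNP count must be >= 1", call. = FALSE)
  if (x$score_r2_train < 0 || x$score_r2_train >= 1)
    stop("infeasible score_r2_train: the implied genetic variance must lie ",
         "in [0, 1)", call. = FALSE)
  if (x$pi_null < 0 || x$pi_null > 1)
    stop("pi_null must be in [0, 1]", call. = FALSE)
  if (x$alpha <= 0 || x$alpha > 1) stop("alpha must be in (0, 1]",
                                        call. = FALSE)
  if (trait == "binary") {
    for (p in c(x$prevalence_train, x$prevalence_target))
      if (is.na(p) || p <= 0 || p >= 1)
        stop("binary traits need prevalences in (0, 1)", call. = FALSE)
  }
  class(x) <- "power_inputs"
  x
}

# Expected squared correlation between the estimated score and the target
# phenotype.
#
# Quantitative traits: per-SNP weights estimated with sampling variance
# 1/n_train on the correlation scale, so
#   rho^2 = vg^2 / (vg + n_snps / n_train).
# Binary traits (liability threshold, z_k = dnorm(qnorm(1 - K_k))): the
# observed-scale covariance between a standardized genotype and the 0/1
# trait in a sample with prevalence K is sqrt(v_j) * z, weights are
# estimated on the observed scale with sampling variance K1(1-K1)/n_train
# per SNP, and the target trait has variance K2(1-K2), giving
#   rho^2 = (z1 z2 vg)^2 /
#           ((vg z1^2 + n_snps K1(1-K1)/n_train) * K2(1-K2)).
target_rho2 <- function(x) {
  vg <- x$score_r2_train
  m <- x$n_snps
  if (vg == 0) return(0)
  if (x$trait == "quantitative") {
    vg^2 / (vg + m / x$n_train)
  } else {
    k1 <- x$prevalence_train
    k2 <- x$prevalence_target
    z1 <- stats::dnorm(stats::qnorm(1 - k1))
    z2 <- stats::dnorm(stats::qnorm(1 - k2))
    (z1 * z2 * vg)^2 /
      ((vg * z1^2 + m * k1 * (1 - k1) / x$n_train) * k2 * (1 - k2))
  }
}

#' Closed-form power of the score-trait association in the target sample
#'
#' Maps the training-sample design to the expected squared correlation
#' `rho^2` between the *estimated* score and the target phenotype — the
#' true per-SNP signal shrunk by the weight-estimation noise, whose total
#' variance scales as `n_snps / n_train` — and evaluates the chi-square
#' test of that correlation in the target:
#' `ncp = n_target * rho^2 / (1 - rho^2)`,
#' `power = P(chisq_1(ncp) > chisq_1 quantile at 1 - alpha)`.
#' Binary traits are handled on the liability scale with the stated sample
#' prevalences.
#'
#' @param inputs A [power_inputs()] object.
#' @return A list: `rho2_target` (expected squared score-trait correlation
#'   in the target), `ncp` and `power`.
#' @examples
#' analytic_power(power_inputs(n_train = 704, n_target = 177,
#'                             prevalence_train = 0.278,
#'                             prevalence_target = 0.282,
#'                             n_snps = 231, score_r2_train = 0.075))
#' @export
analytic_power <- function(inputs) {
  stopifnot(inherits(inputs, "power_inputs"))
  rho2 <- target_rho2(inputs)
  ncp <- inputs$n_target * rho2 / (1 - rho2)
  crit <- stats::qchisq(1 - inputs$alpha, df = 1L)
  power <- stats::pchisq(crit, df = 1L, ncp = ncp, lower.tail = FALSE)
  list(rho2_target = rho2, ncp = ncp, power = power)
}

#' Power of the error-free score in the target sample
#'
#' The same chi-square power calculation with the weight-estimation noise
#' removed: the power to detect a score that *truly* explains
#' `score_r2_train` of the (liability-scale) variance, as if its weights
#' were known without error. Neither `n_snps` nor `n_train` enter. This is
#' the upper bound that a finite training sample is shrunk away from, and
#' a useful diagnostic of how much of a power shortfall is attributable to
#' weight estimation.
#'
#' @inheritParams analytic_power
#' @return A list: `rho2_target`, `ncp`, `power`.
#' @export
analytic_power_error_free <- function(inputs) {
  stopifnot(inherits(inputs, "power_inputs"))
  x <- inputs
  vg <- x$score_r2_train
  rho2 <- if (x$trait == "quantitative") vg else {
    k2 <- x$prevalence_target
    z2 <- stats::dnorm(stats::qnorm(1 - k2))
    vg * z2^2 / (k2 * (1 - k2))
  }
  ncp <- x$n_target * rho2 / (1 - rho2)
  crit <- stats::qchisq(1 - x$alpha, df = 1L)
  list(rho2_target = rho2, ncp = ncp,
       power = stats::pchisq(crit, df = 1L, ncp = ncp, lower.tail = FALSE))
}

#' Monte-Carlo power of the training/target score design
#'
#' Simulation oracle for [analytic_power()]: in each replicate a training
#' sample is simulated under the liability-threshold (or quantitative)
#' model with `n_snps` standardized genotypes, per-SNP weights are
#' estimated by marginal regression, an independent target sample is
#' scored with those weights, and the score-trait association is tested at
#' `alpha`. Power is the rejection fraction; its binomial standard error
#' is reported.
#'
#' @inheritParams analytic_power
#' @param reps Number of simulation replicates.
#' @param seed Integer seed.
#' @return A list: `power`, `se`, `reps`.
#' @export
mc_power <- function(inputs, reps = 2000L, seed = 1L) {
  stopifnot(inherits(inputs, "power_inputs"))
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  x <- inputs
  m <- x$n_snps
  vg <- x$score_r2_train
  n_eff <- round(m * (1 - x$pi_null))
  beta <- c(rep(sqrt(vg / max(n_eff, 1)), n_eff), rep(0, m - n_eff))
  t1 <- if (x$trait == "binary") stats::qnorm(1 - x$prevalence_train) else NA
  t2 <- if (x$trait == "binary") stats::qnorm(1 - x$prevalence_target) else NA
  crit <- stats::qchisq(1 - x$alpha, df = 1L)

  draw_geno <- function(n) {
    p <- stats::runif(m, 0.1, 0.5)
    g <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    scale(g, center = 2 * p, scale = sqrt(pmax(2 * p * (1 - p), 1e-12)))
  }
  rej <- 0L
  for (r in seq_len(reps)) {
    G1 <- draw_geno(x$n_train)
    liab1 <- drop(G1 %*% beta) + stats::rnorm(x$n_train, 0, sqrt(1 - vg))
    y1 <- if (x$trait == "binary") as.numeric(liab1 > t1) else liab1
    bh <- colSums(G1 * (y1 - mean(y1))) / (x$n_train - 1)
    G2 <- draw_geno(x$n_target)
    liab2 <- drop(G2 %*% beta) + stats::rnorm(x$n_target, 0, sqrt(1 - vg))
    y2 <- if (x$trait == "binary") as.numeric(liab2 > t2) else liab2
    s2 <- drop(G2 %*% bh)
    if (stats::sd(s2) == 0 || stats::sd(y2) == 0) next
    rho <- stats::cor(s2, y2)
    stat <- x$n_target * rho^2 / (1 - rho^2)
    if (stat > crit) rej <- rej + 1L
  }
  p <- rej / reps
  list(power = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}
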