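#' Simulation settings for an ascertained nuclear-family cohort
#'
#' Bundles every parameter of the synthetic family-cohort generator. The
#' defaults emulate the design of a French-Canadian obesity family study:
#' 222 nuclear families (about 881 individuals), 231 candidate SNPs with a
#' common-variant allele-frequency spectrum, families recruited because at
#' least one parent and one offspring have BMI >= 32 kg/m2, an obesity
#' (BMI >= 30) prevalence close to 28% after ascertainment, and a true
#' polygenic score carrying 7.5% of the BMI variance in the unascertained
#' population.
#'
#' @param n_families Number of nuclear families to generate.
#' @param offspring_min,offspring_max,offspring_mean Distribution of the
#'   number of offspring per family: a shifted binomial on
#'   `offspring_min:offspring_max` with the given mean. Ascertainment
#'   favours larger families, so the default mean of 1.7 yields an
#'   expected *ascertained* cohort of about 881 individuals across 222
#'   families.
#' @param n_snps Number of independent candidate SNPs.
#' @param maf_range Range (min, max) in (0, 0.5] from which founder minor
#'   allele frequencies are drawn uniformly.
#' @param h2_score Proportion of BMI variance carried by the true additive
#'   score in the unascertained population, in `[0, 1)`.
#' @param bmi_base_mean Baseline BMI mean (kg/m2) before covariate and
#'   genetic effects. The default is calibrated so that the default
#'   ascertained design yields close to `target_prevalence` obesity.
#' @param bmi_base_sd Total BMI standard deviation (kg/m2) in the
#'   unascertained population; genetic, covariate and residual components
#'   are scaled to sum to `bmi_base_sd^2`.
#' @param sex_effect BMI shift (kg/m2) for females relative to males.
#' @param age_effect BMI slope per year of age (kg/m2 per year).
#' @param age_range Range of ages (years); parents are drawn from the upper
#'   half of the range and offspring from the lower half.
#' @param ascertainment_bmi BMI threshold (kg/m2) of the recruitment rule.
#' @param tracking_cor Correlation between the recruitment-time BMI (on
#'   which families are ascertained) and the measured BMI. Recruitment of
#'   the emulated cohort predated measurement by years, so applying the
#'   rule to the measured BMI itself (`tracking_cor = 1`) would force at
#'   least two currently obese members per family and a prevalence near
#'   50%; the default 0.5 reconciles the recruitment rule with the ~28%
#'   measured prevalence.
#' @param obesity_threshold BMI threshold (kg/m2) defining obesity.
#' @param missing_rate Probability that a genotype call is missing.
#' @param imputed_fraction Fraction of SNPs flagged as imputed; these carry
#'   an `imputation_r2` drawn uniformly from `imputed_r2_range`.
#' @param imputed_r2_range Range of simulated imputation r2 values.
#' @param target_prevalence Post-ascertainment obesity prevalence that the
#'   default `bmi_base_mean` was calibrated against (see
#'   [calibrate_base_mean()]).
#' @param seed Integer seed making the whole cohort reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_ascertained_cohort()]
#' @export
sim_config <- function(n_families = 222,
                       offspring_min = 1,
                       offspring_max = 3,
                       offspring_mean = 1.7,
                       n_snps = 231,
                       maf_range = c(0.05, 0.5),
                       h2_score = 0.075,
                       bmi_base_mean = 22.85,
                       bmi_base_sd = 6.5,
                       sex_effect = 0.5,
                       age_effect = 0.05,
                       age_range = c(18, 65),
                       ascertainment_bmi = 32,
                       tracking_cor = 0.5,
                       obesity_threshold = 30,
                       missing_rate = 0.01,
                       imputed_fraction = 0.58,
                       imputed_r2_range = c(0.4, 1),
                       target_prevalence = 0.28,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    offspring_min = as.integer(offspring_min),
    offspring_max = as.integer(offspring_max),
    offspring_mean = offspring_mean,
    n_snps = as.integer(n_snps),
    maf_range = maf_range,
    h2_score = h2_score,
    bmi_base_mean = bmi_base_mean,
    bmi_base_sd = bmi_base_sd,
    sex_effect = sex_effect,
    age_effect = age_effect,
    age_range = age_range,
    ascertainment_bmi = ascertainment_bmi,
    tracking_cor = tracking_cor,
    obesity_threshold = obesity_threshold,
    missing_rate = missing_rate,
    imputed_fraction = imputed_fraction,
    imputed_r2_range = imputed_r2_range,
    target_prevalence = target_prevalence,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopif <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  stopif(cfg$n_families < 1L, "n_families must be >= 1")
  stopif(cfg$offspring_min < 0L || cfg$offspring_max < cfg$offspring_min,
         "offspring range must satisfy 0 <= min <= max")
  stopif(cfg$offspring_mean < cfg$offspring_min ||
           cfg$offspring_mean > cfg$offspring_max,
         "offspring_mean must lie inside [offspring_min, offspring_max]")
  stopif(cfg$n_snps < 1L, "n_snps must be >= 1")
  stopif(length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
           any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0,
         "maf_range must be an increasing pair in (0, 0.5]")
  stopif(cfg$h2_score < 0 || cfg$h2_score >= 1, "h2_score must be in [0, 1)")
  stopif(cfg$bmi_base_sd <= 0, "bmi_base_sd must be > 0")
  stopif(cfg$ascertainment_bmi < 0, "ascertainment_bmi must be >= 0")
  stopif(cfg$tracking_cor < 0 || cfg$tracking_cor > 1,
         "tracking_cor must be in [0, 1]")
  stopif(cfg$obesity_threshold <= 0, "obesity_threshold must be > 0")
  stopif(cfg$missing_rate < 0 || cfg$missing_rate >= 1,
         "missing_rate must be in [0, 1)")
  stopif(diff(cfg$age_range) <= 0, "age_range must be increasing")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Family-cohort simulation settings\n")
  cat(sprintf("  families: %d, offspring %d-%d (mean %.2f), SNPs: %d\n",
              x$n_families, x$offspring_min, x$offspring_max,
              x$offspring_mean, x$n_snps))
  cat(sprintf("  h2_score: %.3f, BMI base %.1f (SD %.1f) kg/m2\n",
              x$h2_score, x$bmi_base_mean, x$bmi_base_sd))
  cat(sprintf("  ascertainment BMI >= %.0f, obesity BMI >= %.0f, seed %d\n",
              x$ascertainment_bmi, x$obesity_threshold, x$seed))
  invisible(x)
}

# Variance of age implied by the sampling design: parents uniform on the
# upper half of age_range, offspring on the lower half, mixed with weights
# 2 : offspring_mean per family.
age_variance <- function(cfg) {
  mid <- mean(cfg$age_range)
  r <- diff(cfg$age_range) / 2
  wp <- 2 / (2 + cfg$offspring_mean)
  wo <- 1 - wp
  r^2 / 12 + wp * wo * r^2
}

# Decompose total BMI variance into covariate, genetic and residual parts.
bmi_components <- function(cfg) {
  v_total <- cfg$bmi_base_sd^2
  v_sex <- cfg$sex_effect^2 * 0.25
  v_age <- cfg$age_effect^2 * age_variance(cfg)
  v_score <- cfg$h2_score * v_total
  v_res <- v_total - v_sex - v_age - v_score
  if (v_res <= 0)
    stop("covariate and genetic effects exceed the total BMI variance; ",
         "increase bmi_base_sd or reduce effects", call. = FALSE)
  list(total = v_total, sex = v_sex, age = v_age, score = v_score,
       residual = v_res)
}

# Draw per-SNP additive effects (kg/m2 per counted allele) scaled so that
# the true score has variance v_score under Hardy-Weinberg founder
# frequencies.
draw_snp_effects <- function(n_snps, maf, v_score) {
  raw <- stats::rnorm(n_snps)
  if (v_score == 0) return(rep(0, n_snps))
  v_raw <- sum(raw^2 * 2 * maf * (1 - maf))
  raw * sqrt(v_score / v_raw)
}

simulate_one_family <- function(fam_id, cfg, maf, effects, comp) {
  n_off <- cfg$offspring_min +
    stats::rbinom(1L, cfg$offspring_max - cfg$offspring_min,
                  if (cfg$offspring_max > cfg$offspring_min)
                    (cfg$offspring_mean - cfg$offspring_min) /
                      (cfg$offspring_max - cfg$offspring_min) else 0)
  n <- 2L + n_off
  ids <- paste0(fam_id, "_", c("P1", "P2", paste0("O", seq_len(max(n_off, 0)))))[seq_len(n)]
  m <- length(maf)

  geno <- matrix(0L, nrow = n, ncol = m, dimnames = list(ids, names(maf)))
  geno[1L, ] <- stats::rbinom(m, 2L, maf)
  geno[2L, ] <- stats::rbinom(m, 2L, maf)
  if (n_off > 0) {
    for (k in seq_len(n_off)) {
      geno[2L + k, ] <- stats::rbinom(m, 1L, geno[1L, ] / 2) +
        stats::rbinom(m, 1L, geno[2L, ] / 2)
    }
  }

  mid <- mean(cfg$age_range)
  sex <- c(1L, 2L, stats::rbinom(n_off, 1L, 0.5) + 1L) # 1 male, 2 female
  age <- c(stats::runif(2L, mid, cfg$age_range[2L]),
           stats::runif(n_off, cfg$age_range[1L], mid))
  score <- drop(geno %*% effects)
  bmi <- cfg$bmi_base_mean +
    cfg$sex_effect * ((sex == 2L) - 0.5) +
    cfg$age_effect * (age - mid) +
    (score - sum(effects * 2 * maf)) +
    stats::rnorm(n, 0, sqrt(comp$residual))
  tc <- cfg$tracking_cor
  bmi_rec <- cfg$bmi_base_mean + tc * (bmi - cfg$bmi_base_mean) +
    sqrt(1 - tc^2) * stats::rnorm(n, 0, sqrt(comp$total))

  list(
    ped = data.frame(
      family_id = fam_id, id = ids,
      father_id = c(NA_character_, NA_character_, rep(ids[1L], n_off)),
      mother_id = c(NA_character_, NA_character_, rep(ids[2L], n_off)),
      sex = sex,
      role = c("parent", "parent", rep("offspring", n_off)),
      stringsAsFactors = FALSE
    ),
    geno = geno,
    phen = data.frame(id = ids, bmi = bmi, bmi_at_recruitment = bmi_rec,
                      sex = sex, age = age, stringsAsFactors = FALSE),
    score = stats::setNames(score, ids)
  )
}

family_meets_rule <- function(ped, bmi, threshold) {
  any(bmi[ped$role == "parent"] >= threshold) &&
    any(bmi[ped$role == "offspring"] >= threshold)
}

assemble_cohort <- function(fams, cfg, maf, effects) {
  ped <- do.call(rbind, lapply(fams, `[[`, "ped"))
  geno <- do.call(rbind, lapply(fams, `[[`, "geno"))
  phen <- do.call(rbind, lapply(fams, `[[`, "phen"))
  score <- do.call(c, lapply(fams, `[[`, "score"))
  rownames(ped) <- rownames(phen) <- NULL

  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(geno)) < cfg$missing_rate,
                   nrow = nrow(geno))
    geno[miss] <- NA_integer_
  }
  phen$obesity <- as.integer(phen$bmi >= cfg$obesity_threshold)

  n_imp <- round(cfg$imputed_fraction * cfg$n_snps)
  imputation_r2 <- rep(NA_real_, cfg$n_snps)
  if (n_imp > 0) {
    idx <- sample.int(cfg$n_snps, n_imp)
    imputation_r2[idx] <- stats::runif(n_imp, cfg$imputed_r2_range[1L],
                                       cfg$imputed_r2_range[2L])
  }
  snp_meta <- data.frame(
    snp_id = names(maf),
    counted_allele = "G", other_allele = "A",
    maf = unname(maf), effect = effects,
    imputation_r2 = imputation_r2,
    stringsAsFactors = FALSE
  )

  structure(
    list(ped = ped, genotypes = geno, snp_meta = snp_meta,
         phenotypes = phen, true_score = score, config = cfg),
    class = "family_cohort"
  )
}

#' Simulate an unascertained nuclear-family cohort
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions at each SNP,
#' offspring genotypes by Mendelian transmission from their parents. BMI is
#' Gaussian on the natural scale: baseline + sex and age effects + the true
#' additive score + residual noise, with the components scaled so that the
#' score carries `h2_score` of the BMI variance in this (unascertained)
#' population.
#'
#' @param config A [sim_config()] object.
#' @return A `family_cohort` object: a list with elements `ped` (pedigree
#'   table), `genotypes` (individuals x SNPs allele-count matrix with `NA`
#'   for missing calls), `snp_meta`, `phenotypes` (BMI, obesity flag, sex,
#'   age) and `true_score` (latent genetic value, simulation only).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  maf <- stats::setNames(
    stats::runif(config$n_snps, config$maf_range[1L], config$maf_range[2L]),
    sprintf("snp%04d", seq_len(config$n_snps))
  )
  comp <- bmi_components(config)
  effects <- draw_snp_effects(config$n_snps, maf, comp$score)
  fams <- lapply(seq_len(config$n_families), function(i)
    simulate_one_family(sprintf("F%04d", i), config, maf, effects, comp))
  assemble_cohort(fams, config, maf, effects)
}

#' Simulate a cohort ascertained through an obese parent-offspring pair
#'
#' Families are generated as in [simulate_cohort()] and kept only if at
#' least one parent *and* at least one offspring have BMI at or above
#' `config$ascertainment_bmi` (rejection sampling of whole families), until
#' `config$n_families` families are retained.
#'
#' @inheritParams simulate_cohort
#' @param max_tries Safety cap on the number of candidate families.
#' @return A `family_cohort` of exactly `config$n_families` families, all
#'   satisfying the recruitment rule.
#' @export
simulate_ascertained_cohort <- function(config, max_tries = 1000L * config$n_families) {
  validate_sim_config(config)
  set.seed(config$seed)
  maf <- stats::setNames(
    stats::runif(config$n_snps, config$maf_range[1L], config$maf_range[2L]),
    sprintf("snp%04d", seq_len(config$n_snps))
  )
  comp <- bmi_components(config)
  effects <- draw_snp_effects(config$n_snps, maf, comp$score)

  fams <- vector("list", config$n_families)
  kept <- 0L
  tries <- 0L
  while (kept < config$n_families) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("ascertainment rejection sampling exceeded max_tries; ",
           "is the ascertainment threshold reachable?", call. = FALSE)
    fam <- simulate_one_family(sprintf("F%04d", kept + 1L), config, maf,
                               effects, comp)
    if (family_meets_rule(fam$ped, fam$phen$bmi_at_recruitment,
                          config$ascertainment_bmi)) {
      kept <- kept + 1L
      fams[[kept]] <- fam
    }
  }
  assemble_cohort(fams, config, maf, effects)
}

#' @export
print.family_cohort <- function(x, ...) {
  cat(sprintf("Family cohort: %d individuals in %d families, %d SNPs\n",
              nrow(x$phenotypes), length(unique(x$ped$family_id)),
              ncol(x$genotypes)))
  cat(sprintf("  obesity prevalence: %.1f%%, mean BMI %.1f kg/m2\n",
              100 * mean(x$phenotypes$obesity), mean(x$phenotypes$bmi)))
  invisible(x)
}

#' Number of individuals with phenotype data in a cohort
#' @param cohort A `family_cohort`.
#' @export
n_individuals <- function(cohort) nrow(cohort$phenotypes)

#' Restrict a cohort to a set of individuals
#'
#' Subsets genotypes, phenotypes and the true score. The pedigree table is
#' kept complete so that kinship coefficients of the retained individuals
#' (which flow through dropped relatives) remain computable; use
#' [cohort_kinship()] to obtain the kinship submatrix of the retained set.
#'
#' @param cohort A `family_cohort`.
#' @param ids Individual identifiers to keep.
#' @export
subset_cohort <- function(cohort, ids) {
  ids <- as.character(ids)
  if (!all(ids %in% cohort$phenotypes$id))
    stop("unknown individual ids in subset", call. = FALSE)
  cohort$genotypes <- cohort$genotypes[ids, , drop = FALSE]
  cohort$phenotypes <- cohort$phenotypes[match(ids, cohort$phenotypes$id), ]
  rownames(cohort$phenotypes) <- NULL
  cohort$true_score <- cohort$true_score[ids]
  cohort
}

#' Keep only families meeting the obese parent-offspring recruitment rule
#'
#' Retains exactly the families with at least one parent *and* at least one
#' offspring at or above the BMI threshold. An empty cohort yields an empty
#' result.
#'
#' @param cohort A `family_cohort`.
#' @param threshold BMI threshold in kg/m2 (default the config's
#'   ascertainment threshold, or 32 if unavailable).
#' @param on Phenotype column the rule is applied to: the measured `"bmi"`
#'   (default) or, for simulated cohorts, `"bmi_at_recruitment"` (the
#'   basis [simulate_ascertained_cohort()] itself uses).
#' @export
ascertain_families <- function(cohort, threshold = NULL,
                               on = c("bmi", "bmi_at_recruitment")) {
  on <- match.arg(on)
  if (is.null(threshold))
    threshold <- if (!is.null(cohort$config)) cohort$config$ascertainment_bmi else 32
  fams <- unique(cohort$ped$family_id)
  keep_fam <- vapply(fams, function(f) {
    ped_f <- cohort$ped[cohort$ped$family_id == f, ]
    in_phen <- ped_f$id %in% cohort$phenotypes$id
    ped_f <- ped_f[in_phen, , drop = FALSE]
    if (nrow(ped_f) == 0L) return(FALSE)
    bmi_f <- cohort$phenotypes[[on]][match(ped_f$id, cohort$phenotypes$id)]
    family_meets_rule(ped_f, bmi_f, threshold)
  }, logical(1L))
  keep_ids <- cohort$phenotypes$id[
    cohort$phenotypes$id %in% cohort$ped$id[cohort$ped$family_id %in% fams[keep_fam]]]
  out <- subset_cohort(cohort, keep_ids)
  out$ped <- out$ped[out$ped$family_id %in% fams[keep_fam], ]
  rownames(out$ped) <- NULL
  out
}

#' Split a cohort into discovery and validation partitions
#'
#' Random partition of individuals with sizes `floor(fraction * n)` and the
#' remainder. With `stratify_by_obesity` the obese and non-obese are split
#' separately so the partitions have near-identical obesity prevalence.
#' With `by_family` whole families are allocated to one partition or the
#' other (sizes then only approximate the fraction).
#'
#' @param cohort A `family_cohort`.
#' @param fraction Proportion of individuals in the first partition,
#'   in (0, 1).
#' @param seed Integer seed for the random allocation.
#' @param stratify_by_obesity Balance obesity prevalence across partitions.
#' @param by_family Keep families intact across partitions.
#' @return A list with `family_cohort` elements `discovery` and
#'   `validation`.
#' @export
split_cohort <- function(cohort, fraction = 0.8, seed = 1L,
                         stratify_by_obesity = TRUE, by_family = FALSE) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  set.seed(as.integer(seed))
  phen <- cohort$phenotypes
  n <- nrow(phen)
  if (by_family) {
    fams <- unique(cohort$ped$family_id[cohort$ped$id %in% phen$id])
    fams <- sample(fams)
    sizes <- vapply(fams, function(f)
      sum(phen$id %in% cohort$ped$id[cohort$ped$family_id == f]), integer(1L))
    take <- cumsum(sizes) <= floor(fraction * n)
    ids1 <- phen$id[phen$id %in%
                      cohort$ped$id[cohort$ped$family_id %in% fams[take]]]
  } else if (stratify_by_obesity) {
    n1 <- floor(fraction * n)
    ob <- phen$id[phen$obesity == 1L]
    nb <- phen$id[phen$obesity == 0L]
    k_ob <- min(round(fraction * length(ob)), n1)
    ids1 <- c(sample(ob, k_ob), sample(nb, n1 - k_ob))
  } else {
    ids1 <- sample(phen$id, floor(fraction * n))
  }
  ids2 <- setdiff(phen$id, ids1)
  # preserve input individual order within each partition
  ids1 <- phen$id[phen$id %in% ids1]
  ids2 <- phen$id[phen$id %in% ids2]
  list(discovery = subset_cohort(cohort, ids1),
       validation = subset_cohort(cohort, ids2))
}

#' Calibrate the baseline BMI mean against a target obesity prevalence
#'
#' Bisection on `bmi_base_mean` so that the post-ascertainment obesity
#' prevalence of the design matches `target` on average. The prevalence at
#' each candidate baseline is evaluated with a genotype-free family-BMI
#' simulator: parental true scores are Gaussian with the configured score
#' variance and offspring scores are midparent plus Mendelian segregation
#' noise of half that variance, which for a score of hundreds of
#' independent SNPs is an excellent approximation and orders of magnitude
#' faster than dropping genotypes; the same simulated family skeletons
#' are reused across every bisection step (common random numbers). Used
#' once to fix the default baseline of [sim_config()]; exposed so
#' alternative designs can be recalibrated.
#'
#' @param config A [sim_config()].
#' @param target Target obesity prevalence (default the config's).
#' @param n_families Families per Monte-Carlo evaluation of the prevalence.
#' @param tol Bisection tolerance on the prevalence.
#' @param interval Search interval for `bmi_base_mean`.
#' @param seed Seed of the calibration Monte-Carlo.
#' @return The calibrated `sim_config`.
#' @export
calibrate_base_mean <- function(config, target = config$target_prevalence,
                                n_families = 20000L, tol = 0.002,
                                interval = c(15, 35), seed = 1L) {
  comp <- bmi_components(config)
  mid_age <- mean(config$age_range)
  r_age <- diff(config$age_range) / 2
  set.seed(as.integer(seed))
  # fixed family skeletons reused across bisection steps (common random
  # numbers): offspring count, sexes, ages, score and residual z-scores
  p_off <- if (config$offspring_max > config$offspring_min)
    (config$offspring_mean - config$offspring_min) /
      (config$offspring_max - config$offspring_min) else 0
  fams <- lapply(seq_len(n_families), function(i) {
    n_off <- config$offspring_min +
      stats::rbinom(1L, config$offspring_max - config$offspring_min, p_off)
    n <- 2L + n_off
    sex <- c(1L, 2L, stats::rbinom(n_off, 1L, 0.5) + 1L)
    age <- c(stats::runif(2L, mid_age, config$age_range[2L]),
             stats::runif(n_off, config$age_range[1L], mid_age))
    sp <- stats::rnorm(2L, 0, sqrt(comp$score))
    so <- (sp[1L] + sp[2L]) / 2 +
      stats::rnorm(n_off, 0, sqrt(comp$score / 2))
    dev <- config$sex_effect * ((sex == 2L) - 0.5) +
      config$age_effect * (age - mid_age) +
      c(sp, so) + stats::rnorm(n, 0, sqrt(comp$residual))
    tc <- config$tracking_cor
    dev_rec <- tc * dev + sqrt(1 - tc^2) * stats::rnorm(n, 0, sqrt(comp$total))
    list(dev = dev, dev_rec = dev_rec,
         role = c("parent", "parent", rep("offspring", n_off)))
  })
  prev_at <- function(mu) {
    kept_ob <- kept_n <- 0
    for (f in fams) {
      bmi <- mu + f$dev
      bmi_rec <- mu + f$dev_rec
      if (any(bmi_rec[f$role == "parent"] >= config$ascertainment_bmi) &&
          any(bmi_rec[f$role == "offspring"] >= config$ascertainment_bmi)) {
        kept_ob <- kept_ob + sum(bmi >= config$obesity_threshold)
        kept_n <- kept_n + length(bmi)
      }
    }
    if (kept_n == 0) return(0)
    kept_ob / kept_n
  }
  lo <- interval[1L]; hi <- interval[2L]
  mid <- (lo + hi) / 2
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    p <- prev_at(mid)
    if (abs(p - target) < tol) break
    if (p > target) hi <- mid else lo <- mid
  }
  config$bmi_base_mean <- mid
  config
}
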