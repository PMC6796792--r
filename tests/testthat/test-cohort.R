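test_that("simulation settings are validated", {
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2_score = 1), "h2_score")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(obesity_threshold = 0), "obesity_threshold")
  expect_error(sim_config(tracking_cor = 1.2), "tracking_cor")
})

test_that("offspring genotypes are Mendelian-consistent with parents", {
  cfg <- sim_config(n_families = 60, n_snps = 12, missing_rate = 0,
                    seed = 21)
  co <- simulate_cohort(cfg)
  ped <- co$ped
  off <- ped[ped$role == "offspring", ]
  gf <- co$genotypes[off$father_id, , drop = FALSE]
  gm <- co$genotypes[off$mother_id, , drop = FALSE]
  gc <- co$genotypes[off$id, , drop = FALSE]
  # child allele count bounded by what each parent can transmit
  lower <- (gf == 2) + (gm == 2)
  upper <- 2 - ((gf == 0) + (gm == 0))
  expect_true(all(gc >= lower & gc <= upper))
  # in particular, two homozygous-0 parents force genotype 0
  both0 <- gf == 0 & gm == 0
  expect_true(any(both0))
  expect_true(all(gc[both0] == 0))
})

test_that("identical seed and config give byte-identical cohorts", {
  cfg <- sim_config(n_families = 25, n_snps = 8, seed = 5)
  expect_identical(simulate_ascertained_cohort(cfg),
                   simulate_ascertained_cohort(cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("the true score carries the configured share of BMI variance", {
  # null effect
  co0 <- simulate_cohort(sim_config(n_families = 2700, n_snps = 40,
                                    h2_score = 0, missing_rate = 0,
                                    seed = 8))
  expect_gt(nrow(co0$phenotypes), 9000)
  r2_null <- if (var(co0$true_score) == 0) 0 else
    cor(co0$true_score, co0$phenotypes$bmi)^2
  expect_lt(r2_null, 0.005)

  # 7.5% target, ~20k unascertained individuals
  co <- simulate_cohort(sim_config(n_families = 5500, n_snps = 60,
                                   h2_score = 0.075, missing_rate = 0,
                                   seed = 9))
  expect_gt(nrow(co$phenotypes), 19000)
  r2 <- summary(lm(co$phenotypes$bmi ~ co$true_score))$r.squared
  expect_lt(abs(r2 - 0.075), 0.01)
})

test_that("founder allele frequencies match the configured MAFs", {
  cfg <- sim_config(n_families = 800, n_snps = 25, missing_rate = 0,
                    seed = 13)
  co <- simulate_cohort(cfg)
  founders <- co$ped$id[is.na(co$ped$father_id)]
  freq <- colMeans(co$genotypes[founders, ]) / 2
  p <- co$snp_meta$maf
  se <- sqrt(p * (1 - p) / (2 * length(founders)))
  expect_true(all(abs(freq - p) <= 3.5 * se))
})

test_that("transmission frequencies match the Mendelian table", {
  # ~10,000 parent-offspring transmissions at a single MAF-0.5 SNP
  cfg <- sim_config(n_families = 3000, n_snps = 1, maf_range = c(0.5, 0.5),
                    missing_rate = 0, seed = 14)
  co <- simulate_cohort(cfg)
  ped <- co$ped[co$ped$role == "offspring", ]
  expect_gt(2 * nrow(ped), 10000)
  g <- co$genotypes[, 1]
  combos <- paste(pmin(g[ped$father_id], g[ped$mother_id]),
                  pmax(g[ped$father_id], g[ped$mother_id]))
  child <- g[ped$id]
  expected <- list("0 0" = c(1, 0, 0), "0 1" = c(.5, .5, 0),
                   "0 2" = c(0, 1, 0), "1 1" = c(.25, .5, .25),
                   "1 2" = c(0, .5, .5), "2 2" = c(0, 0, 1))
  x2 <- 0; df <- 0
  for (cb in names(expected)) {
    idx <- combos == cb
    if (sum(idx) < 30) next
    obs <- tabulate(child[idx] + 1L, 3L)
    e <- expected[[cb]] * sum(idx)
    keep <- e > 0
    expect_equal(sum(obs[!keep]), 0)  # impossible genotypes never occur
    x2 <- x2 + sum((obs[keep] - e[keep])^2 / e[keep])
    df <- df + sum(keep) - 1
  }
  expect_gt(pchisq(x2, df, lower.tail = FALSE), 0.001)
})

test_that("the recruitment rule retains exactly the qualifying families", {
  co <- make_bmi_cohort(list(
    list(parents = c(33, 25), offspring = c(28, 31.9)),   # no offspring >= 32
    list(parents = c(33, 25), offspring = c(35, 20)),     # qualifies
    list(parents = c(28, 29), offspring = c(40, 41)),     # no parent >= 32
    list(parents = c(32, 25), offspring = c(32))))        # boundary qualifies
  kept <- ascertain_families(co, threshold = 32)
  expect_setequal(unique(kept$ped$family_id), c("F02", "F04"))
  # thresholds at zero retain everything
  all_kept <- ascertain_families(co, threshold = 0)
  expect_equal(n_individuals(all_kept), n_individuals(co))
  # an empty cohort passes through without error
  none <- subset_cohort(co, character(0))
  none$ped <- none$ped[0, ]
  expect_equal(n_individuals(ascertain_families(none, threshold = 32)), 0)
})

test_that("ascertainment enriches obesity prevalence", {
  prev <- vapply(1:20, function(s) {
    cfg <- sim_config(n_families = 40, n_snps = 15, seed = s)
    asc <- simulate_ascertained_cohort(cfg)
    un <- simulate_cohort(sim_config(n_families = 150, n_snps = 15,
                                     seed = s + 1000))
    mean(asc$phenotypes$obesity) - mean(un$phenotypes$obesity)
  }, numeric(1))
  expect_true(all(prev > 0))
})

test_that("the 80/20 split reproduces the cohort partition arithmetic", {
  co <- make_unrelated_cohort(881, n_obese = 246, seed = 2)
  sp <- split_cohort(co, fraction = 0.8, seed = 3)
  expect_equal(n_individuals(sp$discovery), 704)
  expect_equal(n_individuals(sp$validation), 177)
  # stratified allocation puts 196 or 197 of the 246 obese in discovery
  expect_true(sum(sp$discovery$phenotypes$obesity) %in% c(196, 197))
  # same seed, same split
  sp2 <- split_cohort(co, fraction = 0.8, seed = 3)
  expect_identical(sp$discovery$phenotypes$id, sp2$discovery$phenotypes$id)
})

test_that("stratified splits balance prevalence within the stated bound", {
  co10 <- make_unrelated_cohort(10, n_obese = 5, seed = 4)
  sp <- split_cohort(co10, fraction = 0.5, seed = 1)
  n_ob <- sum(sp$discovery$phenotypes$obesity)
  expect_true(n_ob >= 2 && n_ob <= 3)
  for (s in 1:10) {
    co <- make_unrelated_cohort(173, n_obese = 48, seed = s)
    sp <- split_cohort(co, fraction = 0.7, seed = s)
    p1 <- mean(sp$discovery$phenotypes$obesity)
    p2 <- mean(sp$validation$phenotypes$obesity)
    bound <- 1 / min(n_individuals(sp$discovery),
                     n_individuals(sp$validation))
    expect_lte(abs(p1 - p2), bound + 1e-12)
  }
  expect_error(split_cohort(co10, fraction = 1), "fraction")
  expect_error(split_cohort(co10, fraction = 0), "fraction")
})

test_that("family-level splits keep families intact", {
  cfg <- sim_config(n_families = 30, n_snps = 5, seed = 6)
  co <- simulate_ascertained_cohort(cfg)
  sp <- split_cohort(co, fraction = 0.8, seed = 2, by_family = TRUE)
  f1 <- unique(co$ped$family_id[co$ped$id %in% sp$discovery$phenotypes$id])
  f2 <- unique(co$ped$family_id[co$ped$id %in% sp$validation$phenotypes$id])
  expect_length(intersect(f1, f2), 0)
})
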