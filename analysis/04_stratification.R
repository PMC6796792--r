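#!/usr/bin/env Rscript
# Stage 4: how well does the weighted score stratify obesity?
#
# For each partition: the continuous score and its quintiles, the linear
# trend odds ratio and quintile odds ratios (logistic mixed models with a
# kinship random effect), the optimism-corrected AUC of covariates-only
# versus covariates + score (1000 bootstrap resamples), NRI and IDI, and
# the share of BMI variance the score explains (linear mixed model).
# Validation individuals are scored with discovery weights and
# discovery allele frequencies.

suppressPackageStartupMessages(library(famprs))

st <- readRDS("results/partitions.rds")
weights <- st$weights
disc_freqs <- vapply(weights$snp_id, function(s)
  compute_maf_callrate(st$discovery$genotypes[, s])$counted_freq,
  numeric(1))

evaluate <- function(part, label) {
  phen <- part$phenotypes
  rel <- cohort_relationship(part)
  prs <- compute_prs(part$genotypes, weights, freqs = disc_freqs)
  quint <- assign_quintiles(prs)

  tt <- trend_test(prs, phen$obesity, phen$sex, phen$age, rel$G,
                   blocks = rel$blocks)
  tt_sd <- trend_test(prs, phen$obesity, phen$sex, phen$age, rel$G,
                      blocks = rel$blocks, per_sd = TRUE)
  qq <- quintile_or_test(quint, phen$obesity, phen$sex, phen$age, rel$G,
                         blocks = rel$blocks)
  dat <- data.frame(obesity = phen$obesity, sex = phen$sex,
                    age = phen$age, prs = prs)
  cmp <- compare_auc_adj(dat, "obesity", c("sex", "age"),
                         c("sex", "age", "prs"), B = 1000L, seed = 7L)
  p_old <- glm(obesity ~ sex + age, binomial, dat)$fitted.values
  p_new <- glm(obesity ~ sex + age + prs, binomial, dat)$fitted.values
  rc <- nri_idi(p_old, p_new, phen$obesity, B = 1000L, seed = 7L)
  ve <- variance_explained(phen$bmi, prs, phen$sex, phen$age, rel$G,
                           blocks = rel$blocks)

  cat(sprintf("\n== %s (n = %d) ==\n", label, nrow(phen)))
  cat(sprintf("OR_trend %.3f [%.3f, %.3f], P = %.2g (per unit of score)\n",
              tt$or_trend, tt$ci[1], tt$ci[2], tt$p))
  cat(sprintf("OR_trend %.3f [%.3f, %.3f] per SD of score\n",
              tt_sd$or_trend, tt_sd$ci[1], tt_sd$ci[2]))
  cat(sprintf("AUC_adj: %.3f (covariates) -> %.3f (+score), diff %.3f [%.3f, %.3f]%s\n",
              cmp$auc_adj_base, cmp$auc_adj_full, cmp$delta_auc_adj,
              cmp$ci_diff[1], cmp$ci_diff[2],
              if (cmp$significant) " *" else ""))
  cat(sprintf("NRI %.3f [%.3f, %.3f]; IDI %.3f [%.3f, %.3f]\n",
              rc$nri, rc$nri_ci[1], rc$nri_ci[2],
              rc$idi, rc$idi_ci[1], rc$idi_ci[2]))
  cat(sprintf("BMI variance explained by the score: %.3f\n", ve$r2))

  trend_tab <- data.frame(partition = label, per = c("unit", "sd"),
                          or_trend = c(tt$or_trend, tt_sd$or_trend),
                          ci_lower = c(tt$ci[1], tt_sd$ci[1]),
                          ci_upper = c(tt$ci[2], tt_sd$ci[2]),
                          p = c(tt$p, tt_sd$p))
  qq$partition <- label
  list(trend = trend_tab, quintiles = qq,
       auc = data.frame(partition = label,
                        auc_adj_base = cmp$auc_adj_base,
                        auc_adj_full = cmp$auc_adj_full,
                        delta = cmp$delta_auc_adj,
                        ci_lower = cmp$ci_diff[1],
                        ci_upper = cmp$ci_diff[2],
                        significant = cmp$significant),
       reclass = data.frame(partition = label, nri = rc$nri,
                            nri_lo = rc$nri_ci[1], nri_hi = rc$nri_ci[2],
                            nri_p = rc$nri_p, idi = rc$idi,
                            idi_lo = rc$idi_ci[1], idi_hi = rc$idi_ci[2],
                            idi_p = rc$idi_p),
       r2 = data.frame(partition = label, r2 = ve$r2,
                       r2_partial = ve$r2_partial,
                       beta_prs = ve$beta_prs, p = ve$p_prs),
       scores = data.frame(id = phen$id, partition = label, prs = prs,
                           quintile = as.character(quint)))
}

res_d <- evaluate(st$discovery, "discovery")
res_v <- evaluate(st$validation, "validation")

for (nm in c("trend", "quintiles", "auc", "reclass", "r2", "scores")) {
  tab <- rbind(res_d[[nm]], res_v[[nm]])
  write.table(tab, sprintf("results/stratification_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("\nwrote results/stratification_*.tsv\n")
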