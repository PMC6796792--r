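#!/usr/bin/env Rscript
# Stage 2: per-SNP quality control of the candidate panel.
#
# Filters follow the genotyping inclusion criteria: MAF > 1%, call rate
# > 95%, Hardy-Weinberg exact P > 2.6e-4, and imputation r2 > 0.3 for
# imputed SNPs — all strict inequalities, computed on founders only (the
# family structure would otherwise distort the MAF and Hardy-Weinberg
# statistics). Writes the QC report and the filtered cohort.

suppressPackageStartupMessages(library(famprs))

cohort <- readRDS("results/cohort.rds")
qc <- apply_qc(cohort, qc_thresholds(), founders_only = TRUE)

cat(sprintf("%d of %d SNPs pass QC\n", sum(qc$pass), nrow(qc)))
if (any(!qc$pass)) {
  cat("failure reasons:\n")
  print(table(qc$fail_reasons[!qc$pass]))
}
write.table(qc, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

filtered <- filter_cohort_snps(cohort, qc)
saveRDS(filtered, "results/cohort_qc.rds")
cat("wrote results/qc_report.tsv and the filtered cohort\n")
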