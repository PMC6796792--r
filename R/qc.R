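#' QC thresholds for candidate SNPs
#'
#' Inclusion filters for BMI-associated SNPs: minor allele frequency,
#' per-SNP call rate, Hardy-Weinberg exact-test p-value, and (for imputed
#' SNPs) imputation quality r2. All filters are strict: a SNP passes only
#' if its statistic is strictly greater than the threshold, so boundary
#' values fail.
#'
#' @param min_maf Minimum minor allele frequency (exclusive).
#' @param min_call_rate Minimum call rate (exclusive).
#' @param min_hwe_p Minimum Hardy-Weinberg exact p-value (exclusive).
#' @param min_imputation_r2 Minimum imputation r2 (exclusive); only applied
#'   to SNPs carrying an imputation r2.
#' @export
qc_thresholds <- function(min_maf = 0.01, min_call_rate = 0.95,
                          min_hwe_p = 2.6e-4, min_imputation_r2 = 0.3) {
  th <- list(min_maf = min_maf, min_call_rate = min_call_rate,
             min_hwe_p = min_hwe_p, min_imputation_r2 = min_imputation_r2)
  if (any(unlist(th) < 0) || any(unlist(th) > 1))
    stop("QC thresholds must lie in [0, 1]", call. = FALSE)
  class(th) <- "qc_thresholds"
  th
}

#' Allele frequency and call rate of one genotype column
#'
#' @param g Vector of allele counts in `{0, 1, 2}` with `NA` for missing
#'   calls.
#' @return A list with `counted_freq` (frequency of the counted allele over
#'   non-missing alleles), `maf` (`min(f, 1 - f)`, `NA` if the column is
#'   entirely missing) and `call_rate`.
#' @examples
#' compute_maf_callrate(c(0, 1, 2, 2)) # counted freq 0.625, maf 0.375
#' @export
compute_maf_callrate <- function(g) {
  if (!all(g %in% c(0, 1, 2) | is.na(g)))
    stop("genotypes must be allele counts 0/1/2 or NA", call. = FALSE)
  n <- length(g)
  ok <- !is.na(g)
  call_rate <- if (n == 0L) 0 else sum(ok) / n
  if (!any(ok))
    return(list(counted_freq = NA_real_, maf = NA_real_, call_rate = call_rate))
  f <- sum(g[ok]) / (2 * sum(ok))
  list(counted_freq = f, maf = min(f, 1 - f), call_rate = call_rate)
}

# log P(n_het | allele counts) for all feasible heterozygote counts, via the
# stable recurrence P(h+2)/P(h) = (na-h)(nb-h) / ((h+2)(h+1)) on the
# conditional (fixed allele count) distribution. Returns the normalized
# probability vector indexed by het = minhet, minhet+2, ..., maxhet.
hwe_het_distribution <- function(n_a, n_total) {
  n_b <- 2L * n_total - n_a
  rare <- min(n_a, n_b)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  if (length(hets) > 1L) {
    h <- hets[-length(hets)]
    steps <- log(n_a - h) + log(n_b - h) - log(h + 2) - log(h + 1)
    logp <- c(0, cumsum(steps))
  } else logp <- 0
  logp <- logp - max(logp)
  p <- exp(logp)
  list(hets = hets, prob = p / sum(p))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test: with the allele counts fixed, the probabilities
#' of every feasible heterozygote count are enumerated and the two-sided
#' p-value sums the probabilities of all tables no more probable than the
#' observed one (the standard exact SNP-HWE test, not mid-p).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (homozygous counted allele,
#'   heterozygous, homozygous other allele).
#' @return The exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(57, 78, 13)
#' hwe_exact_test(0, 0, 100) # monomorphic: 1
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n == 0L) stop("total genotype count must be > 0", call. = FALSE)
  n_a <- 2L * n_aa + n_ab
  d <- hwe_het_distribution(n_a, n)
  p_obs <- d$prob[match(n_ab, d$hets)]
  if (is.na(p_obs)) stop("inconsistent genotype counts", call. = FALSE)
  min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-7)]))
}

#' Chi-square test of Hardy-Weinberg proportions
#'
#' One-degree-of-freedom goodness-of-fit test against expected
#' Hardy-Weinberg genotype proportions; provided for parity with
#' array-QC pipelines that use the asymptotic test.
#'
#' @inheritParams hwe_exact_test
#' @export
hwe_chisq_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  stats::pchisq(x2, df = 1L, lower.tail = FALSE)
}

#' Apply per-SNP quality-control filters
#'
#' Computes MAF, call rate and the Hardy-Weinberg exact p-value for every
#' SNP and tests each against [qc_thresholds()]. All comparisons are
#' strict (`>`); `fail_reasons` enumerates every violated filter. By
#' default MAF and Hardy-Weinberg statistics are computed on founders only,
#' since related individuals distort both; an all-individuals mode is
#' available for parity with naive pipelines.
#'
#' @param cohort A `family_cohort`, or a genotype matrix (individuals x
#'   SNPs) if `snp_meta` is supplied.
#' @param thresholds A [qc_thresholds()] object.
#' @param founders_only Compute MAF/HWE on pedigree founders only.
#' @param snp_meta Optional per-SNP metadata (`snp_id`, `imputation_r2`)
#'   when `cohort` is a bare matrix.
#' @param hwe_test `"exact"` (default) or `"chisq"`.
#' @return A data frame with one row per SNP: `snp_id`, `maf`, `call_rate`,
#'   `hwe_p`, `imputation_r2`, `pass`, `fail_reasons` (semicolon-joined).
#' @export
apply_qc <- function(cohort, thresholds = qc_thresholds(),
                     founders_only = TRUE, snp_meta = NULL,
                     hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  if (inherits(cohort, "family_cohort")) {
    geno <- cohort$genotypes
    snp_meta <- cohort$snp_meta
    founder_ids <- cohort$ped$id[is.na(cohort$ped$father_id) &
                                   is.na(cohort$ped$mother_id)]
    sub <- if (founders_only)
      geno[rownames(geno) %in% founder_ids, , drop = FALSE] else geno
  } else {
    geno <- cohort
    sub <- geno
    if (is.null(snp_meta))
      snp_meta <- data.frame(snp_id = colnames(geno),
                             imputation_r2 = NA_real_)
  }
  if (is.null(snp_meta$imputation_r2)) snp_meta$imputation_r2 <- NA_real_

  hwe_fun <- if (hwe_test == "exact") hwe_exact_test else hwe_chisq_test
  res <- lapply(seq_len(ncol(geno)), function(j) {
    fr_all <- compute_maf_callrate(geno[, j])          # call rate: everyone
    fr <- compute_maf_callrate(sub[, j])               # MAF/HWE basis
    gj <- sub[, j]
    gj <- gj[!is.na(gj)]
    hwe_p <- if (length(gj) == 0L) NA_real_ else
      hwe_fun(sum(gj == 2L), sum(gj == 1L), sum(gj == 0L))
    data.frame(snp_id = snp_meta$snp_id[j],
               maf = fr$maf, call_rate = fr_all$call_rate, hwe_p = hwe_p,
               imputation_r2 = snp_meta$imputation_r2[j],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  reasons <- lapply(seq_len(nrow(res)), function(i) {
    r <- character(0)
    if (is.na(res$maf[i]) || !(res$maf[i] > thresholds$min_maf))
      r <- c(r, "maf")
    if (!(res$call_rate[i] > thresholds$min_call_rate))
      r <- c(r, "call_rate")
    if (is.na(res$hwe_p[i]) || !(res$hwe_p[i] > thresholds$min_hwe_p))
      r <- c(r, "hwe")
    if (!is.na(res$imputation_r2[i]) &&
        !(res$imputation_r2[i] > thresholds$min_imputation_r2))
      r <- c(r, "imputation_r2")
    r
  })
  res$pass <- lengths(reasons) == 0L
  res$fail_reasons <- vapply(reasons, paste, character(1L), collapse = ";")
  res
}

#' Drop QC-failing SNPs from a cohort
#'
#' @param cohort A `family_cohort`.
#' @param qc A QC report from [apply_qc()].
#' @export
filter_cohort_snps <- function(cohort, qc) {
  keep <- qc$snp_id[qc$pass]
  cohort$genotypes <- cohort$genotypes[, colnames(cohort$genotypes) %in% keep,
                                       drop = FALSE]
  cohort$snp_meta <- cohort$snp_meta[cohort$snp_meta$snp_id %in% keep, ]
  rownames(cohort$snp_meta) <- NULL
  cohort
}
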