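#' Prevalence as a percentage
#'
#' @param case_count Number of cases.
#' @param n Total sample size (> 0).
#' @return A list with `raw` (unrounded percentage, `100 * case_count / n`)
#'   and `percent` (rounded to one decimal for display).
#' @examples
#' compute_prevalence(68 + 128, 235 + 273 + 68 + 128)$percent # 27.8
#' @export
compute_prevalence <- function(case_count, n) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (case_count < 0 || case_count > n)
    stop("case_count must lie in [0, n]", call. = FALSE)
  raw <- 100 * case_count / n
  list(raw = raw, percent = round(raw, 1))
}

#' End-to-end pipeline configuration
#'
#' One config object driving simulate -> QC -> kinship -> association ->
#' weights -> score -> stratification evaluation -> power. Exactly one
#' genotype source is used: a simulation config (default) or a previously
#' built `family_cohort`.
#'
#' @param sim A [sim_config()] (ignored when `cohort` is given).
#' @param cohort Optional pre-built `family_cohort`.
#' @param qc [qc_thresholds()].
#' @param founders_only_qc Compute MAF/HWE on founders only.
#' @param split_fraction,split_seed,split_stratified,split_by_family
#'   Discovery/validation split settings (see [split_cohort()]).
#' @param weight_mode Score weighting, `"or"` or `"logor"`.
#' @param scan_alpha Significance level of the single-SNP scan.
#' @param scan_sigma2g `"per_snp"` or `"null_fixed"` (see
#'   [single_snp_scan()]).
#' @param bootstrap_B,bootstrap_seed Optimism/NRI/IDI bootstrap settings.
#' @param power_alpha Significance level of the power calculation.
#' @export
pipeline_config <- function(sim = sim_config(), cohort = NULL,
                            qc = qc_thresholds(), founders_only_qc = TRUE,
                            split_fraction = 0.8, split_seed = 1L,
                            split_stratified = TRUE,
                            split_by_family = FALSE,
                            weight_mode = c("or", "logor"),
                            scan_alpha = 0.05,
                            scan_sigma2g = c("per_snp", "null_fixed"),
                            bootstrap_B = 1000L, bootstrap_seed = 1L,
                            power_alpha = 0.05) {
  structure(list(sim = sim, cohort = cohort, qc = qc,
                 founders_only_qc = founders_only_qc,
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 split_stratified = split_stratified,
                 split_by_family = split_by_family,
                 weight_mode = match.arg(weight_mode),
                 scan_alpha = scan_alpha,
                 scan_sigma2g = match.arg(scan_sigma2g),
                 bootstrap_B = as.integer(bootstrap_B),
                 bootstrap_seed = as.integer(bootstrap_seed),
                 power_alpha = power_alpha),
            class = "pipeline_config")
}

eval_partition <- function(cohort, weights, freqs, config) {
  phen <- cohort$phenotypes
  rel <- cohort_relationship(cohort)
  prs <- compute_prs(cohort$genotypes, weights, freqs = freqs)
  quint <- assign_quintiles(prs)
  dat <- data.frame(obesity = phen$obesity, sex = phen$sex, age = phen$age,
                    prs = prs)
  trend <- trend_test(prs, phen$obesity, phen$sex, phen$age,
                      rel$G, blocks = rel$blocks)
  quint_or <- quintile_or_test(quint, phen$obesity, phen$sex, phen$age,
                               rel$G, blocks = rel$blocks)
  auc_cmp <- compare_auc_adj(dat, "obesity", c("sex", "age"),
                             c("sex", "age", "prs"),
                             B = config$bootstrap_B,
                             seed = config$bootstrap_seed)
  p_old <- risk_fitter(dat, "obesity", c("sex", "age"))(dat)
  p_new <- risk_fitter(dat, "obesity", c("sex", "age", "prs"))(dat)
  reclass <- nri_idi(p_old, p_new, phen$obesity, B = config$bootstrap_B,
                     seed = config$bootstrap_seed)
  ve <- variance_explained(phen$bmi, prs, phen$sex, phen$age,
                           rel$G, blocks = rel$blocks)
  prev <- compute_prevalence(sum(phen$obesity), nrow(phen))
  list(n = nrow(phen), n_cases = sum(phen$obesity), prevalence = prev,
       trend = trend[c("or_trend", "ci", "p", "per")],
       quintile_or = quint_or,
       auc = auc_cmp,
       nri_idi = reclass[c("nri", "nri_ci", "nri_p", "idi", "idi_ci",
                           "idi_p")],
       variance_explained = ve[c("r2", "r2_partial", "beta_prs", "p_prs")],
       prs_summary = c(mean = mean(prs), sd = stats::sd(prs)))
}

#' Run the whole stratification pipeline
#'
#' Executes, in order: cohort simulation (ascertained families), SNP QC,
#' discovery/validation split, kinship construction, the single-SNP
#' logistic mixed-model scan on the discovery partition, score-weight
#' derivation, scoring of both partitions (validation scored with
#' discovery weights and frequencies), stratification evaluation (trend
#' and quintile odds ratios, optimism-corrected AUC comparison, NRI/IDI,
#' BMI variance explained) per partition, and the analytic power of the
#' validation-sample score test. The returned report records every seed;
#' identical configs give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list (see [validate_report()]).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$cohort)) config$cohort else
    simulate_ascertained_cohort(config$sim)

  qc_report <- apply_qc(cohort, config$qc,
                        founders_only = config$founders_only_qc)
  filtered <- filter_cohort_snps(cohort, qc_report)

  parts <- split_cohort(filtered, fraction = config$split_fraction,
                        seed = config$split_seed,
                        stratify_by_obesity = config$split_stratified,
                        by_family = config$split_by_family)
  disc <- parts$discovery
  valid <- parts$validation

  assoc <- single_snp_scan(disc, alpha = config$scan_alpha,
                           sigma2g_mode = config$scan_sigma2g)
  usable <- assoc[assoc$skipped %in% c("", "separation_warning") &
                    !is.na(assoc$or), , drop = FALSE]
  weights <- build_weights(usable, mode = config$weight_mode)
  disc_freqs <- vapply(weights$snp_id, function(s)
    compute_maf_callrate(disc$genotypes[, s])$counted_freq, numeric(1))

  eval_disc <- eval_partition(disc, weights, disc_freqs, config)
  eval_valid <- eval_partition(valid, weights, disc_freqs, config)

  pw_in <- power_inputs(
    n_train = eval_disc$n, n_target = eval_valid$n,
    prevalence_train = eval_disc$prevalence$raw / 100,
    prevalence_target = eval_valid$prevalence$raw / 100,
    n_snps = nrow(weights),
    score_r2_train = eval_disc$variance_explained$r2,
    alpha = config$power_alpha)
  pw <- analytic_power(pw_in)

  report <- list(
    version = as.character(utils::packageVersion("famprs")),
    seeds = list(simulation = if (is.null(config$cohort))
      config$sim$seed else NA_integer_,
      split = config$split_seed, bootstrap = config$bootstrap_seed),
    cohort = list(n = n_individuals(cohort),
                  n_families = length(unique(cohort$ped$family_id)),
                  prevalence = compute_prevalence(
                    sum(cohort$phenotypes$obesity), n_individuals(cohort))),
    qc = list(n_snps_in = nrow(qc_report),
              n_snps_pass = sum(qc_report$pass),
              fail_table = table(qc_report$fail_reasons[!qc_report$pass])),
    split = list(fraction = config$split_fraction,
                 n_discovery = eval_disc$n, n_validation = eval_valid$n),
    association = list(n_tested = sum(usable$skipped == ""),
                       n_significant = length(attr(assoc, "significant")),
                       alpha = config$scan_alpha),
    weights = list(mode = config$weight_mode, n_snps = nrow(weights)),
    discovery = eval_disc,
    validation = eval_valid,
    power = c(pw, list(inputs = unclass(pw_in)))
  )
  class(report) <- "pipeline_report"
  validate_report(report)
  report
}

report_schema <- function() {
  list(top = c("version", "seeds", "cohort", "qc", "split", "association",
               "weights", "discovery", "validation", "power"),
       partition = c("n", "n_cases", "prevalence", "trend", "quintile_or",
                     "auc", "nri_idi", "variance_explained", "prs_summary"))
}

#' Validate a pipeline report against the expected schema
#'
#' Checks the report's structure (required fields at the top level and in
#' each partition summary) and internal consistency (prevalences equal
#' case count over partition size).
#'
#' @param report A `pipeline_report`.
#' @return The report, invisibly; errors describe any violation.
#' @export
validate_report <- function(report) {
  sch <- report_schema()
  missing_top <- setdiff(sch$top, names(report))
  if (length(missing_top))
    stop("report is missing fields: ", paste(missing_top, collapse = ", "),
         call. = FALSE)
  for (part in c("discovery", "validation")) {
    p <- report[[part]]
    miss <- setdiff(sch$partition, names(p))
    if (length(miss))
      stop(part, " summary is missing fields: ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (abs(p$prevalence$raw - 100 * p$n_cases / p$n) > 1e-12)
      stop(part, " prevalence does not equal cases/n", call. = FALSE)
  }
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Polygenic-score stratification pipeline report\n")
  cat(sprintf("  cohort: %d individuals / %d families, prevalence %.1f%%\n",
              x$cohort$n, x$cohort$n_families, x$cohort$prevalence$percent))
  cat(sprintf("  QC: %d of %d SNPs pass\n", x$qc$n_snps_pass,
              x$qc$n_snps_in))
  cat(sprintf("  split: %d discovery / %d validation\n",
              x$split$n_discovery, x$split$n_validation))
  cat(sprintf("  scan: %d significant of %d tested (alpha %.2f)\n",
              x$association$n_significant, x$association$n_tested,
              x$association$alpha))
  for (part in c("discovery", "validation")) {
    p <- x[[part]]
    cat(sprintf(
      "  %s: OR_trend %.3f [%.3f, %.3f], AUC_adj %.3f (+PRS %.3f), R2 %.3f\n",
      part, p$trend$or_trend, p$trend$ci[1], p$trend$ci[2],
      p$auc$auc_adj_base, p$auc$auc_adj_full, p$variance_explained$r2))
  }
  cat(sprintf("  power of validation score test: %.3f\n", x$power$power))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  out <- rapply(unclass(report), function(x)
    if (is.table(x)) as.list(x) else x, how = "replace")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
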