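#' Build polygenic score weights from association results
#'
#' The default weighting multiplies each counted allele by its estimated
#' odds ratio, exactly as the score was originally described; `"logor"`
#' uses the field-standard log-odds weights instead. Both are first-class
#' because the literal OR weighting and common practice disagree.
#'
#' @param assoc Association results from [single_snp_scan()] (or any data
#'   frame with `snp_id`, `counted_allele` and `or`). SNPs that were
#'   skipped (no OR) are rejected with an error naming them.
#' @param mode `"or"` or `"logor"`.
#' @return A data frame of class `score_weights`: `snp_id`, `counted_allele`,
#'   `weight`, with the mode stored as an attribute.
#' @export
build_weights <- function(assoc, mode = c("or", "logor")) {
  mode <- match.arg(mode)
  if (any(is.na(assoc$or)))
    stop("missing odds ratio for SNP(s): ",
         paste(assoc$snp_id[is.na(assoc$or)], collapse = ", "),
         call. = FALSE)
  w <- data.frame(snp_id = assoc$snp_id,
                  counted_allele = assoc$counted_allele,
                  weight = if (mode == "or") assoc$or else log(assoc$or),
                  stringsAsFactors = FALSE)
  if (!all(is.finite(w$weight)))
    stop("non-finite weights", call. = FALSE)
  attr(w, "mode") <- mode
  class(w) <- c("score_weights", class(w))
  w
}

#' Compute the weighted polygenic risk score
#'
#' `score_i = sum_j weight_j * g_ij`: the sum over SNPs of the counted
#' allele count multiplied by its weight. Missing genotypes contribute
#' `weight * 2 * (counted-allele frequency)`, with the frequency taken
#' from the non-missing calls of the supplied genotype matrix unless
#' `freqs` provides it (e.g. discovery-sample frequencies applied to a
#' validation sample).
#'
#' @param genotypes Individuals x SNPs allele-count matrix (`NA` missing).
#' @param weights A [build_weights()] table (or any data frame with
#'   `snp_id` and `weight`). Every weight SNP must be a genotype column.
#' @param freqs Optional named vector of counted-allele frequencies used
#'   for mean imputation.
#' @return Numeric vector of scores, named by individual.
#' @export
compute_prs <- function(genotypes, weights, freqs = NULL) {
  missing_snps <- setdiff(weights$snp_id, colnames(genotypes))
  if (length(missing_snps))
    stop("weight SNP(s) absent from genotypes: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  g <- genotypes[, weights$snp_id, drop = FALSE]
  if (anyNA(g)) {
    f <- if (!is.null(freqs)) unname(freqs[weights$snp_id]) else
      vapply(seq_len(ncol(g)), function(j)
        compute_maf_callrate(g[, j])$counted_freq, numeric(1))
    for (j in which(colSums(is.na(g)) > 0)) {
      if (is.na(f[j]))
        stop("cannot impute an all-missing SNP: ", weights$snp_id[j],
             call. = FALSE)
      g[is.na(g[, j]), j] <- 2 * f[j]
    }
  }
  drop(g %*% weights$weight)
}

#' Assign score quintiles
#'
#' Rank-based split into five groups of size `ceiling(n/5)` or
#' `floor(n/5)` (sizes differ by at most one); ties are broken by stable
#' input order. `Q1` holds the lowest scores.
#'
#' @param prs Numeric score vector, `n >= 5`.
#' @return Ordered factor with levels `Q1` to `Q5`, named as `prs`.
#' @export
assign_quintiles <- function(prs) {
  n <- length(prs)
  if (n < 5L) stop("need at least 5 individuals for quintiles", call. = FALSE)
  rk <- rank(prs, ties.method = "first")
  sizes <- rep(n %/% 5L, 5L)
  if (n %% 5L) sizes[seq_len(n %% 5L)] <- sizes[seq_len(n %% 5L)] + 1L
  q <- rep(seq_len(5L), times = sizes)[rk]
  stats::setNames(factor(paste0("Q", q), levels = paste0("Q", 1:5),
                         ordered = TRUE), names(prs))
}
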