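# Plain-text readers and writers for the cohort's standard formats:
# VCF (GT field, one sample per individual), 6-column PED/FAM pedigree,
# TSV dosage table, and TSV phenotype/weight/score/QC tables.

#' Write a cohort's genotypes as a VCF
#'
#' Minimal VCF 4.2 with a GT field per individual; the counted allele is
#' written as ALT so that the ALT allele count equals the genotype coding.
#' Missing calls become `./.`.
#'
#' @param cohort A `family_cohort`.
#' @param path Output file (plain text).
#' @export
write_cohort_vcf <- function(cohort, path) {
  g <- cohort$genotypes
  ids <- rownames(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=famprs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(g))) {
    calls <- ifelse(is.na(g[, j]), "./.", gt_code[as.character(g[, j])])
    writeLines(paste(c("1", j, cohort$snp_meta$snp_id[j],
                       cohort$snp_meta$other_allele[j],
                       cohort$snp_meta$counted_allele[j],
                       ".", "PASS", ".", "GT", calls), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read genotypes from a VCF into an allele-count matrix
#'
#' Parses the GT field with \pkg{vcfR}; the returned matrix counts ALT
#' alleles (0/1/2, `NA` for missing), individuals in rows.
#'
#' @param path VCF file.
#' @return List with `genotypes` and `snp_meta` (`snp_id`,
#'   `counted_allele`, `other_allele`).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                   dimnames = list(colnames(gt), rownames(gt)))
  for (j in seq_len(nrow(gt))) {
    x <- gt[j, ]
    counts[, j] <- vapply(strsplit(x, "[/|]"), function(a) {
      if (any(a == ".") || length(a) != 2L) NA_integer_
      else sum(a == "1")
    }, integer(1))
  }
  meta <- data.frame(snp_id = unname(v@fix[, "ID"]),
                     counted_allele = unname(v@fix[, "ALT"]),
                     other_allele = unname(v@fix[, "REF"]),
                     stringsAsFactors = FALSE)
  list(genotypes = counts, snp_meta = meta)
}

#' Write genotypes as a TSV dosage table
#'
#' Individuals in rows (first column `id`), SNPs in columns, values in
#' 0/1/2 with `NA` for missing.
#'
#' @param genotypes Allele-count matrix.
#' @param path Output file.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV dosage table
#' @param path Dosage file from [write_dosage_tsv()].
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' Write a 6-column PED/FAM-style pedigree
#'
#' Columns: family, individual, father (0 if founder), mother (0 if
#' founder), sex (1 male / 2 female), phenotype (obesity 2/1 when
#' phenotypes are available, else 0).
#'
#' @param cohort A `family_cohort`.
#' @param path Output file.
#' @export
write_pedigree <- function(cohort, path) {
  ped <- cohort$ped
  phen_code <- rep(0L, nrow(ped))
  m <- match(ped$id, cohort$phenotypes$id)
  phen_code[!is.na(m)] <- cohort$phenotypes$obesity[m[!is.na(m)]] + 1L
  df <- data.frame(ped$family_id, ped$id,
                   ifelse(is.na(ped$father_id), "0", ped$father_id),
                   ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                   ped$sex, phen_code)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column PED/FAM-style pedigree
#' @param path Pedigree file (family, individual, father, mother, sex,
#'   phenotype; 0 for missing parents).
#' @return Pedigree data frame (`family_id`, `id`, `father_id`,
#'   `mother_id`, `sex`, `phenotype`).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("family_id", "id", "father_id",
                                        "mother_id", "sex", "phenotype"))
  df$father_id[df$father_id == "0"] <- NA_character_
  df$mother_id[df$mother_id == "0"] <- NA_character_
  df
}

#' Write the phenotype/covariate table
#' @param cohort A `family_cohort`.
#' @param path Output TSV.
#' @export
write_phenotypes <- function(cohort, path) {
  utils::write.table(cohort$phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#' @param path TSV with header (`id`, `bmi`, `sex`, `age`, optionally
#'   `obesity`).
#' @param obesity_threshold Threshold used to derive the obesity flag when
#'   absent.
#' @export
read_phenotypes <- function(path, obesity_threshold = 30) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(df$obesity))
    df$obesity <- as.integer(df$bmi >= obesity_threshold)
  df
}

#' Write a cohort to a set of plain-text files
#'
#' Writes `<prefix>.vcf`, `<prefix>.dosage.tsv`, `<prefix>.ped`,
#' `<prefix>.pheno.tsv` and `<prefix>.snps.tsv`.
#'
#' @param cohort A `family_cohort`.
#' @param prefix Path prefix.
#' @return The prefix, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  write_cohort_vcf(cohort, paste0(prefix, ".vcf"))
  write_dosage_tsv(cohort$genotypes, paste0(prefix, ".dosage.tsv"))
  write_pedigree(cohort, paste0(prefix, ".ped"))
  write_phenotypes(cohort, paste0(prefix, ".pheno.tsv"))
  utils::write.table(cohort$snp_meta, paste0(prefix, ".snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Rebuild a cohort from plain-text files
#'
#' Counterpart of [write_cohort()]; genotypes may come from either the
#' VCF (needs \pkg{vcfR}) or the dosage table.
#'
#' @param prefix Path prefix used by [write_cohort()].
#' @param from `"dosage"` (default) or `"vcf"`.
#' @export
read_cohort <- function(prefix, from = c("dosage", "vcf")) {
  from <- match.arg(from)
  ped <- read_pedigree(paste0(prefix, ".ped"))
  phen <- read_phenotypes(paste0(prefix, ".pheno.tsv"))
  snp_meta <- utils::read.table(paste0(prefix, ".snps.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  if (from == "vcf") {
    gv <- read_genotypes_vcf(paste0(prefix, ".vcf"))
    geno <- gv$genotypes
  } else {
    geno <- read_dosage_tsv(paste0(prefix, ".dosage.tsv"))
  }
  geno <- geno[phen$id, snp_meta$snp_id, drop = FALSE]
  ped$role <- ifelse(is.na(ped$father_id), "parent", "offspring")
  structure(list(ped = ped[, c("family_id", "id", "father_id", "mother_id",
                               "sex", "role")],
                 genotypes = geno, snp_meta = snp_meta,
                 phenotypes = phen[, intersect(c("id", "bmi", "sex", "age",
                                                 "obesity"), names(phen))],
                 true_score = NULL, config = NULL),
            class = "family_cohort")
}

#' Write a kinship (or relationship) matrix as TSV
#' @param m Symmetric matrix with id dimnames.
#' @param path Output file.
#' @export
write_kinship_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinship (or relationship) matrix from TSV
#' @param path File from [write_kinship_tsv()].
#' @export
read_kinship_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
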