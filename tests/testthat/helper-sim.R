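# Shared simulation helpers: hand-built cohorts with controllable
# phenotypes, and a family GLMM generator with a known SNP effect.

# A cohort of `n` unrelated individuals (each their own single-founder
# family) with fully controllable obesity flags; genotypes optional.
make_unrelated_cohort <- function(n, n_obese = round(0.3 * n), n_snps = 0,
                                  seed = 1) {
  set.seed(seed)
  ids <- sprintf("I%04d", seq_len(n))
  ped <- data.frame(family_id = ids, id = ids,
                    father_id = NA_character_, mother_id = NA_character_,
                    sex = rep_len(c(1L, 2L), n), role = "parent",
                    stringsAsFactors = FALSE)
  obesity <- rep(0L, n)
  obesity[sample.int(n, n_obese)] <- 1L
  phen <- data.frame(id = ids, bmi = ifelse(obesity == 1, 33, 24),
                     sex = ped$sex, age = round(runif(n, 20, 60)),
                     obesity = obesity, stringsAsFactors = FALSE)
  geno <- if (n_snps > 0) {
    g <- matrix(rbinom(n * n_snps, 2L, 0.3), n, n_snps,
                dimnames = list(ids, sprintf("snp%03d", seq_len(n_snps))))
    g
  } else matrix(integer(0), n, 0, dimnames = list(ids, NULL))
  snp_meta <- if (n_snps > 0)
    data.frame(snp_id = colnames(geno), counted_allele = "G",
               other_allele = "A", imputation_r2 = NA_real_,
               stringsAsFactors = FALSE)
  else data.frame(snp_id = character(0), counted_allele = character(0),
                  other_allele = character(0), imputation_r2 = numeric(0))
  structure(list(ped = ped, genotypes = geno, snp_meta = snp_meta,
                 phenotypes = phen, true_score = NULL, config = NULL),
            class = "family_cohort")
}

# A hand-built nuclear-family cohort from explicit per-family BMI lists:
# fams is a list of list(parents = c(...), offspring = c(...)) BMI values.
make_bmi_cohort <- function(fams, obesity_threshold = 30) {
  ped <- NULL; phen <- NULL
  for (f in seq_along(fams)) {
    np <- length(fams[[f]]$parents)
    no <- length(fams[[f]]$offspring)
    fid <- sprintf("F%02d", f)
    ids <- paste0(fid, "_", c(paste0("P", seq_len(np)),
                              paste0("O", seq_len(no))))
    ped <- rbind(ped, data.frame(
      family_id = fid, id = ids,
      father_id = c(rep(NA_character_, np), rep(ids[1], no)),
      mother_id = c(rep(NA_character_, np),
                    rep(if (np > 1) ids[2] else ids[1], no)),
      sex = rep_len(c(1L, 2L), np + no),
      role = c(rep("parent", np), rep("offspring", no)),
      stringsAsFactors = FALSE))
    bmi <- c(fams[[f]]$parents, fams[[f]]$offspring)
    phen <- rbind(phen, data.frame(
      id = ids, bmi = bmi, sex = rep_len(c(1L, 2L), np + no),
      age = rep_len(c(50, 48, 25, 22, 28), np + no),
      obesity = as.integer(bmi >= obesity_threshold),
      stringsAsFactors = FALSE))
  }
  geno <- matrix(integer(0), nrow(phen), 0, dimnames = list(phen$id, NULL))
  structure(list(ped = ped, genotypes = geno,
                 snp_meta = data.frame(snp_id = character(0),
                                       counted_allele = character(0),
                                       other_allele = character(0),
                                       imputation_r2 = numeric(0)),
                 phenotypes = phen, true_score = NULL, config = NULL),
            class = "family_cohort")
}

# Nuclear families with a latent polygenic random effect and one SNP of
# known log-odds effect on a binary outcome; returns design pieces and a
# proper family_cohort for scan-level tests.
sim_glmm_families <- function(seed, n_fam = 60, beta_snp = 0.3, s2g = 0.5,
                              maf = 0.3, b0 = -0.8, beta_sex = 0.3,
                              beta_age = 0.01) {
  set.seed(seed)
  ped <- vector("list", n_fam); G <- vector("list", n_fam)
  g <- integer(0); fam <- character(0)
  for (f in seq_len(n_fam)) {
    n_off <- sample(1:3, 1)
    fid <- paste0("F", f)
    ids <- paste0(fid, "_", c("P1", "P2", paste0("O", seq_len(n_off))))
    p <- data.frame(family_id = fid, id = ids,
                    father_id = c(NA, NA, rep(ids[1], n_off)),
                    mother_id = c(NA, NA, rep(ids[2], n_off)),
                    sex = NA_integer_, role = c("parent", "parent",
                                                rep("offspring", n_off)),
                    stringsAsFactors = FALSE)
    gp <- rbinom(2, 2, maf)
    go <- rbinom(n_off, 1, gp[1] / 2) + rbinom(n_off, 1, gp[2] / 2)
    ped[[f]] <- p
    G[[f]] <- 2 * kinship_from_pedigree(p)
    g <- c(g, gp, go)
    fam <- c(fam, rep(fid, 2L + n_off))
  }
  n <- length(g)
  b <- unlist(lapply(G, function(m)
    drop(crossprod(chol(m + diag(1e-8, nrow(m))), rnorm(nrow(m))) *
           sqrt(s2g))))
  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 20, 60)
  y <- rbinom(n, 1, plogis(b0 + beta_snp * g + beta_sex * sex +
                             beta_age * age + b))
  ped_all <- do.call(rbind, ped)
  ped_all$sex <- sex + 1L
  ids <- ped_all$id
  geno <- matrix(g, n, 1, dimnames = list(ids, "snp001"))
  cohort <- structure(list(
    ped = ped_all,
    genotypes = geno,
    snp_meta = data.frame(snp_id = "snp001", counted_allele = "G",
                          other_allele = "A", imputation_r2 = NA_real_,
                          stringsAsFactors = FALSE),
    phenotypes = data.frame(id = ids, bmi = ifelse(y == 1, 33, 24),
                            sex = sex + 1L, age = age, obesity = y,
                            stringsAsFactors = FALSE),
    true_score = NULL, config = NULL), class = "family_cohort")
  list(y = y, X = cbind(intercept = 1, sex = sex, age = age, snp = g),
       g = g, G = G, fam = fam, cohort = cohort)
}

# Random multi-generation pedigree: `n_founders` founders then `n_extra`
# individuals whose parents are drawn from all earlier individuals
# (loops and inbreeding arise naturally).
random_pedigree <- function(n_founders = 10, n_extra = 20, seed = 1) {
  set.seed(seed)
  n <- n_founders + n_extra
  id <- sprintf("I%02d", seq_len(n))
  fa <- mo <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pr <- sample(seq_len(i - 1L), 2L)
    fa[i] <- id[pr[1]]
    mo[i] <- id[pr[2]]
  }
  data.frame(id = id, father_id = fa, mother_id = mo,
             stringsAsFactors = FALSE)
}

# Direct-formula conditional probabilities of every heterozygote count
# given the allele counts (independent oracle for the exact HWE test).
hwe_oracle_probs <- function(n_a, n_total) {
  n_b <- 2 * n_total - n_a
  hets <- seq.int(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  lp <- lgamma(n_total + 1) - lgamma((n_a - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((n_b - hets) / 2 + 1) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n_total + 1) +
    hets * log(2)
  list(hets = hets, prob = exp(lp))
}
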