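#' Kinship matrix from a pedigree (recursive tabular method)
#'
#' Computes the kinship coefficients phi_ij for every pair of individuals
#' in a pedigree: phi_ij is the probability that one allele sampled from i
#' and one from j are identical by descent. Founders are taken as non-inbred
#' and mutually unrelated (`phi_ii = 1/2`, `phi_ij = 0`); for an individual
#' i with parents (f, m), `phi_ij = (phi_fj + phi_mj) / 2` for `j != i` and
#' `phi_ii = (1 + phi_fm) / 2`.
#'
#' @param ped A pedigree data frame with columns `id`, `father_id`,
#'   `mother_id` (both `NA` for founders). Parents must be rows of the
#'   pedigree; cycles are rejected.
#' @return A symmetric matrix of kinship coefficients, ordered and named as
#'   the input pedigree.
#' @examples
#' ped <- data.frame(id = c("f", "m", "c"),
#'                   father_id = c(NA, NA, "f"),
#'                   mother_id = c(NA, NA, "m"))
#' kinship_from_pedigree(ped)["f", "c"] # parent-offspring: 0.25
#' @export
kinship_from_pedigree <- function(ped) {
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicated individual ids", call. = FALSE)
  fa <- match(as.character(ped$father_id), ids)
  mo <- match(as.character(ped$mother_id), ids)
  has_fa <- !is.na(ped$father_id)
  has_mo <- !is.na(ped$mother_id)
  if (any(has_fa & is.na(fa)) || any(has_mo & is.na(mo)))
    stop("pedigree references a parent that is not in the pedigree",
         call. = FALSE)
  if (any(has_fa != has_mo))
    stop("individuals must have either both parents or none", call. = FALSE)

  n <- length(ids)
  # topological order: parents before offspring; failure => cycle
  order <- integer(0)
  placed <- logical(n)
  repeat {
    ready <- !placed &
      (!has_fa | placed[ifelse(is.na(fa), 1L, fa)]) &
      (!has_mo | placed[ifelse(is.na(mo), 1L, mo)])
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    order <- c(order, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order) < n)
    stop("pedigree contains a cycle (an individual is its own ancestor)",
         call. = FALSE)

  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in order) {
    if (!has_fa[i]) {
      phi[i, i] <- 0.5
    } else {
      f <- fa[i]; m <- mo[i]
      prev <- order[seq_len(match(i, order) - 1L)]
      if (length(prev)) {
        v <- (phi[f, prev] + phi[m, prev]) / 2
        phi[i, prev] <- v
        phi[prev, i] <- v
      }
      phi[i, i] <- (1 + phi[f, m]) / 2
    }
  }
  phi
}

#' Additive relationship matrix
#'
#' Returns `2 * phi`, the covariance structure of additive genetic effects
#' used as the random-effect covariance in the mixed models. Positive
#' semidefiniteness is verified (smallest eigenvalue >= -1e-8) and any
#' tiny negative eigenvalues are clipped to zero.
#'
#' @param kin A kinship matrix from [kinship_from_pedigree()].
#' @export
relationship_matrix <- function(kin) {
  a <- 2 * kin
  e <- eigen(a, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("relationship matrix is not positive semidefinite", call. = FALSE)
  if (min(e$values) < 0) {
    v <- pmax(e$values, 0)
    a <- e$vectors %*% (v * t(e$vectors))
    dimnames(a) <- dimnames(kin)
  }
  a
}

#' Kinship submatrix for the individuals of a cohort
#'
#' Derives kinship from the cohort's complete pedigree and restricts it to
#' the individuals present in the phenotype table (e.g. after a split).
#'
#' @param cohort A `family_cohort`.
#' @export
cohort_kinship <- function(cohort) {
  phi <- kinship_from_pedigree(cohort$ped)
  ids <- cohort$phenotypes$id
  phi[ids, ids, drop = FALSE]
}

#' Per-family relationship blocks for a cohort
#'
#' Kinship between members of different families is exactly zero, so the
#' additive relationship matrix of a cohort is block-diagonal across
#' families. This returns it in block form — a list of per-family `2 *
#' kinship` matrices plus the family grouping vector — which the mixed
#' models exploit and which avoids ever forming the dense n x n matrix.
#'
#' @param cohort A `family_cohort`.
#' @return A list with `blocks` (family id per phenotyped individual, in
#'   phenotype-table order) and `G` (list of per-family relationship
#'   matrices in order of first appearance).
#' @export
cohort_relationship <- function(cohort) {
  phen_ids <- cohort$phenotypes$id
  fam <- cohort$ped$family_id[match(phen_ids, cohort$ped$id)]
  fams <- unique(fam)
  G <- lapply(fams, function(f) {
    ped_f <- cohort$ped[cohort$ped$family_id == f, , drop = FALSE]
    phi <- kinship_from_pedigree(ped_f)
    ids_f <- phen_ids[fam == f]
    2 * phi[ids_f, ids_f, drop = FALSE]
  })
  list(blocks = fam, G = G)
}

#' Monte-Carlo kinship by gene dropping
#'
#' Independent verification of the tabular kinship computation: two alleles
#' per founder are labelled uniquely and dropped through the pedigree by
#' simulated Mendelian transmission; the kinship estimate for a pair is the
#' fraction of drops in which one allele sampled from each is identical by
#' descent (computed exactly per drop as the expected IBD sharing of the
#' realized allele labels).
#'
#' @param ped Pedigree data frame as in [kinship_from_pedigree()].
#' @param n_drops Number of independent gene drops.
#' @param seed Integer seed.
#' @return Estimated kinship matrix.
#' @export
gene_drop_kinship <- function(ped, n_drops = 2e5, seed = 1L) {
  set.seed(as.integer(seed))
  ids <- as.character(ped$id)
  n <- length(ids)
  fa <- match(as.character(ped$father_id), ids)
  mo <- match(as.character(ped$mother_id), ids)
  is_founder <- is.na(fa)
  # topological order
  order <- integer(0); placed <- logical(n)
  repeat {
    ready <- !placed & (is_founder | (placed[ifelse(is.na(fa), 1L, fa)] &
                                        placed[ifelse(is.na(mo), 1L, mo)]))
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    order <- c(order, which(ready)); placed[ready] <- TRUE
  }
  if (length(order) < n) stop("pedigree contains a cycle", call. = FALSE)

  # allele labels per drop: matrices n_drops x n for the two gametes
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in order) {
    if (is_founder[i]) {
      a1[, i] <- lab + 1L
      a2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick1 <- stats::runif(n_drops) < 0.5
      pick2 <- stats::runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick1, a1[, fa[i]], a2[, fa[i]])
      a2[, i] <- ifelse(pick2, a1[, mo[i]], a2[, mo[i]])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
        (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
      phi[i, j] <- phi[j, i] <- mean(ibd) / 4
    }
  }
  phi
}
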