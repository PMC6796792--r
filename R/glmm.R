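# Mixed-model machinery shared by the logistic (PQL) and linear (REML)
# fits. The random-effect covariance is sigma2_g * G with G the additive
# relationship matrix (2 * kinship). G is block-diagonal across families,
# which is exploited: eigendecompositions are done per block, making each
# solve O(sum k_b^2) instead of O(n^3), and G may be supplied directly as
# a list of per-family blocks so the dense n x n matrix is never formed.

# Normalize the covariance argument to a list of (idx, M) blocks.
# G: dense matrix (blocks optional) or list of per-block matrices
# (blocks mandatory, one block per list element, in order of first
# appearance of each block label).
cov_blocks <- function(G, blocks, n) {
  if (is.matrix(G)) {
    if (nrow(G) != n || ncol(G) != n)
      stop("G must be n x n", call. = FALSE)
    idxs <- if (is.null(blocks)) list(seq_len(n)) else
      unname(split(seq_len(n), factor(blocks, levels = unique(blocks))))
    return(lapply(idxs, function(idx)
      list(idx = idx, M = G[idx, idx, drop = FALSE])))
  }
  if (is.list(G)) {
    if (is.null(blocks))
      stop("blocks is required when G is a list of block matrices",
           call. = FALSE)
    idxs <- unname(split(seq_len(n), factor(blocks, levels = unique(blocks))))
    if (length(idxs) != length(G))
      stop("number of covariance blocks does not match blocks", call. = FALSE)
    return(Map(function(idx, M) {
      if (nrow(M) != length(idx))
        stop("covariance block size mismatch", call. = FALSE)
      list(idx = idx, M = as.matrix(M))
    }, idxs, G))
  }
  stop("G must be a matrix or a list of block matrices", call. = FALSE)
}

# Blockwise symmetric eigendecomposition of diag-scale * M * diag-scale.
block_eigen <- function(cb, scale = NULL) {
  lapply(cb, function(b) {
    M <- if (is.null(scale)) b$M else
      b$M * tcrossprod(scale[b$idx])
    e <- eigen(M, symmetric = TRUE)
    list(idx = b$idx, q = e$vectors, lambda = pmax(e$values, 0))
  })
}

# Rotate columns of X by t(Q) blockwise.
block_rotate <- function(eig, X) {
  out <- X
  for (b in eig) out[b$idx, ] <- crossprod(b$q, X[b$idx, , drop = FALSE])
  out
}

# Back-rotate: multiply by Q blockwise.
block_unrotate <- function(eig, v) {
  out <- v
  for (b in eig) out[b$idx] <- b$q %*% v[b$idx]
  out
}

# Blockwise G %*% v.
block_mult <- function(cb, v) {
  out <- v
  for (b in cb) out[b$idx] <- b$M %*% v[b$idx]
  out
}

# Restricted log-likelihood (up to constants) of the rotated linear model
# zs = Xs beta + eps, Var(eps_i) = s2 * lambda_i + phi, and the GLS
# estimate at that variance.
reml_gls <- function(zs, Xs, lambda, s2, phi = 1) {
  d <- s2 * lambda + phi
  w <- 1 / d
  XtWX <- crossprod(Xs, Xs * w)
  XtWz <- crossprod(Xs, zs * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(reml = -Inf))
  beta <- backsolve(ch, backsolve(ch, XtWz, transpose = TRUE))
  r <- zs - Xs %*% beta
  quad <- sum(r^2 * w)
  reml <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(ch))) + quad)
  list(reml = reml, beta = drop(beta), cov_beta = chol2inv(ch),
       resid = drop(r), w = w)
}

#' Logistic mixed model with a kinship random effect (PQL)
#'
#' Fits `logit P(y = 1) = X beta + b`, `b ~ N(0, sigma2_g * G)`, by
#' penalized quasi-likelihood: iterating (i) the working response from the
#' current linear predictor, (ii) a linear mixed-model solve for the fixed
#' effects and BLUPs, and (iii) a restricted-likelihood update of
#' `sigma2_g` on the working variates, until the largest absolute
#' parameter change falls below `tol`.
#'
#' @param y Binary outcome vector (0/1); both classes must be present.
#' @param X Fixed-effect design matrix (an intercept is *not* added).
#' @param G Symmetric positive-semidefinite relatedness matrix (`2 *`
#'   kinship): either a dense `n x n` matrix, or a list of per-family
#'   block matrices (then `blocks` is required), e.g. from
#'   [cohort_relationship()].
#' @param blocks Optional grouping vector (e.g. family ids) declaring G
#'   block-diagonal; exploited for speed.
#' @param sigma2g `NULL` to estimate the variance component (default), or a
#'   fixed non-negative value (e.g. from a covariates-only fit, to speed up
#'   a genome scan).
#' @param tol Convergence tolerance on parameter changes.
#' @param max_iter Iteration cap.
#' @return An object of class `glmm_fit`: `coefficients` (estimate, se, z,
#'   p per fixed effect), `sigma2g`, `logql` (restricted quasi-likelihood
#'   of the final working model), `converged`, `n_iter`, `separation`,
#'   `fitted_pop` (population-level probabilities, random effect at zero)
#'   and `fitted_cond` (conditional on the BLUPs).
#' @export
fit_logistic_mixed <- function(y, X, G, blocks = NULL, sigma2g = NULL,
                               tol = 1e-6, max_iter = 100L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: y has a single class", call. = FALSE)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("dimension mismatch between y and X", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("X is not of full column rank", call. = FALSE)
  cb <- cov_blocks(G, blocks, n)

  # initialize at the plain logistic fit
  fit0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit0$coefficients
  eta <- drop(X %*% beta)
  s2 <- if (is.null(sigma2g)) 0.1 else sigma2g
  estimate_s2 <- is.null(sigma2g)

  converged <- FALSE
  iter <- 0L
  gls <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    eig <- block_eigen(cb, scale = sw)    # W^(1/2) G W^(1/2), blockwise
    lambda <- numeric(n)
    for (b in eig) lambda[b$idx] <- b$lambda
    zs <- drop(block_rotate(eig, cbind(sw * z)))
    Xs <- block_rotate(eig, sw * X)

    if (estimate_s2) {
      opt <- stats::optimize(function(ls2)
        reml_gls(zs, Xs, lambda, exp(ls2))$reml,
        interval = c(-12, 6), maximum = TRUE, tol = 1e-8)
      s2_new <- exp(opt$maximum)
      if (s2_new < 1e-6) s2_new <- 0
    } else s2_new <- s2
    gls <- reml_gls(zs, Xs, lambda, s2_new)
    beta_new <- gls$beta

    # BLUP: b = s2 * G * V^{-1} (z - X beta), with V^{-1} applied in the
    # rotated space.
    vres <- sw * block_unrotate(eig, gls$resid * gls$w)
    b_hat <- s2_new * block_mult(cb, vres)
    eta_new <- drop(X %*% beta_new) + b_hat

    delta <- max(abs(c(beta_new - beta, s2_new - s2)))
    beta <- beta_new
    s2 <- s2_new
    eta <- eta_new
    if (delta < tol) { converged <- TRUE; break }
  }

  se <- sqrt(diag(gls$cov_beta))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  separation <- any(abs(beta) > 20)
  if (separation)
    warning("possible separation: |beta| > 20", call. = FALSE)
  coefs <- data.frame(
    term = if (!is.null(colnames(X))) colnames(X) else
      paste0("x", seq_along(beta)),
    estimate = unname(beta), se = unname(se), z = unname(zval),
    p = unname(pval), stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, sigma2g = s2, logql = gls$reml,
                 converged = converged, n_iter = iter,
                 separation = separation,
                 fitted_pop = stats::plogis(drop(X %*% beta)),
                 fitted_cond = stats::plogis(eta)),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic mixed model (PQL): sigma2_g = %.4f, %s in %d iterations\n",
    x$sigma2g, if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Linear mixed model with a kinship random effect (REML)
#'
#' Fits `y = X beta + g + e`, `g ~ N(0, sigma2_g * G)`,
#' `e ~ N(0, sigma2_e * I)` by restricted maximum likelihood, profiling the
#' residual variance and optimizing the variance ratio on the spectrum of G
#' (eigendecomposition once, blockwise across families).
#'
#' @inheritParams fit_logistic_mixed
#' @param y Quantitative outcome vector.
#' @return A list: `coefficients` (estimate, se, z, p), `sigma2g`,
#'   `sigma2e`, `reml`, `fitted` (fixed-effect part).
#' @export
fit_linear_mixed <- function(y, X, G, blocks = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("dimension mismatch", call. = FALSE)
  cb <- cov_blocks(G, blocks, n)
  eig <- block_eigen(cb)
  lambda <- numeric(n)
  for (b in eig) lambda[b$idx] <- b$lambda
  ys <- drop(block_rotate(eig, cbind(y)))
  Xs <- block_rotate(eig, X)
  p <- ncol(X)

  profile <- function(ldelta) {
    delta <- exp(ldelta)
    d <- delta * lambda + 1
    w <- 1 / d
    XtWX <- crossprod(Xs, Xs * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(reml = -Inf))
    beta <- backsolve(ch, backsolve(ch, crossprod(Xs, ys * w),
                                    transpose = TRUE))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 * w)
    s2e <- rss / (n - p)
    reml <- -0.5 * ((n - p) * log(s2e) + sum(log(d)) +
                      2 * sum(log(diag(ch))) + (n - p))
    list(reml = reml, beta = drop(beta), s2e = s2e,
         cov_beta = chol2inv(ch) * s2e, delta = delta)
  }
  opt <- stats::optimize(function(l) profile(l)$reml,
                         interval = c(-15, 15), maximum = TRUE, tol = 1e-9)
  # guard against a boundary optimum at delta ~ 0
  cand <- c(opt$maximum, -15)
  fits <- lapply(cand, profile)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "reml"))]]
  s2g <- best$delta * best$s2e
  if (best$delta <= exp(-14.5)) s2g <- 0
  beta <- best$beta
  se <- sqrt(diag(best$cov_beta))
  coefs <- data.frame(
    term = if (!is.null(colnames(X))) colnames(X) else
      paste0("x", seq_along(beta)),
    estimate = unname(beta), se = unname(se),
    z = unname(beta / se), p = unname(2 * stats::pnorm(-abs(beta / se))),
    stringsAsFactors = FALSE)
  list(coefficients = coefs, sigma2g = s2g, sigma2e = best$s2e,
       reml = best$reml, fitted = drop(X %*% beta))
}

#' Single-SNP association scan for obesity
#'
#' Fits one logistic mixed model per SNP with the additive allele count,
#' sex and age as fixed effects and the kinship random effect, and reports
#' the per-allele odds ratio with a two-sided Wald p-value. Missing
#' genotypes are mean-imputed to `2 * (counted-allele frequency)`;
#' monomorphic SNPs are skipped with a reason.
#'
#' @param cohort A `family_cohort` (typically the QC-filtered discovery
#'   partition).
#' @param alpha Significance level defining the reported significant set.
#' @param sigma2g_mode `"per_snp"` re-estimates the variance component in
#'   every SNP model; `"null_fixed"` estimates it once in the
#'   covariates-only model and holds it fixed across SNPs (much faster for
#'   large scans).
#' @return A data frame with one row per SNP: `snp_id`, `counted_allele`,
#'   `beta`, `se`, `or`, `p`, `freq_case`, `freq_control`, `converged`,
#'   `skipped`, plus attribute `significant` (snp ids with `p < alpha`).
#' @export
single_snp_scan <- function(cohort, alpha = 0.05,
                            sigma2g_mode = c("per_snp", "null_fixed")) {
  sigma2g_mode <- match.arg(sigma2g_mode)
  phen <- cohort$phenotypes
  rel <- cohort_relationship(cohort)
  y <- phen$obesity
  Xbase <- cbind(intercept = 1, sex = phen$sex - 1, age = phen$age)

  s2_fixed <- NULL
  if (sigma2g_mode == "null_fixed") {
    null_fit <- fit_logistic_mixed(y, Xbase, rel$G, blocks = rel$blocks)
    s2_fixed <- null_fit$sigma2g
  }

  rows <- lapply(seq_len(ncol(cohort$genotypes)), function(j) {
    g <- cohort$genotypes[, j]
    f <- compute_maf_callrate(g)$counted_freq
    out <- data.frame(snp_id = cohort$snp_meta$snp_id[j],
                      counted_allele = cohort$snp_meta$counted_allele[j],
                      beta = NA_real_, se = NA_real_, or = NA_real_,
                      p = NA_real_, freq_case = NA_real_,
                      freq_control = NA_real_, converged = NA,
                      skipped = "", stringsAsFactors = FALSE)
    if (is.na(f) || f == 0 || f == 1) {
      out$skipped <- if (is.na(f)) "all_missing" else "monomorphic"
      return(out)
    }
    g[is.na(g)] <- 2 * f
    out$freq_case <- mean(g[y == 1]) / 2
    out$freq_control <- mean(g[y == 0]) / 2
    fit <- withCallingHandlers(
      fit_logistic_mixed(y, cbind(Xbase, snp = g), rel$G,
                         blocks = rel$blocks, sigma2g = s2_fixed),
      warning = function(w) invokeRestart("muffleWarning"))
    k <- nrow(fit$coefficients)
    out$beta <- fit$coefficients$estimate[k]
    out$se <- fit$coefficients$se[k]
    out$or <- exp(out$beta)
    out$p <- fit$coefficients$p[k]
    out$converged <- fit$converged
    if (fit$separation) out$skipped <- "separation_warning"
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "significant") <- res$snp_id[!is.na(res$p) & res$p < alpha]
  attr(res, "alpha") <- alpha
  res
}
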