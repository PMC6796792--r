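#' Linear trend test of the score on obesity
#'
#' Logistic mixed model with sex, age and the continuous polygenic score
#' as fixed effects and the kinship random effect; `OR_trend` is the
#' exponentiated score coefficient, per unit of score by default or per
#' standard deviation of the score with `per_sd`.
#'
#' @param prs Numeric score vector.
#' @param obesity Binary outcome (0/1).
#' @param sex Sex coded 1/2 (male/female) or 0/1.
#' @param age Age in years.
#' @param G Relationship structure (dense matrix or per-family block list).
#' @param blocks Family grouping vector (required when G is a block list).
#' @param per_sd Report the odds ratio per score standard deviation.
#' @param conf_level Confidence level of the Wald interval.
#' @return A list: `or_trend`, `ci` (lower, upper), `p`, `beta`, `se`,
#'   `per`, `fit` (the underlying `glmm_fit`) and `model` description.
#' @export
trend_test <- function(prs, obesity, sex, age, G, blocks = NULL,
                       per_sd = FALSE, conf_level = 0.95) {
  x <- if (per_sd) prs / stats::sd(prs) else prs
  X <- cbind(intercept = 1, sex = sex - min(sex), age = age, prs = x)
  fit <- fit_logistic_mixed(obesity, X, G, blocks = blocks)
  k <- nrow(fit$coefficients)
  b <- fit$coefficients$estimate[k]
  se <- fit$coefficients$se[k]
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or_trend = exp(b), ci = exp(c(b - zc * se, b + zc * se)),
       p = fit$coefficients$p[k], beta = b, se = se,
       per = if (per_sd) "sd" else "unit", fit = fit,
       model = "obesity ~ sex + age + prs, random = kinship")
}

#' Quintile odds ratios against the lowest quintile
#'
#' Logistic mixed model with sex, age and four indicator contrasts for
#' quintiles Q2-Q5 versus Q1 as fixed effects and the kinship random
#' effect. Q1 is the reference with OR fixed at 1. A quintile with no
#' cases (or a separation-flagged fit) is marked non-estimable.
#'
#' @param quintiles Ordered factor from [assign_quintiles()].
#' @inheritParams trend_test
#' @return A data frame with one row per quintile: `quintile`, `or`,
#'   `ci_lower`, `ci_upper`, `p`, `estimable`.
#' @export
quintile_or_test <- function(quintiles, obesity, sex, age, G, blocks = NULL,
                             conf_level = 0.95) {
  if (sum(obesity == 1) < 1 || sum(obesity == 0) < 1)
    stop("need at least one case and one control", call. = FALSE)
  Q <- stats::model.matrix(~q, data.frame(q = factor(quintiles,
                                                     ordered = FALSE)))[, -1,
                                                                        drop = FALSE]
  colnames(Q) <- paste0("Q", 2:5)
  X <- cbind(intercept = 1, sex = sex - min(sex), age = age, Q)
  fit <- withCallingHandlers(
    fit_logistic_mixed(obesity, X, G, blocks = blocks),
    warning = function(w) invokeRestart("muffleWarning"))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  cases_per_q <- tapply(obesity, quintiles, sum)
  out <- data.frame(quintile = paste0("Q", 1:5), or = 1,
                    ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
                    estimable = TRUE, stringsAsFactors = FALSE)
  for (k in 2:5) {
    row <- match(paste0("Q", k), fit$coefficients$term)
    b <- fit$coefficients$estimate[row]
    se <- fit$coefficients$se[row]
    out$or[k] <- exp(b)
    out$ci_lower[k] <- exp(b - zc * se)
    out$ci_upper[k] <- exp(b + zc * se)
    out$p[k] <- fit$coefficients$p[row]
    out$estimable[k] <- is.finite(b) && abs(b) <= 20 &&
      cases_per_q[paste0("Q", k)] > 0
  }
  attr(out, "fit") <- fit
  attr(out, "separation") <- fit$separation
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted one half.
#'
#' @param pred Risk scores or probabilities.
#' @param y Binary outcome (0/1); both classes must be present.
#' @export
auc <- function(pred, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("AUC requires both classes", call. = FALSE)
  r <- rank(pred)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Resample indices; redraw (bounded) if a class is lost. family_ids
# non-NULL switches to family-block resampling.
boot_indices <- function(y, family_ids = NULL) {
  for (try in 1:100) {
    if (is.null(family_ids)) {
      idx <- sample.int(length(y), replace = TRUE)
    } else {
      fams <- unique(family_ids)
      pick <- sample(fams, length(fams), replace = TRUE)
      idx <- unlist(lapply(pick, function(f) which(family_ids == f)),
                    use.names = FALSE)
    }
    if (length(unique(y[idx])) == 2L) return(idx)
  }
  stop("could not draw a bootstrap resample with both classes",
       call. = FALSE)
}

# Fit a logistic risk model on data[predictors] and return a prediction
# closure (population-level probabilities). engine "glm" refits plain
# logistic regression (the population-level fixed effects; coherent with
# individual resampling, which breaks family structure anyway); "glmm"
# refits the kinship model and predicts with the random effect at zero.
risk_fitter <- function(data, outcome, predictors, engine = "glm",
                        G = NULL, blocks = NULL) {
  f <- stats::as.formula(paste(outcome, "~",
                               paste(predictors, collapse = " + ")))
  if (engine == "glm") {
    fit <- suppressWarnings(stats::glm(f, data = data,
                                       family = stats::binomial()))
    function(newdata)
      stats::predict(fit, newdata = newdata, type = "response")
  } else {
    X <- stats::model.matrix(f, data)
    fit <- fit_logistic_mixed(data[[outcome]], X, G, blocks = blocks)
    beta <- fit$coefficients$estimate
    function(newdata) {
      Xn <- stats::model.matrix(f, newdata)
      stats::plogis(drop(Xn %*% beta))
    }
  }
}

#' Optimism-corrected AUC by bootstrap
#'
#' Harrell-style optimism correction: the model is refit on each of `B`
#' bootstrap resamples; the optimism of a resample is the AUC of the
#' resample-fit on the resample minus its AUC on the original data, and
#' `auc_adj = apparent - mean(optimism)`. With `B = 0` no correction is
#' applied.
#'
#' @param data Data frame holding the outcome and predictor columns.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor column names.
#' @param B Number of bootstrap resamples (study default 1000).
#' @param seed Integer seed.
#' @param engine `"glm"` (default) or `"glmm"` (kinship refits; requires
#'   `G`/`blocks`).
#' @param family_ids Optional family vector switching to family-block
#'   resampling, the safer choice for related individuals.
#' @param G,blocks Passed to the `"glmm"` engine.
#' @return A list: `apparent`, `optimism`, `auc_adj`, `B`, and the
#'   bootstrap vectors `boot_apparent` / `boot_test` for reuse.
#' @export
auc_optimism <- function(data, outcome, predictors, B = 1000L, seed = 1L,
                         engine = c("glm", "glmm"), family_ids = NULL,
                         G = NULL, blocks = NULL) {
  engine <- match.arg(engine)
  if (engine == "glmm" && is.list(G))
    stop("the glmm engine requires a dense G matrix", call. = FALSE)
  set.seed(as.integer(seed))
  y <- data[[outcome]]
  pred0 <- risk_fitter(data, outcome, predictors, engine, G, blocks)(data)
  apparent <- auc(pred0, y)
  if (B == 0L)
    return(list(apparent = apparent, optimism = 0, auc_adj = apparent,
                B = 0L, boot_apparent = numeric(0), boot_test = numeric(0)))
  boot_app <- boot_test <- numeric(B)
  for (b in seq_len(B)) {
    idx <- boot_indices(y, family_ids)
    db <- data[idx, , drop = FALSE]
    predfun <- risk_fitter(db, outcome, predictors, engine,
                           if (engine == "glmm") G[idx, idx] else NULL,
                           if (!is.null(blocks)) blocks[idx] else NULL)
    boot_app[b] <- auc(predfun(db), db[[outcome]])
    boot_test[b] <- auc(predfun(data), y)
  }
  optimism <- mean(boot_app - boot_test)
  list(apparent = apparent, optimism = optimism,
       auc_adj = apparent - optimism, B = B,
       boot_apparent = boot_app, boot_test = boot_test)
}

#' Compare optimism-corrected AUCs of nested risk models
#'
#' Both models are refit on the same paired bootstrap resamples; the
#' difference in optimism-corrected AUC is reported with a bias-corrected
#' (BC, no acceleration) percentile confidence interval of the difference,
#' and flagged significant when that interval excludes zero.
#'
#' @inheritParams auc_optimism
#' @param predictors_base,predictors_full Predictor sets of the two models
#'   (typically covariates only versus covariates + score).
#' @param conf_level Confidence level of the interval.
#' @return A list: per-model `auc_adj`, `delta_auc_adj`, `ci_diff`,
#'   `significant`, `B`.
#' @export
compare_auc_adj <- function(data, outcome, predictors_base, predictors_full,
                            B = 1000L, seed = 1L, engine = c("glm", "glmm"),
                            family_ids = NULL, G = NULL, blocks = NULL,
                            conf_level = 0.95) {
  engine <- match.arg(engine)
  if (engine == "glmm" && is.list(G))
    stop("the glmm engine requires a dense G matrix", call. = FALSE)
  set.seed(as.integer(seed))
  y <- data[[outcome]]
  app <- vapply(list(predictors_base, predictors_full), function(p)
    auc(risk_fitter(data, outcome, p, engine, G, blocks)(data), y),
    numeric(1))
  boot <- matrix(NA_real_, B, 4L)  # app_base, test_base, app_full, test_full
  for (b in seq_len(B)) {
    idx <- boot_indices(y, family_ids)
    db <- data[idx, , drop = FALSE]
    Gb <- if (engine == "glmm" && !is.list(G)) G[idx, idx] else NULL
    blb <- if (!is.null(blocks)) blocks[idx] else NULL
    for (m in 1:2) {
      p <- list(predictors_base, predictors_full)[[m]]
      predfun <- risk_fitter(db, outcome, p, engine, Gb, blb)
      boot[b, 2 * m - 1] <- auc(predfun(db), db[[outcome]])
      boot[b, 2 * m] <- auc(predfun(data), y)
    }
  }
  adj <- c(app[1] - mean(boot[, 1] - boot[, 2]),
           app[2] - mean(boot[, 3] - boot[, 4]))
  delta <- adj[2] - adj[1]
  delta_boot <- boot[, 3] - boot[, 1]
  # bias-corrected percentile interval of the difference
  z0 <- stats::qnorm(pmin(pmax(mean(delta_boot < delta), 1 / (B + 1)),
                          B / (B + 1)))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  ci <- unname(stats::quantile(delta_boot, probs, type = 6))
  list(auc_adj_base = adj[1], auc_adj_full = adj[2],
       apparent_base = app[1], apparent_full = app[2],
       delta_auc_adj = delta, ci_diff = ci,
       significant = !(ci[1] <= 0 && ci[2] >= 0), B = B)
}

# point estimates of category-free NRI and IDI
nri_idi_point <- function(p_old, p_new, y) {
  ev <- y == 1
  up <- p_new > p_old
  down <- p_new < p_old
  nri_ev <- mean(up[ev]) - mean(down[ev])
  nri_ne <- mean(down[!ev]) - mean(up[!ev])
  idi <- (mean(p_new[ev]) - mean(p_old[ev])) -
    (mean(p_new[!ev]) - mean(p_old[!ev]))
  c(nri = nri_ev + nri_ne, idi = idi,
    event_up = mean(up[ev]), event_down = mean(down[ev]),
    nonevent_up = mean(up[!ev]), nonevent_down = mean(down[!ev]))
}

#' Net reclassification and integrated discrimination improvement
#'
#' Category-free (continuous) NRI: the net fraction of events whose
#' predicted risk rises under the new model plus the net fraction of
#' non-events whose risk falls. IDI: the change, between events and
#' non-events, in mean predicted risk. Confidence intervals are bootstrap
#' percentile intervals and p-values are two-sided normal tests on the
#' bootstrap standard error.
#'
#' @param p_old,p_new Predicted risks in `[0, 1]` under the two models.
#' @param y Binary outcome (0/1), both classes present.
#' @param B Bootstrap resamples for the intervals (0 for point estimates
#'   only).
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @return A list: `nri`, `nri_ci`, `nri_p`, `idi`, `idi_ci`, `idi_p`, and
#'   the event/non-event up/down fractions.
#' @export
nri_idi <- function(p_old, p_new, y, B = 1000L, seed = 1L,
                    conf_level = 0.95) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("NRI/IDI require both classes", call. = FALSE)
  if (any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1))
    stop("risks must lie in [0, 1]", call. = FALSE)
  pt <- nri_idi_point(p_old, p_new, y)
  out <- list(nri = unname(pt["nri"]), idi = unname(pt["idi"]),
              event_up = unname(pt["event_up"]),
              event_down = unname(pt["event_down"]),
              nonevent_up = unname(pt["nonevent_up"]),
              nonevent_down = unname(pt["nonevent_down"]),
              nri_ci = c(NA_real_, NA_real_), nri_p = NA_real_,
              idi_ci = c(NA_real_, NA_real_), idi_p = NA_real_, B = B)
  if (B > 0L) {
    set.seed(as.integer(seed))
    bs <- vapply(seq_len(B), function(b) {
      idx <- boot_indices(y)
      nri_idi_point(p_old[idx], p_new[idx], y[idx])[c("nri", "idi")]
    }, numeric(2))
    a <- (1 - conf_level) / 2
    out$nri_ci <- unname(stats::quantile(bs[1, ], c(a, 1 - a), type = 6))
    out$idi_ci <- unname(stats::quantile(bs[2, ], c(a, 1 - a), type = 6))
    out$nri_p <- 2 * stats::pnorm(-abs(out$nri / stats::sd(bs[1, ])))
    out$idi_p <- 2 * stats::pnorm(-abs(out$idi / stats::sd(bs[2, ])))
  }
  out
}

#' BMI variance explained by the polygenic score
#'
#' Linear mixed models of BMI on sex and age, with and without the score,
#' both with the kinship random effect. The variance explained is the drop
#' in unexplained (residual + polygenic random) variance when the score is
#' added, as a fraction of the total BMI variance. The squared partial
#' correlation implied by the score's Wald statistic is reported alongside
#' as an alternative definition.
#'
#' @param bmi Quantitative outcome (kg/m2).
#' @inheritParams trend_test
#' @return A list: `r2`, `r2_partial`, `beta_prs`, `p_prs`, and the two
#'   model fits.
#' @export
variance_explained <- function(bmi, prs, sex, age, G, blocks = NULL) {
  Xr <- cbind(intercept = 1, sex = sex - min(sex), age = age)
  Xf <- cbind(Xr, prs = prs)
  red <- fit_linear_mixed(bmi, Xr, G, blocks = blocks)
  full <- fit_linear_mixed(bmi, Xf, G, blocks = blocks)
  v_red <- red$sigma2g + red$sigma2e
  v_full <- full$sigma2g + full$sigma2e
  r2 <- min(max((v_red - v_full) / stats::var(bmi), 0), 1)
  k <- nrow(full$coefficients)
  tstat <- full$coefficients$z[k]
  df <- length(bmi) - ncol(Xf)
  list(r2 = r2, r2_partial = tstat^2 / (tstat^2 + df),
       beta_prs = full$coefficients$estimate[k],
       p_prs = full$coefficients$p[k],
       fit_full = full, fit_reduced = red,
       model = "bmi ~ sex + age (+ prs), random = kinship")
}
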