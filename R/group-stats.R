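# Group-level inference on the beta table: linear mixed-effects models with
# participant random intercepts, Benjamini-Hochberg FDR over the ROI
# family, one-sample t-tests on RT betas, BIC-approximate Bayes-factor
# model comparison, and voxelwise-within-ROI FDR tests.

# Reshape the item-regressor rows of a beta table for one ROI into the
# observation-level frame used by the mixed models: one row per
# (participant, run, condition, memory) cell.
roi_lme_frame <- function(beta_rows) {
  d <- beta_rows[beta_rows$regressor %in%
                 c("reward_remembered", "reward_forgotten",
                   "neutral_remembered", "neutral_forgotten"), , drop = FALSE]
  d$condition <- ifelse(grepl("^reward_", d$regressor), 1, 0)
  d$memory <- ifelse(grepl("_remembered$", d$regressor), 1, 0)
  d
}

#' Mixed-effects model of ROI betas (condition + memory)
#'
#' Fits `beta ~ condition + memory + (1 | participant)` by REML for one
#' ROI's item-regressor betas; reports fixed-effect estimates, the
#' standardized statistic (estimate / SE), and two-sided p-values from the
#' t distribution with Satterthwaite degrees of freedom, which stays
#' calibrated at small participant counts where the plain normal
#' approximation is anticonservative. A singular fit falls back to pooled
#' OLS (flagged in the output). With balanced data and zero
#' random-intercept variance the fixed effects equal the pooled OLS
#' estimates.
#'
#' @param beta_rows rows of a [fit_roi_glms()] beta table for one ROI.
#' @return data.frame with one row per effect (`condition`, `memory`):
#'   estimate, se, z (standardized statistic), df, p, n_participants,
#'   n_obs, singular flag.
#' @export
fit_lme <- function(beta_rows) {
  d <- roi_lme_frame(beta_rows)
  if (length(unique(d$participant)) < 2L)
    stop("need at least 2 participants", call. = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(beta ~ condition + memory + (1 | participant), data = d,
                   REML = TRUE)))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  eff <- c("condition", "memory")
  if (singular) {
    ols <- stats::lm(beta ~ condition + memory, data = d)
    co <- summary(ols)$coefficients
    est <- co[eff, "Estimate"]
    se <- co[eff, "Std. Error"]
    df <- rep(stats::df.residual(ols), 2)
  } else {
    co <- suppressMessages(summary(fit))$coefficients
    est <- co[eff, "Estimate"]
    se <- co[eff, "Std. Error"]
    df <- co[eff, "df"]
  }
  z <- ifelse(se > 0, est / se, 0)
  data.frame(roi = d$roi[1], effect = eff,
             estimate = unname(est), se = unname(se), z = unname(z),
             df = unname(df),
             p = 2 * stats::pt(-abs(unname(z)), unname(df)),
             n_participants = length(unique(d$participant)),
             n_obs = nrow(d), singular = singular,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR step-up procedure
#'
#' Rejects all hypotheses with p at or below p_(k), where k is the largest
#' i with p_(i) <= i*q/m; adjusted p-values use the standard monotone
#' transform (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with logical `reject` and numeric `p_adjusted`, in input
#'   order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value vector", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  ok <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  list(reject = reject, p_adjusted = stats::p.adjust(p_values, "BH"))
}

#' One-sample t-test of betas against zero
#'
#' @param betas numeric vector (e.g. per-participant RT-regressor betas).
#' @return list with `t`, `p`, `mean`, `n`, `degenerate`.
#' @export
one_sample_t <- function(betas) {
  if (length(betas) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(betas) == 0)
    return(list(t = if (all(betas == 0)) 0 else NA_real_, p = NA_real_,
                mean = mean(betas), n = length(betas), degenerate = TRUE))
  tt <- stats::t.test(betas)
  list(t = unname(tt$statistic), p = tt$p.value, mean = mean(betas),
       n = length(betas), degenerate = FALSE)
}

#' BIC-approximate Bayes-factor model comparison for one ROI
#'
#' Fits four candidate mixed models of the item betas by maximum
#' likelihood -- intercept-only, condition-only, memory-only, and
#' condition + memory, all with a participant random intercept -- and
#' approximates Bayes factors against the intercept-only model by
#' `BF = exp((BIC_0 - BIC_m) / 2)` (unit-information-prior approximation).
#'
#' @param beta_rows rows of a beta table for one ROI.
#' @return list of class `model_comparison`: `roi`, `bic` (named), `bf_10`
#'   (vs intercept-only), `preferred`.
#' @export
compare_models_bic <- function(beta_rows) {
  d <- roi_lme_frame(beta_rows)
  forms <- list(
    intercept_only = beta ~ 1 + (1 | participant),
    condition_only = beta ~ condition + (1 | participant),
    memory_only = beta ~ memory + (1 | participant),
    condition_memory = beta ~ condition + memory + (1 | participant)
  )
  bic <- vapply(forms, function(f) {
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, REML = FALSE))), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else stats::BIC(fit)
  }, numeric(1))
  bf <- exp((bic["intercept_only"] - bic) / 2)
  preferred <- names(bf)[which.max(bf)]
  structure(list(roi = d$roi[1], bic = bic, bf_10 = bf,
                 preferred = preferred),
            class = "model_comparison")
}

#' Group-level results across ROIs with FDR correction
#'
#' Runs [fit_lme()] per ROI and applies Benjamini-Hochberg FDR across the
#' ROI family separately for the condition and the memory effect.
#'
#' @param beta_table long beta table from [fit_roi_glms()].
#' @param q FDR level.
#' @return data.frame of per-ROI effects with `p_fdr` and `significant`.
#' @export
group_roi_stats <- function(beta_table, q = 0.05) {
  res <- do.call(rbind, lapply(split(beta_table, beta_table$roi), fit_lme))
  for (eff in unique(res$effect)) {
    i <- res$effect == eff
    adj <- fdr_bh(res$p[i], q)
    res$p_fdr[i] <- adj$p_adjusted
    res$significant[i] <- adj$reject
  }
  rownames(res) <- NULL
  res
}

#' Voxelwise GLM within one ROI with FDR over its voxels
#'
#' Fits the design to every voxel in the mask support (PSC-converted), takes
#' the t-test p-value of one contrast, and FDR-corrects across those voxels
#' only.
#'
#' @param bold4d 4D array.
#' @param mask a [prob_mask()] with at least 2 support voxels.
#' @param design design matrix (frames x regressors).
#' @param contrast named contrast weights over design columns (e.g.
#'   `c(reward_remembered = 1, reward_forgotten = -1)`).
#' @param q FDR level.
#' @return list with `significant_voxels` (linear indices into the grid),
#'   `p`, `p_adjusted`, `voxel_indices`.
#' @export
voxelwise_roi_fdr <- function(bold4d, mask, design, contrast, q = 0.05) {
  y <- if (is.list(bold4d)) bold4d$data else bold4d
  w <- as.vector(mask$data)
  idx <- which(w > 0)
  if (length(idx) < 2L)
    stop("mask support must contain at least 2 voxels", call. = FALSE)
  nt <- dim(y)[4]
  Y <- t(matrix(y, ncol = nt)[idx, , drop = FALSE])      # frames x voxels
  Y <- sweep(Y, 2, colMeans(Y), "/") * 100 - 100
  cw <- stats::setNames(rep(0, ncol(design)), colnames(design))
  cw[names(contrast)] <- contrast
  qr_ <- qr(design)
  B <- qr.coef(qr_, Y)
  B[is.na(B)] <- 0
  res <- Y - design %*% B
  dof <- nt - qr_$rank
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(design)))
  cvar <- as.numeric(t(cw) %*% xtx_inv %*% cw)
  tval <- as.vector(cw %*% B) / sqrt(cvar * sigma2)
  p <- 2 * stats::pt(-abs(tval), dof)
  adj <- fdr_bh(p, q)
  list(significant_voxels = idx[adj$reject], p = p,
       p_adjusted = adj$p_adjusted, voxel_indices = idx)
}
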