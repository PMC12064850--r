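# Ordinary-least-squares fitting, PPI regressor construction, and the
# per-run / per-ROI GLM driver producing the long beta table.

#' Psychophysiological-interaction regressors
#'
#' The seed timeseries is demeaned; the psychological indicator columns
#' (HRF-convolved condition and memory regressors) are mean-centered; the
#' interactions are their elementwise products with the demeaned seed. The
#' seed main effect is returned alongside.
#'
#' @param seed_series seed timeseries (PSC), vector or `bold_series`.
#' @param condition_indicator,memory_indicator HRF-convolved indicator
#'   columns.
#' @return matrix with columns `seed`, `ppi_condition`, `ppi_memory`.
#' @export
ppi_columns <- function(seed_series, condition_indicator, memory_indicator) {
  s <- if (inherits(seed_series, "bold_series")) seed_series$values
       else seed_series
  if (length(s) != length(condition_indicator) ||
      length(s) != length(memory_indicator))
    stop("lengths differ", call. = FALSE)
  sd_ <- s - mean(s)
  ci <- condition_indicator - mean(condition_indicator)
  mi <- memory_indicator - mean(memory_indicator)
  if (stats::sd(ci) == 0 || stats::sd(mi) == 0)
    warning("constant indicator: PPI column is proportional to the seed")
  cbind(seed = sd_, ppi_condition = sd_ * ci, ppi_memory = sd_ * mi)
}

#' Fit a timeseries GLM by ordinary least squares
#'
#' Minimizes ||y - X b||^2 via the QR decomposition; standard errors come
#' from the unscaled covariance (X'X)^-1 times the residual variance
#' ||r||^2 / dof. A rank-deficient design triggers a warning and a
#' minimum-norm (pivoted-QR) solution flagged in the result.
#'
#' @param X design matrix (frames x regressors) with column names.
#' @param y response vector (e.g. a PSC ROI timeseries) or `bold_series`.
#' @return list of class `glm_fit`: `beta`, `se`, `sigma2`, `dof`,
#'   `rank_deficient`, `residuals`.
#' @export
fit_ols <- function(X, y) {
  if (inherits(y, "bold_series")) y <- y$values
  stopifnot(nrow(X) == length(y))
  qr_ <- qr(X)
  rank_def <- qr_$rank < ncol(X)
  if (rank_def)
    warning("design is rank deficient; reporting a minimum-norm solution")
  beta <- qr.coef(qr_, y)
  beta[is.na(beta)] <- 0
  res <- y - X %*% beta
  dof <- length(y) - qr_$rank
  if (dof <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- sum(res^2) / dof
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  se <- if (is.null(xtx_inv)) rep(NA_real_, ncol(X))
        else sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  structure(list(beta = stats::setNames(as.vector(beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 sigma2 = sigma2, dof = dof, rank_deficient = rank_def,
                 residuals = as.vector(res)),
            class = "glm_fit")
}

# Build the design for one run of a synthetic dataset.
#   variant 1: 4 condition x memory item regressors (+ misclassified
#              nuisance when present) + number/outcome onsets + confounds
#   variant 2: variant 1 + z-scored confidence parametric modulator
#   variant 3: variant 1 + RT-duration regressor
build_run_design <- function(run, behavior_run, memory, config,
                             ventricle_series, variant = 1L,
                             hrf = double_gamma_hrf()) {
  ft <- run$frame_times
  X_task <- build_task_regressors(run$events, hrf, ft)
  extra <- NULL
  if (variant == 2L) {
    d <- behavior_run[behavior_run$item_response_correct, , drop = FALSE]
    conf <- memory$confidence[match(d$item_id, memory$item_id)]
    ev <- data.frame(onset_s = d$item_onset_s, duration_s = 2)
    extra <- add_parametric_modulator(ev, conf, hrf, ft)
    colnames(extra) <- "confidence_mod"
  } else if (variant == 3L) {
    ev <- data.frame(onset_s = behavior_run$item_onset_s,
                     rt_s = behavior_run$item_rt_s)
    extra <- build_rt_regressor(ev, hrf, ft)
  }
  nt <- length(ft)
  conf_block <- assemble_confounds(
    run$motion, framewise_displacement(run$motion), run$dvars %||% rep(0, nt),
    dct_basis(nt, 12L),
    retroicor_regressors(run$physio, ft),
    ventricle_series)
  X <- cbind(X_task, extra, conf_block)
  roles <- c(rep("task", ncol(X_task)),
             if (!is.null(extra)) rep("modulator", ncol(extra)),
             rep("confound", ncol(conf_block)))
  list(X = X, roles = stats::setNames(roles, colnames(X)), frame_times = ft)
}

#' Fit the per-run, per-ROI GLMs of a synthetic dataset
#'
#' Applies the run-exclusion rule (runs with more than 50% incorrectly
#' classified items are dropped), builds the requested GLM variant's
#' design per run (task regressors split by condition and subsequent
#' memory, a misclassified-item nuisance regressor when needed, the full
#' confound block, and for variant 2/3 the confidence modulator or the
#' RT-duration regressor), extracts each ROI's probability-weighted PSC
#' timeseries, and fits OLS.
#'
#' @param dataset a [make_dataset()] bundle with BOLD volumes.
#' @param masks named list of masks to analyze (defaults to the dataset's
#'   truth masks minus the fourth ventricle).
#' @param glm_variant 1, 2, or 3.
#' @param hrf HRF kernel.
#' @return list with `betas` (long data.frame: participant, run, roi,
#'   regressor, role, beta, se) and `exclusions`.
#' @export
fit_roi_glms <- function(dataset, masks = NULL, glm_variant = 1L,
                         hrf = double_gamma_hrf()) {
  config <- dataset$config
  if (is.null(masks)) {
    masks <- dataset$masks
    masks$fourth_ventricle <- NULL
  }
  rows <- list()
  exclusions <- list()
  for (pp in dataset$participants) {
    excl <- exclude_bad_runs(pp$behavior)
    if (length(excl$dropped_runs))
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        participant = pp$participant, run = excl$dropped_runs,
        reason = "more than 50% misclassified items")
    surviving <- setdiff(vapply(pp$runs, `[[`, 0L, "run_index"),
                         excl$dropped_runs)
    if (!length(surviving)) {
      message(sprintf("participant %d dropped: no surviving runs",
                      pp$participant))
      next
    }
    for (run in pp$runs) {
      if (!run$run_index %in% surviving) next
      beh <- pp$behavior[pp$behavior$run_index == run$run_index, ,
                         drop = FALSE]
      vent <- percent_signal_change(
        extract_weighted_ts(run$bold, dataset$masks$fourth_ventricle,
                            config$tr_s, run$run_index))
      run$dvars <- dvars(run$bold)
      des <- build_run_design(run, beh, pp$memory, config, vent,
                              glm_variant, hrf)
      for (roi in names(masks)) {
        series <- percent_signal_change(
          extract_weighted_ts(run$bold, masks[[roi]], config$tr_s,
                              run$run_index))
        fit <- fit_ols(des$X, series)
        keep <- des$roles != "confound"
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pp$participant, run = run$run_index, roi = roi,
          regressor = names(fit$beta)[keep],
          role = unname(des$roles[keep]),
          beta = unname(fit$beta[keep]), se = unname(fit$se[keep]),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(betas = if (length(rows)) do.call(rbind, rows) else NULL,
       exclusions = if (length(exclusions)) do.call(rbind, exclusions)
                    else NULL)
}

#' Fit PPI GLMs from a hippocampal seed to each AAS ROI
#'
#' The seed is the probability-weighted union of CA1, CA3, and DG. Per run,
#' the variant-1 design is augmented with the seed main effect and its
#' interactions with the (centered) condition and memory indicator columns;
#' the augmented model predicts each target ROI's timeseries.
#'
#' @param dataset a [make_dataset()] bundle with BOLD volumes.
#' @param target_rois ROIs to predict (default the six AAS nuclei).
#' @param hrf HRF kernel.
#' @return long data.frame of PPI betas (`ppi_condition`, `ppi_memory`,
#'   `seed`).
#' @export
fit_ppi_glms <- function(dataset,
                         target_rois = c("LC", "BF", "MRN", "DRN", "SN",
                                         "VTA"),
                         hrf = double_gamma_hrf()) {
  config <- dataset$config
  hip <- hippocampus_union_mask(dataset$masks)
  rows <- list()
  for (pp in dataset$participants) {
    excl <- exclude_bad_runs(pp$behavior)
    for (run in pp$runs) {
      if (run$run_index %in% excl$dropped_runs) next
      beh <- pp$behavior[pp$behavior$run_index == run$run_index, ,
                         drop = FALSE]
      vent <- percent_signal_change(
        extract_weighted_ts(run$bold, dataset$masks$fourth_ventricle,
                            config$tr_s, run$run_index))
      run$dvars <- dvars(run$bold)
      des <- build_run_design(run, beh, pp$memory, config, vent, 1L, hrf)
      seed <- percent_signal_change(
        extract_weighted_ts(run$bold, hip, config$tr_s, run$run_index))
      ind <- psych_indicators(des$X)
      # with sparse cells the two indicators can coincide (e.g. only
      # reward-remembered and neutral-forgotten items in a run); the PPI
      # contrast is then unidentifiable and the run is skipped
      if (stats::sd(ind$condition) == 0 || stats::sd(ind$memory) == 0 ||
          abs(stats::cor(ind$condition, ind$memory)) > 0.999) {
        message(sprintf(
          "participant %d run %d skipped for PPI: indicators collinear",
          pp$participant, run$run_index))
        next
      }
      Xp <- cbind(des$X, ppi_columns(seed, ind$condition, ind$memory))
      for (roi in target_rois) {
        series <- percent_signal_change(
          extract_weighted_ts(run$bold, dataset$masks[[roi]], config$tr_s,
                              run$run_index))
        fit <- fit_ols(Xp, series)
        keep <- c("seed", "ppi_condition", "ppi_memory")
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pp$participant, run = run$run_index, roi = roi,
          regressor = keep, beta = unname(fit$beta[keep]),
          se = unname(fit$se[keep]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# Condition and memory indicator columns from the fitted task columns:
# condition = reward items minus neutral items; memory = remembered minus
# forgotten (both from the HRF-convolved item regressors).
psych_indicators <- function(X) {
  pick <- function(patterns) {
    cols <- intersect(patterns, colnames(X))
    if (!length(cols)) return(rep(0, nrow(X)))
    rowSums(X[, cols, drop = FALSE])
  }
  list(
    condition = pick(c("reward_remembered", "reward_forgotten")) -
      pick(c("neutral_remembered", "neutral_forgotten")),
    memory = pick(c("reward_remembered", "neutral_remembered")) -
      pick(c("reward_forgotten", "neutral_forgotten"))
  )
}

#' Probability-weighted union of the hippocampal subfield masks
#'
#' @param masks named mask list containing CA1, CA3, DG.
#' @return a [prob_mask()] named "hippocampus" (voxelwise maximum weight).
#' @export
hippocampus_union_mask <- function(masks) {
  d <- pmax(masks$CA1$data, masks$CA3$data, masks$DG$data)
  prob_mask(d, masks$CA1$voxel_size_mm, "hippocampus")
}
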