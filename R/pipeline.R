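# End-to-end orchestration: generate -> segment -> extract -> GLM variants
# -> group statistics -> report, streaming participant by participant so a
# default-size synthetic study fits comfortably in memory.

#' Pipeline configuration
#'
#' @param synth a [synth_config()] (synthetic mode).
#' @param glm_variants which GLM variants to fit (subset of 1:3).
#' @param fdr_q FDR level over the ROI family.
#' @param roi_names ROIs analyzed at group level (default the study's 10).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), glm_variants = c(1L, 3L),
                            fdr_q = 0.05,
                            roi_names = c("LC", "BF", "MRN", "DRN", "SN",
                                          "VTA", "striatum", "CA1", "CA3",
                                          "DG")) {
  if (fdr_q <= 0 || fdr_q >= 1) stop("`fdr_q` must lie in (0, 1)")
  if (!length(roi_names)) stop("ROI list must be non-empty")
  structure(list(synth = synth, glm_variants = glm_variants, fdr_q = fdr_q,
                 roi_names = roi_names),
            class = "pipeline_config")
}

#' Run the full synthetic-mode pipeline
#'
#' Stages: (1) generate masks, the published-prior-style LC mask, and the
#' MT-like anatomical volume; (2) segment the LC from the MT image and
#' resolve LC / fourth-ventricle overlap; (3) per participant, simulate
#' behavior, physiology, and BOLD, extract probability-weighted PSC
#' timeseries, and fit the requested GLM variants plus the
#' hippocampus-seeded PPI model; (4) group statistics: mixed-effects
#' condition and memory effects with FDR over the ROI family, one-sample
#' t-tests on RT betas (variant 3), BIC-approximate model comparison per
#' ROI, and PPI group tests; (5) recovery diagnostics against the
#' generator's ground truth.
#'
#' @param config a [pipeline_config()].
#' @param seed optional master seed overriding `config$synth$seed`.
#' @param quiet suppress stage messages.
#' @return list of class `pipeline_result`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         quiet = TRUE) {
  sc <- config$synth
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage 1/5: masks, prior, MT image")
  masks_truth <- make_masks(sc)
  lc_prior <- make_lc_prior(sc, masks_truth$LC)
  mt <- make_mt_image(sc, masks_truth$LC, masks_truth$fourth_ventricle,
                      seed = substream_seed(sc$seed, 101L))

  say("stage 2/5: LC segmentation and overlap resolution")
  lc_seg <- segment_lc(mt, lc_prior)
  ov <- resolve_overlap(lc_seg, masks_truth$fourth_ventricle)
  masks_analysis <- masks_truth
  masks_analysis$LC <- ov$a
  masks_analysis$fourth_ventricle <- ov$b

  say("stage 3/5: per-participant simulation, extraction, GLMs")
  run_dur <- sc$n_vols_per_run * sc$tr_s
  betas <- list(); ppi <- list(); behavior <- list(); exclusions <- list()
  for (p in seq_len(sc$n_participants)) {
    pp <- simulate_participant(sc, masks_truth, p, run_dur)
    behavior[[p]] <- pp$behavior
    mini <- structure(list(config = sc, masks = masks_analysis,
                           participants = list(pp)),
                      class = "synth_dataset")
    for (v in config$glm_variants) {
      fr <- fit_roi_glms(mini, masks_analysis[config$roi_names],
                         glm_variant = v)
      if (!is.null(fr$betas)) {
        fr$betas$variant <- v
        betas[[length(betas) + 1L]] <- fr$betas
      }
      if (!is.null(fr$exclusions) && v == config$glm_variants[1])
        exclusions[[length(exclusions) + 1L]] <- fr$exclusions
    }
    ppi_p <- fit_ppi_glms(mini)
    if (!is.null(ppi_p)) ppi[[length(ppi) + 1L]] <- ppi_p
    rm(pp, mini); gc(FALSE)
  }
  beta_table <- do.call(rbind, betas)
  ppi_table <- if (length(ppi)) do.call(rbind, ppi) else NULL

  say("stage 4/5: group statistics")
  v1 <- beta_table[beta_table$variant == 1L, , drop = FALSE]
  group <- group_roi_stats(v1, config$fdr_q)
  model_cmp <- lapply(split(v1, v1$roi), compare_models_bic)
  rt_tests <- NULL
  if (3L %in% config$glm_variants) {
    v3 <- beta_table[beta_table$variant == 3L &
                     beta_table$regressor == "rt_duration", , drop = FALSE]
    rt_tests <- do.call(rbind, lapply(split(v3, v3$roi), function(d) {
      per_part <- tapply(d$beta, d$participant, mean)
      tt <- one_sample_t(as.numeric(per_part))
      data.frame(roi = d$roi[1], mean_beta = tt$mean, t = tt$t, p = tt$p,
                 n = tt$n, stringsAsFactors = FALSE)
    }))
    if (!is.null(rt_tests)) {
      adj <- fdr_bh(rt_tests$p, config$fdr_q)
      rt_tests$p_fdr <- adj$p_adjusted
      rt_tests$significant <- adj$reject
      rownames(rt_tests) <- NULL
    }
  }
  ppi_tests <- NULL
  if (!is.null(ppi_table)) {
    cells <- split(ppi_table,
                   list(ppi_table$roi, ppi_table$regressor), drop = TRUE)
    ppi_tests <- do.call(rbind, lapply(cells, function(d) {
      per_part <- tapply(d$beta, d$participant, mean)
      tt <- one_sample_t(as.numeric(per_part))
      data.frame(roi = d$roi[1], regressor = d$regressor[1],
                 mean_beta = tt$mean, t = tt$t, p = tt$p,
                 stringsAsFactors = FALSE)
    }))
    rownames(ppi_tests) <- NULL
  }
  beh_all <- do.call(rbind, behavior)
  beh_summary <- summarize_behavior(beh_all)

  say("stage 5/5: recovery diagnostics")
  sig_cond <- group$roi[group$effect == "condition" & group$significant]
  sig_mem <- group$roi[group$effect == "memory" & group$significant]
  diagnostics <- list(
    significant_condition_rois = sig_cond,
    significant_memory_rois = sig_mem,
    truth_condition_rois = sc$condition_rois,
    truth_memory_rois = sc$memory_rois,
    condition_recovered = setdiff(sc$condition_rois, sig_cond),
    memory_false_positives = setdiff(sig_mem, sc$memory_rois))

  structure(list(config = config, seed = sc$seed, group = group,
                 model_comparison = model_cmp, rt_tests = rt_tests,
                 ppi_tests = ppi_tests, beta_table = beta_table,
                 behavior_summary = beh_summary,
                 exclusions = if (length(exclusions))
                   do.call(rbind, exclusions) else NULL,
                 lc_segmentation = list(mask = masks_analysis$LC,
                                        n_overlap_resolved = ov$n_overlap),
                 diagnostics = diagnostics),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %d, %d participants\n", x$seed,
              x$config$synth$n_participants))
  cat("FDR-significant condition effects:",
      paste(x$diagnostics$significant_condition_rois, collapse = ", "), "\n")
  cat("FDR-significant memory effects:",
      paste(x$diagnostics$significant_memory_rois, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a synthetic (or loaded) dataset bundle
#'
#' Structural checks that report problems instead of raising: mask values
#' in [0, 1], grids consistent with the config, positive TR, event onsets
#' within the run, physiological traces covering the run, finite BOLD
#' values.
#'
#' @param dataset a [make_dataset()] bundle.
#' @return data.frame with `where` and `problem` (zero rows when valid).
#' @export
validate_inputs <- function(dataset) {
  problems <- list()
  note <- function(where, problem)
    problems[[length(problems) + 1L]] <<- data.frame(
      where = where, problem = problem, stringsAsFactors = FALSE)
  cfg <- dataset$config
  if (cfg$tr_s <= 0) note("config", "non-positive TR")
  run_dur <- cfg$n_vols_per_run * cfg$tr_s
  for (nm in names(dataset$masks)) {
    m <- dataset$masks[[nm]]$data
    if (any(m < 0 | m > 1))
      note(paste0("mask:", nm), "values outside [0, 1]")
    if (!identical(dim(m), cfg$grid_shape))
      note(paste0("mask:", nm), "grid does not match config")
  }
  for (pp in dataset$participants) {
    pid <- paste0("participant:", pp$participant)
    for (run in pp$runs) {
      rid <- sprintf("%s run:%d", pid, run$run_index)
      if (any(run$events$onset_s > run_dur))
        note(rid, "event onset beyond run duration")
      if (run$physio$duration_s < run_dur)
        note(rid, "physiological trace shorter than run")
      if (!is.null(run$bold) && any(!is.finite(run$bold)))
        note(rid, "non-finite BOLD values")
      if (!is.null(run$bold) &&
          !identical(dim(run$bold)[1:3], cfg$grid_shape))
        note(rid, "BOLD grid does not match config")
    }
  }
  if (length(problems)) do.call(rbind, problems)
  else data.frame(where = character(), problem = character())
}
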