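# Synthetic study generator: probabilistic ROI masks, an MT-weighted-like
# anatomical volume with a hyperintense LC next to bright CSF, physiological
# traces, 4D BOLD with known injected effects, and full multi-participant
# bundles. Every generator is a pure function of (config, seed).

#' Construct a probabilistic mask
#'
#' @param data 3D array of membership weights in [0, 1].
#' @param voxel_size_mm voxel spacing per axis (length 3).
#' @param name region name.
#' @return object of class `prob_mask`.
#' @export
prob_mask <- function(data, voxel_size_mm, name = "roi") {
  stopifnot(length(dim(data)) == 3L, length(voxel_size_mm) == 3L)
  if (any(!is.finite(data)) || any(data < 0) || any(data > 1))
    stop("mask values must be finite and in [0, 1]", call. = FALSE)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 name = name), class = "prob_mask")
}

#' @export
print.prob_mask <- function(x, ...) {
  cat(sprintf("<prob_mask '%s'> %s voxels @ %s mm, support %d voxels\n",
              x$name, paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              sum(x$data > 0)))
  invisible(x)
}

#' Default ROI geometry for the synthetic brain
#'
#' Ten regions of interest (the six ascending-arousal-system nuclei LC, BF,
#' MRN, DRN, SN, VTA plus striatum and hippocampal subfields CA1, CA3, DG)
#' and the fourth ventricle, as spheres on the default grid. The LC and
#' fourth ventricle are placed close enough that their probabilistic
#' supports overlap, exercising the overlap-resolution step.
#'
#' @return data.frame with `name`, voxel-center coordinates `cx, cy, cz`
#'   (1-based), `radius_mm`, and `laterality`.
#' @export
default_roi_spec <- function() {
  data.frame(
    name = c("LC", "fourth_ventricle", "MRN", "DRN", "BF", "SN", "VTA",
             "striatum", "CA1", "CA3", "DG"),
    cx = c(20, 20, 20, 28, 20, 14, 26, 8, 8, 14, 8),
    cy = c(26, 22, 14, 30, 8, 14, 14, 8, 30, 34, 22),
    cz = c(8, 8, 8, 14, 20, 14, 14, 20, 20, 20, 24),
    radius_mm = c(3, 4.5, 3, 3, 4.5, 4.5, 4.5, 6, 4.5, 4.5, 4.5),
    laterality = "midline",
    stringsAsFactors = FALSE
  )
}

#' Synthetic study configuration
#'
#' Defaults describe a desk-scale study: a 40 x 40 x 30 grid of 1.5 mm
#' voxels, TR 1.38 s, 2 runs of 120 volumes, 8 participants, and 10 MID
#' trials per run (the most that fit a 165.6 s run at the task's ITI
#' distribution). True effects are injected in percent-signal-change (PSC)
#' units: a reward-vs-neutral condition effect in the six AAS nuclei plus
#' striatum, CA1 and DG, and a remembered-vs-forgotten memory effect in
#' CA1 and CA3 only.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size_mm spacing per axis (mm).
#' @param tr_s repetition time (s).
#' @param n_vols_per_run,n_runs,n_participants study size.
#' @param trials_per_run MID trials per run (even).
#' @param roi_spec data.frame as from [default_roi_spec()].
#' @param condition_effect_psc,memory_effect_psc injected effect sizes (PSC).
#' @param condition_rois,memory_rois which ROIs carry each effect.
#' @param noise_sd_psc voxelwise white-noise SD (PSC).
#' @param drift_amp_psc low-frequency drift amplitude (PSC).
#' @param physio_amp_psc physiological signal amplitude (PSC).
#' @param baseline BOLD baseline intensity (arbitrary units).
#' @param heart_rate_bpm,resp_rate_hz,physio_jitter physiological trace
#'   parameters.
#' @param seed master integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(40L, 40L, 30L),
                         voxel_size_mm = c(1.5, 1.5, 1.5),
                         tr_s = 1.38,
                         n_vols_per_run = 120L, n_runs = 2L,
                         n_participants = 8L,
                         trials_per_run = 10L,
                         roi_spec = default_roi_spec(),
                         condition_effect_psc = 0.4,
                         memory_effect_psc = 0.4,
                         condition_rois = c("LC", "BF", "MRN", "DRN", "SN",
                                            "VTA", "striatum", "CA1", "DG"),
                         memory_rois = c("CA1", "CA3"),
                         noise_sd_psc = 1.0,
                         drift_amp_psc = 1.0,
                         physio_amp_psc = 0.5,
                         baseline = 1000,
                         heart_rate_bpm = 65, resp_rate_hz = 0.25,
                         physio_jitter = 0.05,
                         seed = 1L) {
  stopifnot_scalar_pos(tr_s, "tr_s")
  if (noise_sd_psc < 0) stop("`noise_sd_psc` must be >= 0", call. = FALSE)
  if (any(roi_spec$radius_mm <= 0)) stop("all ROI radii must be positive")
  rad_vox <- roi_spec$radius_mm / min(voxel_size_mm)
  inside <- roi_spec$cx - rad_vox >= 1 & roi_spec$cx + rad_vox <= grid_shape[1] &
    roi_spec$cy - rad_vox >= 1 & roi_spec$cy + rad_vox <= grid_shape[2] &
    roi_spec$cz - rad_vox >= 1 & roi_spec$cz + rad_vox <= grid_shape[3]
  if (!all(inside))
    stop(sprintf("ROI(s) outside grid: %s",
                 paste(roi_spec$name[!inside], collapse = ", ")), call. = FALSE)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm), tr_s = tr_s,
              n_vols_per_run = as.integer(n_vols_per_run),
              n_runs = as.integer(n_runs),
              n_participants = as.integer(n_participants),
              trials_per_run = as.integer(trials_per_run),
              roi_spec = roi_spec,
              condition_effect_psc = condition_effect_psc,
              memory_effect_psc = memory_effect_psc,
              condition_rois = condition_rois, memory_rois = memory_rois,
              noise_sd_psc = noise_sd_psc, drift_amp_psc = drift_amp_psc,
              physio_amp_psc = physio_amp_psc, baseline = baseline,
              heart_rate_bpm = heart_rate_bpm, resp_rate_hz = resp_rate_hz,
              physio_jitter = physio_jitter,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Generate probabilistic ROI masks
#'
#' Each mask is 1 at the ROI center and decays as a Gaussian with
#' sigma = radius/2 (in mm), truncated to 0 beyond the stated radius.
#'
#' @param config a [synth_config()].
#' @return named list of [prob_mask()] objects.
#' @export
make_masks <- function(config) {
  spec <- config$roi_spec
  required <- c("LC", "BF", "MRN", "DRN", "SN", "VTA", "striatum",
                "CA1", "CA3", "DG", "fourth_ventricle")
  missing <- setdiff(required, spec$name)
  if (length(missing))
    stop(sprintf("roi_spec lacks required ROI(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  gs <- config$grid_shape
  vs <- config$voxel_size_mm
  xs <- (seq_len(gs[1]) - 1) * vs[1]
  ys <- (seq_len(gs[2]) - 1) * vs[2]
  zs <- (seq_len(gs[3]) - 1) * vs[3]
  masks <- list()
  for (i in seq_len(nrow(spec))) {
    ctr <- c((spec$cx[i] - 1) * vs[1], (spec$cy[i] - 1) * vs[2],
             (spec$cz[i] - 1) * vs[3])
    r <- spec$radius_mm[i]
    sigma <- r / 2
    d2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"),
                (zs - ctr[3])^2, "+")
    w <- exp(-d2 / (2 * sigma^2))
    w[d2 > r^2] <- 0
    masks[[spec$name[i]]] <- prob_mask(w, vs, spec$name[i])
  }
  masks
}

#' Generate an MT-weighted-like anatomical volume
#'
#' A flat background plus a hyperintense LC-like nucleus and a brighter
#' CSF compartment (so the mu + 3 sigma cutoff of the segmentation is
#' exercised), with additive Gaussian noise.
#'
#' @param config a [synth_config()].
#' @param lc_truth,csf_truth [prob_mask()] objects on the config grid.
#' @param mu_bg background intensity.
#' @param lc_offset,csf_offset intensity raises for LC and CSF.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return list with `data` (3D array) and `voxel_size_mm`.
#' @export
make_mt_image <- function(config, lc_truth, csf_truth, mu_bg = 100,
                          lc_offset = 30, csf_offset = 120, noise_sd = 3,
                          seed = 1L) {
  if (!identical(dim(lc_truth$data), dim(csf_truth$data)) ||
      !identical(dim(lc_truth$data), config$grid_shape))
    stop("mask grids do not match the config grid", call. = FALSE)
  with_seed(seed, {
    img <- array(mu_bg, dim = config$grid_shape) +
      lc_offset * lc_truth$data + csf_offset * csf_truth$data
    if (noise_sd > 0)
      img <- img + array(stats::rnorm(prod(config$grid_shape), 0, noise_sd),
                         dim = config$grid_shape)
    list(data = img, voxel_size_mm = config$voxel_size_mm)
  })
}

#' Generate quasi-periodic cardiac and respiratory traces
#'
#' Cycle lengths are jittered multiplicatively (Gaussian, truncated at
#' +/- 3 jitter); within each cycle the signal is a raised cosine, so each
#' cardiac cycle carries exactly one local maximum above half amplitude.
#'
#' @param duration_s trace duration (s).
#' @param heart_rate_bpm mean heart rate (beats/min).
#' @param resp_rate_hz mean respiration rate (Hz).
#' @param jitter relative SD of cycle length.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param seed integer seed.
#' @return list of class `physio_trace` with `time_s`, `cardiac`,
#'   `respiratory`, `sampling_rate_hz`, `duration_s`.
#' @export
make_physio <- function(duration_s, heart_rate_bpm = 65, resp_rate_hz = 0.25,
                        jitter = 0.05, sampling_rate_hz = 50, seed = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  stopifnot_scalar_pos(heart_rate_bpm, "heart_rate_bpm")
  stopifnot_scalar_pos(resp_rate_hz, "resp_rate_hz")
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  with_seed(seed, {
    tt <- seq(0, duration_s, by = 1 / sampling_rate_hz)
    phase_of <- function(mean_cycle_s) {
      n_cyc <- ceiling(duration_s / mean_cycle_s) + 2L
      mult <- 1 + pmax(pmin(stats::rnorm(n_cyc, 0, jitter), 3 * jitter),
                       -3 * jitter)
      lens <- mean_cycle_s * mult
      bounds <- c(0, cumsum(lens))
      idx <- findInterval(tt, bounds, rightmost.closed = TRUE)
      2 * pi * (tt - bounds[idx]) / lens[idx]
    }
    cardiac <- -cos(phase_of(60 / heart_rate_bpm))
    respiratory <- -cos(phase_of(1 / resp_rate_hz))
    structure(list(time_s = tt, cardiac = cardiac, respiratory = respiratory,
                   sampling_rate_hz = sampling_rate_hz,
                   duration_s = duration_s),
              class = "physio_trace")
  })
}

#' Generate a 4D BOLD run with known injected effects
#'
#' Forward model per voxel v and volume t:
#' \deqn{y_v(t) = B (1 + [\sum_k w_{v,roi(k)} \beta_k x_k(t) + drift(t) +
#'   physio(t)]/100) + \epsilon_v(t)}
#' where `x_k` are HRF-convolved task regressors in PSC units, `w` the
#' voxel's mask weight, `B` the baseline, drift a random combination of the
#' first 3 DCT components, physio a scaled copy of the cardiac/respiratory
#' traces resampled at frame times, and epsilon white Gaussian noise.
#'
#' @param config a [synth_config()].
#' @param masks named list of [prob_mask()] from [make_masks()].
#' @param design_truth list with `frame_times` and matrix `X` of
#'   HRF-convolved task columns (PSC units).
#' @param effect_psc named list: `effect_psc[[roi]][[column]]` -> true beta.
#' @param physio optional [make_physio()] trace for the physio component.
#' @param seed integer seed.
#' @return list with `bold` (4D array), `truth` (long data.frame of true
#'   betas), `drift`, `physio_frames`.
#' @export
make_bold <- function(config, masks, design_truth, effect_psc,
                      physio = NULL, seed = 1L) {
  X <- design_truth$X
  nt <- config$n_vols_per_run
  if (nrow(X) != nt)
    stop("design length does not match n_vols_per_run", call. = FALSE)
  gs <- config$grid_shape
  nv <- prod(gs)
  B <- config$baseline
  with_seed(seed, {
    # per-voxel task signal, restricted to voxels with any ROI weight
    sig <- matrix(0, nrow = nv, ncol = nt)
    truth <- list()
    for (roi in names(effect_psc)) {
      betas <- effect_psc[[roi]]
      w <- as.vector(masks[[roi]]$data)
      idx <- which(w > 0)
      if (!length(idx)) next
      for (colname in names(betas)) {
        b <- betas[[colname]]
        if (b == 0) next
        sig[idx, ] <- sig[idx, ] +
          outer(w[idx], b * X[, colname])
        truth[[length(truth) + 1L]] <- data.frame(
          roi = roi, regressor = colname, beta_psc = b,
          stringsAsFactors = FALSE)
      }
    }
    drift <- if (config$drift_amp_psc > 0) {
      dct <- dct_basis(nt, 3L)
      comps <- sweep(dct, 2, apply(abs(dct), 2, max), "/")
      as.vector(comps %*% stats::rnorm(3L, 0, config$drift_amp_psc / 2))
    } else rep(0, nt)
    physio_frames <- if (!is.null(physio) && config$physio_amp_psc > 0) {
      ft <- design_truth$frame_times
      config$physio_amp_psc *
        (0.5 * stats::approx(physio$time_s, physio$cardiac, ft, rule = 2)$y +
         0.5 * stats::approx(physio$time_s, physio$respiratory, ft,
                             rule = 2)$y)
    } else rep(0, nt)
    shared <- drift + physio_frames
    y <- B * (1 + sweep(sig, 2, shared, "+") / 100)
    if (config$noise_sd_psc > 0)
      y <- y + matrix(stats::rnorm(nv * nt, 0, config$noise_sd_psc / 100 * B),
                      nrow = nv)
    list(bold = array(y, dim = c(gs, nt)),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(roi = character(), regressor = character(),
                      beta_psc = numeric()),
         drift = drift, physio_frames = physio_frames)
  })
}

# Published-prior-style LC mask: the true LC weight map shifted by one voxel
# (imperfect registration) and renormalized -- a synthetic stand-in for a
# published probabilistic atlas.
make_lc_prior <- function(config, lc_truth) {
  d <- lc_truth$data
  shifted <- array(0, dim = dim(d))
  shifted[, seq_len(dim(d)[2] - 1L), ] <- d[, -1L, ]
  prior <- pmax(d * 0.5 + shifted * 0.5, 0)
  prob_mask(prior / max(prior), config$voxel_size_mm, "LC_prior")
}

#' Acquisition frame times for a run
#'
#' Volume v (0-based) is referenced to t = v * TR + TR/2, the middle of its
#' acquisition window (matching slice-time correction to half the TR).
#'
#' @param n_vols number of volumes.
#' @param tr_s repetition time (s).
#' @return numeric vector of frame times (s).
#' @export
frame_times <- function(n_vols, tr_s) (seq_len(n_vols) - 1) * tr_s + tr_s / 2

#' Generate a complete multi-participant synthetic study
#'
#' For each participant: an MID schedule sized to the run length, a
#' simulated agent, a delayed recognition test, physiological traces,
#' motion parameters (slow random walk), and per-run 4D BOLD volumes whose
#' ROI responses carry the configured condition and memory effects. The
#' condition effect is injected in all four item regressors of reward
#' trials; the memory effect in the remembered regressors of both
#' conditions. Shared across participants: the truth masks, a
#' published-prior-style LC mask, and the MT-like anatomical volume.
#'
#' @param config a [synth_config()].
#' @param keep_bold keep the 4D arrays in the bundle (set `FALSE` to
#'   retain only ROI-level ground truth and save memory).
#' @return list of class `synth_dataset`.
#' @export
make_dataset <- function(config, keep_bold = TRUE) {
  masks <- make_masks(config)
  lc_prior <- make_lc_prior(config, masks$LC)
  mt <- make_mt_image(config, masks$LC, masks$fourth_ventricle,
                      seed = substream_seed(config$seed, 101L))
  run_dur <- config$n_vols_per_run * config$tr_s
  participants <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    participants[[p]] <- simulate_participant(config, masks, p, run_dur)
    if (!keep_bold)
      for (r in seq_along(participants[[p]]$runs))
        participants[[p]]$runs[[r]]$bold <- NULL
  }
  structure(list(
    config = config, masks = masks, lc_prior = lc_prior, mt_image = mt,
    participants = participants,
    ground_truth = list(condition_rois = config$condition_rois,
                        memory_rois = config$memory_rois,
                        condition_effect_psc = config$condition_effect_psc,
                        memory_effect_psc = config$memory_effect_psc)),
    class = "synth_dataset")
}

# One participant: behavior, memory test, and per-run physio/motion/BOLD.
simulate_participant <- function(config, masks, p, run_dur) {
  sched <- generate_schedule(
    n_runs = config$n_runs, trials_per_run = config$trials_per_run,
    seed = substream_seed(config$seed, p, 1L),
    iti_mean_s = 5, iti_lo_s = 2, iti_hi_s = 11)
  # re-sample any schedule whose events spill past the run (rare at defaults)
  tries <- 0L
  while (max(sched$outcome_onset_s) > run_dur - 15 && tries < 20L) {
    tries <- tries + 1L
    sched <- generate_schedule(
      n_runs = config$n_runs, trials_per_run = config$trials_per_run,
      seed = substream_seed(config$seed, p, 1L, 900L + tries),
      iti_mean_s = 5, iti_lo_s = 2, iti_hi_s = 11)
  }
  if (max(sched$outcome_onset_s) > run_dur - 10)
    stop("schedule does not fit the run: reduce trials_per_run", call. = FALSE)
  behavior <- simulate_agent(sched, seed = substream_seed(config$seed, p, 2L))
  behavior$participant <- p
  memory <- simulate_memory_test(behavior,
                                 seed = substream_seed(config$seed, p, 3L))
  remembered_ids <- memory$item_id[memory$truth == "old" &
                                   memory$response == "old"]
  behavior$remembered <- behavior$item_id %in% remembered_ids
  ft <- frame_times(config$n_vols_per_run, config$tr_s)
  hrf <- double_gamma_hrf()
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    run0 <- r - 1L
    d <- behavior[behavior$run_index == run0, , drop = FALSE]
    events <- mid_event_table(d)
    X <- build_task_regressors(events, hrf, ft)
    eff <- truth_effects(config, colnames(X))
    physio <- make_physio(run_dur + 5, config$heart_rate_bpm,
                          config$resp_rate_hz, config$physio_jitter,
                          seed = substream_seed(config$seed, p, r, 4L))
    motion <- make_motion_params(config$n_vols_per_run,
                                 seed = substream_seed(config$seed, p, r, 5L))
    bold <- make_bold(config, masks, list(frame_times = ft, X = X), eff,
                      physio = physio,
                      seed = substream_seed(config$seed, p, r, 6L))
    runs[[r]] <- list(run_index = run0, bold = bold$bold, events = events,
                      physio = physio, motion = motion,
                      truth_betas = bold$truth, frame_times = ft)
  }
  list(participant = p, behavior = behavior, memory = memory, runs = runs)
}

# MID events for one run: item regressors split condition x subsequent
# memory (misclassified items set aside as a nuisance event type), plus
# number and outcome onsets.
mid_event_table <- function(run_records) {
  d <- run_records
  item_type <- ifelse(!d$item_response_correct, "misclassified",
                      paste0(d$condition, "_",
                             ifelse(d$remembered, "remembered", "forgotten")))
  rbind(
    data.frame(onset_s = d$item_onset_s, duration_s = 2,
               regressor = item_type, modulation = 1,
               item_id = d$item_id, stringsAsFactors = FALSE),
    data.frame(onset_s = d$number_onset_s, duration_s = 0.001,
               regressor = "number_onset", modulation = 1,
               item_id = d$item_id, stringsAsFactors = FALSE),
    data.frame(onset_s = d$outcome_onset_s, duration_s = 0.001,
               regressor = "outcome_onset", modulation = 1,
               item_id = d$item_id, stringsAsFactors = FALSE)
  )
}

# True beta map (roi -> regressor -> PSC) given the config's effect plan.
truth_effects <- function(config, design_cols) {
  item_cols <- intersect(c("reward_remembered", "reward_forgotten",
                           "neutral_remembered", "neutral_forgotten"),
                         design_cols)
  eff <- list()
  all_rois <- union(config$condition_rois, config$memory_rois)
  for (roi in all_rois) {
    b <- stats::setNames(rep(0, length(item_cols)), item_cols)
    if (roi %in% config$condition_rois)
      b[grepl("^reward_", names(b))] <-
        b[grepl("^reward_", names(b))] + config$condition_effect_psc
    if (roi %in% config$memory_rois)
      b[grepl("_remembered$", names(b))] <-
        b[grepl("_remembered$", names(b))] + config$memory_effect_psc
    eff[[roi]] <- as.list(b[b != 0])
  }
  eff[vapply(eff, length, 1L) > 0]
}

# Slow random-walk rigid-body motion parameters (3 translations mm,
# 3 rotations rad); used only to exercise FD and the confound block.
make_motion_params <- function(n_vols, sd_trans = 0.02, sd_rot = 2e-4,
                               seed = 1L) {
  with_seed(seed, {
    m <- cbind(
      apply(matrix(stats::rnorm(n_vols * 3, 0, sd_trans), ncol = 3), 2,
            cumsum),
      apply(matrix(stats::rnorm(n_vols * 3, 0, sd_rot), ncol = 3), 2, cumsum))
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
}
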