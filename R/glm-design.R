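# Event-related design construction: canonical double-gamma HRF, boxcar
# convolution on an oversampled grid, parametric modulators, the
# RT-duration regressor, and the discrete-cosine drift basis.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (a peak at ~6 s minus a ratio-scaled
#' undershoot at ~16 s), sampled on an oversampled grid and normalized to
#' unit peak. The kernel is 0 at t = 0.
#'
#' @param peak_delay_s,undershoot_delay_s gamma means (s).
#' @param peak_dispersion,undershoot_dispersion gamma scales.
#' @param undershoot_ratio weight of the undershoot term.
#' @param kernel_length_s kernel support (s).
#' @param oversampling_dt_s sampling step (s).
#' @return list of class `hrf_kernel` with `t` and `values`.
#' @export
double_gamma_hrf <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                             peak_dispersion = 1, undershoot_dispersion = 1,
                             undershoot_ratio = 1 / 6,
                             kernel_length_s = 32, oversampling_dt_s = 0.05) {
  pars <- c(peak_delay_s, undershoot_delay_s, peak_dispersion,
            undershoot_dispersion, undershoot_ratio, kernel_length_s,
            oversampling_dt_s)
  if (any(pars <= 0)) stop("all HRF parameters must be positive")
  t <- seq(0, kernel_length_s, by = oversampling_dt_s)
  h <- stats::dgamma(t, shape = peak_delay_s / peak_dispersion,
                     scale = peak_dispersion) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay_s /
                                       undershoot_dispersion,
                                     scale = undershoot_dispersion)
  structure(list(t = t, values = h / max(h), dt = oversampling_dt_s),
            class = "hrf_kernel")
}

# Convolve boxcars (onset, duration, amplitude) with the HRF kernel on the
# oversampled grid and sample at the frame times.
convolve_events <- function(onsets, durations, amplitudes, hrf, frame_times) {
  dt <- hrf$dt
  t_max <- max(frame_times) + dt
  n <- ceiling(t_max / dt) + 1L
  box <- numeric(n)
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] / dt) + 1L
    i1 <- max(i0, ceiling((onsets[i] + durations[i]) / dt))
    box[i0:min(i1, n)] <- box[i0:min(i1, n)] + amplitudes[i]
  }
  conv <- stats::convolve(box, rev(hrf$values), type = "open")[seq_len(n)] * dt
  stats::approx((seq_len(n) - 1) * dt, conv, xout = frame_times,
                rule = 2)$y
}

#' Build HRF-convolved task regressors from an event table
#'
#' One column per unique `regressor` name: a boxcar of the stated onset,
#' duration, and modulation amplitude, convolved with the kernel on the
#' oversampled grid and sampled at the frame times.
#'
#' @param events data.frame with `onset_s`, `duration_s`, `regressor`, and
#'   optionally `modulation` (default 1).
#' @param hrf an [double_gamma_hrf()] kernel.
#' @param frame_times per-volume acquisition times (s), see [frame_times()].
#' @return matrix of task columns (frames x regressors).
#' @export
build_task_regressors <- function(events, hrf, frame_times) {
  if (any(events$onset_s < 0)) stop("onsets must be >= 0", call. = FALSE)
  if (any(events$onset_s > max(frame_times)))
    stop("event onset beyond run end", call. = FALSE)
  if (is.null(events$modulation)) events$modulation <- 1
  names <- unique(events$regressor)
  X <- vapply(names, function(nm) {
    e <- events[events$regressor == nm, , drop = FALSE]
    convolve_events(e$onset_s, e$duration_s, e$modulation, hrf, frame_times)
  }, numeric(length(frame_times)))
  X <- matrix(X, ncol = length(names), dimnames = list(NULL, names))
  X
}

#' Parametric modulator column
#'
#' Per-event values are z-scored (within the supplied set, i.e. within
#' participant) and used as boxcar amplitudes; the unmodulated main-effect
#' column should be retained alongside in the design.
#'
#' @param events event rows (one per value) with `onset_s`, `duration_s`.
#' @param values one covariate value per event.
#' @param hrf HRF kernel.
#' @param frame_times frame times (s).
#' @return single-column matrix named `<modulator>`.
#' @export
add_parametric_modulator <- function(events, values, hrf, frame_times) {
  if (nrow(events) != length(values))
    stop("need one value per event", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("modulator values have zero variance; cannot z-score", call. = FALSE)
  z <- (values - mean(values)) / s
  col <- convolve_events(events$onset_s, events$duration_s, z, hrf,
                         frame_times)
  matrix(col, ncol = 1, dimnames = list(NULL, "modulator"))
}

#' Reaction-time-duration regressor
#'
#' Boxcars whose durations equal the per-trial reaction times (not the
#' fixed item duration), convolved with the HRF. Events with missing RTs
#' are omitted with a warning.
#'
#' @param events event rows with `onset_s` and `rt_s`.
#' @param hrf HRF kernel.
#' @param frame_times frame times (s).
#' @return single-column matrix named `rt_duration`.
#' @export
build_rt_regressor <- function(events, hrf, frame_times) {
  miss <- is.na(events$rt_s)
  if (any(miss)) {
    warning(sprintf("%d event(s) without RT omitted from the RT regressor",
                    sum(miss)))
    events <- events[!miss, , drop = FALSE]
  }
  if (any(events$rt_s <= 0)) stop("RTs must be positive", call. = FALSE)
  col <- convolve_events(events$onset_s, events$rt_s,
                         rep(1, nrow(events)), hrf, frame_times)
  matrix(col, ncol = 1, dimnames = list(NULL, "rt_duration"))
}

#' Discrete-cosine drift basis
#'
#' The first `n_functions` non-constant DCT-II components over the frame
#' index; columns are mutually orthogonal.
#'
#' @param n_frames number of volumes.
#' @param n_functions number of components (default 12).
#' @return matrix (frames x components) named `dct_1` ...
#' @export
dct_basis <- function(n_frames, n_functions = 12L) {
  if (n_functions >= n_frames)
    stop("`n_functions` must be smaller than `n_frames`", call. = FALSE)
  n <- seq_len(n_frames) - 1
  X <- vapply(seq_len(n_functions), function(k)
    sqrt(2 / n_frames) * cos(pi * (n + 0.5) * k / n_frames),
    numeric(n_frames))
  colnames(X) <- paste0("dct_", seq_len(n_functions))
  X
}
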