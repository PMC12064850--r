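# Confound model: RETROICOR cardiac/respiratory phase regressors, framewise
# displacement, DVARS, and assembly of the full nuisance block
# (6 motion + FD + DVARS + 12 DCT + 18 RETROICOR + 1 mean-centered
# fourth-ventricle column = 39 regressors).

# Indices of local maxima above a threshold.
find_peaks <- function(x, min_height = NULL) {
  d <- diff(sign(diff(x)))
  idx <- which(d < 0) + 1L
  if (!is.null(min_height)) idx <- idx[x[idx] >= min_height]
  idx
}

#' Count the quasi-periodic peaks in a physiological trace
#'
#' Peaks are local maxima above half the trace's amplitude (midpoint of its
#' range).
#'
#' @param signal amplitude series.
#' @return number of peaks.
#' @export
count_peaks <- function(signal) {
  thr <- mean(range(signal))
  length(find_peaks(signal, thr))
}

# Cardiac phase at arbitrary times: linear 0 -> 2*pi between successive
# detected peaks, extrapolated with the mean cycle before the first and
# after the last peak.
cardiac_phase <- function(trace, at_times) {
  thr <- mean(range(trace$cardiac))
  pk <- find_peaks(trace$cardiac, thr)
  if (length(pk) < 2L) stop("fewer than 2 cardiac peaks detected",
                            call. = FALSE)
  pt <- trace$time_s[pk]
  cyc <- mean(diff(pt))
  n_pre <- max(ceiling((pt[1] - min(at_times)) / cyc), 0) + 1L
  n_post <- max(ceiling((max(at_times) - pt[length(pt)]) / cyc), 0) + 1L
  bounds <- c(pt[1] - cyc * seq_len(n_pre), pt,
              pt[length(pt)] + cyc * seq_len(n_post))
  bounds <- sort(unique(bounds))
  idx <- findInterval(at_times, bounds, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= length(bounds)] <- length(bounds) - 1L
  2 * pi * (at_times - bounds[idx]) / (bounds[idx + 1L] - bounds[idx])
}

# Respiratory phase by amplitude-histogram equalization with the sign of
# the derivative: phi = pi * F(x) * sign(dx/dt), in [-pi, pi].
respiratory_phase <- function(trace, at_times) {
  x <- trace$respiratory
  F <- stats::ecdf(x)
  xi <- stats::approx(trace$time_s, x, at_times, rule = 2)$y
  dx <- stats::approx(trace$time_s[-1] - 0.5 / trace$sampling_rate_hz,
                      diff(x), at_times, rule = 2)$y
  pi * F(xi) * ifelse(dx >= 0, 1, -1)
}

#' RETROICOR physiological noise regressors
#'
#' Fourier expansion of cardiac and respiratory phase: cos/sin of
#' k * cardiac phase for k up to `cardiac_order`, cos/sin of k * respiratory
#' phase up to `resp_order`, and cos/sin of the sum and difference of the
#' two phases for the interaction order. The defaults (3, 4, 1) yield
#' 6 + 8 + 4 = 18 columns, all within [-1, 1].
#'
#' @param physio a [make_physio()] trace covering all frame times.
#' @param frame_times per-volume acquisition times (s).
#' @param cardiac_order,resp_order,interaction_order expansion orders.
#' @return matrix (frames x 18 at defaults) with named columns.
#' @export
retroicor_regressors <- function(physio, frame_times, cardiac_order = 3L,
                                 resp_order = 4L, interaction_order = 1L) {
  if (max(frame_times) > physio$duration_s)
    stop("physiological trace does not cover all frame times", call. = FALSE)
  phi_c <- cardiac_phase(physio, frame_times)
  phi_r <- respiratory_phase(physio, frame_times)
  cols <- list()
  for (k in seq_len(cardiac_order)) {
    cols[[paste0("retro_c_cos", k)]] <- cos(k * phi_c)
    cols[[paste0("retro_c_sin", k)]] <- sin(k * phi_c)
  }
  for (k in seq_len(resp_order)) {
    cols[[paste0("retro_r_cos", k)]] <- cos(k * phi_r)
    cols[[paste0("retro_r_sin", k)]] <- sin(k * phi_r)
  }
  for (k in seq_len(interaction_order)) {
    cols[[paste0("retro_x_cos_plus", k)]] <- cos(k * (phi_c + phi_r))
    cols[[paste0("retro_x_sin_plus", k)]] <- sin(k * (phi_c + phi_r))
    cols[[paste0("retro_x_cos_minus", k)]] <- cos(k * (phi_c - phi_r))
    cols[[paste0("retro_x_sin_minus", k)]] <- sin(k * (phi_c - phi_r))
  }
  do.call(cbind, cols)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' `FD_t = sum |delta translation| + 50 * sum |delta rotation|`, rotations
#' in radians converted to arc length on a 50 mm sphere; the first frame
#' is 0.
#'
#' @param motion_params matrix (frames x 6): 3 translations (mm) then
#'   3 rotations (rad).
#' @return numeric vector of per-frame FD (mm).
#' @export
framewise_displacement <- function(motion_params) {
  stopifnot(ncol(motion_params) == 6L)
  d <- rbind(0, abs(diff(motion_params)))
  rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE])
}

#' DVARS: RMS over voxels of the temporal difference image
#'
#' @param bold4d 4D array (x, y, z, t).
#' @return numeric vector of per-frame DVARS; frame 1 is 0.
#' @export
dvars <- function(bold4d) {
  y <- if (is.list(bold4d)) bold4d$data else bold4d
  nt <- dim(y)[4]
  if (nt < 2L) stop("need at least 2 frames", call. = FALSE)
  ym <- matrix(y, ncol = nt)
  c(0, sqrt(colMeans((ym[, -1L, drop = FALSE] -
                      ym[, -nt, drop = FALSE])^2)))
}

#' Assemble the full confound block
#'
#' Concatenates 6 motion parameters, FD, DVARS, the DCT drift basis, the
#' RETROICOR block, and the mean-centered fourth-ventricle timeseries.
#' At the defaults this is 6 + 1 + 1 + 12 + 18 + 1 = 39 columns.
#'
#' @param motion matrix (frames x 6).
#' @param fd,dvars per-frame vectors.
#' @param dct DCT basis matrix.
#' @param retroicor RETROICOR matrix (or a same-width replacement block,
#'   e.g. data-driven noise components when physiology is missing).
#' @param ventricle_series raw fourth-ventricle timeseries (centered here).
#' @return confound matrix with named columns.
#' @export
assemble_confounds <- function(motion, fd, dvars, dct, retroicor,
                               ventricle_series) {
  v <- if (inherits(ventricle_series, "bold_series")) ventricle_series$values
       else ventricle_series
  parts <- list(motion, fd, dvars, dct, retroicor, v)
  n <- vapply(parts, NROW, 1L)
  if (length(unique(n)) != 1L)
    stop("confound blocks have mismatched lengths", call. = FALSE)
  colnames(motion) <- colnames(motion) %||%
    c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  X <- cbind(motion, fd = fd, dvars = dvars, dct, retroicor,
             ventricle = v - mean(v))
  X
}
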