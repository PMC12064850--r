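# Probability-weighted ROI timeseries extraction from unsmoothed 4D data,
# percent-signal-change conversion, and temporal SNR.

#' Extract a probability-weighted ROI timeseries
#'
#' `s(t) = sum_v w_v y_v(t) / sum_v w_v` over the mask support, on
#' unsmoothed data. Voxels with non-finite values at any timepoint are
#' dropped from the weighted sum (with a warning counting them).
#'
#' @param bold4d 4D array (x, y, z, t) or a list with `data`.
#' @param mask a [prob_mask()] on the same spatial grid.
#' @param tr_s repetition time (s), stored on the output.
#' @param run_id optional run identifier.
#' @return list of class `bold_series` with `values`, `tr_s`,
#'   `units = "raw"`, `roi_name`, `run_id`.
#' @export
extract_weighted_ts <- function(bold4d, mask, tr_s = NA_real_, run_id = NA) {
  y <- if (is.list(bold4d)) bold4d$data else bold4d
  stopifnot(length(dim(y)) == 4L)
  if (!identical(dim(y)[1:3], dim(mask$data)))
    stop("BOLD and mask grids do not match", call. = FALSE)
  w <- as.vector(mask$data)
  idx <- which(w > 0)
  if (!length(idx)) stop("mask has zero total weight", call. = FALSE)
  nt <- dim(y)[4]
  nv <- prod(dim(y)[1:3])
  # gather only the support voxels (avoids copying the full 4D array)
  ymat <- matrix(y[as.vector(outer(idx, (seq_len(nt) - 1L) * nv, "+"))],
                 nrow = length(idx))
  bad <- !stats::complete.cases(ymat) | apply(!is.finite(ymat), 1, any)
  if (any(bad)) {
    warning(sprintf("%d voxel(s) with non-finite values excluded", sum(bad)))
    ymat <- ymat[!bad, , drop = FALSE]
    idx <- idx[!bad]
    if (!nrow(ymat)) stop("no finite voxels left in mask", call. = FALSE)
  }
  wv <- w[idx]
  structure(list(values = as.vector(crossprod(ymat, wv)) / sum(wv),
                 tr_s = tr_s, units = "raw", roi_name = mask$name,
                 run_id = run_id),
            class = "bold_series")
}

#' Convert a raw timeseries to percent signal change
#'
#' `p(t) = 100 * s(t) / mean(s) - 100`; the output mean is exactly zero.
#'
#' @param series a `bold_series` in raw units, or a numeric vector.
#' @return same kind of object in PSC units.
#' @export
percent_signal_change <- function(series) {
  v <- if (inherits(series, "bold_series")) series$values else series
  m <- mean(v)
  if (!is.finite(m) || m == 0)
    stop("temporal mean is zero; cannot convert to percent signal change",
         call. = FALSE)
  p <- 100 * v / m - 100
  if (inherits(series, "bold_series")) {
    series$values <- p
    series$units <- "psc"
    series
  } else p
}

#' Temporal signal-to-noise ratio
#'
#' Temporal mean divided by temporal SD of a raw timeseries.
#'
#' @param series a `bold_series` in raw units, or a numeric vector.
#' @return scalar tSNR.
#' @export
tsnr <- function(series) {
  v <- if (inherits(series, "bold_series")) series$values else series
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("temporal SD is zero", call. = FALSE)
  mean(v) / s
}
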