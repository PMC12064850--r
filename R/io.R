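# Disk formats: NIfTI-1 volumes and masks, BIDS-style events TSV,
# two-column physiological TSV, and JSON ground truth.

#' Write a 3D/4D volume or probabilistic mask as NIfTI-1
#'
#' @param x a [prob_mask()], a list with `data` and `voxel_size_mm`, or an
#'   array (then `voxel_size_mm` is required).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm spacing, if `x` is a bare array.
#' @param tr_s repetition time stored in the header for 4D data.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(x, path, voxel_size_mm = NULL, tr_s = NULL) {
  d <- if (is.list(x)) x$data else x
  vs <- if (is.list(x)) x$voxel_size_mm else voxel_size_mm
  if (is.null(vs)) stop("`voxel_size_mm` required", call. = FALSE)
  img <- RNifti::asNifti(d)
  RNifti::pixdim(img) <- if (length(dim(d)) == 4L) c(vs, tr_s %||% 1) else vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path input path.
#' @return list with `data` (array), `voxel_size_mm`, and `tr_s` (4D only).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  d <- array(as.numeric(img), dim = dim(img))
  list(data = d, voxel_size_mm = as.numeric(pix[1:3]),
       tr_s = if (length(dim(d)) == 4L) as.numeric(pix[4]) else NULL)
}

#' Write a BIDS-style events table
#'
#' Columns follow the BIDS convention: `onset`, `duration`, `trial_type`,
#' plus any additional columns present (e.g. `response_time`, `points`).
#'
#' @param events data.frame with `onset_s`, `duration_s`, `regressor` (or
#'   already-BIDS column names).
#' @param path output `events.tsv` path.
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- events
  ren <- c(onset_s = "onset", duration_s = "duration",
           regressor = "trial_type")
  for (nm in names(ren))
    if (nm %in% names(out)) names(out)[names(out) == nm] <- ren[[nm]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' @param path `events.tsv` path.
#' @return data.frame with `onset_s`, `duration_s`, `regressor` columns.
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  ren <- c(onset = "onset_s", duration = "duration_s",
           trial_type = "regressor")
  for (nm in names(ren))
    if (nm %in% names(d)) names(d)[names(d) == nm] <- ren[[nm]]
  d
}

#' Write a physiological trace as two-column TSV
#'
#' @param physio a [make_physio()] trace.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_physio_tsv <- function(physio, path) {
  utils::write.table(
    data.frame(cardiac = physio$cardiac, respiratory = physio$respiratory),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth record of a synthetic dataset as JSON
#'
#' @param dataset a [make_dataset()] bundle (or its `ground_truth` element).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ground_truth_json <- function(dataset, path) {
  gt <- if (!is.null(dataset$ground_truth)) dataset$ground_truth else dataset
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
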