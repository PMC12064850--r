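# Semi-automated locus coeruleus segmentation: intensity statistics weighted
# by a probabilistic prior, two logistic sigmoid maps (a lower intensity
# cutoff at mu and a CSF cutoff at mu + 3 sigma), grey-scale dilation in
# physical millimetres, multiplicative combination with a square root, and
# resolution of LC / fourth-ventricle overlap.

#' Prior-weighted intensity mean and SD
#'
#' @param image list with a 3D `data` array (e.g. from [make_mt_image()]).
#' @param prior a [prob_mask()] on the same grid.
#' @return list with `mu` and `sigma` (weighted mean and SD).
#' @export
weighted_stats <- function(image, prior) {
  if (!identical(dim(image$data), dim(prior$data)))
    stop("image and prior grids do not match", call. = FALSE)
  w <- as.vector(prior$data)
  if (sum(w) <= 0) stop("prior has zero total weight", call. = FALSE)
  x <- as.vector(image$data)
  mu <- sum(w * x) / sum(w)
  sigma <- sqrt(sum(w * (x - mu)^2) / sum(w))
  list(mu = mu, sigma = sigma)
}

#' Voxelwise logistic sigmoid of image intensity
#'
#' `1 / (1 + exp(-(I - center)/slope))`: 0.5 at the center, monotone
#' nondecreasing in intensity.
#'
#' @param image list with a 3D `data` array.
#' @param center sigmoid midpoint (intensity units).
#' @param slope sigmoid slope parameter (> 0, intensity units).
#' @return 3D array of values in [0, 1].
#' @export
sigmoid_map <- function(image, center, slope) {
  if (!is.numeric(slope) || slope <= 0)
    stop("`slope` must be positive", call. = FALSE)
  1 / (1 + exp(-(image$data - center) / slope))
}

#' Grey-scale dilation with a spherical structuring element
#'
#' Each voxel takes the maximum of the input over the neighborhood of the
#' given physical radius (converted to voxel offsets via the spacing).
#' Radius 0, or any radius smaller than the smallest voxel dimension,
#' leaves the input unchanged. On binary masks this reduces to ordinary
#' binary dilation.
#'
#' @param map 3D array, or a [prob_mask()].
#' @param radius_mm dilation radius in millimetres (>= 0).
#' @param voxel_size_mm spacing (taken from the mask if `map` is one).
#' @return object of the same kind as `map`.
#' @export
dilate_map <- function(map, radius_mm, voxel_size_mm = NULL) {
  is_mask <- inherits(map, "prob_mask")
  d <- if (is_mask) map$data else map
  vs <- if (is_mask) map$voxel_size_mm else voxel_size_mm
  if (is.null(vs)) stop("`voxel_size_mm` required for a plain array")
  if (radius_mm < 0) stop("`radius_mm` must be >= 0", call. = FALSE)
  rng <- floor(radius_mm / vs)
  offs <- expand.grid(dx = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                      dz = -rng[3]:rng[3])
  keep <- (offs$dx * vs[1])^2 + (offs$dy * vs[2])^2 +
    (offs$dz * vs[3])^2 <= radius_mm^2
  offs <- offs[keep, , drop = FALSE]
  gs <- dim(d)
  out <- d
  for (i in seq_len(nrow(offs))) {
    o <- as.integer(offs[i, ])
    if (all(o == 0L)) next
    xs <- pmax(1L, 1L - o[1]):pmin(gs[1], gs[1] - o[1])
    ys <- pmax(1L, 1L - o[2]):pmin(gs[2], gs[2] - o[2])
    zs <- pmax(1L, 1L - o[3]):pmin(gs[3], gs[3] - o[3])
    out[xs, ys, zs] <- pmax(out[xs, ys, zs],
                            d[xs + o[1], ys + o[2], zs + o[3]])
  }
  if (is_mask) prob_mask(out, vs, map$name) else out
}

#' Combine prior, intensity sigmoid, and CSF sigmoid into the LC mask
#'
#' `M = sqrt(dilate(prior, r) * sigmoid_lo * (1 - dilate(csf_sigmoid, r)))`.
#' The low-intensity sigmoid is never dilated; the prior and the CSF
#' sigmoid are.
#'
#' @param prior a [prob_mask()].
#' @param sigmoid_lo 3D array, the lower-cutoff sigmoid map.
#' @param csf_sigmoid 3D array, the high-intensity (CSF) sigmoid map.
#' @param radius_mm dilation radius (default 0.5 mm).
#' @return a [prob_mask()].
#' @export
combine_lc_mask <- function(prior, sigmoid_lo, csf_sigmoid, radius_mm = 0.5) {
  if (!identical(dim(prior$data), dim(sigmoid_lo)) ||
      !identical(dim(prior$data), dim(csf_sigmoid)))
    stop("grids do not match", call. = FALSE)
  rng <- range(sigmoid_lo, csf_sigmoid)
  if (rng[1] < 0 || rng[2] > 1)
    stop("sigmoid maps must lie in [0, 1]", call. = FALSE)
  dp <- dilate_map(prior, radius_mm)
  dc <- dilate_map(csf_sigmoid, radius_mm, prior$voxel_size_mm)
  prob_mask(sqrt(dp$data * sigmoid_lo * (1 - dc)), prior$voxel_size_mm, "LC")
}

#' Semi-automated LC segmentation
#'
#' Composes the full procedure: weighted intensity statistics within the
#' published prior; a lower-cutoff sigmoid centered at the weighted mean
#' with slope equal to the weighted SD; a CSF sigmoid centered at
#' mu + 3 sigma with the same slope; dilation of the prior and the CSF
#' sigmoid by `radius_mm`; multiplicative combination and square root.
#' The result is invariant to affine intensity rescaling a*I + b (a > 0).
#' A zero weighted SD (constant image) is guarded by an epsilon-scaled
#' slope with a warning.
#'
#' @param mt_image list with a 3D `data` array.
#' @param published_prior a [prob_mask()].
#' @param radius_mm dilation radius (default 0.5 mm).
#' @return a [prob_mask()] for the LC.
#' @export
segment_lc <- function(mt_image, published_prior, radius_mm = 0.5) {
  ws <- weighted_stats(mt_image, published_prior)
  slope <- ws$sigma
  if (slope <= 0) {
    slope <- max(abs(ws$mu), 1) * sqrt(.Machine$double.eps)
    warning("weighted SD is zero; using an epsilon-scaled sigmoid slope")
  }
  s_lo <- sigmoid_map(mt_image, ws$mu, slope)
  s_csf <- sigmoid_map(mt_image, ws$mu + 3 * ws$sigma, slope)
  combine_lc_mask(published_prior, s_lo, s_csf, radius_mm)
}

#' Resolve overlapping voxels between two probabilistic masks
#'
#' Wherever both masks are positive, the voxel is kept in the mask with the
#' higher probability and removed (set to 0) from the other. Ties are kept
#' in the first mask. All other voxels are unchanged, so the supports are
#' disjoint afterwards and the per-voxel maximum over the pair is
#' preserved.
#'
#' @param mask_a,mask_b [prob_mask()] objects on one grid.
#' @return list with the two adjusted masks (`a`, `b`) and the number of
#'   `n_overlap` voxels resolved.
#' @export
resolve_overlap <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a$data), dim(mask_b$data)))
    stop("mask grids do not match", call. = FALSE)
  a <- mask_a$data; b <- mask_b$data
  both <- a > 0 & b > 0
  a_wins <- both & (a >= b)
  b_wins <- both & (b > a)
  a[b_wins] <- 0
  b[a_wins] <- 0
  list(a = prob_mask(a, mask_a$voxel_size_mm, mask_a$name),
       b = prob_mask(b, mask_b$voxel_size_mm, mask_b$name),
       n_overlap = sum(both))
}

#' Dice overlap of two binarized masks
#'
#' @param mask_a,mask_b [prob_mask()] objects or 3D arrays.
#' @param threshold binarization threshold (default 0.5).
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(mask_a, mask_b, threshold = 0.5) {
  a <- (if (inherits(mask_a, "prob_mask")) mask_a$data else mask_a) >= threshold
  b <- (if (inherits(mask_b, "prob_mask")) mask_b$data else mask_b) >= threshold
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
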