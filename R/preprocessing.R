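#' ROI intensity preprocessing
#'
#' Before texture extraction the ROI is cleaned in two steps, independently
#' per modality: (1) outlier re-segmentation, restricting the mask to voxels
#' whose intensity falls within the 1st-99th percentile band of the in-mask
#' distribution; (2) fixed-bin-count discretization of the surviving
#' intensities into 64 grey levels. A fixed bin count normalises across
#' scanners with arbitrary intensity units while preserving contrast.
#' No denoising filter and no global intensity normalisation are applied.
#'
#' @name preprocessing
NULL

#' Default preprocessing configuration
#'
#' @param low_percentile,high_percentile re-segmentation band, percent.
#' @param bin_count number of discretization levels.
#' @param min_slice_pixels slices with fewer ROI pixels are dropped
#'   (texture matrices need at least one neighbouring pair).
#' @return list of settings.
#' @export
preprocessing_config <- function(low_percentile = 1, high_percentile = 99,
                                 bin_count = 64, min_slice_pixels = 2) {
  stopifnot(low_percentile >= 0, low_percentile < high_percentile,
            high_percentile <= 100, bin_count >= 2, min_slice_pixels >= 1)
  list(low_percentile = low_percentile, high_percentile = high_percentile,
       bin_count = bin_count, min_slice_pixels = min_slice_pixels)
}

#' Outlier re-segmentation of a mask
#'
#' Restricts the mask to voxels whose intensity lies within the closed
#' percentile band `[P_low, P_high]` of the original in-mask distribution.
#' Percentiles use linear interpolation between order statistics
#' (\code{\link[stats]{quantile}} type 7). Ties at the bounds are retained.
#'
#' @param volume `image_volume` supplying the intensities.
#' @param mask nonempty `segmentation_mask` on the same grid.
#' @param cfg a [preprocessing_config()].
#' @return The refined `segmentation_mask` (same provenance).
#' @export
resegment <- function(volume, mask, cfg = preprocessing_config()) {
  sel <- mask$voxels == 1
  if (!any(sel)) stop("empty mask cannot be re-segmented")
  vals <- volume$voxels[sel]
  q <- stats::quantile(vals,
                       c(cfg$low_percentile, cfg$high_percentile) / 100,
                       type = 7, names = FALSE)
  keep <- sel & volume$voxels >= q[1] & volume$voxels <= q[2]
  if (!any(keep))
    stop("re-segmentation removed every voxel (degenerate intensities)")
  segmentation_mask(keep + 0L, mask$spacing, mask$provenance)
}

#' Fixed-bin-count discretization of ROI intensities
#'
#' Maps each in-mask intensity x to level
#' `1 + floor(bin_count * (x - min) / (max - min))`, clamped to `bin_count`
#' at `x = max`; the range is computed over the (re-segmented) ROI of this
#' volume. A constant ROI maps entirely to level 1. Levels are therefore
#' invariant to any positive affine transform of the intensities.
#'
#' @inheritParams resegment
#' @param mask the re-segmented mask.
#' @return An object of class `discretized_roi`: list with `levels`
#'   (integer 3D array, 0 outside the ROI), `bin_count`, `slice_indices`
#'   (axial indices intersecting the ROI), `modality`.
#' @export
discretize <- function(volume, mask, cfg = preprocessing_config(),
                       modality = c("t2w", "adc")) {
  modality <- match.arg(modality)
  sel <- mask$voxels == 1
  if (!any(sel)) stop("empty mask cannot be discretized")
  vals <- volume$voxels[sel]
  lo <- min(vals); hi <- max(vals)
  lev <- array(0L, dim = dim(volume$voxels))
  if (hi > lo) {
    l <- 1L + as.integer(floor(cfg$bin_count * (vals - lo) / (hi - lo)))
    l[l > cfg$bin_count] <- cfg$bin_count
  } else {
    l <- rep(1L, length(vals))
  }
  lev[sel] <- l
  slices <- which(apply(sel, 3, any))
  structure(list(levels = lev, bin_count = cfg$bin_count,
                 slice_indices = slices, modality = modality),
            class = "discretized_roi")
}

#' Split a discretized ROI into per-slice 2D grids
#'
#' Slices with fewer than `min_slice_pixels` ROI pixels are dropped (they
#' cannot support neighbourhood statistics); dropped slices are reported in
#' the `dropped` attribute.
#'
#' @param droi a `discretized_roi`.
#' @param min_slice_pixels minimum in-slice ROI pixel count.
#' @return list of 2D integer matrices (0 = background), named by axial
#'   index, with attribute `dropped`.
#' @export
slice_decompose <- function(droi, min_slice_pixels = 2) {
  out <- list(); dropped <- integer(0)
  for (s in droi$slice_indices) {
    sl <- droi$levels[, , s]
    if (sum(sl > 0) >= min_slice_pixels) out[[as.character(s)]] <- sl
    else dropped <- c(dropped, s)
  }
  if (!length(out))
    stop("every slice fell below the minimum ROI pixel count")
  attr(out, "dropped") <- dropped
  out
}
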