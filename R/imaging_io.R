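#' Image volumes, segmentation masks and study cases
#'
#' Volumes are stored as plain 3D arrays indexed `[row, col, slice]`; the
#' third axis is the axial axis over which 2.5D texture extraction iterates.
#' World coordinates are axis-aligned: voxel centre `(i, j, k)` (0-based)
#' sits at `(i*dx, j*dy, k*dz)` mm. The NIfTI affine is used only for voxel
#' spacing; cohort volumes are treated as axis-aligned.
#'
#' @name imaging-io
NULL

#' Construct an image volume
#'
#' @param voxels 3D numeric array, `[row, col, slice]`.
#' @param spacing numeric length-3, voxel spacing in mm `(dx, dy, dz)`;
#'   `dz` is the slice thickness.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("not a 3D volume (payload has ", length(dim(voxels)), " dimensions)")
  if (any(!is.finite(voxels)))
    stop("volume contains non-finite voxel values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return An `image_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) != 3L)
    stop("not a 3D volume: ", path)
  image_volume(vox, RNifti::pixdim(img)[1:3])
}

#' Write a volume to NIfTI
#'
#' @param vol an `image_volume` or `segmentation_mask`.
#' @param path output path.
#' @export
write_volume <- function(vol, path) {
  arr <- vol$voxels
  if (inherits(vol, "segmentation_mask")) storage.mode(arr) <- "integer"
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = if (inherits(vol, "segmentation_mask"))
    "uint8" else "auto")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a binary segmentation mask
#'
#' @param voxels 3D array of 0/1 (or logical) values aligned to its
#'   reference volume's grid.
#' @param spacing voxel spacing in mm, inherited from the reference volume.
#' @param provenance `"manual"` or `"automatic"`.
#' @param allow_empty permit a mask with no foreground voxel.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(voxels, spacing, provenance = "manual",
                              allow_empty = FALSE) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("mask must be a 3D grid")
  if (is.logical(voxels)) voxels <- voxels + 0L
  if (!all(voxels %in% c(0, 1))) stop("mask values must be 0/1")
  if (!allow_empty && sum(voxels) == 0) stop("mask has no foreground voxel")
  provenance <- match.arg(provenance, c("manual", "automatic"))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 provenance = provenance),
            class = "segmentation_mask")
}

#' Read a binary mask from NIfTI
#'
#' Any voxel > 0.5 is treated as foreground.
#' @inheritParams read_volume
#' @param provenance `"manual"` or `"automatic"`.
#' @param allow_empty permit an empty mask.
#' @export
read_mask <- function(path, provenance = "manual", allow_empty = FALSE) {
  vol <- read_volume(path)
  segmentation_mask((vol$voxels > 0.5) + 0L, vol$spacing, provenance,
                    allow_empty = allow_empty)
}

# voxel-centre world coordinates along one axis (0-based index * spacing)
.axis_coords <- function(n, d) (seq_len(n) - 1) * d

#' Resample a volume onto a reference grid
#'
#' Trilinear interpolation for intensities, nearest neighbour for masks.
#' Both grids share the world origin at the centre of voxel (0,0,0);
#' reference voxels falling outside the moving volume's field are 0.
#'
#' @param moving `image_volume` to resample.
#' @param reference `image_volume` defining the target grid.
#' @param mode `"linear"` or `"nearest"`.
#' @return An `image_volume` on the reference grid.
#' @export
resample_to_grid <- function(moving, reference, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  dm <- dim(moving$voxels); dr <- dim(reference$voxels)
  ext_m <- (dm - 1) * moving$spacing
  ext_r <- (dr - 1) * reference$spacing
  if (any(pmin(ext_m, ext_r) < 0) || any(ext_m < 0))
    stop("degenerate volume extent")
  if (any(ext_r > ext_m + moving$spacing) && all(ext_m == 0))
    stop("empty world-space overlap")
  # target voxel centres in moving-volume continuous index space
  idx <- lapply(1:3, function(a)
    .axis_coords(dr[a], reference$spacing[a]) / moving$spacing[a])
  out <- array(0, dim = dr)
  if (mode == "nearest") {
    ii <- round(idx[[1]]) + 1L; jj <- round(idx[[2]]) + 1L; kk <- round(idx[[3]]) + 1L
    iok <- ii >= 1L & ii <= dm[1]; jok <- jj >= 1L & jj <= dm[2]; kok <- kk >= 1L & kk <= dm[3]
    if (!any(iok) || !any(jok) || !any(kok)) stop("empty world-space overlap")
    out[iok, jok, kok] <- moving$voxels[ii[iok], jj[jok], kk[kok]]
  } else {
    # trilinear: separable gather of the 8 corners
    lo <- lapply(idx, function(v) pmin(pmax(floor(v), 0), Inf))
    fr <- Map(function(v, l) v - l, idx, lo)
    ok <- Map(function(v, n) v >= 0 & v <= n - 1, idx, as.list(dm))
    if (!any(ok[[1]]) || !any(ok[[2]]) || !any(ok[[3]]))
      stop("empty world-space overlap")
    clamp <- function(v, n) pmin(pmax(v, 1L), n)
    i0 <- clamp(lo[[1]] + 1L, dm[1]); i1 <- clamp(lo[[1]] + 2L, dm[1])
    j0 <- clamp(lo[[2]] + 1L, dm[2]); j1 <- clamp(lo[[2]] + 2L, dm[2])
    k0 <- clamp(lo[[3]] + 1L, dm[3]); k1 <- clamp(lo[[3]] + 2L, dm[3])
    fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
    v <- moving$voxels
    acc <- array(0, dim = dr)
    for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
      wi <- if (ci == 0) 1 - fx else fx
      wj <- if (cj == 0) 1 - fy else fy
      wk <- if (ck == 0) 1 - fz else fz
      ii <- if (ci == 0) i0 else i1
      jj <- if (cj == 0) j0 else j1
      kk <- if (ck == 0) k0 else k1
      w <- outer(outer(wi, wj), wk)
      acc <- acc + w * v[ii, jj, kk]
    }
    infield <- outer(outer(ok[[1]], ok[[2]]), ok[[3]])
    out <- acc
    out[!infield] <- 0
  }
  image_volume(out, reference$spacing)
}

#' Dice similarity coefficient between two masks
#'
#' DSC = 2|A inter B| / (|A| + |B|). Two empty masks agree on absence and
#' score 1. Masks with DSC below `exclusion_threshold` carry `excluded = TRUE`
#' (tumours the automatic segmentation failed to find are dropped from
#' construction data at DSC < 0.20).
#'
#' @param a,b `segmentation_mask` objects on the same grid.
#' @param exclusion_threshold DSC below which the pair is flagged excluded.
#' @return list with `value` and `excluded`.
#' @export
dice <- function(a, b, exclusion_threshold = 0.20) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("mask grids differ in shape")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  value <- if (na + nb == 0) 1.0 else 2 * sum(a$voxels * b$voxels) / (na + nb)
  list(value = value, excluded = value < exclusion_threshold)
}

#' ROI volume in cubic millimetres
#'
#' @param mask a nonempty `segmentation_mask`.
#' @param spacing optional spacing override (mm); defaults to the mask's own.
#' @return foreground voxel count times the voxel volume, in mm^3.
#' @export
roi_volume_mm3 <- function(mask, spacing = mask$spacing) {
  n <- sum(mask$voxels)
  if (n == 0) stop("empty mask has no ROI volume")
  n * prod(spacing)
}

#' Response label from tumour regression grade
#'
#' Mandard TRG 1-2 indicates pathological response; TRG 3-5 non-response.
#'
#' @param trg integer vector with values in 1..5.
#' @return character vector, `"responder"` or `"nonresponder"`.
#' @export
label_from_trg <- function(trg) {
  if (any(is.na(trg)) || any(trg != round(trg)) || any(trg < 1) || any(trg > 5))
    stop("TRG must be an integer in 1..5")
  ifelse(trg <= 2, "responder", "nonresponder")
}

#' Assemble a study case
#'
#' @param id case identifier.
#' @param centre centre code (`"A"`, `"B"` or `"C"`).
#' @param t2w T2-weighted `image_volume`.
#' @param adc ADC `image_volume`; resampled (linear) onto the T2w grid at
#'   ingestion if the grids differ, so one mask serves both modalities.
#' @param masks named list of `segmentation_mask` objects keyed by
#'   provenance (`manual`, `automatic`), aligned to the T2w grid.
#' @param trg tumour regression grade, 1..5.
#' @param split `"construction-train"`, `"construction-test"` or
#'   `"validation"`.
#' @return An object of class `study_case`.
#' @export
study_case <- function(id, centre, t2w, adc, masks, trg, split) {
  centre <- match.arg(centre, c("A", "B", "C"))
  split <- match.arg(split,
    c("construction-train", "construction-test", "validation"))
  if (!identical(dim(adc$voxels), dim(t2w$voxels)) ||
      !isTRUE(all.equal(adc$spacing, t2w$spacing)))
    adc <- resample_to_grid(adc, t2w, "linear")
  for (m in masks)
    if (!identical(dim(m$voxels), dim(t2w$voxels)))
      stop("mask not aligned to the T2w grid (case ", id, ")")
  structure(list(id = as.character(id), centre = centre, t2w = t2w, adc = adc,
                 masks = masks, trg = as.integer(trg),
                 label = label_from_trg(trg), split = split),
            class = "study_case")
}

#' Read a cohort from a clinical table
#'
#' The CSV must have columns `id`, `centre`, `trg`, `split`, `t2w_path`,
#' `adc_path`, `mask_manual` and optionally `mask_automatic`; paths are
#' resolved relative to the CSV's directory unless absolute.
#'
#' @param csv_path path to the clinical table.
#' @return list of `study_case` objects.
#' @export
read_cohort <- function(csv_path) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("id", "centre", "trg", "split", "t2w_path", "adc_path", "mask_manual")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table misses columns: ",
                         paste(miss, collapse = ", "))
  base <- dirname(normalizePath(csv_path))
  rel <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    masks <- list(manual = read_mask(rel(r$mask_manual), "manual"))
    if (!is.null(tab$mask_automatic) && nzchar(r$mask_automatic))
      masks$automatic <- read_mask(rel(r$mask_automatic), "automatic")
    study_case(r$id, r$centre, read_volume(rel(r$t2w_path)),
               read_volume(rel(r$adc_path)), masks, r$trg, r$split)
  })
}
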