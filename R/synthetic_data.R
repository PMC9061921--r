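#' Synthetic multicentre cohort and feature-table generators
#'
#' Desk-scale stand-ins for the undeposited patient data, with the
#' statistical structure the analysis assumes. The cohort generator builds
#' per-case 3D phantoms: an ellipsoidal tumour mask in a textured volume
#' whose in-plane correlation length and contrast amplitude depend on the
#' response class (quantities co-occurrence/run-length features provably
#' respond to), an ADC map with a class-dependent mean shift generated on a
#' coarser diffusion-like grid and resampled at ingestion, three centres
#' with distinct voxel spacings, and an "automatic" mask derived from the
#' manual one by seeded perturbation to a controllable Dice overlap. All
#' generators are bit-reproducible given (spec, seed).
#'
#' @name synthetic-data
NULL

#' Cohort generator specification
#'
#' @param n_responders,n_nonresponders class sizes.
#' @param centres named list of voxel spacings (mm); defaults mirror a
#'   three-centre acquisition (A 0.43x0.43x4, B 0.47x0.47x3.5, C 0.8x0.8x3).
#' @param validation_fraction fraction of cases (per class) assigned to
#'   centre C as the external validation set, when `"C"` is present.
#' @param test_fraction fraction of construction cases held out as the
#'   construction-test split.
#' @param extent_mm physical field of view (mm).
#' @param radius_range_mm tumour equatorial radius range (mm).
#' @param texture per-class texture parameters: in-plane correlation length
#'   of the T2w random field in voxels (`corr_vox`) and contrast amplitude;
#'   `jitter_sd` is the log-normal sd of the per-case variation of both,
#'   emulating biological heterogeneity within a class. The correlation
#'   length is defined on the native voxel grid so that the class texture
#'   signature is comparable across centres with different spacings, much
#'   as fixed-bin-count discretization normalises intensity scales.
#' @param adc per-class ADC parameters (10^-3 mm^2/s units): ROI mean,
#'   voxel noise `sd`, and `between_sd`, the case-level sd of the ROI mean
#'   within a class. Between-case variance is what keeps ROI-averaged
#'   features honestly noisy; without it every case of a class would share
#'   an essentially identical ADC mean and any classifier would separate
#'   the classes perfectly.
#' @param mask_dsc target Dice of the automatic mask against the manual one.
#' @param trg_probs within-class TRG sampling probabilities (responders
#'   over grades 1:2, nonresponders over 3:4), defaulting to the cohort
#'   marginals 16:26 and 26:27.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders = 10, n_nonresponders = 10,
                        centres = list(A = c(0.43, 0.43, 4),
                                       B = c(0.47, 0.47, 3.5),
                                       C = c(0.8, 0.8, 3)),
                        validation_fraction = 1 / 3,
                        test_fraction = 0.3,
                        extent_mm = c(34, 34, 28),
                        radius_range_mm = c(5.5, 8),
                        texture = list(
                          responder = list(corr_vox = 2.0, contrast = 60),
                          nonresponder = list(corr_vox = 1.25, contrast = 85),
                          jitter_sd = 0.25),
                        adc = list(responder = list(mean = 1.30, sd = 0.12,
                                                    between_sd = 0.10),
                                   nonresponder = list(mean = 1.05, sd = 0.12,
                                                       between_sd = 0.10)),
                        mask_dsc = 0.8,
                        trg_probs = list(responder = c(16, 26) / 42,
                                         nonresponder = c(26, 27) / 53),
                        seed = 1L) {
  stopifnot(n_responders >= 1, n_nonresponders >= 1,
            mask_dsc > 0, mask_dsc <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# separable Gaussian smoothing of a matrix, edge-renormalized
.smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n); j <- i + d
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# ellipsoid mask centred in a grid, radii in mm
.ellipsoid_mask <- function(dims, spacing, radii_mm, centre_mm = NULL) {
  if (is.null(centre_mm)) centre_mm <- (dims - 1) / 2 * spacing
  cx <- .axis_coords(dims[1], spacing[1])
  cy <- .axis_coords(dims[2], spacing[2])
  cz <- .axis_coords(dims[3], spacing[3])
  d2 <- outer(outer(((cx - centre_mm[1]) / radii_mm[1])^2,
                    ((cy - centre_mm[2]) / radii_mm[2])^2, "+"),
              ((cz - centre_mm[3]) / radii_mm[3])^2, "+")
  (d2 <= 1) + 0L
}

#' Generate a synthetic cohort
#'
#' Cases are allocated to centres and splits the way the study cohort was
#' organised: centre C cases form the external validation set; centres A
#' and B share the construction cases, which are further split (stratified
#' by class) into construction-train and construction-test. TRG is sampled
#' within class, consistently with the class label.
#'
#' @param spec a [cohort_spec()].
#' @return list of `study_case` objects.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  labels <- c(rep("responder", spec$n_responders),
              rep("nonresponder", spec$n_nonresponders))
  n <- length(labels)
  cn <- names(spec$centres)
  has_val <- "C" %in% cn
  constr_cn <- setdiff(cn, "C")
  centre_of <- character(n); split_of <- character(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nv <- if (has_val && length(constr_cn))
      round(spec$validation_fraction * length(idx))
    else if (has_val) length(idx) else 0
    vidx <- if (nv > 0) idx[seq_len(nv)] else integer(0)
    centre_of[vidx] <- "C"; split_of[vidx] <- "validation"
    cidx <- setdiff(idx, vidx)
    if (length(cidx)) {
      if (!length(constr_cn)) stop("no construction centre available")
      centre_of[cidx] <- rep_len(constr_cn, length(cidx))
      nt <- max(1, round(spec$test_fraction * length(cidx)))
      te <- cidx[seq_len(min(nt, length(cidx) - 1))]
      split_of[te] <- "construction-test"
      split_of[setdiff(cidx, te)] <- "construction-train"
    }
  }
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((spec$seed * 1000L + i) %% .Machine$integer.max)
    cl <- labels[i]
    sp <- spec$centres[[centre_of[i]]]
    dims <- pmax(8L, round(spec$extent_mm / sp))
    r_eq <- stats::runif(1, spec$radius_range_mm[1], spec$radius_range_mm[2])
    radii <- c(r_eq, r_eq * stats::runif(1, 0.8, 1), r_eq * 0.85)
    mask_arr <- .ellipsoid_mask(dims, sp, radii)
    tx <- spec$texture[[cl]]
    jit <- if (is.null(spec$texture$jitter_sd)) 0 else spec$texture$jitter_sd
    sigma_vox <- tx$corr_vox * exp(jit * stats::rnorm(1))
    contrast_i <- tx$contrast * exp(jit * stats::rnorm(1))
    vox <- array(0, dims)
    for (s in seq_len(dims[3]))
      vox[, , s] <- 400 + contrast_i *
        .smooth2d(matrix(stats::rnorm(dims[1] * dims[2]), dims[1]), sigma_vox) *
        sqrt(max(1, 4 * sigma_vox^2))   # keep amplitude ~contrast after smoothing
    t2w <- image_volume(vox, sp)
    # ADC on a coarser diffusion-like grid, resampled at ingestion
    adc_sp <- c(sp[1] * 2, sp[2] * 2, sp[3])
    adc_dims <- pmax(6L, round(spec$extent_mm / adc_sp))
    ap <- spec$adc[[cl]]
    bsd <- if (is.null(ap$between_sd)) 0 else ap$between_sd
    mu_i <- ap$mean + bsd * stats::rnorm(1)
    adc_vox <- array(mu_i + ap$sd * stats::rnorm(prod(adc_dims)), adc_dims)
    adc <- image_volume(adc_vox, adc_sp)
    manual <- segmentation_mask(mask_arr, sp, "manual")
    auto <- perturb_mask(manual, spec$mask_dsc,
                         seed = (spec$seed * 1000L + i + 500L) %%
                           .Machine$integer.max)
    trg_pool <- if (cl == "responder") 1:2 else 3:4
    trg <- sample(trg_pool, 1, prob = spec$trg_probs[[cl]])
    cases[[i]] <- study_case(sprintf("case_%03d", i), centre_of[i], t2w, adc,
                             list(manual = manual, automatic = auto),
                             trg, split_of[i])
  }
  cases
}

# one 6-connected morphological step on a 3D binary array
.morph3d <- function(arr, op = c("erode", "dilate")) {
  op <- match.arg(op)
  d <- dim(arr)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  cnt <- array(0L, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    idx <- lapply(1:3, function(a) (2:(d[a] + 1)) + if (a == ax) s else 0L)
    cnt <- cnt + pad[idx[[1]], idx[[2]], idx[[3]]]
  }
  if (op == "erode") ((arr == 1L) & (cnt == 6L)) + 0L
  else ((arr == 1L) | (cnt > 0L)) + 0L
}

.translate3d <- function(arr, shift) {
  d <- dim(arr)
  out <- array(0L, d)
  src <- dst <- list()
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    src[[a]] <- if (s >= 0) 1:(d[a] - s) else (1 - s):d[a]
    dst[[a]] <- if (s >= 0) (1 + s):d[a] else 1:(d[a] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Perturb a mask to a target Dice overlap
#'
#' Emulates an automatic segmentation by combining a seeded translation
#' with boundary erosion/dilation, searched until the Dice similarity
#' against the original lies within `target_dsc` plus or minus 0.05. The
#' low-DSC regime (below 0.2) is supported so the construction-set
#' exclusion rule can be exercised.
#'
#' @param mask a `segmentation_mask`.
#' @param target_dsc target Dice in (0, 1].
#' @param seed RNG seed (translation direction).
#' @param tol acceptance half-width around the target.
#' @return a `segmentation_mask` with provenance `"automatic"`.
#' @export
perturb_mask <- function(mask, target_dsc, seed = 1L, tol = 0.05) {
  stopifnot(target_dsc > 0, target_dsc <= 1)
  if (target_dsc >= 1 - 1e-12)
    return(segmentation_mask(mask$voxels, mask$spacing, "automatic"))
  set.seed(seed)
  dir2 <- stats::rnorm(2)
  dir2 <- dir2 / sqrt(sum(dir2^2))
  base <- mask$voxels
  ref <- segmentation_mask(base, mask$spacing, "manual")
  d <- dim(base)
  dice_of <- function(cand) dice(segmentation_mask(cand, mask$spacing,
                                                   "automatic",
                                                   allow_empty = TRUE),
                                 ref)$value
  # coarse stage: translation plus boundary erosion/dilation; keep the
  # candidate with the smallest dice still at or above the target
  best_hi <- base; best_hi_d <- 1
  for (step in 0:max(d)) {
    tr <- .translate3d(base, c(round(dir2 * step), 0L))
    for (morph in -2:2) {
      cand <- tr
      if (morph < 0) for (j in seq_len(-morph)) cand <- .morph3d(cand, "erode")
      if (morph > 0) for (j in seq_len(morph)) cand <- .morph3d(cand, "dilate")
      if (sum(cand) == 0) next
      dc <- dice_of(cand)
      if (abs(dc - target_dsc) <= tol)
        return(segmentation_mask(cand, mask$spacing, "automatic"))
      if (dc >= target_dsc && dc < best_hi_d) { best_hi <- cand; best_hi_d <- dc }
    }
    if (dice_of(tr) < max(0, target_dsc - 2 * tol)) break
  }
  # fine stage: peel random boundary voxels off the closest from-above
  # candidate; each voxel moves the dice by about 2 / (|a| + |b|)
  cand <- best_hi; dc <- best_hi_d
  for (attempt in 1:500) {
    if (abs(dc - target_dsc) <= tol)
      return(segmentation_mask(cand, mask$spacing, "automatic"))
    if (dc < target_dsc - tol) break
    boundary <- which(cand == 1L & .morph3d(cand, "erode") == 0L)
    if (length(boundary) < 2) break
    n_flip <- max(1, min(length(boundary) - 1,
                         floor((dc - target_dsc) * sum(cand) * 0.5)))
    cand[sample(boundary, n_flip)] <- 0L
    if (sum(cand) == 0) break
    dc <- dice_of(cand)
  }
  stop(sprintf("could not reach target DSC %.2f (closest %.3f)",
               target_dsc, dc))
}

#' Tabular feature-set generator
#'
#' Multivariate normal feature table with a known informative structure:
#' `n_informative` features carry a standardized class mean shift `d`, each
#' paired with a duplicate correlated at `r`; the remaining columns are
#' pure noise. Ground truth is recorded in attributes
#' `informative_features` and `duplicate_features`.
#'
#' @param n_cases number of cases.
#' @param n_features total features (catalogue names are used at 157).
#' @param n_informative informative originals.
#' @param d standardized class shift of informative features.
#' @param r correlation of each duplicate with its original.
#' @param class_balance fraction of responders.
#' @param test_fraction construction-test fraction.
#' @param seed RNG seed.
#' @return data.frame feature table with metadata columns.
#' @export
generate_feature_table <- function(n_cases = 67, n_features = 157,
                                   n_informative = 10, d = 0.8, r = 0.9,
                                   class_balance = 0.4, test_fraction = 0.3,
                                   seed = 1L) {
  stopifnot(2 * n_informative <= n_features, abs(r) < 1)
  set.seed(seed)
  feats <- if (n_features == 157) feature_catalogue()$name
           else sprintf("f%03d", seq_len(n_features))
  n1 <- max(1, round(class_balance * n_cases))
  y <- c(rep(1, n1), rep(0, n_cases - n1))
  x <- matrix(stats::rnorm(n_cases * n_features), n_cases, n_features,
              dimnames = list(NULL, feats))
  info <- sample(feats, n_informative)
  dup_src <- info
  dup <- sample(setdiff(feats, info), n_informative)
  for (k in seq_len(n_informative)) {
    base <- stats::rnorm(n_cases) + d * y
    x[, info[k]] <- base
    x[, dup[k]] <- r * (base - d * y) + sqrt(1 - r^2) * stats::rnorm(n_cases) +
      d * y
  }
  trg <- ifelse(y == 1, sample(1:2, n_cases, TRUE, c(16, 26) / 42),
                sample(3:4, n_cases, TRUE, c(26, 27) / 53))
  split <- rep("construction-train", n_cases)
  for (cl in c(0, 1)) {
    idx <- which(y == cl)
    nt <- max(1, round(test_fraction * length(idx)))
    split[sample(idx, nt)] <- "construction-test"
  }
  out <- data.frame(id = sprintf("case_%03d", seq_len(n_cases)),
                    centre = "A", trg = trg,
                    label = ifelse(y == 1, "responder", "nonresponder"),
                    split = split, provenance = "manual", x,
                    check.names = FALSE)
  attr(out, "informative_features") <- info
  attr(out, "duplicate_features") <- stats::setNames(dup, dup_src)
  out
}

#' Write a cohort to disk in the layout [read_cohort()] expects
#'
#' @param cases list of `study_case` objects.
#' @param dir output directory (created).
#' @return path of the clinical CSV.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cs) {
    t2p <- paste0(cs$id, "_t2w.nii.gz"); adp <- paste0(cs$id, "_adc.nii.gz")
    mmp <- paste0(cs$id, "_mask_manual.nii.gz")
    write_volume(cs$t2w, file.path(dir, t2p))
    write_volume(cs$adc, file.path(dir, adp))
    write_volume(cs$masks$manual, file.path(dir, mmp))
    map <- ""
    if (!is.null(cs$masks$automatic)) {
      map <- paste0(cs$id, "_mask_automatic.nii.gz")
      write_volume(cs$masks$automatic, file.path(dir, map))
    }
    data.frame(id = cs$id, centre = cs$centre, trg = cs$trg, split = cs$split,
               t2w_path = t2p, adc_path = adp, mask_manual = mmp,
               mask_automatic = map)
  })
  csv <- file.path(dir, "clinical.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  csv
}
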