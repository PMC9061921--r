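#' Texture feature computation
#'
#' Feature definitions follow the reference co-occurrence / run-length /
#' size-zone / grey-tone-difference / dependence formulations used across
#' standardised radiomics software, computed per slice (and per in-plane
#' direction where the family is directional) and aggregated by the 2.5D
#' averaged scheme. Degenerate conventions, applied consistently here and
#' documented per feature: correlation and information measures are 0 when a
#' marginal variance/entropy vanishes; NGTDM coarseness is capped at 1e6
#' when its denominator vanishes; busyness and strength are 0 when their
#' denominators vanish. Features of an empty matrix are an error.
#'
#' @name texture-features
NULL

.xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' GLCM features (25)
#'
#' @param m a `texture_matrix` of family `"glcm"`.
#' @return named numeric vector following the catalogue order.
#' @export
glcm_features <- function(m) {
  P <- m$p
  if (sum(P) == 0) stop("empty co-occurrence matrix")
  ng <- m$n_levels
  i <- seq_len(ng)
  I <- matrix(i, ng, ng); J <- t(I)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px)); sy <- sqrt(sum((i - muy)^2 * py))
  # diagonal-sum / diagonal-difference marginals
  ks <- 2:(2 * ng); kd <- 0:(ng - 1)
  psum <- as.vector(rowsum(as.vector(P), as.vector(I + J)))
  pdiff <- as.vector(rowsum(as.vector(P), as.vector(abs(I - J))))
  da <- sum(kd * pdiff)
  sa <- sum(ks * psum)
  hxy <- -sum(.xlog2(P))
  pxpy <- outer(px, py)
  hxy1 <- -sum(ifelse(P > 0 & pxpy > 0, P * log2(pxpy), 0))
  hxy2 <- -sum(.xlog2(pxpy))
  hx <- -sum(.xlog2(px)); hy <- -sum(.xlog2(py))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sx > 0 && sy > 0) (sum(I * J * P) - mux * muy) / (sx * sy) else 0
  c(autocorrelation = sum(I * J * P),
    cluster_prominence = sum((I + J - mux - muy)^4 * P),
    cluster_shade = sum((I + J - mux - muy)^3 * P),
    cluster_tendency = sum((I + J - mux - muy)^2 * P),
    contrast = sum((I - J)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(.xlog2(pdiff)),
    difference_variance = sum((kd - da)^2 * pdiff),
    dissimilarity = sum(abs(I - J) * P),
    id = sum(P / (1 + abs(I - J))),
    idm = sum(P / (1 + (I - J)^2)),
    idmn = sum(P / (1 + (I - J)^2 / ng^2)),
    idn = sum(P / (1 + abs(I - J) / ng)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_variance = sum(pdiff[kd > 0] / kd[kd > 0]^2),
    joint_average = mux,
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    joint_maximum = max(P),
    sum_average = sa,
    sum_entropy = -sum(.xlog2(psum)),
    sum_squares = sum((I - mux)^2 * P),
    sum_variance = sum((ks - sa)^2 * psum))
}

# shared body for the run-length / size-zone style families: counts indexed
# by grey level x size-like quantity, normalizer nrm, pixel count np
.rl_style_features <- function(counts, np) {
  ns <- sum(counts)
  if (ns == 0) stop("empty texture matrix")
  i <- seq_len(nrow(counts)); j <- seq_len(ncol(counts))
  I <- matrix(i, length(i), length(j)); J <- t(matrix(j, length(j), length(i)))
  p <- counts / ns
  mu_i <- sum(I * p); mu_j <- sum(J * p)
  list(se = sum(counts / J^2) / ns,
       le = sum(counts * J^2) / ns,
       gln = sum(rowSums(counts)^2) / ns,
       glnn = sum(rowSums(counts)^2) / ns^2,
       sn = sum(colSums(counts)^2) / ns,
       snn = sum(colSums(counts)^2) / ns^2,
       pct = ns / np,
       glv = sum((I - mu_i)^2 * p),
       sv = sum((J - mu_j)^2 * p),
       ent = -sum(.xlog2(p)),
       lgle = sum(counts / I^2) / ns,
       hgle = sum(counts * I^2) / ns,
       slgle = sum(counts / (I^2 * J^2)) / ns,
       shgle = sum(counts * I^2 / J^2) / ns,
       llgle = sum(counts * J^2 / I^2) / ns,
       lhgle = sum(counts * I^2 * J^2) / ns)
}

#' GLRLM features (16)
#' @param m a `texture_matrix` of family `"glrlm"`.
#' @export
glrlm_features <- function(m) {
  f <- .rl_style_features(m$counts, m$n_pixels)
  c(short_run_emphasis = f$se, long_run_emphasis = f$le,
    gray_level_nonuniformity = f$gln,
    gray_level_nonuniformity_normalized = f$glnn,
    run_length_nonuniformity = f$sn,
    run_length_nonuniformity_normalized = f$snn,
    run_percentage = f$pct, gray_level_variance = f$glv,
    run_variance = f$sv, run_entropy = f$ent,
    low_gray_level_run_emphasis = f$lgle,
    high_gray_level_run_emphasis = f$hgle,
    short_run_low_gray_level_emphasis = f$slgle,
    short_run_high_gray_level_emphasis = f$shgle,
    long_run_low_gray_level_emphasis = f$llgle,
    long_run_high_gray_level_emphasis = f$lhgle)
}

#' GLSZM features (16)
#' @param m a `texture_matrix` of family `"glszm"`.
#' @export
glszm_features <- function(m) {
  f <- .rl_style_features(m$counts, m$n_pixels)
  c(small_area_emphasis = f$se, large_area_emphasis = f$le,
    gray_level_nonuniformity = f$gln,
    gray_level_nonuniformity_normalized = f$glnn,
    size_zone_nonuniformity = f$sn,
    size_zone_nonuniformity_normalized = f$snn,
    zone_percentage = f$pct, gray_level_variance = f$glv,
    zone_variance = f$sv, zone_entropy = f$ent,
    low_gray_level_zone_emphasis = f$lgle,
    high_gray_level_zone_emphasis = f$hgle,
    small_area_low_gray_level_emphasis = f$slgle,
    small_area_high_gray_level_emphasis = f$shgle,
    large_area_low_gray_level_emphasis = f$llgle,
    large_area_high_gray_level_emphasis = f$lhgle)
}

#' NGTDM features (5)
#' @param m a `texture_matrix` of family `"ngtdm"`.
#' @export
ngtdm_features <- function(m) {
  n <- m$n; s <- m$s
  N <- sum(n)
  if (N == 0) stop("empty grey-tone difference matrix")
  p <- n / N
  i <- seq_along(n)
  pr <- p > 0
  ngp <- sum(pr)
  ip <- i[pr]; pp <- p[pr]; sp <- s[pr]
  coarse_den <- sum(pp * sp)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1)
    sum(outer(pp, pp) * outer(ip, ip, function(a, b) (a - b)^2)) /
      (ngp * (ngp - 1)) * sum(s) / N else 0
  busy_den <- sum(abs(outer(ip * pp, ip * pp, "-")))
  busyness <- if (busy_den > 0) sum(pp * sp) / busy_den else 0
  Dif <- abs(outer(ip, ip, "-"))
  complexity <- sum(Dif * (outer(pp * sp, pp * sp, "+")) /
                      outer(pp, pp, "+")) / N
  strength <- if (sum(s) > 0)
    sum(outer(pp, pp, "+") * outer(ip, ip, function(a, b) (a - b)^2)) /
      sum(s) else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' GLDM features (14)
#' @param m a `texture_matrix` of family `"gldm"`.
#' @export
gldm_features <- function(m) {
  f <- .rl_style_features(m$counts, sum(m$counts))
  c(small_dependence_emphasis = f$se, large_dependence_emphasis = f$le,
    gray_level_nonuniformity = f$gln,
    dependence_nonuniformity = f$sn,
    dependence_nonuniformity_normalized = f$snn,
    gray_level_variance = f$glv,
    dependence_variance = f$sv, dependence_entropy = f$ent,
    low_gray_level_emphasis = f$lgle,
    high_gray_level_emphasis = f$hgle,
    small_dependence_low_gray_level_emphasis = f$slgle,
    small_dependence_high_gray_level_emphasis = f$shgle,
    large_dependence_low_gray_level_emphasis = f$llgle,
    large_dependence_high_gray_level_emphasis = f$lhgle)
}

#' Compute the features of one texture matrix
#'
#' @param family matrix family.
#' @param m the matrix from [build_texture_matrix()].
#' @return named numeric vector.
#' @export
compute_family_features <- function(family, m) {
  switch(match.arg(family, c("glcm", "glrlm", "glszm", "ngtdm", "gldm")),
         glcm = glcm_features(m), glrlm = glrlm_features(m),
         glszm = glszm_features(m), ngtdm = ngtdm_features(m),
         gldm = gldm_features(m))
}

#' 2.5D slice-averaged aggregation
#'
#' Directional families (GLCM, GLRLM) are averaged over the four in-plane
#' directions within each slice, then unweighted over slices, making the
#' aggregate invariant to in-plane rotations by multiples of 90 degrees.
#' Non-directional families average over slices only.
#'
#' @param values for directional families a list (slices) of lists
#'   (directions) of named vectors; otherwise a list (slices) of named
#'   vectors.
#' @return per-feature scalar vector.
#' @export
aggregate_25d <- function(values) {
  if (!length(values)) stop("no retained slices to aggregate")
  per_slice <- lapply(values, function(v) {
    if (is.list(v)) Reduce(`+`, v) / length(v) else v
  })
  Reduce(`+`, per_slice) / length(per_slice)
}

#' First-order ADC statistics
#'
#' Mean, sample standard deviation (n-1 denominator), skewness (m3/m2^1.5)
#' and uncorrected kurtosis (m4/m2^2, so a normal sample scores about 3) of
#' the raw in-mask ADC values. ADC is treated as intrinsically normalised:
#' no rescaling is applied. A degenerate (constant) sample returns 0 for
#' skewness and kurtosis by convention.
#'
#' @param values numeric vector of re-segmented in-mask ADC intensities.
#' @return named vector `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
adc_first_order <- function(values) {
  if (length(values) < 2) stop("need at least two ADC values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  c(mean = m,
    sd = stats::sd(values),
    skewness = mean((values - m)^3) / m2^1.5,
    kurtosis = mean((values - m)^4) / m2^2)
}

# features of one matrix, or NULL when the matrix holds no mass (a slice can
# lack neighbouring pairs along a direction); such entries are dropped from
# the 2.5D average rather than poisoning it
.try_family <- function(fam, sl, n_levels, direction = "0") {
  tryCatch(compute_family_features(
    fam, build_texture_matrix(fam, sl, n_levels, direction = direction,
                              min_slice_pixels = 1)),
    error = function(e) NULL)
}

# all 76 texture features of one modality from its per-slice level grids
.modality_texture_features <- function(slices, n_levels) {
  fam_names <- texture_feature_names()
  dirs <- names(inplane_directions())
  out <- numeric(0)
  for (fam in names(fam_names)) {
    vals <- lapply(slices, function(sl) {
      if (fam %in% c("glcm", "glrlm")) {
        dv <- Filter(Negate(is.null),
                     lapply(dirs, function(d) .try_family(fam, sl, n_levels, d)))
        if (length(dv)) dv else NULL
      } else {
        .try_family(fam, sl, n_levels)
      }
    })
    vals <- Filter(Negate(is.null), vals)
    if (!length(vals))
      stop("no slice supports ", fam, " features")
    agg <- aggregate_25d(vals)
    names(agg) <- paste(fam, fam_names[[fam]], sep = ".")
    out <- c(out, agg)
  }
  out
}

#' Extract the full 157-feature vector of one case
#'
#' Runs per-modality re-segmentation and discretization under the requested
#' mask provenance, computes the T2w shape feature, the four ADC first-order
#' statistics, and the 76 texture features per modality with 2.5D
#' aggregation.
#'
#' @param case a `study_case`.
#' @param provenance which mask to use, `"manual"` or `"automatic"`.
#' @param cfg a [preprocessing_config()].
#' @return named numeric vector over the catalogue's 157 names.
#' @export
extract_case_features <- function(case, provenance = "manual",
                                  cfg = preprocessing_config()) {
  mask <- case$masks[[provenance]]
  if (is.null(mask)) stop("case ", case$id, " has no ", provenance, " mask")
  out <- tryCatch({
    v <- c(t2w.shape.roi_volume = roi_volume_mm3(mask, case$t2w$spacing))
    adc_mask <- resegment(case$adc, mask, cfg)
    fo <- adc_first_order(case$adc$voxels[adc_mask$voxels == 1])
    names(fo) <- paste("adc.firstorder", adc_firstorder_names(), sep = ".")
    v <- c(v, fo)
    for (mod in c("t2w", "adc")) {
      vol <- case[[mod]]
      rmask <- if (mod == "adc") adc_mask else resegment(vol, mask, cfg)
      droi <- discretize(vol, rmask, cfg, modality = mod)
      slices <- slice_decompose(droi, cfg$min_slice_pixels)
      tf <- .modality_texture_features(slices, cfg$bin_count)
      names(tf) <- paste(mod, names(tf), sep = ".")
      v <- c(v, tf)
    }
    v
  }, error = function(e)
    stop("feature extraction failed for case ", case$id, " (", provenance,
         "): ", conditionMessage(e), call. = FALSE))
  cat_names <- feature_catalogue()$name
  out <- out[cat_names]
  if (any(is.na(out)) || any(!is.finite(out)))
    stop("non-finite features for case ", case$id)
  out
}

#' Extract the feature table of a cohort
#'
#' One row per (case, provenance); metadata columns `id`, `centre`, `trg`,
#' `label`, `split`, `provenance` precede the 157 catalogue columns.
#'
#' @param cases list of `study_case` objects.
#' @param provenances provenance tracks to extract (those present per case).
#' @param cfg a [preprocessing_config()].
#' @return data.frame feature table.
#' @export
extract_feature_table <- function(cases, provenances = c("manual", "automatic"),
                                  cfg = preprocessing_config()) {
  rows <- list()
  for (case in cases) for (pv in intersect(provenances, names(case$masks))) {
    fv <- extract_case_features(case, pv, cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      id = case$id, centre = case$centre, trg = case$trg, label = case$label,
      split = case$split, provenance = pv, t(fv), check.names = FALSE)
  }
  do.call(rbind, rows)
}

#' Metadata column names of a feature table
#' @export
feature_table_meta_cols <- function()
  c("id", "centre", "trg", "label", "split", "provenance")
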