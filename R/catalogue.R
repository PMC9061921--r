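#' The 157-feature radiomics catalogue
#'
#' One shape feature (ROI volume from the T2w mask), four first-order
#' intensity statistics from the ADC map, and five texture families per
#' modality: 25 grey-level co-occurrence (GLCM), 16 run-length (GLRLM),
#' 16 size-zone (GLSZM), 5 neighbourhood grey-tone difference (NGTDM) and
#' 14 dependence (GLDM) features, i.e. 76 texture features per modality.
#' Total: 1 + 4 + 2 x 76 = 157 (77 T2w-derived, 80 ADC-derived).
#'
#' This catalogue is the single source of truth for feature names and
#' ordering; the extractor emits exactly these names.
#'
#' @return data.frame with columns `name`, `modality`, `family`, `feature`.
#' @export
feature_catalogue <- function() {
  fam <- texture_feature_names()
  rows <- list(data.frame(modality = "t2w", family = "shape",
                          feature = "roi_volume"))
  rows <- c(rows, list(data.frame(modality = "adc", family = "firstorder",
                                  feature = adc_firstorder_names())))
  for (mod in c("t2w", "adc"))
    for (f in names(fam))
      rows <- c(rows, list(data.frame(modality = mod, family = f,
                                      feature = fam[[f]])))
  out <- do.call(rbind, rows)
  out$name <- paste(out$modality, out$family, out$feature, sep = ".")
  rownames(out) <- NULL
  out[, c("name", "modality", "family", "feature")]
}

#' @rdname feature_catalogue
#' @export
adc_firstorder_names <- function() c("mean", "sd", "skewness", "kurtosis")

#' Per-family texture feature names
#'
#' @return named list of character vectors, one per family.
#' @export
texture_feature_names <- function() {
  list(
    glcm = c("autocorrelation", "cluster_prominence", "cluster_shade",
             "cluster_tendency", "contrast", "correlation",
             "difference_average", "difference_entropy", "difference_variance",
             "dissimilarity", "id", "idm", "idmn", "idn", "imc1", "imc2",
             "inverse_variance", "joint_average", "joint_energy",
             "joint_entropy", "joint_maximum", "sum_average", "sum_entropy",
             "sum_squares", "sum_variance"),
    glrlm = c("short_run_emphasis", "long_run_emphasis",
              "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
              "run_length_nonuniformity", "run_length_nonuniformity_normalized",
              "run_percentage", "gray_level_variance", "run_variance",
              "run_entropy", "low_gray_level_run_emphasis",
              "high_gray_level_run_emphasis",
              "short_run_low_gray_level_emphasis",
              "short_run_high_gray_level_emphasis",
              "long_run_low_gray_level_emphasis",
              "long_run_high_gray_level_emphasis"),
    glszm = c("small_area_emphasis", "large_area_emphasis",
              "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
              "size_zone_nonuniformity", "size_zone_nonuniformity_normalized",
              "zone_percentage", "gray_level_variance", "zone_variance",
              "zone_entropy", "low_gray_level_zone_emphasis",
              "high_gray_level_zone_emphasis",
              "small_area_low_gray_level_emphasis",
              "small_area_high_gray_level_emphasis",
              "large_area_low_gray_level_emphasis",
              "large_area_high_gray_level_emphasis"),
    ngtdm = c("coarseness", "contrast", "busyness", "complexity", "strength"),
    gldm = c("small_dependence_emphasis", "large_dependence_emphasis",
             "gray_level_nonuniformity", "dependence_nonuniformity",
             "dependence_nonuniformity_normalized", "gray_level_variance",
             "dependence_variance", "dependence_entropy",
             "low_gray_level_emphasis", "high_gray_level_emphasis",
             "small_dependence_low_gray_level_emphasis",
             "small_dependence_high_gray_level_emphasis",
             "large_dependence_low_gray_level_emphasis",
             "large_dependence_high_gray_level_emphasis")
  )
}

#' Write the catalogue as JSON
#'
#' @param path output path.
#' @export
write_catalogue_json <- function(path) {
  jsonlite::write_json(feature_catalogue(), path, dataframe = "rows",
                       auto_unbox = TRUE)
  invisible(path)
}
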