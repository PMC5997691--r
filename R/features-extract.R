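# The 60-feature panel: manifest and per-lesion extraction.

.panel_hist <- c("mean", "median", "minimum", "maximum", "range", "sd",
                 "variance", "skewness", "kurtosis", "energy", "entropy",
                 "rms", "iqr", "mad", "upp", "p2_5", "p25", "p75", "p97_5")
.panel_nine <- c("mean", "median", "sd", "minimum", "maximum", "skewness",
                 "kurtosis", "energy", "entropy")
.panel_shape <- c("volume", "surface_area", "surface_to_volume", "compactness",
                  "sphericity", "convexity", "max_3d_diameter", "elongation",
                  "density", "mass")
.panel_glcm <- c("glcm_autocorrelation", "glcm_contrast", "glcm_correlation",
                 "glcm_dissimilarity", "glcm_energy", "glcm_entropy",
                 "glcm_homogeneity", "glcm_cluster_shade",
                 "glcm_cluster_prominence", "glcm_sum_average", "glcm_variance")
.panel_isz <- c("intensity_variability", "size_zone_variability")

#' The 60-feature panel manifest
#'
#' Names and categories of the fixed feature panel: 19 whole-ROI histogram
#' features, 9 outer-rim and 9 core-minus-rim (delta) partition features,
#' 10 shape features, 11 GLCM features and 2 intensity size-zone features.
#' A versioned YAML copy ships in `inst/extdata/feature_manifest.yaml`.
#'
#' @return A data.frame with columns `name` and `category`
#'   (`histogram`, `outer`, `delta`, `shape`, `glcm`, `iszm`), 60 rows.
#' @export
feature_manifest <- function() {
  df <- data.frame(
    name = c(.panel_hist,
             paste0(.panel_nine, "_outer"),
             paste0(.panel_nine, "_delta"),
             .panel_shape, .panel_glcm, .panel_isz),
    category = c(rep("histogram", length(.panel_hist)),
                 rep("outer", length(.panel_nine)),
                 rep("delta", length(.panel_nine)),
                 rep("shape", length(.panel_shape)),
                 rep("glcm", length(.panel_glcm)),
                 rep("iszm", length(.panel_isz))),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(df) == 60L, !anyDuplicated(df$name))
  df
}

new_feature_vector <- function(values, reasons, patient_id = NULL,
                               lesion_id = NULL, n_lesions = NULL) {
  manifest <- feature_manifest()
  stopifnot(identical(names(values), manifest$name))
  structure(list(values = values, reasons = reasons,
                 patient_id = patient_id, lesion_id = lesion_id,
                 n_lesions = n_lesions),
            class = "feature_vector")
}

block_or_na <- function(expr, names_) {
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    list(values = stats::setNames(rep(NA_real_, length(names_)), names_),
         reasons = stats::setNames(rep(conditionMessage(res), length(names_)), names_))
  } else res
}

#' Extract the full 60-feature panel from one lesion
#'
#' Composes histogram (19), partition outer/delta (9 + 9), shape (10), GLCM
#' (11) and size-zone (2) features into one named vector of exactly 60
#' entries. Extraction is deterministic; a failing component records its
#' features as missing with the failure reason rather than dropping keys.
#'
#' @param lesion a [lesion_record()] with image and mask present, or a list
#'   with elements `image` and `mask`.
#' @param glcm_levels,iszm_levels gray-level discretization (defaults 256
#'   and 32).
#' @return An object of class `feature_vector`: `values` (named numeric,
#'   60 entries in manifest order), `reasons` (named character for missing
#'   entries), plus patient/lesion ids when available.
#' @export
extract_features <- function(lesion, glcm_levels = 256L, iszm_levels = 32L) {
  image <- lesion$image
  mask <- lesion$mask
  if (is.null(image) || is.null(mask))
    stopf("lesion has no image/mask attached")
  check_alignment(image, mask)
  fg_vals <- image$voxels[mask$voxels > 0]

  hist_b <- block_or_na(histogram_features(fg_vals), .panel_hist)
  part_b <- block_or_na({
    part <- partition_roi(mask)
    partition_features(image, part)
  }, c(paste0(.panel_nine, "_outer"), paste0(.panel_nine, "_delta")))
  shape_b <- block_or_na(shape_features(mask, image), .panel_shape)
  glcm_b <- block_or_na({
    G <- glcm_matrix(image, mask, levels = glcm_levels)
    list(values = glcm_features(G), reasons = character(0))
  }, .panel_glcm)
  isz_b <- block_or_na({
    Z <- iszm_matrix(image, mask, levels = iszm_levels)
    list(values = iszm_features(Z), reasons = character(0))
  }, .panel_isz)

  values <- c(hist_b$values, part_b$values, shape_b$values,
              glcm_b$values, isz_b$values)
  stopifnot(identical(names(values), feature_manifest()$name))
  reasons <- c(hist_b$reasons, part_b$reasons, shape_b$reasons,
               glcm_b$reasons, isz_b$reasons)
  new_feature_vector(values, reasons,
                     patient_id = lesion$patient_id %||% NULL,
                     lesion_id = lesion$lesion_id %||% NULL)
}

#' @export
print.feature_vector <- function(x, ...) {
  who <- paste(c(x$patient_id, x$lesion_id), collapse = " / ")
  cat(sprintf("Radiomic feature vector%s: %d features, %d missing\n",
              if (nzchar(who)) paste0(" (", who, ")") else "",
              length(x$values), sum(is.na(x$values))))
  cats <- split(x$values, feature_manifest()$category)
  for (nm in names(cats))
    cat(sprintf("  %-9s %2d features\n", nm, length(cats[[nm]])))
  invisible(x)
}
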