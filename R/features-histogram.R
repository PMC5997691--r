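# Histogram (first-order intensity) features.
#
# Conventions, fixed in the shipped feature manifest:
#   * skewness = m3 / m2^1.5 and kurtosis = m4 / m2^2 use population (1/N)
#     central moments; kurtosis is Pearson (non-excess, Gaussian = 3);
#   * sd / variance are the sample (N-1) estimators;
#   * energy = sum(x^2) (intensity-based), RMS = sqrt(energy / N);
#   * entropy is Shannon entropy (bits) over 256 fixed-width bins spanning
#     the sample's own [min, max];
#   * UPP (uniformity of positive gray-level values) = sum of squared bin
#     probabilities over bins whose center is > 0 HU;
#   * percentiles use linear interpolation (quantile type 7); MAD is the
#     plain median absolute deviation from the median (no consistency
#     constant).

hist_entropy_upp <- function(x, bins = 256L) {
  mn <- min(x)
  mx <- max(x)
  if (mx <= mn) {
    return(list(entropy = 0, upp = if (mn > 0) 1 else 0))
  }
  b <- pmin(bins, as.integer(floor((x - mn) / (mx - mn) * bins)) + 1L)
  p <- tabulate(b, nbins = bins) / length(x)
  centers <- mn + (seq_len(bins) - 0.5) * (mx - mn) / bins
  list(entropy = -sum(p[p > 0] * log2(p[p > 0])),
       upp = sum(p[centers > 0]^2))
}

#' Whole-ROI histogram features (19)
#'
#' First-order features of the HU intensity distribution inside an ROI.
#' On constant input the second central moment vanishes and skewness /
#' kurtosis are reported as missing with a reason; the other 17 features are
#' still returned.
#'
#' @param values numeric vector of ROI intensities (HU), length >= 2.
#' @return A list with `values` (named numeric, 19 entries) and `reasons`
#'   (named character vector for missing entries).
#' @export
histogram_features <- function(values) {
  if (length(values) < 2) stopf("need at least 2 intensity values")
  if (any(!is.finite(values))) stopf("intensities must be finite")
  n <- length(values)
  mo <- pop_moments(values)
  qs <- stats::quantile(values, c(0.025, 0.25, 0.75, 0.975), names = FALSE, type = 7)
  eu <- hist_entropy_upp(values)
  energy <- sum(values^2)
  med <- stats::median(values)
  out <- c(
    mean = mean(values),
    median = med,
    minimum = min(values),
    maximum = max(values),
    range = max(values) - min(values),
    sd = stats::sd(values),
    variance = stats::var(values),
    skewness = if (mo$m2 > 0) mo$m3 / mo$m2^1.5 else NA_real_,
    kurtosis = if (mo$m2 > 0) mo$m4 / mo$m2^2 else NA_real_,
    energy = energy,
    entropy = eu$entropy,
    rms = sqrt(energy / n),
    iqr = qs[3] - qs[2],
    mad = stats::median(abs(values - med)),
    upp = eu$upp,
    p2_5 = qs[1],
    p25 = qs[2],
    p75 = qs[3],
    p97_5 = qs[4]
  )
  reasons <- character(0)
  if (mo$m2 <= 0)
    reasons <- c(skewness = "constant input: second central moment is zero",
                 kurtosis = "constant input: second central moment is zero")
  list(values = out, reasons = reasons)
}

# The nine-feature subset computed on each partition sub-ROI. Energy here is
# the per-voxel mean square rather than the raw sum of squares: the core and
# rim differ in voxel count by construction (2 : 1), so the extensive sum
# would make every energy delta a volume artifact rather than an intensity
# contrast.
partition_nine <- function(values) {
  if (length(values) < 2) stopf("sub-ROI has fewer than 2 voxels")
  mo <- pop_moments(values)
  eu <- hist_entropy_upp(values)
  out <- c(
    mean = mean(values),
    median = stats::median(values),
    sd = stats::sd(values),
    minimum = min(values),
    maximum = max(values),
    skewness = if (mo$m2 > 0) mo$m3 / mo$m2^1.5 else NA_real_,
    kurtosis = if (mo$m2 > 0) mo$m4 / mo$m2^2 else NA_real_,
    energy = mean(values^2),
    entropy = eu$entropy
  )
  reasons <- character(0)
  if (mo$m2 <= 0)
    reasons <- c(skewness = "constant sub-ROI: second central moment is zero",
                 kurtosis = "constant sub-ROI: second central moment is zero")
  list(values = out, reasons = reasons)
}

#' Partition-based histogram features (9 outer + 9 delta)
#'
#' Computes the nine-feature subset (mean, median, sd, minimum, maximum,
#' skewness, kurtosis, energy, entropy) separately on the inner (core) and
#' outer (rim) sub-ROIs and reports the outer values (suffix `_outer`) and
#' the inner-minus-outer differences (suffix `_delta`). Inner values are an
#' intermediate only; an undefined moment on a constant sub-ROI propagates
#' as missing-with-reason to the affected outputs. Sub-ROI energy is the
#' per-voxel mean square, so that deltas compare intensity content rather
#' than the fixed 2:1 core/rim volume ratio.
#'
#' @param image an [image_volume()].
#' @param part a [partition_roi()] result aligned with `image`.
#' @return A list with `values` (named numeric, 18 entries) and `reasons`.
#' @export
partition_features <- function(image, part) {
  stopifnot(inherits(image, "image_volume"), inherits(part, "partitioned_roi"))
  inner_vals <- image$voxels[part$inner$voxels > 0]
  outer_vals <- image$voxels[part$outer$voxels > 0]
  inn <- partition_nine(inner_vals)
  out <- partition_nine(outer_vals)
  delta <- inn$values - out$values
  values <- c(stats::setNames(out$values, paste0(names(out$values), "_outer")),
              stats::setNames(delta, paste0(names(inn$values), "_delta")))
  reasons <- character(0)
  if (length(out$reasons))
    reasons <- c(reasons, stats::setNames(
      paste0("outer: ", out$reasons), paste0(names(out$reasons), "_outer")))
  for (nm in union(names(inn$reasons), names(out$reasons))) {
    reasons[paste0(nm, "_delta")] <- "undefined on a constant sub-ROI"
  }
  list(values = values, reasons = reasons)
}
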