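# Patient-level aggregation of lesion features and univariate logistic
# screening against the binary marker label.

#' Aggregate lesion feature vectors to one patient vector
#'
#' Element-wise arithmetic mean over the patient's (up to five) selected
#' lesions. Missing-with-reason entries are excluded pairwise, i.e. each
#' feature is averaged over the lesions where it is defined; a feature
#' missing in every lesion stays missing.
#'
#' @param vectors list of 1-5 [extract_features()] results sharing one
#'   key set (and, normally, one patient).
#' @return A `feature_vector` with `n_lesions` set.
#' @export
aggregate_patient <- function(vectors) {
  if (length(vectors) < 1 || length(vectors) > 5)
    stopf("expected 1-5 lesion feature vectors, got %d", length(vectors))
  ref <- names(vectors[[1]]$values)
  for (v in vectors)
    if (!identical(names(v$values), ref))
      stopf("schema error: lesion feature vectors do not share one key set")
  vals <- do.call(rbind, lapply(vectors, function(v) v$values))
  out <- colMeans(vals, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  reasons <- character(0)
  all_na <- colSums(!is.na(vals)) == 0
  if (any(all_na))
    reasons <- stats::setNames(rep("missing in every lesion", sum(all_na)),
                               ref[all_na])
  pid <- unique(vapply(vectors, function(v) v$patient_id %||% NA_character_, character(1)))
  new_feature_vector(out, reasons,
                     patient_id = if (length(pid) == 1) pid else NULL,
                     n_lesions = length(vectors))
}

#' Univariate logistic screening of one covariate
#'
#' Maximum-likelihood fit of `logit P(y = 1) = b0 + b1 x` by iteratively
#' reweighted least squares (tolerance 1e-8, at most 50 iterations, via
#' `stats::glm`). Continuous predictors are standardized to zero mean / unit
#' SD before fitting, so the odds ratio is per SD; two-level predictors are
#' coded 0/1 and left unscaled. Complete separation is flagged (odds ratio
#' unreported) rather than raised.
#'
#' @param x covariate (numeric, factor, or character).
#' @param y binary 0/1 labels with both classes present.
#' @param name variable name for the output row.
#' @return A one-row data.frame (`screen_row`): `variable`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `direction`, `separated`, `n`.
#' @export
univariate_logistic <- function(x, y, name = deparse(substitute(x))) {
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1")
  if (length(unique(y)) < 2) stopf("labels must contain both classes")
  if (is.factor(x) || is.character(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) != 2) stopf("categorical screen variable must have 2 levels")
    x <- as.numeric(match(as.character(x), lev) - 1)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  ux <- unique(x)
  if (length(ux) < 2) stopf("covariate is constant")
  if (length(ux) == 2) {
    x <- as.numeric(x == max(ux))
  } else {
    x <- (x - mean(x)) / stats::sd(x)
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  co <- summary(fit)$coefficients
  b1 <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  separated <- !fit$converged || all(abs(fit$fitted.values - y) < 1e-6) || se > 100
  if (separated) {
    row <- data.frame(variable = name, odds_ratio = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, direction = NA_character_,
                      separated = TRUE, n = length(y),
                      stringsAsFactors = FALSE)
  } else {
    z <- b1 / se
    row <- data.frame(
      variable = name,
      odds_ratio = exp(b1),
      ci_low = exp(b1 - stats::qnorm(0.975) * se),
      ci_high = exp(b1 + stats::qnorm(0.975) * se),
      p_value = 2 * stats::pnorm(-abs(z)),
      direction = if (b1 > 0) "higher in positives" else "lower in positives",
      separated = FALSE, n = length(y),
      stringsAsFactors = FALSE)
  }
  class(row) <- c("screen_row", class(row))
  row
}

#' Screen all clinical variables and features against the marker label
#'
#' Runs [univariate_logistic()] for every clinical covariate (age, sex,
#' smoking, EGFR when present) and every feature column, against the binary
#' TS label. Rows are flagged significant at `p < alpha` with no multiplicity
#' correction by default (Benjamini-Hochberg available behind `adjust`).
#'
#' @param clinical cohort data.frame (see [validate_cohort()]).
#' @param features optional data.frame of patient-level features with a
#'   `patient_id` column; merged onto `clinical`.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame of screen rows with `significant` flag (and
#'   `p_adjusted` when `adjust = "BH"`).
#' @export
screen_all <- function(clinical, features = NULL, alpha = 0.05,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(clinical) < 20) stopf("need at least 20 patients to screen")
  y <- clinical$ts_label
  vars <- list(age = clinical$age, sex = clinical$sex, smoking = clinical$smoking)
  if ("egfr" %in% names(clinical)) {
    eg <- clinical$egfr
    eg[eg == "unknown"] <- NA
    vars$egfr <- eg
  }
  if ("suvmax" %in% names(clinical)) vars$suvmax <- clinical$suvmax
  feat_mat <- NULL
  if (!is.null(features)) {
    m <- match(clinical$patient_id, features$patient_id)
    feat_mat <- features[m, setdiff(names(features), c("patient_id", "lesion_id")), drop = FALSE]
    for (cn in names(feat_mat)) vars[[cn]] <- feat_mat[[cn]]
  }
  rows <- lapply(names(vars), function(nm) {
    tryCatch(univariate_logistic(vars[[nm]], y, name = nm),
             error = function(e) data.frame(
               variable = nm, odds_ratio = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, p_value = NA_real_,
               direction = NA_character_, separated = NA, n = NA_integer_,
               stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  } else {
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
  }
  class(out) <- c("screen_result", class(out))
  out
}
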