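# Kaplan-Meier estimation and two-group log-rank comparison of survival
# endpoints. The estimators are the standard ones from the survival package,
# exposed behind a small pipeline-facing surface; at tied times events
# precede censorings (the usual product-limit convention).

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (months), non-negative.
#' @param events binary event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve`: `time`, `surv` (with `S(0) = 1`
#'   prepended), `n_risk`, `n_event`, `n_censor`, `median` (NA when the
#'   curve never crosses 0.5).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stopf("empty input")
  if (any(times < 0)) stopf("times must be >= 0")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n_risk = c(length(times), fit$n.risk),
                 n_event = c(0, fit$n.event), n_censor = c(0, fit$n.censor),
                 median = med),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function lookup.
#'
#' @param curve a [km_estimate()] result.
#' @param t times at which to evaluate `S(t)`.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(t, curve$time)
  curve$surv[pmax(idx, 1)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, median %s\n",
              x$n_risk[1], sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ..., xlab = "Time (months)", ylab = "Survival probability") {
  graphics::plot(x$time, x$surv, type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  cens <- x$n_censor > 0
  if (any(cens))
    graphics::points(x$time[cens], x$surv[cens], pch = 3)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance,
#' referred to chi-square with 1 degree of freedom.
#'
#' @param times follow-up times.
#' @param events binary event indicators.
#' @param group two-group factor (or any vector with exactly 2 levels).
#' @return An object of class `logrank_result`: `chi_square`, `p_value`,
#'   `observed`, `expected` (per group), `n` (per group).
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (length(levels(group)) != 2) stopf("exactly 2 groups required")
  if (any(table(group) == 0)) stopf("one group is empty")
  if (sum(events) < 1) stopf("need at least one event")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group)
  chi <- unname(sd_$chisq)
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = as.numeric(sd_$obs),
                 expected = as.numeric(sd_$exp),
                 n = as.numeric(sd_$n),
                 groups = levels(group)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test (1 df)\n")
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: n = %d, observed %g, expected %.2f\n",
                x$groups[i], x$n[i], x$observed[i], x$expected[i]))
  cat(sprintf("  chi-square = %.3f, p = %.4g\n", x$chi_square, x$p_value))
  invisible(x)
}
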