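#' Per-study odds ratio with confidence interval
#'
#' One study's effect estimate as typically printed: an odds ratio with a
#' Wald confidence interval. The log odds ratio and its standard error are
#' back-calculated from the interval by [log_or_and_se()].
#'
#' Consistency of the printed interval with the printed point estimate is
#' checked on the log scale: `|ln(OR) - (ln L + ln U)/2|` must not exceed
#' 0.05, a tolerance that accommodates the two-decimal rounding of published
#' CIs; a larger discrepancy indicates a transcription error and is
#' rejected. A degenerate interval (`L == U`) would imply zero standard
#' error and infinite meta-analytic weight, and is rejected outright.
#'
#' @param odds_ratio Positive odds ratio.
#' @param ci_lower,ci_upper Positive confidence bounds with
#'   `ci_lower <= odds_ratio <= ci_upper` and `ci_lower < ci_upper`.
#' @param ci_level Confidence level of the interval, default 0.95.
#' @param label Study label used in error messages and weight names.
#' @return An object of class `study_effect`.
#' @examples
#' study_effect(1.23, 1.09, 1.41, label = "study B")
#' @export
study_effect <- function(odds_ratio, ci_lower, ci_upper, ci_level = 0.95,
                         label = "") {
  stopifnot(is.numeric(odds_ratio), length(odds_ratio) == 1L,
            is.numeric(ci_lower), length(ci_lower) == 1L,
            is.numeric(ci_upper), length(ci_upper) == 1L,
            is.numeric(ci_level), length(ci_level) == 1L,
            is.character(label), length(label) == 1L)
  who <- if (nzchar(label)) sprintf("study '%s': ", label) else ""
  if (!is.finite(odds_ratio) || odds_ratio <= 0 ||
      !is.finite(ci_lower) || ci_lower <= 0 ||
      !is.finite(ci_upper) || ci_upper <= 0) {
    stop(who, "odds ratio and confidence bounds must be positive and finite")
  }
  if (ci_lower >= ci_upper) {
    stop(who, "ci_lower must be strictly less than ci_upper ",
         "(a degenerate interval implies zero standard error)")
  }
  if (odds_ratio < ci_lower || odds_ratio > ci_upper) {
    stop(who, "odds ratio must lie within [ci_lower, ci_upper]")
  }
  if (ci_level <= 0 || ci_level >= 1) {
    stop(who, "ci_level must be in (0, 1)")
  }
  mid_gap <- abs(log(odds_ratio) - (log(ci_lower) + log(ci_upper)) / 2)
  if (mid_gap > 0.05) {
    stop(who, sprintf(
      "confidence interval is not consistent with the odds ratio on the log scale (|gap| = %.4f > 0.05)",
      mid_gap))
  }
  structure(
    list(odds_ratio = odds_ratio, ci_lower = ci_lower, ci_upper = ci_upper,
         ci_level = ci_level, label = label),
    class = "study_effect"
  )
}

#' Normal critical value for a two-sided confidence level
#'
#' @param level Confidence level in (0, 1).
#' @return The `(1 + level) / 2` standard normal quantile, e.g.
#'   `z_crit(0.95)` is approximately 1.959964.
#' @export
z_crit <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  stats::qnorm((1 + level) / 2)
}

#' Two-sided p-value from a z statistic
#'
#' @param z Real z statistic (vectorised).
#' @return `2 * (1 - Phi(|z|))`, in (0, 1].
#' @export
two_sided_p_from_z <- function(z) {
  stopifnot(is.numeric(z))
  2 * stats::pnorm(-abs(z))
}

#' Log odds ratio and its standard error from a printed OR and CI
#'
#' The Wald back-calculation: the log odds ratio is `ln(OR)` and the
#' standard error is the log-scale CI width divided by twice the normal
#' critical value, `SE = (ln U - ln L) / (2 * z_crit(level))`.
#'
#' @param effect A [study_effect()].
#' @return Named numeric vector with elements `log_or` and `se`.
#' @examples
#' log_or_and_se(study_effect(1.23, 1.09, 1.41))
#' @export
log_or_and_se <- function(effect) {
  stopifnot(inherits(effect, "study_effect"))
  se <- (log(effect$ci_upper) - log(effect$ci_lower)) /
    (2 * z_crit(effect$ci_level))
  c(log_or = log(effect$odds_ratio), se = se)
}

#' Fixed-effect inverse-variance meta-analysis of odds ratios
#'
#' Pools per-study log odds ratios, each weighted by its reciprocal
#' variance: `w_i = 1 / SE_i^2`, pooled log OR `sum(w_i * b_i) / sum(w_i)`,
#' pooled SE `sum(w_i)^(-1/2)`, Wald z, and a two-sided normal p-value.
#' Standard errors are derived from the printed confidence intervals via
#' [log_or_and_se()]. The result is invariant to study order.
#'
#' @param effects Non-empty list of [study_effect()] objects (a single
#'   `study_effect` is accepted and treated as a list of one).
#' @return An object of class `meta_result`: `pooled_log_or`, `pooled_se`,
#'   `pooled_or`, `z_statistic`, `p_two_sided`, and `per_study_weights`
#'   (inverse-variance weights, named by study label where labels exist).
#' @examples
#' fixed_effect_meta(list(
#'   study_effect(1.09, 1.01, 1.16, label = "A"),
#'   study_effect(1.23, 1.09, 1.41, label = "B"),
#'   study_effect(1.20, 1.07, 1.33, label = "C")))
#' @export
fixed_effect_meta <- function(effects) {
  if (inherits(effects, "study_effect")) effects <- list(effects)
  stopifnot(is.list(effects))
  if (length(effects) == 0L) {
    stop("fixed_effect_meta() requires at least one study effect")
  }
  for (i in seq_along(effects)) {
    if (!inherits(effects[[i]], "study_effect")) {
      stop(sprintf("element %d is not a study_effect", i))
    }
  }
  est <- vapply(effects, log_or_and_se, c(log_or = 0, se = 0))
  w <- 1 / est["se", ]^2
  labels <- vapply(effects, `[[`, "", "label")
  if (any(nzchar(labels))) names(w) <- labels
  pooled_log_or <- sum(w * est["log_or", ]) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled_log_or / pooled_se
  structure(
    list(pooled_log_or = pooled_log_or,
         pooled_se = pooled_se,
         pooled_or = exp(pooled_log_or),
         z_statistic = z,
         p_two_sided = two_sided_p_from_z(z),
         per_study_weights = w),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat("<meta_result> fixed-effect inverse-variance pooling\n")
  cat(sprintf("  pooled OR %.4f (log OR %.5f, SE %.5f)\n",
              x$pooled_or, x$pooled_log_or, x$pooled_se))
  cat(sprintf("  z = %.4f, two-sided p = %.3g\n",
              x$z_statistic, x$p_two_sided))
  cat(sprintf("  %d stud%s\n", length(x$per_study_weights),
              if (length(x$per_study_weights) == 1L) "y" else "ies"))
  invisible(x)
}

#' Strict significance-threshold classification
#'
#' @param p P-value(s) in (0, 1] (vectorised).
#' @param threshold Significance threshold in (0, 1), e.g. the genome-wide
#'   level 5e-8.
#' @return Logical vector: `TRUE` iff `p < threshold` (strict, so a p-value
#'   exactly at the threshold does not pass).
#' @examples
#' passes_threshold(c(6.1e-9, 5.1e-8), 5e-8)  # TRUE FALSE
#' @export
passes_threshold <- function(p, threshold) {
  stopifnot(is.numeric(p), is.numeric(threshold), length(threshold) == 1L)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p must be in (0, 1]")
  }
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)")
  }
  p < threshold
}
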