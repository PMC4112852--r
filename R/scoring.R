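#' Rubric configuration
#'
#' Point values, significance thresholds, and the strong-evidence cutoff for
#' the Diverse Convergent Evidence rubric. The defaults implement the
#' published point system: 1 point for a single significant omic finding,
#' plus either 3 points (standard statistical validation) or 2 points
#' (alternative statistical validation, e.g. by meta-analysis or a distinct
#' analytic method), 3 points for informatic evidence, 3 points for
#' experimental evidence, and a composite score of at least 6 indicating
#' strong evidence.
#'
#' The discovery threshold defaults to the conventional genome-wide
#' significance level 5e-8; the choice is deliberately configurable since a
#' number of thresholds can be defended, as long as one is applied
#' consistently within a run. Validation evidence (standard or alternative)
#' is judged against a separate nominal threshold, default 0.05, since
#' validation results such as a pooled meta-analysis p-value are reported at
#' conventional significance, not genome-wide significance.
#'
#' @param discovery_threshold Significance threshold for omic discovery
#'   items; strict comparison (`p < threshold`). Default 5e-8.
#' @param validation_threshold Nominal significance threshold for validation
#'   items. Default 0.05.
#' @param points_single_finding Points for one significant omic discovery.
#' @param points_standard_validation Points for standard statistical
#'   validation (independent sample, same analytic approach).
#' @param points_alternative_validation Points for alternative statistical
#'   validation (meta-analysis, distinct analytic method, covariate
#'   accounting); must not exceed the standard award.
#' @param points_informatic Points for supportive informatic evidence.
#' @param points_experimental Points for supportive experimental evidence.
#' @param strong_cutoff Total at or above which the evidence is classified
#'   strong. Must be attainable under the configured point values.
#' @param require_reviewed If `TRUE` (default), machine-proposed items with
#'   `reviewed = FALSE` are excluded from scoring.
#' @param validation_requires_discovery If `TRUE` (default), validation
#'   points are only awarded when the single-finding point is earned: a
#'   validated result presupposes a qualifying initial finding.
#' @return An object of class `rubric_config`.
#' @export
rubric_config <- function(discovery_threshold = 5e-8,
                          validation_threshold = 0.05,
                          points_single_finding = 1L,
                          points_standard_validation = 3L,
                          points_alternative_validation = 2L,
                          points_informatic = 3L,
                          points_experimental = 3L,
                          strong_cutoff = 6L,
                          require_reviewed = TRUE,
                          validation_requires_discovery = TRUE) {
  pts <- c(points_single_finding, points_standard_validation,
           points_alternative_validation, points_informatic,
           points_experimental, strong_cutoff)
  stopifnot(is.numeric(discovery_threshold), length(discovery_threshold) == 1L,
            discovery_threshold > 0, discovery_threshold < 1,
            is.numeric(validation_threshold), length(validation_threshold) == 1L,
            validation_threshold > 0, validation_threshold < 1,
            is.numeric(pts), all(pts >= 0), all(pts == as.integer(pts)),
            is.logical(require_reviewed), length(require_reviewed) == 1L,
            is.logical(validation_requires_discovery),
            length(validation_requires_discovery) == 1L)
  if (points_alternative_validation > points_standard_validation) {
    stop("points_alternative_validation must not exceed ",
         "points_standard_validation")
  }
  max_total <- points_single_finding + points_standard_validation +
    points_informatic + points_experimental
  if (strong_cutoff > max_total) {
    stop(sprintf("strong_cutoff (%d) exceeds the maximum attainable total (%d)",
                 as.integer(strong_cutoff), as.integer(max_total)))
  }
  structure(
    list(discovery_threshold = discovery_threshold,
         validation_threshold = validation_threshold,
         points_single_finding = as.integer(points_single_finding),
         points_standard_validation = as.integer(points_standard_validation),
         points_alternative_validation = as.integer(points_alternative_validation),
         points_informatic = as.integer(points_informatic),
         points_experimental = as.integer(points_experimental),
         strong_cutoff = as.integer(strong_cutoff),
         require_reviewed = require_reviewed,
         validation_requires_discovery = validation_requires_discovery),
    class = "rubric_config"
  )
}

# items assumed all-omic; applies the reviewed filter internally so the
# function gives the same answer standalone as inside score_dossier.
.score_omic_impl <- function(items, config) {
  if (config$require_reviewed) {
    items <- Filter(function(it) it$reviewed, items)
  }
  sub <- vapply(items, `[[`, "", "subtype")
  ids <- vapply(items, `[[`, "", "item_id")
  sig <- vapply(items, function(it) {
    .item_significant(it, .item_threshold(it, config))
  }, NA)

  disc_ids <- ids[sub == "discovery" & sig]
  single <- if (length(disc_ids)) config$points_single_finding else 0L

  std_ids <- ids[sub == "standard_validation" & sig]
  alt_ids <- ids[sub == "alternative_validation" & sig]
  if (length(std_ids)) {
    val <- config$points_standard_validation
    val_ids <- std_ids
  } else if (length(alt_ids)) {
    val <- config$points_alternative_validation
    val_ids <- alt_ids
  } else {
    val <- 0L
    val_ids <- character()
  }
  if (config$validation_requires_discovery && single == 0L) {
    val <- 0L
    val_ids <- character()
  }
  list(single_finding_points = as.integer(single),
       validation_points = as.integer(val),
       attribution = list(single_finding = sort(disc_ids),
                          validation = sort(val_ids)))
}

# presence-scored categories (informatic, experimental): full points when at
# least one qualifying item exists; additional items never accumulate.
.score_presence_impl <- function(items, points, config) {
  if (config$require_reviewed) {
    items <- Filter(function(it) it$reviewed, items)
  }
  ids <- sort(vapply(items, `[[`, "", "item_id"))
  list(points = if (length(ids)) as.integer(points) else 0L,
       attribution = ids)
}

.assert_category <- function(items, category, caller) {
  cats <- vapply(items, `[[`, "", "category")
  if (any(cats != category)) {
    stop(sprintf("%s(): item(s) %s are not in category '%s'", caller,
                 paste(vapply(items[cats != category], `[[`, "", "item_id"),
                       collapse = ", "),
                 category))
  }
}

#' Score the omic evidence category
#'
#' Awards the single-finding point when at least one discovery item is
#' significant (strict `p < discovery_threshold`, or an explicit significance
#' override such as fine mapping), and the validation points when at least
#' one significant validation item is present — standard validation takes
#' strict precedence over alternative validation; the two never add. Under
#' `validation_requires_discovery` (the default), validation points are
#' withheld when the single-finding point is not earned.
#'
#' @param items List of omic-category [evidence_item()]s, already
#'   deduplicated. A non-omic item is an error (caller misuse).
#' @param config A [rubric_config()].
#' @return List with `single_finding_points`, `validation_points`, and
#'   `attribution` (item ids awarding each component; all qualifying items
#'   are listed, ties do not change points).
#' @export
score_omic <- function(items, config = rubric_config()) {
  stopifnot(is.list(items), inherits(config, "rubric_config"))
  .assert_category(items, "omic", "score_omic")
  .score_omic_impl(items, config)
}

#' Score the informatic (biological database) evidence category
#'
#' Full informatic points when at least one reviewed informatic item is
#' present — literature, pathway, expression or other database evidence
#' linking the factor to the pathophysiology. Items beyond the first do not
#' accumulate: validation counts within a category are deliberately not
#' folded into the rubric.
#'
#' @inheritParams score_omic
#' @param items List of informatic-category [evidence_item()]s, deduplicated.
#' @return List with `points` and `attribution`.
#' @export
score_informatic <- function(items, config = rubric_config()) {
  stopifnot(is.list(items), inherits(config, "rubric_config"))
  .assert_category(items, "informatic", "score_informatic")
  .score_presence_impl(items, config$points_informatic, config)
}

#' Score the experimental (laboratory) evidence category
#'
#' Full experimental points when at least one reviewed experimental item is
#' present — animal models, cell/molecular work, or treatment experiments
#' demonstrating a role of the factor in the pathophysiology. Multiple
#' experiments do not accumulate.
#'
#' @inheritParams score_omic
#' @param items List of experimental-category [evidence_item()]s,
#'   deduplicated.
#' @return List with `points` and `attribution`.
#' @export
score_experimental <- function(items, config = rubric_config()) {
  stopifnot(is.list(items), inherits(config, "rubric_config"))
  .assert_category(items, "experimental", "score_experimental")
  .score_presence_impl(items, config$points_experimental, config)
}

#' Classify a composite score as strong or weak evidence
#'
#' @param total Non-negative integer composite score.
#' @param config A [rubric_config()]; supplies the cutoff (default 6).
#' @return `"strong"` if `total >= strong_cutoff`, else `"weak"`.
#' @examples
#' classify(9)  # "strong"
#' classify(5)  # "weak"
#' @export
classify <- function(total, config = rubric_config()) {
  stopifnot(is.numeric(total), length(total) == 1L, total >= 0,
            inherits(config, "rubric_config"))
  if (total >= config$strong_cutoff) "strong" else "weak"
}

#' Compute the composite DiCE score for a dossier
#'
#' Validates the dossier, excludes unreviewed items (under the default
#' configuration), collapses duplicate results so each is counted once,
#' applies the three category scorers, and sums the components into the
#' composite score. The result is fully deterministic and independent of
#' item ordering, and the attribution map accounts for every awarded point.
#'
#' @param d A [dossier()].
#' @param config A [rubric_config()].
#' @return An object of class `dice_score`: a list with integer components
#'   `single_finding_points`, `validation_points`, `informatic_points`,
#'   `experimental_points`, their sum `total`, the `classification`
#'   (`"strong"`/`"weak"`), and `attribution` mapping each component to the
#'   item ids that awarded it.
#' @examples
#' d <- dossier(
#'   dice_factor("ATP2B4"), phenotype("malaria resistance"),
#'   items = list(
#'     evidence_item("snp1", "omic", "discovery", p_value = 6.1e-9,
#'                   result_key = "gwas:snp1"),
#'     evidence_item("ko1", "experimental", "animal_model",
#'                   source = "knockout model", result_key = "exp:ko1")
#'   ))
#' score_dossier(d)
#' @export
score_dossier <- function(d, config = rubric_config()) {
  stopifnot(inherits(d, "dice_dossier"), inherits(config, "rubric_config"))
  violations <- validate_dossier(d)
  if (length(violations)) {
    stop("invalid dossier:\n  ", paste(violations, collapse = "\n  "))
  }
  items <- d$items
  if (config$require_reviewed) {
    items <- Filter(function(it) it$reviewed, items)
  }
  items <- deduplicate(items, config)
  cats <- vapply(items, `[[`, "", "category")
  om <- .score_omic_impl(items[cats == "omic"], config)
  info <- .score_presence_impl(items[cats == "informatic"],
                               config$points_informatic, config)
  ex <- .score_presence_impl(items[cats == "experimental"],
                             config$points_experimental, config)
  total <- om$single_finding_points + om$validation_points + info$points +
    ex$points
  structure(
    list(single_finding_points = om$single_finding_points,
         validation_points = om$validation_points,
         informatic_points = info$points,
         experimental_points = ex$points,
         total = as.integer(total),
         classification = classify(total, config),
         attribution = list(single_finding = om$attribution$single_finding,
                            validation = om$attribution$validation,
                            informatic = info$attribution,
                            experimental = ex$attribution)),
    class = "dice_score"
  )
}

#' @export
print.dice_score <- function(x, ...) {
  cat("<dice_score>\n")
  cat(sprintf("  single finding: %d\n  validation:     %d\n",
              x$single_finding_points, x$validation_points))
  cat(sprintf("  informatic:     %d\n  experimental:   %d\n",
              x$informatic_points, x$experimental_points))
  cat(sprintf("  total: %d (%s evidence)\n", x$total, x$classification))
  invisible(x)
}
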