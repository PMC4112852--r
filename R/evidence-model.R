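#' @keywords internal
"_PACKAGE"

# Controlled vocabularies for the evidence model. Subtypes are nested under
# their category; scoring and schema validation both consult these tables.
.dice_categories <- c("omic", "informatic", "experimental")

.dice_subtypes <- list(
  omic         = c("discovery", "standard_validation", "alternative_validation"),
  informatic   = c("literature", "pathway_db", "expression_db", "other_db"),
  experimental = c("animal_model", "cell_molecular", "treatment")
)

.dice_factor_classes <- c("gene", "variant", "exposure", "pathway", "other")

#' Candidate risk factor
#'
#' A factor is the unit of assessment: a gene, variant, exposure, or pathway
#' whose involvement in a phenotype is being evaluated.
#'
#' @param name Factor name (gene symbol, variant id, exposure or pathway
#'   name). Must be a non-empty string.
#' @param factor_class One of `"gene"`, `"variant"`, `"exposure"`,
#'   `"pathway"`, `"other"`.
#' @param aliases Character vector of alternative names (may be empty). Must
#'   not repeat `name`.
#' @return An object of class `dice_factor`.
#' @examples
#' dice_factor("ATP2B4", "gene")
#' dice_factor("TAT", "gene", aliases = "tyrosine aminotransferase")
#' @export
dice_factor <- function(name, factor_class = "gene", aliases = character()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(factor_class), length(factor_class) == 1L,
            is.character(aliases))
  structure(
    list(name = name, factor_class = factor_class,
         aliases = as.character(aliases)),
    class = "dice_factor"
  )
}

#' Phenotype under study
#'
#' @param name Phenotype name (non-empty string), e.g. "malaria resistance".
#' @param description Optional free-text description.
#' @return An object of class `dice_phenotype`.
#' @export
phenotype <- function(name, description = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(description)) {
    stopifnot(is.character(description), length(description) == 1L)
  }
  structure(list(name = name, description = description),
            class = "dice_phenotype")
}

#' A single piece of evidence
#'
#' One evidence item records one result bearing on a (factor, phenotype)
#' pair: an omic association (discovery or validation), an informatic hit
#' (literature or database), or a laboratory experiment.
#'
#' Constructors check structure (types and lengths) only; value-level
#' invariants (p-value range, category/subtype consistency, result-key
#' presence) are checked by [validate_dossier()], so that invalid dossiers
#' can be represented and reported rather than being unconstructible.
#'
#' @param item_id Identifier, unique within a dossier.
#' @param category Evidence category: `"omic"`, `"informatic"` or
#'   `"experimental"`.
#' @param subtype Subtype within the category: for omic one of `"discovery"`,
#'   `"standard_validation"`, `"alternative_validation"`; for informatic one
#'   of `"literature"`, `"pathway_db"`, `"expression_db"`, `"other_db"`; for
#'   experimental one of `"animal_model"`, `"cell_molecular"`, `"treatment"`.
#' @param p_value Optional p-value in (0, 1].
#' @param significant_override Optional logical. When present it supersedes
#'   the p-value comparison entirely — used for explicit significance calls
#'   with no single scan p-value, e.g. significance attained by fine mapping.
#' @param effect Optional [study_effect()] carrying an odds ratio and CI.
#' @param source Citation, accession, or query description.
#' @param reviewed Logical; `TRUE` for human-confirmed evidence, `FALSE` for
#'   machine-proposed items (see [propose_items()]), which are excluded from
#'   scoring under the default configuration.
#' @param result_key Identifier of the underlying result. Two items sharing a
#'   `result_key` describe the same result and are counted once by
#'   [deduplicate()].
#' @return An object of class `evidence_item`.
#' @examples
#' evidence_item("snp1", "omic", "discovery", p_value = 6.1e-9,
#'               source = "GWAS", result_key = "gwas:snp1")
#' @export
evidence_item <- function(item_id, category, subtype,
                          p_value = NULL, significant_override = NULL,
                          effect = NULL, source = "", reviewed = TRUE,
                          result_key = item_id) {
  stopifnot(is.character(item_id), length(item_id) == 1L,
            is.character(category), length(category) == 1L,
            is.character(subtype), length(subtype) == 1L,
            is.character(source), length(source) == 1L,
            is.logical(reviewed), length(reviewed) == 1L, !is.na(reviewed),
            is.character(result_key), length(result_key) == 1L)
  if (!is.null(p_value)) {
    stopifnot(is.numeric(p_value), length(p_value) == 1L)
    p_value <- as.numeric(p_value)
  }
  if (!is.null(significant_override)) {
    stopifnot(is.logical(significant_override),
              length(significant_override) == 1L, !is.na(significant_override))
  }
  if (!is.null(effect)) stopifnot(inherits(effect, "study_effect"))
  structure(
    list(item_id = item_id, category = category, subtype = subtype,
         p_value = p_value, significant_override = significant_override,
         effect = effect, source = source, reviewed = reviewed,
         result_key = result_key),
    class = "evidence_item"
  )
}

#' Evidence dossier for one (factor, phenotype) pair
#'
#' The dossier is the scoring engine's input unit: every evidence item
#' gathered for one candidate factor and one phenotype, plus free-text notes
#' (provenance, caveats).
#'
#' @param factor A [dice_factor()].
#' @param phenotype A [phenotype()].
#' @param items List of [evidence_item()] objects (may be empty).
#' @param notes Free text.
#' @return An object of class `dice_dossier`.
#' @export
dossier <- function(factor, phenotype, items = list(), notes = "") {
  stopifnot(inherits(factor, "dice_factor"),
            inherits(phenotype, "dice_phenotype"),
            is.list(items),
            is.character(notes), length(notes) == 1L)
  for (it in items) stopifnot(inherits(it, "evidence_item"))
  structure(
    list(factor = factor, phenotype = phenotype, items = items,
         notes = notes),
    class = "dice_dossier"
  )
}

#' @export
print.dice_dossier <- function(x, ...) {
  cat(sprintf("<dice_dossier> %s / %s\n", x$factor$name, x$phenotype$name))
  cat(sprintf("  %d evidence item(s)", length(x$items)))
  if (length(x$items)) {
    tab <- table(vapply(x$items, `[[`, "", "category"))
    cat(": ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        sep = "")
  }
  cat("\n")
  if (nzchar(x$notes)) cat("  notes: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Validate a dossier against the evidence-model invariants
#'
#' Checks every invariant of the evidence model and returns violations as a
#' character vector (empty when the dossier is valid) instead of raising, so
#' that all problems in a file can be reported at once. Each violation names
#' the offending item id and field.
#'
#' @param d A [dossier()].
#' @return Character vector of violation descriptions; `character(0)` if the
#'   dossier is valid.
#' @examples
#' d <- dossier(dice_factor("G1"), phenotype("disease"))
#' validate_dossier(d)  # character(0): an empty dossier is vacuously valid
#' @export
validate_dossier <- function(d) {
  stopifnot(inherits(d, "dice_dossier"))
  v <- character()
  if (!nzchar(d$factor$name)) {
    v <- c(v, "factor: name must be non-empty")
  }
  if (!d$factor$factor_class %in% .dice_factor_classes) {
    v <- c(v, sprintf("factor: factor_class '%s' not one of %s",
                      d$factor$factor_class,
                      paste(.dice_factor_classes, collapse = ", ")))
  }
  if (d$factor$name %in% d$factor$aliases) {
    v <- c(v, "factor: aliases must not contain the factor name")
  }
  if (!nzchar(d$phenotype$name)) {
    v <- c(v, "phenotype: name must be non-empty")
  }
  ids <- vapply(d$items, `[[`, "", "item_id")
  for (id in unique(ids[duplicated(ids)])) {
    v <- c(v, sprintf("item %s: item_id is duplicated", id))
  }
  for (it in d$items) {
    id <- it$item_id
    if (!nzchar(id)) v <- c(v, "item: item_id must be non-empty")
    if (!it$category %in% .dice_categories) {
      v <- c(v, sprintf("item %s: category '%s' not one of %s", id,
                        it$category, paste(.dice_categories, collapse = ", ")))
    } else if (!it$subtype %in% .dice_subtypes[[it$category]]) {
      v <- c(v, sprintf("item %s: subtype '%s' not valid for category '%s'",
                        id, it$subtype, it$category))
    }
    if (!is.null(it$p_value) &&
        (is.na(it$p_value) || it$p_value <= 0 || it$p_value > 1)) {
      v <- c(v, sprintf("item %s: p_value must be in (0, 1] (got %s)",
                        id, format(it$p_value)))
    }
    if (!nzchar(it$result_key)) {
      v <- c(v, sprintf("item %s: result_key must be non-empty", id))
    }
  }
  v
}

# Significance of a single item: an explicit override supersedes the p-value
# comparison; otherwise a present p-value is compared strictly against the
# threshold; an item with neither is not significant.
.item_significant <- function(item, threshold) {
  if (!is.null(item$significant_override)) {
    return(isTRUE(item$significant_override))
  }
  if (!is.null(item$p_value)) return(item$p_value < threshold)
  FALSE
}

# Threshold that applies to an omic item given its subtype: the genome-wide
# discovery threshold for discovery items, the nominal validation threshold
# for validation items. Non-omic items are "present" evidence, no threshold.
.item_threshold <- function(item, config) {
  if (identical(item$category, "omic") && identical(item$subtype, "discovery"))
    config$discovery_threshold
  else
    config$validation_threshold
}

# Category priority used for deterministic tie-breaking when one underlying
# result appears under several categories.
.category_rank <- function(category) {
  match(category, c("omic", "experimental", "informatic"), nomatch = 4L)
}

#' Collapse duplicate results so each is counted once
#'
#' Items sharing a `result_key` describe the same underlying result, which
#' must contribute to the composite score at most once. When a result appears
#' under several categories, the survivor is the assignment under which the
#' item set earns the most points (the scoring-maximal category), so a result
#' is credited fully, but only once. Ties are broken by category priority
#' omic > experimental > informatic, then by item id, making the outcome
#' deterministic and independent of input order.
#'
#' The maximisation is over the whole item set, not item-by-item: keeping a
#' 1-point discovery item can be worth more than keeping a 3-point
#' experimental duplicate when the discovery unlocks validation points. All
#' survivor combinations are enumerated exactly (falling back to a per-group
#' greedy choice only beyond 4096 combinations, far past any realistic
#' dossier), which makes `deduplicate` idempotent and the total score
#' monotone under evidence addition.
#'
#' @param items List of [evidence_item()] objects (validated).
#' @param config A [rubric_config()]; supplies the point values and
#'   thresholds that define "scoring-maximal".
#' @return List of evidence items with unique `result_key`s, sorted by
#'   item id.
#' @export
deduplicate <- function(items, config = rubric_config()) {
  stopifnot(is.list(items), inherits(config, "rubric_config"))
  if (length(items) < 2L) return(.sort_items(items))
  keys <- vapply(items, `[[`, "", "result_key")
  groups <- split(seq_along(items), keys)
  # deterministic candidate order within each group
  groups <- lapply(groups, function(idx) {
    idx[order(vapply(items[idx], `[[`, "", "item_id"))]
  })
  groups <- groups[order(names(groups))]
  sizes <- vapply(groups, length, 1L)
  if (all(sizes == 1L)) return(.sort_items(items))

  if (prod(sizes) <= 4096) {
    combos <- expand.grid(groups, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    best <- NULL
    best_total <- -1
    best_key <- NULL
    for (r in seq_len(nrow(combos))) {
      keep <- as.integer(combos[r, ])
      cand <- items[keep]
      total <- .score_items_total(cand, config)
      key <- unlist(lapply(cand, function(it) {
        c(.category_rank(it$category), match(it$item_id, sort(unique(
          vapply(items, `[[`, "", "item_id")))))
      }))
      if (total > best_total ||
          (total == best_total && .lex_less(key, best_key))) {
        best <- keep
        best_total <- total
        best_key <- key
      }
    }
    .sort_items(items[best])
  } else {
    # greedy fallback: per-group, keep the item with the largest standalone
    # point value, same tie-break
    keep <- vapply(groups, function(idx) {
      pts <- vapply(items[idx], .item_static_points, 0, config = config)
      rk <- vapply(items[idx], function(it) .category_rank(it$category), 1L)
      idx[order(-pts, rk)][1L]
    }, 1L)
    .sort_items(items[keep])
  }
}

.sort_items <- function(items) {
  if (length(items) < 2L) return(items)
  items[order(vapply(items, `[[`, "", "item_id"))]
}

.lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Standalone point value of one item under the rubric, ignoring interactions
# (used only by the greedy fallback).
.item_static_points <- function(item, config) {
  if (config$require_reviewed && !item$reviewed) return(0)
  switch(item$category,
    omic = {
      if (!.item_significant(item, .item_threshold(item, config))) return(0)
      switch(item$subtype,
        discovery = config$points_single_finding,
        standard_validation = config$points_standard_validation,
        alternative_validation = config$points_alternative_validation,
        0)
    },
    informatic = config$points_informatic,
    experimental = config$points_experimental,
    0)
}

# Total rubric points for an arbitrary item set (used when comparing
# candidate dedup assignments). Mirrors score_dossier without validation,
# deduplication or attribution.
.score_items_total <- function(items, config) {
  cats <- vapply(items, `[[`, "", "category")
  om <- .score_omic_impl(items[cats == "omic"], config)
  info <- .score_presence_impl(items[cats == "informatic"],
                               config$points_informatic, config)
  ex <- .score_presence_impl(items[cats == "experimental"],
                             config$points_experimental, config)
  om$single_finding_points + om$validation_points + info$points + ex$points
}
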