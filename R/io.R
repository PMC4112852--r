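# shared parser for dossier documents; format decided by file extension
.parse_dossier_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    stop("unsupported dossier format '", ext, "' (expected yaml/yml/json)")
  }
}

#' Read an evidence dossier from a YAML or JSON file
#'
#' Parses the file, checks it against the published schema
#' ([dossier_schema()]) reporting every violation with its field path, then
#' constructs the dossier and checks the evidence-model invariants with
#' [validate_dossier()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` dossier file.
#' @return A [dossier()].
#' @seealso [write_dossier()] for the inverse; the two round-trip: reading a
#'   written dossier reproduces it exactly.
#' @export
read_dossier <- function(path) {
  x <- .parse_dossier_file(path)
  violations <- check_dossier_schema(x)
  if (length(violations)) {
    stop("schema violations in ", path, ":\n  ",
         paste(violations, collapse = "\n  "))
  }
  d <- .dossier_from_list(x)
  violations <- validate_dossier(d)
  if (length(violations)) {
    stop("invalid dossier in ", path, ":\n  ",
         paste(violations, collapse = "\n  "))
  }
  d
}

.dossier_from_list <- function(x) {
  eff_from <- function(e) {
    if (is.null(e)) return(NULL)
    study_effect(odds_ratio = as.numeric(e$odds_ratio),
                 ci_lower = as.numeric(e$ci_lower),
                 ci_upper = as.numeric(e$ci_upper),
                 ci_level = if (is.null(e$ci_level)) 0.95
                            else as.numeric(e$ci_level),
                 label = if (is.null(e$label)) "" else e$label)
  }
  items <- lapply(x$items, function(it) {
    evidence_item(
      item_id = it$item_id, category = it$category, subtype = it$subtype,
      p_value = if (is.null(it$p_value)) NULL else as.numeric(it$p_value),
      significant_override = it$significant_override,
      effect = eff_from(it$effect),
      source = if (is.null(it$source)) "" else it$source,
      reviewed = if (is.null(it$reviewed)) TRUE else it$reviewed,
      result_key = it$result_key)
  })
  dossier(
    factor = dice_factor(
      name = x$factor$name,
      factor_class = if (is.null(x$factor$factor_class)) "gene"
                     else x$factor$factor_class,
      aliases = if (is.null(x$factor$aliases)) character()
                else unlist(x$factor$aliases)),
    phenotype = phenotype(x$phenotype$name,
                          description = x$phenotype$description),
    items = items,
    notes = if (is.null(x$notes)) "" else x$notes)
}

# canonical plain-list form of a dossier (NULL/default fields omitted) used
# for serialisation; numbers are kept numeric, so YAML/JSON writers control
# their own representation
.dossier_to_list <- function(d) {
  drop_null <- function(x) x[!vapply(x, is.null, NA)]
  item_to <- function(it) {
    eff <- NULL
    if (!is.null(it$effect)) {
      e <- it$effect
      eff <- drop_null(list(
        odds_ratio = e$odds_ratio, ci_lower = e$ci_lower,
        ci_upper = e$ci_upper,
        ci_level = if (identical(e$ci_level, 0.95)) NULL else e$ci_level,
        label = if (nzchar(e$label)) e$label else NULL))
    }
    drop_null(list(
      item_id = it$item_id, category = it$category, subtype = it$subtype,
      p_value = it$p_value, significant_override = it$significant_override,
      effect = eff, source = if (nzchar(it$source)) it$source else NULL,
      reviewed = if (isTRUE(it$reviewed)) NULL else it$reviewed,
      result_key = it$result_key))
  }
  drop_null(list(
    factor = drop_null(list(
      name = d$factor$name, factor_class = d$factor$factor_class,
      aliases = if (length(d$factor$aliases)) as.list(d$factor$aliases)
                else NULL)),
    phenotype = drop_null(list(name = d$phenotype$name,
                               description = d$phenotype$description)),
    items = lapply(d$items, item_to),
    notes = if (nzchar(d$notes)) d$notes else NULL))
}

#' Write an evidence dossier to a YAML or JSON file
#'
#' @param d A [dossier()].
#' @param path Output path; the extension (`.yaml`/`.yml`/`.json`) selects
#'   the format.
#' @return `path`, invisibly.
#' @export
write_dossier <- function(d, path) {
  stopifnot(inherits(d, "dice_dossier"))
  x <- .dossier_to_list(d)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported dossier format '", ext, "' (expected yaml/yml/json)")
  }
  invisible(path)
}

#' Render a score report
#'
#' Serialises a [score_dossier()] result as JSON (stable key order),
#' Markdown (per-category attribution and the strong/weak verdict against
#' the cutoff), or a single TSV row. Rendering is pure: identical inputs
#' produce byte-identical output.
#'
#' @param score A `dice_score`.
#' @param format `"json"`, `"markdown"` or `"tsv"`.
#' @param d Optional [dossier()]; adds factor/phenotype context.
#' @param config Optional [rubric_config()]; embeds the effective
#'   configuration (JSON) and the cutoff (Markdown) for auditability.
#' @param path Optional output file; when given the report is also written
#'   there.
#' @return The report as a single string, invisibly when `path` is given.
#' @export
write_report <- function(score, format = c("json", "markdown", "tsv"),
                         d = NULL, config = NULL, path = NULL) {
  stopifnot(inherits(score, "dice_score"))
  format <- match.arg(format)
  if (!is.null(d)) stopifnot(inherits(d, "dice_dossier"))
  cutoff <- if (is.null(config)) NULL else config$strong_cutoff
  txt <- switch(format,
    json = .report_json(score, d, config),
    markdown = .report_markdown(score, d, cutoff),
    tsv = .report_tsv(score, d))
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

.report_json <- function(score, d, config) {
  out <- list()
  if (!is.null(d)) {
    out$factor <- d$factor$name
    out$phenotype <- d$phenotype$name
  }
  out$single_finding_points <- score$single_finding_points
  out$validation_points <- score$validation_points
  out$informatic_points <- score$informatic_points
  out$experimental_points <- score$experimental_points
  out$total <- score$total
  out$classification <- score$classification
  out$attribution <- lapply(score$attribution, as.list)
  if (!is.null(config)) out$config <- unclass(config)
  paste0(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE),
         "\n")
}

.report_markdown <- function(score, d, cutoff) {
  lines <- "# DiCE score report"
  if (!is.null(d)) {
    lines <- c(lines, "",
               sprintf("Factor: **%s**  ", d$factor$name),
               sprintf("Phenotype: **%s**", d$phenotype$name))
  }
  attr_str <- function(ids) {
    if (length(ids)) paste(ids, collapse = ", ") else "-"
  }
  lines <- c(lines, "",
    "| Component | Points | Awarded by |",
    "|---|---|---|",
    sprintf("| Single significant finding | %d | %s |",
            score$single_finding_points,
            attr_str(score$attribution$single_finding)),
    sprintf("| Statistical validation | %d | %s |",
            score$validation_points, attr_str(score$attribution$validation)),
    sprintf("| Informatic evidence | %d | %s |",
            score$informatic_points, attr_str(score$attribution$informatic)),
    sprintf("| Experimental evidence | %d | %s |",
            score$experimental_points,
            attr_str(score$attribution$experimental)),
    sprintf("| **Total** | **%d** | |", score$total),
    "")
  verdict <- if (is.null(cutoff)) {
    sprintf("Verdict: **%s** evidence.", score$classification)
  } else {
    sprintf("Verdict: **%s** evidence (total %d %s cutoff %d).",
            score$classification, score$total,
            if (score$classification == "strong") ">=" else "<", cutoff)
  }
  paste0(paste(c(lines, verdict), collapse = "\n"), "\n")
}

.report_tsv <- function(score, d) {
  header <- c("factor", "phenotype", "single_finding", "validation",
              "informatic", "experimental", "total", "classification")
  row <- c(if (is.null(d)) c(NA, NA) else c(d$factor$name, d$phenotype$name),
           score$single_finding_points, score$validation_points,
           score$informatic_points, score$experimental_points,
           score$total, score$classification)
  paste0(paste(header, collapse = "\t"), "\n",
         paste(row, collapse = "\t"), "\n")
}

#' Read a GWAS hit table
#'
#' Reads a tab-delimited table of association results with columns
#' `variant_id`, `gene` (the attributed factor, which may deliberately
#' differ from the nearest gene), `p_value`, and optionally `or`,
#' `ci_lower`, `ci_upper` (per-variant effect) and `intergenic` (logical;
#' marks attributions where the variant lies outside the gene).
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per variant. Duplicate `variant_id`s
#'   are an error.
#' @export
read_gwas_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "gene", "p_value")
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    stop("hit table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(hits$variant_id)) {
    stop("duplicate variant_id in ", path, ": ",
         paste(unique(hits$variant_id[duplicated(hits$variant_id)]),
               collapse = ", "))
  }
  bad <- !is.finite(hits$p_value) | hits$p_value <= 0 | hits$p_value > 1
  if (any(bad)) {
    stop("p_value out of (0, 1] for variant(s): ",
         paste(hits$variant_id[bad], collapse = ", "))
  }
  if (is.null(hits$intergenic)) hits$intergenic <- FALSE
  hits$intergenic <- as.logical(hits$intergenic)
  hits
}

#' Read study effects from a tab-delimited file
#'
#' Reads a 4-column table (`label`, `or`, `ci_lower`, `ci_upper`) into a
#' list of [study_effect()]s for [fixed_effect_meta()].
#'
#' @param path Path to the TSV file.
#' @param ci_level Confidence level of the intervals, default 0.95.
#' @return List of `study_effect` objects.
#' @export
read_study_effects <- function(path, ci_level = 0.95) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "or", "ci_lower", "ci_upper")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("effects table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    study_effect(tab$or[i], tab$ci_lower[i], tab$ci_upper[i],
                 ci_level = ci_level, label = tab$label[i])
  })
}
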