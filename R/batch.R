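#' Batch-score a GWAS hit table against an evidence directory
#'
#' Triage for a list of association results: each hit's attributed gene is
#' scored with its evidence dossier (looked up as `<gene>.yaml`/`.yml`/
#' `.json` in `evidence_dir`; a missing file means an empty dossier) merged
#' with the hit itself as an omic discovery item. This characterises both
#' genome-wide-significant hits (likelihood of a false positive conclusion)
#' and sub-threshold hits (likelihood of a false negative): a hit failing
#' the configured discovery threshold contributes no single-finding point
#' but still appears in the report.
#'
#' Multiple hits attributed to the same gene (e.g. several SNPs in one
#' locus) are merged into that gene's single dossier, giving one row per
#' scored dossier. Rows are sorted by total (descending), then by the
#' gene's smallest hit p-value (ascending). Each row carries an advisory
#' next-step flag: `"laboratory follow-up"` when the evidence is strong;
#' for weak evidence, `"consider nearby-factor reattribution"` when any of
#' the gene's hits is flagged intergenic (the association may act through a
#' neighbouring factor), otherwise `"gather informatic/experimental
#' evidence"`.
#'
#' An unreadable or invalid dossier file does not abort the run: the gene's
#' row reports the error and NA points.
#'
#' @param hits Data frame as returned by [read_gwas_hits()] (or built in
#'   code with the same columns).
#' @param evidence_dir Directory of per-gene dossier files; `NULL` scores
#'   every gene against an empty dossier.
#' @param config A [rubric_config()]. For nominal-significance triage pass
#'   `rubric_config(discovery_threshold = 0.05)`; the threshold is one
#'   config value per run so that a consistent rationale applies to all
#'   hits.
#' @param phenotype_name Phenotype used for genes without a dossier file.
#' @return An object of class `batch_report`: list with `rows` (data
#'   frame), the effective `config`, and `notes`.
#' @export
batch_score <- function(hits, evidence_dir = NULL, config = rubric_config(),
                        phenotype_name = "unspecified phenotype") {
  stopifnot(is.data.frame(hits), inherits(config, "rubric_config"))
  if (nrow(hits) > 0) {
    need <- c("variant_id", "gene", "p_value")
    missing <- setdiff(need, names(hits))
    if (length(missing)) {
      stop("hits lacks column(s): ", paste(missing, collapse = ", "))
    }
    if (anyDuplicated(hits$variant_id)) {
      stop("duplicate variant_id: ",
           paste(unique(hits$variant_id[duplicated(hits$variant_id)]),
                 collapse = ", "))
    }
  }
  if (is.null(hits$intergenic)) hits$intergenic <- rep(FALSE, nrow(hits))

  genes <- unique(hits$gene)
  rows <- lapply(genes, function(g) {
    gh <- hits[hits$gene == g, , drop = FALSE]
    res <- tryCatch({
      d <- .load_gene_dossier(g, evidence_dir, phenotype_name)
      d <- .merge_hits(d, gh)
      s <- score_dossier(d, config)
      data.frame(
        factor = g, phenotype = d$phenotype$name,
        single_finding = s$single_finding_points,
        validation = s$validation_points,
        informatic = s$informatic_points,
        experimental = s$experimental_points,
        total = s$total, classification = s$classification,
        n_hits = nrow(gh), min_p = min(gh$p_value),
        next_step = .next_step(s, any(gh$intergenic)),
        error = NA_character_,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(
        factor = g, phenotype = phenotype_name,
        single_finding = NA_integer_, validation = NA_integer_,
        informatic = NA_integer_, experimental = NA_integer_,
        total = NA_integer_, classification = NA_character_,
        n_hits = nrow(gh), min_p = min(gh$p_value),
        next_step = NA_character_, error = conditionMessage(e),
        stringsAsFactors = FALSE)
    })
    res
  })
  if (length(rows)) {
    rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    ord <- order(-ifelse(is.na(rows$total), -1L, rows$total), rows$min_p,
                 rows$factor)
    rows <- rows[ord, , drop = FALSE]
    rownames(rows) <- NULL
  } else {
    rows <- data.frame(
      factor = character(), phenotype = character(),
      single_finding = integer(), validation = integer(),
      informatic = integer(), experimental = integer(),
      total = integer(), classification = character(),
      n_hits = integer(), min_p = numeric(), next_step = character(),
      error = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(rows = rows, config = config,
         notes = sprintf("%d hit(s) in %d dossier(s); evidence_dir: %s",
                         nrow(hits), length(genes),
                         if (is.null(evidence_dir)) "(none)"
                         else evidence_dir)),
    class = "batch_report")
}

.load_gene_dossier <- function(gene, evidence_dir, phenotype_name) {
  if (!is.null(evidence_dir)) {
    for (ext in c("yaml", "yml", "json")) {
      p <- file.path(evidence_dir, paste0(gene, ".", ext))
      if (file.exists(p)) return(read_dossier(p))
    }
  }
  dossier(dice_factor(gene, "gene"), phenotype(phenotype_name))
}

# append the gene's hits as omic discovery items; ids/keys derive from the
# variant id so re-running is deterministic and hits never collide with
# dossier items unless they genuinely describe the same result
.merge_hits <- function(d, gh) {
  existing <- vapply(d$items, `[[`, "", "item_id")
  for (i in seq_len(nrow(gh))) {
    vid <- gh$variant_id[i]
    iid <- paste0("hit_", vid)
    if (iid %in% existing) iid <- paste0(iid, "_batch")
    eff <- NULL
    if (!is.null(gh$or) && is.finite(gh$or[i])) {
      eff <- study_effect(gh$or[i], gh$ci_lower[i], gh$ci_upper[i],
                          label = vid)
    }
    d$items <- c(d$items, list(evidence_item(
      item_id = iid, category = "omic", subtype = "discovery",
      p_value = gh$p_value[i], effect = eff,
      source = "GWAS hit table", reviewed = TRUE,
      result_key = paste0("gwas:", vid))))
  }
  d
}

.next_step <- function(score, intergenic) {
  if (score$classification == "strong") return("laboratory follow-up")
  if (intergenic) return("consider nearby-factor reattribution")
  "gather informatic/experimental evidence"
}

#' @export
print.batch_report <- function(x, ...) {
  cat("<batch_report> ", x$notes, "\n", sep = "")
  print(x$rows[, c("factor", "single_finding", "validation", "informatic",
                   "experimental", "total", "classification", "next_step")])
  invisible(x)
}

#' Render a batch report
#'
#' Deterministic serialisation of a [batch_score()] report: identical
#' inputs and configuration yield byte-identical output. The effective
#' configuration is embedded (JSON) or listed in header comments (TSV) so
#' every report documents the thresholds and point values it was produced
#' under.
#'
#' @param report A `batch_report`.
#' @param format `"json"` or `"tsv"`.
#' @param path Optional output file.
#' @return The report as a single string, invisibly when `path` is given.
#' @export
format_batch_report <- function(report, format = c("json", "tsv"),
                                path = NULL) {
  stopifnot(inherits(report, "batch_report"))
  format <- match.arg(format)
  txt <- if (format == "json") {
    paste0(jsonlite::toJSON(
      list(rows = report$rows, config = unclass(report$config),
           notes = report$notes),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"), "\n")
  } else {
    cfg <- unclass(report$config)
    hdr <- sprintf("# %s: %s", names(cfg),
                   vapply(cfg, function(x) format(x, digits = 15), ""))
    con <- textConnection("out", "w", local = TRUE)
    writeLines(c(hdr, paste0("# ", report$notes)), con)
    utils::write.table(report$rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paste0(paste(out, collapse = "\n"), "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
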