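.dice_databases <- c("pubmed", "kegg", "geo", "go", "other")

# database -> informatic subtype used for machine-proposed items
.database_subtype <- c(pubmed = "literature", kegg = "pathway_db",
                       go = "pathway_db", geo = "expression_db",
                       other = "other_db")

#' Render a deterministic evidence-search query
#'
#' Builds the query string sent to a literature/database provider from a
#' factor, a phenotype, and a template with `{factor}` and `{phenotype}`
#' placeholders. Rendering is purely deterministic — identical inputs always
#' produce the identical query — so that searches are consistent across a
#' run and comparable across factors.
#'
#' @param factor A [dice_factor()].
#' @param phenotype A [phenotype()].
#' @param database Target database: `"pubmed"`, `"kegg"`, `"geo"`, `"go"`,
#'   or `"other"`.
#' @param template Query template containing both `{factor}` and
#'   `{phenotype}`; a template missing either placeholder is an error.
#' @param factor_term Term substituted for `{factor}`; defaults to the
#'   factor name. Pass an alias (e.g. the full enzyme name) to search under
#'   an alternative designation.
#' @param phenotype_term Term substituted for `{phenotype}`; defaults to the
#'   phenotype name.
#' @return An object of class `evidence_query` with fields `factor_terms`,
#'   `phenotype_terms`, `database`, `raw_query`.
#' @examples
#' tat <- dice_factor("TAT", "gene", aliases = "tyrosine aminotransferase")
#' q <- render_query(tat, phenotype("malaria"), "pubmed",
#'                   factor_term = "tyrosine aminotransferase")
#' q$raw_query  # "tyrosine aminotransferase and malaria"
#' @export
render_query <- function(factor, phenotype, database = "pubmed",
                         template = "{factor} and {phenotype}",
                         factor_term = NULL, phenotype_term = NULL) {
  stopifnot(inherits(factor, "dice_factor"),
            inherits(phenotype, "dice_phenotype"),
            is.character(template), length(template) == 1L)
  database <- match.arg(database, .dice_databases)
  if (!grepl("{factor}", template, fixed = TRUE) ||
      !grepl("{phenotype}", template, fixed = TRUE)) {
    stop("template must contain both {factor} and {phenotype} placeholders")
  }
  factor_terms <- unique(c(factor$name, factor$aliases))
  factor_terms <- factor_terms[nzchar(factor_terms)]
  phenotype_terms <- phenotype$name[nzchar(phenotype$name)]
  if (length(factor_terms) == 0L) stop("factor has no non-empty search terms")
  if (length(phenotype_terms) == 0L) {
    stop("phenotype has no non-empty search terms")
  }
  if (is.null(factor_term)) factor_term <- factor_terms[[1L]]
  if (is.null(phenotype_term)) phenotype_term <- phenotype_terms[[1L]]
  raw <- gsub("{factor}", factor_term, template, fixed = TRUE)
  raw <- gsub("{phenotype}", phenotype_term, raw, fixed = TRUE)
  structure(
    list(factor_terms = factor_terms, phenotype_terms = phenotype_terms,
         database = database, raw_query = raw),
    class = "evidence_query"
  )
}

#' Offline fixture-backed evidence provider
#'
#' Answers evidence queries from a local lookup table instead of a live web
#' service, so that semi-automated evidence gathering is fully reproducible
#' and no test or batch run touches the network. Live adapters (e.g. NCBI
#' E-utilities) would implement the same [search_evidence()] generic for
#' their own provider class; none ship with this package.
#'
#' @param table Either a data frame with columns `raw_query` and
#'   `record_ids` (comma-separated ids), or the path of a two-column
#'   tab-delimited file with those columns.
#' @param databases Databases this provider answers for; default all.
#' @return An object of classes `fixture_provider`, `evidence_provider`.
#' @export
fixture_provider <- function(table, databases = .dice_databases) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE,
                               colClasses = "character")
  }
  stopifnot(is.data.frame(table),
            all(c("raw_query", "record_ids") %in% names(table)))
  databases <- match.arg(databases, .dice_databases, several.ok = TRUE)
  structure(list(table = table, databases = databases),
            class = c("fixture_provider", "evidence_provider"))
}

#' Run an evidence query against a provider
#'
#' @param provider An `evidence_provider`, e.g. [fixture_provider()].
#' @param query An `evidence_query` from [render_query()].
#' @return An object of class `query_result` with the query, `hit_count`,
#'   `record_ids`, `retrieved_at` (`"fixture"` for offline providers), and
#'   `not_in_fixture` (`TRUE` when a fixture provider had no entry for the
#'   query, in which case `hit_count` is 0).
#' @export
search_evidence <- function(provider, query) {
  UseMethod("search_evidence")
}

#' @export
search_evidence.fixture_provider <- function(provider, query) {
  stopifnot(inherits(query, "evidence_query"))
  if (!query$database %in% provider$databases) {
    stop(sprintf("no provider registered for database '%s'", query$database))
  }
  hit <- match(query$raw_query, provider$table$raw_query)
  if (is.na(hit)) {
    ids <- character()
    missing <- TRUE
  } else {
    ids <- strsplit(provider$table$record_ids[hit], ",", fixed = TRUE)[[1L]]
    ids <- trimws(ids)
    ids <- ids[nzchar(ids)]
    missing <- FALSE
  }
  structure(
    list(query = query, hit_count = length(ids), record_ids = ids,
         retrieved_at = "fixture", not_in_fixture = missing),
    class = "query_result"
  )
}

#' @export
search_evidence.default <- function(provider, query) {
  stop("no search_evidence() method for this provider")
}

#' Turn a query result into machine-proposed evidence items
#'
#' A query with at least one hit yields a single informatic evidence item
#' with `reviewed = FALSE`: a *proposal* for human review, never an
#' automatic award — under the default configuration unreviewed items are
#' excluded from scoring, so a proposed item changes no score until an
#' expert confirms it and flips `reviewed`. A query with no hits yields
#' nothing.
#'
#' @param result A `query_result` from [search_evidence()].
#' @param item_id Identifier for the proposed item; a deterministic id
#'   derived from the query is used when omitted.
#' @return List of zero or one [evidence_item()].
#' @export
propose_items <- function(result, item_id = NULL) {
  stopifnot(inherits(result, "query_result"))
  if (result$hit_count < 1L) return(list())
  db <- result$query$database
  if (is.null(item_id)) {
    item_id <- paste0("proposed_", db, "_",
                      gsub("[^a-z0-9]+", "_", tolower(result$query$raw_query)))
  }
  src <- sprintf("%s search '%s' [%s]", db, result$query$raw_query,
                 paste(result$record_ids, collapse = ", "))
  list(evidence_item(
    item_id = item_id, category = "informatic",
    subtype = unname(.database_subtype[db]),
    source = src, reviewed = FALSE,
    result_key = paste0(db, ":", result$query$raw_query)))
}
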