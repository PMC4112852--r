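#' The published dossier schema
#'
#' The dossier file contract (required and optional fields, controlled
#' vocabularies) ships with the package as
#' `extdata/dossier-schema.json`; this function loads it.
#'
#' @return The parsed schema (a nested list).
#' @export
dossier_schema <- function() {
  path <- system.file("extdata", "dossier-schema.json",
                      package = "dicescore", mustWork = TRUE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

.is_scalar_string <- function(x) is.character(x) && length(x) == 1L
.is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L
.is_scalar_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

.check_fields <- function(x, spec, where) {
  v <- character()
  if (!is.list(x)) {
    return(sprintf("%s: expected a mapping, got %s", where, class(x)[1L]))
  }
  for (f in spec$required) {
    if (is.null(x[[f]])) {
      v <- c(v, sprintf("%s: missing required field '%s'", where, f))
    }
  }
  known <- c(spec$required, spec$optional)
  for (f in setdiff(names(x), known)) {
    v <- c(v, sprintf("%s: unknown field '%s'", where, f))
  }
  v
}

#' Check a parsed dossier document against the schema
#'
#' Structural conformance check for a dossier read from YAML or JSON,
#' before object construction: required fields, field types, and controlled
#' vocabularies, with each violation carrying the field path (e.g.
#' `items[3].category`). Value-level invariants (p-value range, duplicate
#' ids) are the province of [validate_dossier()].
#'
#' @param x A nested list as returned by `yaml::read_yaml()` or
#'   `jsonlite::fromJSON(..., simplifyVector = FALSE)`.
#' @param schema Schema list; default [dossier_schema()].
#' @return Character vector of violations; empty if conformant.
#' @export
check_dossier_schema <- function(x, schema = dossier_schema()) {
  v <- .check_fields(x, schema$dossier, "dossier")
  if (length(v)) return(v)

  v <- c(v, .check_fields(x$factor, schema$factor, "factor"))
  if (!is.null(x$factor$name) && !.is_scalar_string(x$factor$name)) {
    v <- c(v, "factor.name: must be a string")
  }
  fc <- x$factor$factor_class
  if (!is.null(fc) && (!.is_scalar_string(fc) ||
                       !fc %in% schema$factor$factor_class_enum)) {
    v <- c(v, sprintf("factor.factor_class: must be one of %s",
                      paste(schema$factor$factor_class_enum, collapse = ", ")))
  }

  v <- c(v, .check_fields(x$phenotype, schema$phenotype, "phenotype"))
  if (!is.null(x$phenotype$name) && !.is_scalar_string(x$phenotype$name)) {
    v <- c(v, "phenotype.name: must be a string")
  }

  if (!is.null(x$notes) && !.is_scalar_string(x$notes)) {
    v <- c(v, "notes: must be a string")
  }

  if (!is.null(x$items) && !is.list(x$items)) {
    v <- c(v, "items: must be a list")
    return(v)
  }
  for (i in seq_along(x$items)) {
    it <- x$items[[i]]
    where <- sprintf("items[%d]", i)
    iv <- .check_fields(it, schema$item, where)
    v <- c(v, iv)
    if (length(iv)) next
    for (f in c("item_id", "category", "subtype", "source", "result_key")) {
      if (!.is_scalar_string(it[[f]])) {
        v <- c(v, sprintf("%s.%s: must be a string", where, f))
      }
    }
    if (.is_scalar_string(it$category)) {
      if (!it$category %in% schema$item$category_enum) {
        v <- c(v, sprintf("%s.category: '%s' not one of %s", where,
                          it$category,
                          paste(schema$item$category_enum, collapse = ", ")))
      } else if (.is_scalar_string(it$subtype) &&
                 !it$subtype %in% schema$item$subtype_enum[[it$category]]) {
        v <- c(v, sprintf("%s.subtype: '%s' not valid for category '%s'",
                          where, it$subtype, it$category))
      }
    }
    if (!is.null(it$p_value) && !.is_scalar_number(it$p_value)) {
      v <- c(v, sprintf("%s.p_value: must be a number", where))
    }
    if (!is.null(it$significant_override) &&
        !.is_scalar_flag(it$significant_override)) {
      v <- c(v, sprintf("%s.significant_override: must be a boolean", where))
    }
    if (!is.null(it$reviewed) && !.is_scalar_flag(it$reviewed)) {
      v <- c(v, sprintf("%s.reviewed: must be a boolean", where))
    }
    if (!is.null(it$effect)) {
      ev <- .check_fields(it$effect, schema$effect,
                          sprintf("%s.effect", where))
      v <- c(v, ev)
      if (!length(ev)) {
        for (f in c("odds_ratio", "ci_lower", "ci_upper")) {
          if (!.is_scalar_number(it$effect[[f]])) {
            v <- c(v, sprintf("%s.effect.%s: must be a number", where, f))
          }
        }
      }
    }
  }
  v
}

#' Validate a dossier file against the published schema
#'
#' Parses a YAML or JSON dossier file and reports schema violations without
#' constructing objects — the check behind the `dice validate-schema`
#' command.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` dossier file.
#' @return Character vector of violations; empty if the file conforms.
#' @export
validate_dossier_file <- function(path) {
  x <- .parse_dossier_file(path)
  check_dossier_schema(x)
}
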