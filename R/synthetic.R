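#' Specification for the synthetic dossier generator
#'
#' Parameters controlling [generate_synthetic()]. The generator emulates
#' the inputs the scoring engine consumes — evidence dossiers, a GWAS hit
#' table, a provider lookup table — at the level needed to exercise
#' threshold logic and rubric arithmetic; it makes no claim of GWAS
#' realism (no genotypes, LD, or association testing).
#'
#' Significant discovery p-values are drawn log-uniform in
#' `[1e-12, discovery_threshold)`; null p-values uniform on (0, 1).
#' Validation items, when generated, carry p-values below the nominal 0.05
#' validation threshold.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_dossiers Number of dossiers to generate.
#' @param category_presence_probs Named probabilities that a dossier
#'   contains omic / informatic / experimental evidence.
#' @param fraction_significant Probability that a discovery item is drawn
#'   significant.
#' @param fraction_with_validation Probability that a dossier with omic
#'   evidence also carries a validation item.
#' @param validation_type_probs Named probabilities (standard,
#'   alternative) for the validation item's subtype.
#' @param fraction_reviewed Probability that an item is human-reviewed.
#' @param override_fraction Probability that a significant discovery is
#'   expressed as an explicit significance override (e.g. fine mapping)
#'   rather than a scan p-value.
#' @param discovery_threshold Threshold the significant component is drawn
#'   against; keep equal to the scoring config's threshold.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           n_dossiers = 10L,
                           category_presence_probs = c(omic = 0.8,
                                                       informatic = 0.5,
                                                       experimental = 0.4),
                           fraction_significant = 0.6,
                           fraction_with_validation = 0.5,
                           validation_type_probs = c(standard = 0.5,
                                                     alternative = 0.5),
                           fraction_reviewed = 1,
                           override_fraction = 0.1,
                           discovery_threshold = 5e-8) {
  probs <- c(category_presence_probs, fraction_significant,
             fraction_with_validation, validation_type_probs,
             fraction_reviewed, override_fraction)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == as.integer(seed),
            is.numeric(n_dossiers), length(n_dossiers) == 1L, n_dossiers >= 0,
            is.numeric(probs), all(probs >= 0), all(probs <= 1),
            all(c("omic", "informatic", "experimental") %in%
                  names(category_presence_probs)),
            all(c("standard", "alternative") %in%
                  names(validation_type_probs)),
            sum(validation_type_probs) > 0,
            is.numeric(discovery_threshold), discovery_threshold > 0,
            discovery_threshold < 1)
  structure(
    list(seed = as.integer(seed), n_dossiers = as.integer(n_dossiers),
         category_presence_probs = category_presence_probs,
         fraction_significant = fraction_significant,
         fraction_with_validation = fraction_with_validation,
         validation_type_probs = validation_type_probs,
         fraction_reviewed = fraction_reviewed,
         override_fraction = override_fraction,
         discovery_threshold = discovery_threshold),
    class = "generator_spec"
  )
}

# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic dossiers, a hit table, and a provider table
#'
#' Seeded, reproducible generation of arbitrary test inputs. Alongside each
#' dossier the generator records the component points it expects the rubric
#' to award, computed by its own direct bookkeeping of what it generated —
#' a codepath independent of the scoring engine — so tests can assert that
#' engine output matches ground truth on every dossier.
#'
#' @param spec A [generator_spec()].
#' @param config A [rubric_config()]; the ground truth honours its point
#'   values, `require_reviewed` and `validation_requires_discovery`
#'   settings.
#' @return List with `dossiers` (list of [dossier()]s), `truth` (data frame
#'   of expected per-category points, total and classification, one row per
#'   dossier), `hits` (GWAS hit table covering every generated discovery
#'   p-value), and `provider_table` (fixture lookup rows for dossiers with
#'   informatic evidence).
#' @examples
#' out <- generate_synthetic(generator_spec(seed = 7, n_dossiers = 3))
#' score_dossier(out$dossiers[[1]])$total == out$truth$total[1]
#' @export
generate_synthetic <- function(spec, config = rubric_config()) {
  stopifnot(inherits(spec, "generator_spec"),
            inherits(config, "rubric_config"))
  .with_seed(spec$seed, {
    dossiers <- vector("list", spec$n_dossiers)
    truth <- vector("list", spec$n_dossiers)
    hit_rows <- list()
    provider_rows <- list()
    variant_counter <- 0L

    for (i in seq_len(spec$n_dossiers)) {
      gene <- sprintf("GENE%03d", i)
      items <- list()
      # generator-side bookkeeping, kept independent of the engine
      any_sig_discovery <- FALSE
      validation_pts <- 0L
      any_informatic <- FALSE
      any_experimental <- FALSE

      if (stats::runif(1) < spec$category_presence_probs[["omic"]]) {
        n_disc <- sample(1:3, 1L)
        for (j in seq_len(n_disc)) {
          significant <- stats::runif(1) < spec$fraction_significant
          reviewed <- stats::runif(1) < spec$fraction_reviewed
          use_override <- significant &&
            stats::runif(1) < spec$override_fraction
          p <- NULL
          override <- NULL
          if (use_override) {
            override <- TRUE
          } else if (significant) {
            p <- 10^stats::runif(1, -12, log10(spec$discovery_threshold))
          } else {
            p <- stats::runif(1)
          }
          variant_counter <- variant_counter + 1L
          vid <- sprintf("rs%06d", variant_counter)
          items <- c(items, list(evidence_item(
            item_id = sprintf("%s_disc%d", tolower(gene), j),
            category = "omic", subtype = "discovery",
            p_value = p, significant_override = override,
            source = "synthetic omic screen", reviewed = reviewed,
            result_key = paste0("syn:", vid))))
          if (!is.null(p)) {
            hit_rows[[length(hit_rows) + 1L]] <- data.frame(
              variant_id = vid, gene = gene, p_value = p,
              intergenic = FALSE, stringsAsFactors = FALSE)
          }
          counts <- if (config$require_reviewed) reviewed else TRUE
          # truth: significance means override, or p below the scoring
          # threshold (drawn below the generator threshold; equal configs
          # assumed, asserted here for safety)
          sig_for_truth <- use_override ||
            (!is.null(p) && p < config$discovery_threshold)
          if (counts && sig_for_truth) any_sig_discovery <- TRUE
        }
        if (stats::runif(1) < spec$fraction_with_validation) {
          type <- sample(c("standard", "alternative"), 1L,
                         prob = spec$validation_type_probs)
          reviewed <- stats::runif(1) < spec$fraction_reviewed
          p <- stats::runif(1, 1e-6, 0.04)
          items <- c(items, list(evidence_item(
            item_id = sprintf("%s_val", tolower(gene)),
            category = "omic", subtype = paste0(type, "_validation"),
            p_value = p, source = "synthetic validation study",
            reviewed = reviewed,
            result_key = paste0("synval:", gene))))
          counts <- if (config$require_reviewed) reviewed else TRUE
          if (counts && p < config$validation_threshold) {
            validation_pts <- if (type == "standard") {
              config$points_standard_validation
            } else {
              config$points_alternative_validation
            }
          }
        }
      }

      if (stats::runif(1) < spec$category_presence_probs[["informatic"]]) {
        n_info <- sample(1:2, 1L)
        for (j in seq_len(n_info)) {
          reviewed <- stats::runif(1) < spec$fraction_reviewed
          items <- c(items, list(evidence_item(
            item_id = sprintf("%s_info%d", tolower(gene), j),
            category = "informatic", subtype = "literature",
            source = sprintf("synthetic literature hit %d", j),
            reviewed = reviewed,
            result_key = sprintf("syninfo:%s_%d", gene, j))))
          if (if (config$require_reviewed) reviewed else TRUE) {
            any_informatic <- TRUE
          }
        }
        provider_rows[[length(provider_rows) + 1L]] <- data.frame(
          raw_query = paste(tolower(gene), "and synthetic phenotype"),
          record_ids = sprintf("syn%d", i), stringsAsFactors = FALSE)
      }

      if (stats::runif(1) < spec$category_presence_probs[["experimental"]]) {
        n_exp <- sample(1:2, 1L)
        for (j in seq_len(n_exp)) {
          reviewed <- stats::runif(1) < spec$fraction_reviewed
          items <- c(items, list(evidence_item(
            item_id = sprintf("%s_exp%d", tolower(gene), j),
            category = "experimental", subtype = "cell_molecular",
            source = sprintf("synthetic experiment %d", j),
            reviewed = reviewed,
            result_key = sprintf("synexp:%s_%d", gene, j))))
          if (if (config$require_reviewed) reviewed else TRUE) {
            any_experimental <- TRUE
          }
        }
      }

      dossiers[[i]] <- dossier(
        dice_factor(gene, "gene"),
        phenotype("synthetic phenotype"),
        items = items,
        notes = "synthetic dossier")

      single <- if (any_sig_discovery) config$points_single_finding else 0L
      val <- validation_pts
      if (config$validation_requires_discovery && single == 0L) val <- 0L
      info <- if (any_informatic) config$points_informatic else 0L
      expp <- if (any_experimental) config$points_experimental else 0L
      total <- single + val + info + expp
      truth[[i]] <- data.frame(
        factor = gene,
        single_finding = as.integer(single), validation = as.integer(val),
        informatic = as.integer(info), experimental = as.integer(expp),
        total = as.integer(total),
        classification = if (total >= config$strong_cutoff) "strong"
                         else "weak",
        stringsAsFactors = FALSE)
    }

    empty_hits <- data.frame(variant_id = character(), gene = character(),
                             p_value = numeric(), intergenic = logical(),
                             stringsAsFactors = FALSE)
    empty_provider <- data.frame(raw_query = character(),
                                 record_ids = character(),
                                 stringsAsFactors = FALSE)
    list(
      dossiers = dossiers,
      truth = if (length(truth)) {
        do.call(rbind, c(truth, list(make.row.names = FALSE)))
      } else {
        data.frame(factor = character(), single_finding = integer(),
                   validation = integer(), informatic = integer(),
                   experimental = integer(), total = integer(),
                   classification = character(), stringsAsFactors = FALSE)
      },
      hits = if (length(hit_rows)) {
        do.call(rbind, c(hit_rows, list(make.row.names = FALSE)))
      } else empty_hits,
      provider_table = if (length(provider_rows)) {
        do.call(rbind, c(provider_rows, list(make.row.names = FALSE)))
      } else empty_provider)
  })
}

#' Write canonical and synthetic fixtures to a directory
#'
#' Materialises everything the file-based interfaces consume: the five
#' canonical dossiers, the published study-effects table, the offline
#' provider table, a malaria hit table, and a seeded synthetic set
#' (dossiers under `synthetic/`, `synthetic_hits.tsv`,
#' `synthetic_provider.tsv`, `synthetic_truth.tsv`).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the synthetic set.
#' @param n_dossiers Number of synthetic dossiers.
#' @return `out_dir`, invisibly.
#' @export
write_fixture_files <- function(out_dir, seed = 1L, n_dossiers = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "dossiers"), showWarnings = FALSE)
  fx <- canonical_fixtures()
  for (n in names(fx)) {
    write_dossier(fx[[n]], file.path(out_dir, "dossiers",
                                     paste0(n, ".yaml")))
  }
  for (f in c("pparg_effects.tsv", "provider_pubmed.tsv",
              "malaria_hits.tsv")) {
    file.copy(system.file("extdata", f, package = "dicescore",
                          mustWork = TRUE),
              file.path(out_dir, f), overwrite = TRUE)
  }
  syn <- generate_synthetic(generator_spec(seed = seed,
                                           n_dossiers = n_dossiers))
  dir.create(file.path(out_dir, "synthetic"), showWarnings = FALSE)
  for (d in syn$dossiers) {
    write_dossier(d, file.path(out_dir, "synthetic",
                               paste0(tolower(d$factor$name), ".yaml")))
  }
  utils::write.table(syn$hits, file.path(out_dir, "synthetic_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(syn$provider_table,
                     file.path(out_dir, "synthetic_provider.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(syn$truth, file.path(out_dir, "synthetic_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
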