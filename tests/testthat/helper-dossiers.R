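# Shorthand builders for evidence items and dossiers used across the suite.

mk_item <- function(id, category, subtype, p = NULL, override = NULL,
                    reviewed = TRUE, key = id, effect = NULL) {
  evidence_item(item_id = id, category = category, subtype = subtype,
                p_value = p, significant_override = override,
                effect = effect, source = paste("test item", id),
                reviewed = reviewed, result_key = key)
}

mk_dossier <- function(items, name = "G1", phen = "test phenotype") {
  dossier(dice_factor(name, "gene"), phenotype(phen), items = items)
}

# A random small item, used by property tests. Duplicate result keys are
# drawn from a small pool so deduplication is actually exercised.
random_item <- function(id, key_pool = sprintf("k%d", 1:4)) {
  category <- sample(c("omic", "informatic", "experimental"), 1)
  subtype <- switch(category,
    omic = sample(c("discovery", "standard_validation",
                    "alternative_validation"), 1),
    informatic = sample(c("literature", "pathway_db", "expression_db",
                          "other_db"), 1),
    experimental = sample(c("animal_model", "cell_molecular", "treatment"),
                          1))
  p <- NULL
  override <- NULL
  if (category == "omic") {
    r <- runif(1)
    if (r < 0.2) {
      override <- sample(c(TRUE, FALSE), 1)
    } else if (r < 0.6) {
      p <- 10^runif(1, -12, log10(5e-8))   # significant at discovery level
    } else {
      p <- runif(1)
    }
  }
  mk_item(id, category, subtype, p = p, override = override,
          reviewed = runif(1) < 0.9, key = sample(key_pool, 1))
}

random_dossier <- function(n_items, name = "GR1") {
  ids <- sprintf("it%02d", seq_len(n_items))
  mk_dossier(lapply(ids, random_item), name = name)
}

# Independent brute-force oracle for the composite score: enumerates every
# subset of items in which each underlying result (result_key) is used at
# most once, scores each subset naively, and returns the maximum. Shares no
# code with the engine. Only feasible for small dossiers (2^n subsets).
oracle_total <- function(items, config = rubric_config()) {
  n <- length(items)
  if (config$require_reviewed) {
    items <- Filter(function(it) it$reviewed, items)
    n <- length(items)
  }
  naive_score <- function(sub) {
    sig <- function(it, thr) {
      if (!is.null(it$significant_override)) return(isTRUE(it$significant_override))
      if (!is.null(it$p_value)) return(it$p_value < thr)
      FALSE
    }
    single <- 0
    val <- 0
    info <- 0
    ex <- 0
    has_std <- FALSE
    has_alt <- FALSE
    for (it in sub) {
      if (it$category == "omic") {
        if (it$subtype == "discovery" && sig(it, config$discovery_threshold))
          single <- config$points_single_finding
        if (it$subtype == "standard_validation" &&
            sig(it, config$validation_threshold)) has_std <- TRUE
        if (it$subtype == "alternative_validation" &&
            sig(it, config$validation_threshold)) has_alt <- TRUE
      } else if (it$category == "informatic") {
        info <- config$points_informatic
      } else if (it$category == "experimental") {
        ex <- config$points_experimental
      }
    }
    if (has_std) val <- config$points_standard_validation
    else if (has_alt) val <- config$points_alternative_validation
    if (config$validation_requires_discovery && single == 0) val <- 0
    single + val + info + ex
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- items[keep]
    keys <- vapply(sub, `[[`, "", "result_key")
    if (anyDuplicated(keys)) next
    best <- max(best, naive_score(sub))
  }
  as.integer(best)
}
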