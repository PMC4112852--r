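make_evidence_dir <- function(genes = c("ATP2B4", "MARVELD3")) {
  dir <- tempfile("evidence")
  dir.create(dir)
  fx <- canonical_fixtures()
  lookup <- c(ATP2B4 = "atp2b4", MARVELD3 = "marveld3", TAT = "tat")
  for (g in genes) {
    write_dossier(fx[[lookup[[g]]]], file.path(dir, paste0(g, ".yaml")))
  }
  dir
}

test_that("batch scoring separates near-identical p-values by their diverse evidence", {
  hits <- read_gwas_hits(system.file("extdata", "malaria_hits.tsv",
                                     package = "dicescore", mustWork = TRUE))
  dir <- make_evidence_dir()
  report <- batch_score(hits, evidence_dir = dir)
  rows <- report$rows
  expect_identical(nrow(rows), 2L)
  # ATP2B4 ranks first on total 9 despite the near-identical p-values
  expect_identical(rows$factor, c("ATP2B4", "MARVELD3"))
  expect_identical(rows$total, c(9L, 1L))
  expect_identical(rows$classification, c("strong", "weak"))
  expect_identical(rows$next_step,
                   c("laboratory follow-up",
                     "consider nearby-factor reattribution"))
  expect_identical(rows$n_hits, c(5L, 1L))
  unlink(dir, recursive = TRUE)
})

test_that("hits without a dossier are scored against an empty dossier, still reported", {
  hits <- data.frame(variant_id = c("v1", "v2"),
                     gene = c("NOVEL1", "NOVEL2"),
                     p_value = c(1e-9, 0.2),
                     stringsAsFactors = FALSE)
  report <- batch_score(hits)
  rows <- report$rows
  # significant hit earns only the single-finding point; the sub-threshold
  # hit contributes nothing but still appears
  expect_identical(rows$total[rows$factor == "NOVEL1"], 1L)
  expect_identical(rows$total[rows$factor == "NOVEL2"], 0L)
  expect_identical(unique(rows$next_step),
                   "gather informatic/experimental evidence")
})

test_that("an unreadable dossier yields a per-row error and the run continues", {
  dir <- tempfile("evidence")
  dir.create(dir)
  writeLines("items: [", file.path(dir, "BROKEN.yaml"))
  hits <- data.frame(variant_id = c("v1", "v2"),
                     gene = c("BROKEN", "OK"),
                     p_value = c(1e-9, 1e-9), stringsAsFactors = FALSE)
  report <- batch_score(hits, evidence_dir = dir)
  rows <- report$rows
  expect_identical(nrow(rows), 2L)
  expect_true(is.na(rows$total[rows$factor == "BROKEN"]))
  expect_false(is.na(rows$error[rows$factor == "BROKEN"]))
  expect_identical(rows$total[rows$factor == "OK"], 1L)
  unlink(dir, recursive = TRUE)
})

test_that("an empty hit table yields an empty report", {
  report <- batch_score(data.frame(variant_id = character(),
                                   gene = character(),
                                   p_value = numeric()))
  expect_identical(nrow(report$rows), 0L)
})

test_that("batch totals match per-dossier recomputation on a synthetic hit table", {
  syn <- generate_synthetic(generator_spec(seed = 99, n_dossiers = 40))
  dir <- tempfile("evidence")
  dir.create(dir)
  for (d in syn$dossiers) {
    write_dossier(d, file.path(dir, paste0(d$factor$name, ".yaml")))
  }
  hits <- syn$hits
  report <- batch_score(hits, evidence_dir = dir)
  expect_identical(nrow(report$rows), length(unique(hits$gene)))
  # oracle: recompute each gene's score from scratch, merging its hits
  for (i in seq_len(nrow(report$rows))) {
    g <- report$rows$factor[i]
    d <- syn$dossiers[[which(vapply(syn$dossiers,
                                    function(x) x$factor$name, "") == g)]]
    gh <- hits[hits$gene == g, , drop = FALSE]
    for (j in seq_len(nrow(gh))) {
      d$items <- c(d$items, list(
        evidence_item(paste0("hit_", gh$variant_id[j]), "omic", "discovery",
                      p_value = gh$p_value[j], source = "hit",
                      result_key = paste0("gwas:", gh$variant_id[j]))))
    }
    expect_identical(report$rows$total[i], score_dossier(d)$total,
                     info = g)
  }
  # rows sorted by total desc then min p asc
  expect_true(all(diff(report$rows$total) <= 0))
  unlink(dir, recursive = TRUE)
})

test_that("batch reports serialise deterministically with the config embedded", {
  hits <- data.frame(variant_id = "v1", gene = "G1", p_value = 1e-9,
                     stringsAsFactors = FALSE)
  report <- batch_score(hits)
  for (fmt in c("json", "tsv")) {
    expect_identical(format_batch_report(report, fmt),
                     format_batch_report(report, fmt))
  }
  js <- jsonlite::fromJSON(format_batch_report(report, "json"))
  expect_identical(js$config$discovery_threshold, 5e-8)
  expect_match(format_batch_report(report, "tsv"),
               "# discovery_threshold: 5e-08", fixed = TRUE)
})
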