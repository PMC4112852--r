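test_that("score_omic awards the single-finding point and the validation tier", {
  cfg <- rubric_config()

  # significant discovery alone: (1, 0)
  r <- score_omic(list(mk_item("d", "omic", "discovery", p = 6.1e-9)), cfg)
  expect_identical(r$single_finding_points, 1L)
  expect_identical(r$validation_points, 0L)
  expect_identical(r$attribution$single_finding, "d")

  # fine-mapping override + alternative validation: (1, 2)
  r <- score_omic(list(
    mk_item("d", "omic", "discovery", override = TRUE),
    mk_item("v", "omic", "alternative_validation", override = TRUE)), cfg)
  expect_identical(r$single_finding_points, 1L)
  expect_identical(r$validation_points, 2L)

  # standard validation strictly supersedes alternative: never both, never 5
  r <- score_omic(list(
    mk_item("d", "omic", "discovery", p = 1e-9),
    mk_item("vs", "omic", "standard_validation", p = 0.001),
    mk_item("va", "omic", "alternative_validation", p = 0.001)), cfg)
  expect_identical(r$validation_points, 3L)
  expect_identical(r$attribution$validation, "vs")

  # sub-threshold discovery + significant meta-analysis validation:
  # (0, 0) because validation presupposes a qualifying initial finding
  r <- score_omic(list(
    mk_item("d", "omic", "discovery", p = 0.0013),
    mk_item("v", "omic", "alternative_validation", p = 1.7e-6)), cfg)
  expect_identical(r$single_finding_points, 0L)
  expect_identical(r$validation_points, 0L)

  # ...but awarded when the requirement is relaxed
  cfg2 <- rubric_config(validation_requires_discovery = FALSE)
  r <- score_omic(list(
    mk_item("d", "omic", "discovery", p = 0.0013),
    mk_item("v", "omic", "alternative_validation", p = 1.7e-6)), cfg2)
  expect_identical(r$validation_points, 2L)

  # empty list
  r <- score_omic(list(), cfg)
  expect_identical(r$single_finding_points, 0L)
  expect_identical(r$validation_points, 0L)

  # non-omic item is caller misuse
  expect_error(score_omic(list(mk_item("x", "informatic", "literature"))),
               "not in category")
})

test_that("informatic and experimental categories award full points once, without accumulation", {
  cfg <- rubric_config()
  one <- list(mk_item("i1", "informatic", "literature"))
  five <- lapply(sprintf("i%d", 1:5), mk_item,
                 category = "informatic", subtype = "literature")
  expect_identical(score_informatic(one, cfg)$points, 3L)
  expect_identical(score_informatic(five, cfg)$points, 3L)
  expect_identical(score_informatic(list(), cfg)$points, 0L)
  # all qualifying items are listed in the attribution
  expect_length(score_informatic(five, cfg)$attribution, 5)

  expect_identical(
    score_experimental(list(mk_item("e1", "experimental", "animal_model")),
                       cfg)$points, 3L)
  expect_identical(
    score_experimental(lapply(sprintf("e%d", 1:3), mk_item,
                              category = "experimental",
                              subtype = "cell_molecular"), cfg)$points, 3L)
  expect_error(score_experimental(one, cfg), "not in category")
})

test_that("classify applies the strong-evidence cutoff inclusively", {
  expect_identical(classify(9), "strong")
  expect_identical(classify(6), "strong")
  expect_identical(classify(5), "weak")
  expect_identical(classify(0), "weak")
  expect_identical(classify(5, rubric_config(strong_cutoff = 5L)), "strong")
})

test_that("score_dossier is additive, attributed, and rejects invalid dossiers", {
  s <- score_dossier(canonical_fixtures()$atp2b4)
  expect_identical(s$total,
                   s$single_finding_points + s$validation_points +
                     s$informatic_points + s$experimental_points)
  # attribution covers every awarded component
  expect_true(length(s$attribution$single_finding) > 0)
  expect_true(length(s$attribution$validation) > 0)
  expect_true(length(s$attribution$informatic) > 0)
  expect_true(length(s$attribution$experimental) > 0)
  # the just-above-threshold SNP does not appear in the attribution
  expect_false("atp2b4_snp4" %in% s$attribution$single_finding)

  expect_identical(score_dossier(mk_dossier(list()))$total, 0L)
  expect_identical(score_dossier(mk_dossier(list()))$classification, "weak")

  bad <- mk_dossier(list(mk_item("x", "omic", "discovery", p = 2)))
  expect_error(score_dossier(bad), "invalid dossier")
})

test_that("unreviewed items are excluded from scoring unless the rubric allows them", {
  items <- list(mk_item("i1", "informatic", "literature", reviewed = FALSE))
  expect_identical(score_dossier(mk_dossier(items))$total, 0L)
  cfg <- rubric_config(require_reviewed = FALSE)
  expect_identical(score_dossier(mk_dossier(items), cfg)$total, 3L)
})

test_that("score_dossier is invariant to item ordering", {
  set.seed(7)
  for (rep in 1:10) {
    d <- random_dossier(6)
    s1 <- score_dossier(d)
    d2 <- d
    d2$items <- sample(d2$items)
    expect_identical(score_dossier(d2), s1)
  }
})

test_that("engine totals agree with the brute-force subset oracle on small dossiers", {
  set.seed(11)
  for (rep in 1:60) {
    d <- random_dossier(sample(1:6, 1))
    expect_identical(score_dossier(d)$total, oracle_total(d$items),
                     info = paste("rep", rep))
  }
})

test_that("adding evidence never decreases the total", {
  set.seed(23)
  for (rep in 1:40) {
    d <- random_dossier(sample(0:5, 1))
    extra <- random_item("extra01")
    d2 <- d
    d2$items <- c(d2$items, list(extra))
    expect_gte(score_dossier(d2)$total, score_dossier(d)$total)
  }
})

test_that("no single category reaches strong under defaults; two categories can", {
  cfg <- rubric_config()
  # maximal single-category dossiers: omic 1+3 = 4, informatic 3,
  # experimental 3 — all below the cutoff of 6
  omic_only <- mk_dossier(list(
    mk_item("d", "omic", "discovery", p = 1e-9, key = "k1"),
    mk_item("v", "omic", "standard_validation", p = 1e-4, key = "k2")))
  info_only <- mk_dossier(lapply(sprintf("i%d", 1:4), mk_item,
                                 category = "informatic",
                                 subtype = "literature"))
  exp_only <- mk_dossier(lapply(sprintf("e%d", 1:4), mk_item,
                                category = "experimental",
                                subtype = "treatment"))
  for (d in list(omic_only, info_only, exp_only)) {
    expect_identical(score_dossier(d, cfg)$classification, "weak")
  }
  # exactly two categories: full omic (4) + informatic (3) = 7, and
  # omic with alternative validation (3) + informatic (3) = 6
  two_a <- mk_dossier(c(omic_only$items,
                        list(mk_item("i", "informatic", "literature"))))
  expect_identical(score_dossier(two_a, cfg)$classification, "strong")
  two_b <- mk_dossier(list(
    mk_item("d", "omic", "discovery", p = 1e-9, key = "k1"),
    mk_item("v", "omic", "alternative_validation", p = 1e-4, key = "k2"),
    mk_item("i", "informatic", "literature")))
  expect_identical(score_dossier(two_b, cfg)$total, 6L)
  expect_identical(score_dossier(two_b, cfg)$classification, "strong")
})

test_that("rubric_config rejects inconsistent settings", {
  expect_error(rubric_config(discovery_threshold = 0))
  expect_error(rubric_config(points_alternative_validation = 4L),
               "must not exceed")
  expect_error(rubric_config(strong_cutoff = 11L), "maximum attainable")
})
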