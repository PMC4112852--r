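test_that("log OR and SE back-calculate from the printed CI", {
  # hand-computed: ln(1.23) = 0.20701, (ln 1.41 - ln 1.09)/(2 * 1.959964)
  est <- log_or_and_se(study_effect(1.23, 1.09, 1.41))
  expect_equal(unname(est["log_or"]), 0.20701, tolerance = 1e-4)
  expect_equal(unname(est["se"]), 0.06567, tolerance = 1e-3)

  est <- log_or_and_se(study_effect(1.09, 1.01, 1.16))
  expect_equal(unname(est["se"]), 0.03532, tolerance = 1e-3)

  # symmetric interval around OR 1: log OR exactly 0
  for (c_ in c(1.2, 2, 5)) {
    est <- log_or_and_se(study_effect(1, 1 / c_, c_))
    expect_identical(unname(est["log_or"]), 0)
  }
})

test_that("study_effect rejects malformed inputs with explanatory errors", {
  expect_error(study_effect(-1, 0.5, 2), "positive")
  expect_error(study_effect(1.2, 1.3, 1.1), "strictly less")
  expect_error(study_effect(1.2, 1.2, 1.2, label = "s"), "degenerate")
  expect_error(study_effect(2, 0.5, 1.5), "within")
  # CI inconsistent with the point estimate beyond log-scale tolerance
  expect_error(study_effect(1.55, 1.0, 1.6), "not consistent")
  expect_error(study_effect(1.2, 1.1, 1.3, ci_level = 1.5), "ci_level")
})

test_that("normal helpers are self-consistent", {
  expect_equal(z_crit(0.95), 1.959964, tolerance = 1e-6)
  expect_identical(two_sided_p_from_z(0), 1)
  expect_equal(two_sided_p_from_z(z_crit(0.95)), 0.05, tolerance = 1e-9)
  expect_equal(z_crit(1 - two_sided_p_from_z(1.7)), 1.7, tolerance = 1e-9)
  expect_error(z_crit(1), "in \\(0, 1\\)")
})

test_that("fixed-effect pooling matches an explicit-summation oracle and metafor", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    b <- rnorm(k, 0, 0.3)
    se <- runif(k, 0.03, 0.3)
    effects <- lapply(seq_len(k), function(i) {
      z <- z_crit(0.95)
      study_effect(exp(b[i]), exp(b[i] - z * se[i]), exp(b[i] + z * se[i]),
                   label = paste0("s", i))
    })
    m <- fixed_effect_meta(effects)
    # oracle: explicit weighted sums from the raw (b, se) pairs
    w <- 1 / se^2
    expect_equal(m$pooled_log_or, sum(w * b) / sum(w), tolerance = 1e-10)
    expect_equal(m$pooled_se, 1 / sqrt(sum(w)), tolerance = 1e-10)
    expect_equal(m$p_two_sided,
                 2 * pnorm(-abs(m$pooled_log_or / m$pooled_se)),
                 tolerance = 1e-12)
    if (requireNamespace("metafor", quietly = TRUE)) {
      fit <- metafor::rma(yi = b, sei = se, method = "FE")
      expect_equal(m$pooled_log_or, as.numeric(fit$beta), tolerance = 1e-8)
      expect_equal(m$pooled_se, as.numeric(fit$se), tolerance = 1e-8)
    }
  }
})

test_that("pooling identities: single study, replicated studies, order invariance", {
  e <- study_effect(1.23, 1.09, 1.41, label = "only")
  est <- log_or_and_se(e)
  m1 <- fixed_effect_meta(list(e))
  expect_equal(m1$pooled_log_or, unname(est["log_or"]))
  expect_equal(m1$pooled_se, unname(est["se"]))
  expect_equal(m1$p_two_sided,
               two_sided_p_from_z(est["log_or"] / est["se"]),
               ignore_attr = TRUE)

  m2 <- fixed_effect_meta(list(e, e))
  expect_equal(m2$pooled_log_or, m1$pooled_log_or)
  expect_equal(m2$pooled_se, m1$pooled_se / sqrt(2))
  for (n in c(3, 7)) {
    mn <- fixed_effect_meta(rep(list(e), n))
    expect_equal(mn$pooled_se, m1$pooled_se / sqrt(n))
  }

  effs <- pparg_study_effects()
  m_fwd <- fixed_effect_meta(effs)
  m_rev <- fixed_effect_meta(rev(effs))
  expect_equal(m_rev$pooled_log_or, m_fwd$pooled_log_or)
  expect_equal(m_rev$p_two_sided, m_fwd$p_two_sided)
})

test_that("inverting every odds ratio negates the pooled log OR and preserves p", {
  effs <- pparg_study_effects()
  inv <- lapply(effs, function(e) {
    study_effect(1 / e$odds_ratio, 1 / e$ci_upper, 1 / e$ci_lower,
                 label = e$label)
  })
  m <- fixed_effect_meta(effs)
  mi <- fixed_effect_meta(inv)
  expect_equal(mi$pooled_log_or, -m$pooled_log_or, tolerance = 1e-10)
  expect_equal(abs(mi$z_statistic), abs(m$z_statistic), tolerance = 1e-10)
  expect_equal(mi$p_two_sided, m$p_two_sided, tolerance = 1e-12)
})

test_that("the pooled SE is below every per-study SE", {
  effs <- pparg_study_effects()
  m <- fixed_effect_meta(effs)
  ses <- vapply(effs, function(e) unname(log_or_and_se(e)["se"]), 0)
  expect_true(all(m$pooled_se < ses))
})

test_that("meta-analysis input errors name the offending study", {
  expect_error(fixed_effect_meta(list()), "at least one")
  expect_error(fixed_effect_meta(list(study_effect(1.2, 1.1, 1.3), "x")),
               "element 2")
})

test_that("passes_threshold is strict and rejects out-of-range input", {
  expect_true(passes_threshold(6.1e-9, 5e-8))
  expect_false(passes_threshold(5e-8, 5e-8))
  expect_false(passes_threshold(0.83, 0.05))
  expect_identical(passes_threshold(c(1e-9, 0.5), 0.05), c(TRUE, FALSE))
  expect_error(passes_threshold(0, 0.05), "p must be")
  expect_error(passes_threshold(0.01, 1), "threshold")
})
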