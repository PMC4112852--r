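---
title: "Scoring diverse convergent evidence: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring diverse convergent evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicescore)
```

## The model

The Diverse Convergent Evidence (DiCE) score is a semi-formal heuristic,
not a probability model: an ordinal summary of how many *independent kinds*
of evidence implicate a candidate factor in a phenotype. Three categories
contribute:

* **Omic/observational** — 1 point for a single significant finding in a
  screening analysis, plus either 3 points for standard statistical
  validation (independent sample, same analytic approach) or 2 points for
  alternative statistical validation (meta-analysis, a distinct analytic
  method, or accounting for a masking covariate). Alternative validation is
  worth less because post hoc confirmation is weaker evidence.
* **Informatic** — 3 points when database or literature searches link the
  factor to the pathophysiology.
* **Experimental** — 3 points when laboratory experiments (animal models,
  cell/molecular work, treatment studies) support a role.

A total of at least 6 is classified *strong*. The three categories carry
roughly equal weight by design — no category can be picked a priori as the
most reliable — and the per-category maxima (4, 3, 3) guarantee that strong
evidence requires convergence from at least two categories. Within a
category, counts do not accumulate: five supportive papers earn the same 3
points as one, because validation counts within one data type have no
consistent relationship to truth and would mostly reward publication
volume.

The assumptions worth stating plainly: the point values are conventions,
not estimates; evidence quality within a category is judged by the human
who marks an item `reviewed`, not by the rubric; and the score is only as
good as the dossier — absent evidence lowers the score whether the factor
was studied and failed or simply never studied.

## Parameters

All tunables live in `rubric_config()`:

| Parameter | Default | Meaning |
|---|---|---|
| `discovery_threshold` | 5e-8 | Significance level for discovery items (strict `<`). The conventional genome-wide level; configurable because other thresholds are defensible, provided one rationale is used per run. |
| `validation_threshold` | 0.05 | Nominal level for validation items. Validation evidence (e.g. a pooled meta-analysis p of 1.7e-6) is reported at conventional significance; holding it to the genome-wide level would make the alternative-validation pathway nearly vacuous. |
| `points_single_finding` / `points_standard_validation` / `points_alternative_validation` | 1 / 3 / 2 | Omic awards. Standard strictly supersedes alternative: never both, never 5. |
| `points_informatic` / `points_experimental` | 3 / 3 | Presence awards. |
| `strong_cutoff` | 6 | Classification boundary, inclusive. |
| `require_reviewed` | TRUE | Machine-proposed items (`reviewed = FALSE`) are ignored until a human confirms them. |
| `validation_requires_discovery` | TRUE | Validation points presuppose a qualifying initial finding (see below). |

Two of these encode genuinely open design choices:

**Validation requires discovery.** In the published component patterns, a
factor with sub-threshold per-scan p-values and a significant meta-analysis
earns 0 validation points, implying that validation cannot stand alone: it
validates *something*, and that something is a qualifying initial finding.
We default `validation_requires_discovery = TRUE` accordingly, but expose
it because the rule is a reading of the worked examples, not an explicit
statement, and a researcher running a nominal-threshold triage
(`discovery_threshold = 0.05`) may reasonably relax it.

**Single counting as constrained maximisation.** A result appearing in
several categories must be counted once. `deduplicate()` keeps each
duplicated result in the category where it earns the dossier the most
points, with ties broken omic > experimental > informatic, then by item id.
The maximisation is over the whole dossier rather than item-by-item: a
1-point discovery item can be worth keeping over a 3-point experimental
duplicate when the discovery unlocks 3 validation points. Survivor
combinations are enumerated exactly (a greedy per-group fallback exists
beyond 4096 combinations, unreachable for realistic dossiers); this choice
is what makes the total monotone — appending evidence can never lower a
score — which we regard as non-negotiable for a metric meant to encourage
evidence collection.

## Numerical conventions and degenerate inputs

* Threshold comparisons are strict: `p = 5e-8` does not pass a 5e-8
  threshold. A p-value of exactly 1 is representable but passes nothing.
* An explicit `significant_override` on an item supersedes the p-value
  comparison entirely (used when significance is attained by fine mapping
  rather than the scan statistic).
* Meta-analysis standard errors come from the Wald back-calculation
  `SE = (ln U − ln L) / (2 z)` with `z = qnorm((1 + level)/2)`. A printed
  CI inconsistent with its printed OR by more than 0.05 on the log scale
  (beyond what two-decimal rounding can explain) is rejected, as is a
  degenerate interval `L = U`, which would otherwise acquire infinite
  weight silently.
* Validation returns violations as data (`validate_dossier()`), so a file
  with three problems reports all three; scoring refuses invalid dossiers.
* Empty dossiers are valid and score 0 (weak). An empty hit table yields an
  empty batch report.
* All serialisation (reports, batch output, fixtures) is deterministic:
  identical inputs and configuration produce byte-identical files.

## The synthetic generator

`generate_synthetic()` produces arbitrary dossiers, a matching GWAS hit
table, and a provider lookup table from a seeded `generator_spec()`. It
emulates exactly what the scoring engine consumes: category presence,
discovery significance (significant p-values drawn log-uniform on
[1e-12, 5e-8), null ones uniform on (0,1), occasional significance
overrides), validation items below the nominal threshold, and a reviewed
flag. It does **not** emulate genotypes, linkage disequilibrium,
association testing, winner's-curse effect inflation, or correlated
evidence across categories — so passing tests demonstrate correct rubric
arithmetic and threshold logic on realistic *inputs*, not that the rubric
ranks real GWAS leads correctly. The canonical dossiers carry that
empirical weight, and only for the four published cases.

Alongside each dossier the generator records the component points it
expects, computed by its own bookkeeping of what it generated — an
independent codepath from the engine — and the test suite asserts exact
agreement on a thousand seeded dossiers. Test and example problem sizes
(tens to a thousand dossiers, six-item dossiers for the exhaustive
brute-force oracle) were chosen to exercise every code path while keeping
the whole suite interactive, around twenty seconds.

## Canonical fixtures and their provenance

Five dossiers ship with the package (`canonical_fixtures()`): Hemoglobin S
and ATP2B4 (strong, 9), MARVELD3 (weak, 1), PPARG (strong, 6 without any
omic points), and the TAT reattribution (weak, 4). The association
p-values, odds ratios and component outcomes are as published. The
alternative-validation entries for Hemoglobin S and ATP2B4 are synthetic
reconstructions: the original implementation detail lived in a supplement
that is not available, so the fixtures encode the reported component
pattern via a significance override and say so in their `notes`. Scores
and classifications are unaffected; the item-level provenance of those two
entries is reconstructed, not sourced.

## Limitations

* The rubric is deliberately coarse: it will not distinguish a strong
  animal model from a marginal one, and it saturates at 10.
* Search providers are offline fixtures; live database adapters must
  implement `search_evidence()` themselves, and hit counts only ever
  *propose* unreviewed items — quality judgment stays with the researcher.
* Random-effects pooling, heterogeneity statistics and publication-bias
  diagnostics are out of scope; the meta-analysis helper exists to make
  the alternative-validation pathway computable, not to replace a
  meta-analysis package.
* Factor names are taken as given: no gene-symbol or rsID resolution, and
  gene attribution in hit tables is the caller's (explicit) claim, never
  inferred from coordinates.
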