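---
title: "Dose, lipophilicity and metabolism as DILI risk factors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose, lipophilicity and metabolism as DILI risk factors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilirisk)
library(dplyr)
```

## The scientific problem

Drug-induced liver injury (DILI) is a leading cause of drug withdrawals
and boxed warnings, yet no preclinical assay predicts it reliably. A
practical alternative is to screen approved drugs for simple
pharmacological properties that are *associated* with hepatotoxicity.
Three such properties recur in the hepatotoxicity literature:

* **daily dose** — hepatic exposure scales with dose; a cut-off of
  100 mg/day separates "high-dose" drugs;
* **lipophilicity** — lipophilic drugs (logP ≥ 3, on the octanol–water
  partition scale) distribute widely and must be metabolised to be
  cleared;
* **extent of hepatic metabolism** — extensively metabolised drugs
  (≥ 50% of the dose) have more opportunity to form reactive
  metabolites. When the metabolised fraction is not documented, a
  fraction excreted unchanged in urine below 20% is taken as indirect
  evidence of extensive metabolism.

The conjunction of the first two — daily dose ≥ 100 mg AND logP ≥ 3 —
is the *Rule-of-Two* (RO2). This package implements the rules, the
consensus annotation across heterogeneous DILI reference lists, the 2×2
association statistics used to quantify each rule's relationship with
DILI risk, and a synthetic cohort generator that makes the whole
pipeline testable with known ground truth.

## Annotation model

DILI reference lists disagree: they use different evidence thresholds
(labelling actions, case-report counts, causality assessment) and cover
different subsets of the pharmacopoeia. The package therefore treats
annotations as a per-source label with three states: `positive`,
`negative`, and `absent`. `absent` covers both "not in this list" and
"in the list but ambiguous" — ambiguous drugs are excluded from
analysis rather than treated as negatives, because an ambiguous
annotation is evidence of neither class.

The consensus source is a per-drug majority vote over the available
(non-absent) labels. Ties go to **positive**: positive annotations are
grounded in clinical evidence of injury, while negative annotations
only record the absence of such evidence, so a split vote should not
launder a drug into the negative class. A drug annotated by a single
source inherits that source's label (`min_sources = 1`); this is what
makes the consensus cohort larger than any single source's, as observed
in the published consensus analysis.

## Risk calls and three-valued logic

Each predicate returns `positive`, `negative` or `undetermined`
(missing input). All thresholds are inclusive (≥), as they are stated
in the literature. Conjunctions follow Kleene logic: a single definite
`negative` component makes the conjunction `negative` even when another
component is missing — a drug dosed at 10 mg/day cannot be RO2-positive
whatever its unknown logP. In practice analysis cohorts are formed with
all required fields present (`analysis_subset()`), so the short-circuit
is a safety net rather than a data-rescue device.

The urinary-excretion fallback applies **only** when the metabolism
fraction is absent; a documented metabolism fraction always wins. The
fallback threshold is strict (`< 0.2`), the metabolism threshold
inclusive (`≥ 0.5`).

For metabolism analyses the cohort filter is "dose present AND the
extensive-metabolism call is determinate" (field key
`metabolism_determinate`), which includes the urinary-fallback drugs.
This keeps the reported class sizes equal to the 2×2 margins. The exact
intersection rule used to form the published 559-drug metabolism cohort
is not documented; exposing `required_fields` explicitly, rather than
hard-coding one rule, is the package's answer to that ambiguity.

## Association statistics

For a 2×2 table (DILI status × factor call) with cells `a–d`:

* **Odds ratio** — the unconditional cross-product `(a·d)/(b·c)`. This
  choice is evidence-based: it reproduces 30 of the 36 odds ratios in
  the published association tables to the printed 2 decimals. The six
  remaining rows are inconsistent with their own printed counts under
  *any* standard estimator we examined (cross-product and logistic MLE
  coincide here) and are flagged `printed_or_consistent = FALSE` in
  the packaged counts (`published_counts()`); they are treated as
  printing inconsistencies, not as a different estimator.
* **Confidence interval** — Wald on the log odds ratio,
  `exp(log OR ± z·√(1/a + 1/b + 1/c + 1/d))`. The published analysis
  says only "derived from logistic regression"; Wald is the standard
  determinate choice, and its 95% coverage is verified by simulation
  (93–97% band) rather than asserted.
* **Logistic route** — `logistic_or()` fits the one-covariate logit
  model by Newton iterations to a score norm below 1e-10. For a single
  binary covariate the MLE equals the cross-product ratio; the package
  keeps both routes and tests their equivalence, with `stats::glm` as
  an additional independent oracle in the test suite.
* **Fisher exact test** — two-sided, minimum-likelihood definition:
  the p-value sums the hypergeometric probabilities of all
  margin-fixed tables whose probability does not exceed the observed
  table's. Probabilities are computed through log-factorials, and a
  relative guard of `1 + 1e-7` prevents ties from being lost to
  floating-point rounding — the same convention as R's `fisher.test`,
  against which the implementation is tested exhaustively on small
  tables. This definition also reproduces the five numerically printed
  p-values of the published tables at their printed precision.
* **Zero cells** — the Haldane–Anscombe correction (+0.5 on all four
  cells) is applied to the OR and CI and flagged in the result. The
  published tables contain no zero cells; synthetic cohorts can.
  `logistic_or()` instead refuses zero-cell tables, since the MLE does
  not exist under separation.

Reported tables round half-to-even to 2 decimals for display; all
stored values are full precision. No multiple-testing correction is
applied, matching the published analysis.

## Concordance analysis

`ro2_concordance()` asks how often the per-source labels corroborate
the rule: for each RO2-positive drug, the number `k` of sources
labelling it DILI-positive; for each RO2-negative drug, the number
labelling it negative. `k` is counted over *all* declared sources —
an absent label is simply non-concordant — because the alternative
(per-`k` denominators restricted to annotating sources) requires
denominators the published figure does not supply. Bars are exact-`k`,
not cumulative, matching a figure legend that contrasts "all five
datasets" with "only one dataset". Both choices are documented here as
the package's conventions, not asserted as the original analysis's.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of the curated
dataset, not its drug identities:

* **Marginals** — daily dose from the discrete levels
  {5, 10, 25, 50, 100, 200, 500, 1000} mg (uniform; half the levels sit
  at or above 100 mg, matching the roughly 60% high-dose fraction of
  the published cohorts), logP ~ Normal(2.0, 1.8) (≈ 29% above 3),
  metabolism fraction ~ Beta(2, 2) (50% above 0.5). The urinary
  fraction is `(1 − metabolism) × Beta(2, 2)`, giving the negative
  coupling the fallback rule presumes.
* **Latent status** — a logistic model over the *binarized* factors
  and their dose interactions. Binarizing inside the generator makes
  the generative odds ratio of a factor profile exactly
  `exp(total logit effect)` — the estimand of the analysis pipeline —
  so parameter recovery is a sharp test rather than an approximation.
  Defaults (`baseline_logit = −1`; effects `log 2.0` for dose,
  `log 1.2` for logP, `log 1.3` for metabolism, `log 1.8` for each
  dose interaction) put the marginal factor odds ratios in the 2–6
  range of the published tables.
* **Sources** — five sources named after the published annotations
  with coverages 504/1036, 275/1036, 217/1036, 178/1036, 343/1036 —
  the annotations' actual shares of the reference set — and moderate
  accuracy (sensitivity 0.85, specificity 0.80). Coverage, then label,
  is drawn per drug and source.
* **Missingness** — fields are masked after the status is drawn
  (missing-completely-at-random), at rates mirroring the published
  data availability: dose 26%, logP 9%, metabolism 35%, urinary 55%.

One random stream per cohort, consumed in documented order (dose, logP,
metabolism, urinary, status, sources in declared order, masks in field
order), so a seed pins the cohort exactly; generation restores the
caller's RNG state.

What the generator does *not* emulate: informative missingness (real
dose data are missing preferentially for topicals and biologics),
correlated annotation errors between sources that share evidence, and
the long right tail of real dose distributions. Passing calibration
tests on these cohorts therefore demonstrates the estimators are
correct and well-calibrated under the stated model — not that the
biological conclusions transfer to any particular real dataset.

## Numerical and design choices

* Fisher p-values clamp to [0, 1] after summation.
* The Newton fit starts at (0, 0) and caps at 100 iterations; all
  zero-free 2×2 tables converge in far fewer.
* `analysis_subset()` is idempotent and order-preserving; reports are
  byte-identical across reruns of the same input.
* Problem sizes used by the packaged calibration checks: 500 null
  cohorts of 200 drugs for the type-I error of the Fisher test, 1000
  replicates of 500 drugs per generative odds ratio (1, 3, 5) for CI
  coverage, and a single 2000-drug cohort for point recovery. These
  sizes give Monte-Carlo standard errors comfortably inside the bands
  being checked (e.g. ±0.7% for a 95% coverage estimate at 1000
  replicates) while keeping the default check fast on a laptop.

## Known limitations

* The packaged published counts are transcriptions of printed tables;
  six rows are internally inconsistent as printed (see above) and are
  excluded from exact-reproduction checks.
* Drug identity resolution is exact-string only; synonym and salt-form
  reconciliation across sources is out of scope.
* Only univariable 2×2 associations are computed — no adjusted or
  multivariable models, and no causality scoring.
* The consensus vote weights all sources equally; sources with very
  different evidence standards arguably deserve weights, but no
  defensible weighting is derivable from the published material.

## Worked example

```{r example}
cohort <- generate_cohort(cohort_params(n_drugs = 800, seed = 101))
tbl <- add_consensus_source(cohort$table)

report <- run_full_analysis(
  tbl,
  factors = builtin_risk_factors(c("ro2", "logp", "dose"))
)
report |> select(factor_key, source, a, b, c, d, or_ci, p_display)
```

The RO2 rows show larger odds ratios than the single factors, the
pattern the rule was proposed for; the consensus row is the most
precisely estimated because its cohort is largest.

```{r concordance, fig.width = 6, fig.height = 3.5}
autoplot(ro2_concordance(tbl, sources = setdiff(dili_sources(tbl), "consensus")))
```
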