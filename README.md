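# dilirisk

Rule-based risk-factor analysis for drug-induced liver injury (DILI).

Hepatotoxicity remains the adverse reaction most often behind drug
withdrawals, and no preclinical assay predicts it well. A pragmatic
screening alternative asks whether simple pharmacological properties of
a drug are statistically associated with DILI across curated reference
lists. This package implements that analysis end to end for anyone
working with DILIrank-style drug tables (one row per drug; daily dose,
logP, extent of hepatic metabolism; one DILI label column per
annotation source):

* **Risk rules** — inclusive-threshold binary predicates: high daily
  dose (DD ≥ 100 mg), high lipophilicity (logP ≥ 3), extensive hepatic
  metabolism (≥ 50%, or < 20% excreted unchanged in urine when the
  metabolised fraction is undocumented), and their conjunctions,
  notably the *Rule-of-Two* RO2 = (DD ≥ 100 mg) ∧ (logP ≥ 3). Calls
  are three-valued (`positive` / `negative` / `undetermined`) so
  missing data propagate honestly.
* **Consensus annotation** — per-drug majority vote across independent
  DILI label sources, ties resolved to positive (positive labels rest
  on clinical evidence; negatives only on its absence), plus
  dataset-membership (Venn) summaries.
* **Association statistics** — for each 2×2 table of DILI status ×
  factor call: the sample odds ratio OR = (a·d)/(b·c) with
  Haldane–Anscombe +0.5 correction on zero cells, the Wald interval
  exp(log OR ± z·√(1/a + 1/b + 1/c + 1/d)), an independent
  single-covariate logistic (Newton) route to the same estimand, and a
  from-scratch two-sided Fisher exact test (minimum-likelihood
  definition, hypergeometric enumeration via log-factorials).
* **Concordance** — how many annotation sources corroborate each
  rule-positive and rule-negative drug.
* **Synthetic cohorts** — a generator with known ground truth
  (logistic model over binarized factors; per-source coverage,
  sensitivity, specificity; realistic missingness) for calibration and
  parameter-recovery experiments.

Everything is tidyverse-shaped: drug tables are tibbles, results have
`tidy()` / `glance()` methods, and result objects plot with
`autoplot()`.

## Worked example

Simulate a DILIrank-like cohort, add the consensus source, and run the
full association analysis:

```r
library(dilirisk)
library(dplyr)

cohort <- generate_cohort(cohort_params(n_drugs = 800, seed = 101))
tbl <- add_consensus_source(cohort$table)

report <- run_full_analysis(
  tbl,
  factors = builtin_risk_factors(c("ro2", "logp", "dose"))
)
report |> select(factor_key, source, a, b, c, d, or_ci, p_display)
#> # A tibble: 18 × 8
#>    factor_key source        a     b     c     d or_ci             p_display
#>    <chr>      <chr>     <int> <int> <int> <int> <chr>             <chr>
#>  1 ro2        chen         26   107     8   116 3.52 (1.53-8.12)  <0.05
#>  2 ro2        greene       14    54     8    61 1.98 (0.77-5.07)  0.17
#>  3 ro2        zhu          15    44     2    51 8.69 (1.88-40.13) <0.05
#>  4 ro2        sakatis       8    36     4    55 3.06 (0.86-10.90) 0.12
#>  5 ro2        xu           11    62    10    73 1.30 (0.52-3.25)  0.64
#>  6 ro2        consensus    51   184    18   188 2.89 (1.63-5.14)  <0.05
#>  7 logp       chen         35    98    28    96 1.22 (0.69-2.17)  0.56
#>  ...
#> 13 dose       chen         86    47    42    82 3.57 (2.14-5.98)  <0.05
#> ...
#> 18 dose       consensus   150    85    70   136 3.43 (2.32-5.08)  <0.05
```

Each row is one annotation source: `a`–`d` are the 2×2 cells
(DILI-positive/negative × factor-positive/negative), `or_ci` the odds
ratio with its Wald 95% interval, `p_display` the two-sided Fisher
exact p. Note the characteristic pattern: the dose-combined RO2 rows
carry larger odds ratios than logP alone, and the consensus row — the
largest cohort — is the most precisely estimated.

The published association tables are packaged as cell counts
(`published_counts()`), so any printed row can be recomputed directly:

```r
associate_counts(99, 214, 23, 232, source = "consensus", factor_name = "RO2")
#> DILI risk-factor association
#>   factor: RO2
#>   source: consensus
#>   DILI+ n = 313, DILI- n = 255
#>   OR (95% CI) = 4.67 (2.86-7.62), Fisher p = <0.05
```

i.e. drugs that are RO2-positive have about 4.7-fold higher odds of a
positive consensus DILI annotation, and the association is far below
the 0.05 significance level.

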