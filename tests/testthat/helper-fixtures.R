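# Fixtures and small independent oracles shared across test files.

# Hand-written 5-drug table: 2 rows missing logP, 1 absent chen label.
toy_table <- function() {
  drug_table(
    tibble::tibble(
      drug_id = c("alpha", "bravo", "charlie", "delta", "echo"),
      daily_dose_mg = c(200, 50, 500, 100, 10),
      logp = c(4.0, NA, 3.0, NA, NA),
      metabolism_fraction = c(0.9, 0.3, NA, 0.6, NA),
      urinary_unchanged_fraction = c(0.05, NA, 0.1, NA, 0.9),
      chen = c("positive", "negative", "positive", "absent", "negative"),
      xu = c("positive", "absent", "negative", "positive", "negative")
    ),
    sources = c("chen", "xu")
  )
}

# Random valid drug table for property-style tests.
random_table <- function(n, n_sources = 3, seed = 1) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      drug_id = sprintf("d%04d", seq_len(n)),
      daily_dose_mg = ifelse(runif(n) < 0.2, NA, sample(c(5, 50, 100, 500), n, TRUE)),
      logp = ifelse(runif(n) < 0.2, NA, round(rnorm(n, 2, 2), 3)),
      metabolism_fraction = ifelse(runif(n) < 0.3, NA, round(runif(n), 3)),
      urinary_unchanged_fraction = ifelse(runif(n) < 0.5, NA, round(runif(n), 3))
    )
    src <- paste0("s", seq_len(n_sources))
    for (s in src) {
      df[[s]] <- sample(c("positive", "negative", "absent"), n, TRUE)
    }
    drug_table(df, sources = src)
  })
}

# Cohort in which the latent status depends only on the RO2 indicator,
# observed through a single perfect source: the generative odds ratio
# is exactly `or` and annotation noise is absent.
ro2_only_params <- function(or, n, seed, baseline_logit = -1) {
  cohort_params(
    n_drugs = n, seed = seed,
    baseline_logit = baseline_logit,
    effect_logits = c(
      dose = 0, logp = 0, metabolism = 0,
      dose_logp = log(or), dose_metabolism = 0
    ),
    sources = tibble::tibble(
      name = "truth", sensitivity = 1, specificity = 1, coverage = 1
    ),
    missing_rate = c(
      daily_dose_mg = 0, logp = 0,
      metabolism_fraction = 0, urinary_unchanged_fraction = 0
    )
  )
}

# Independent minimum-likelihood two-sided Fisher p, via exact binomial
# coefficients and direct probability comparison (no logs).
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  m <- a + b
  k <- a + c
  support <- max(0, m + k - n):min(m, k)
  probs <- choose(m, support) * choose(n - m, k - support) / choose(n, k)
  obs <- probs[support == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Three-valued conjunction oracle: list of component calls -> one call.
conjunction_oracle <- function(calls) {
  if (any(calls == "negative")) return("negative")
  if (any(calls == "undetermined")) return("undetermined")
  "positive"
}
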