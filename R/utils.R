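# Internal vocabularies shared across modules.

# Annotation labels carried by drug tables.
LABEL_LEVELS <- c("positive", "negative", "absent")

# Three-valued outcome of a risk predicate.
CALL_LEVELS <- c("positive", "negative", "undetermined")

# Canonical property columns of a drug table, in storage order.
PROPERTY_FIELDS <- c(
  "daily_dose_mg", "logp",
  "metabolism_fraction", "urinary_unchanged_fraction"
)

# Pseudo-field accepted by analysis_subset(): the extensive-metabolism
# call is determinate (metabolism known, or the urinary fallback fires).
METABOLISM_DETERMINATE <- "metabolism_determinate"

abort_dili <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dilirisk_error"))
}

`%||%` <- rlang::`%||%`

# Report-style display of an odds ratio with its confidence interval,
# e.g. "4.08 (1.57-11.23)". Internal values are never rounded.
format_or_ci <- function(or, low, high, digits = 2) {
  sprintf(
    "%.*f (%.*f-%.*f)",
    digits, round(or, digits),
    digits, round(low, digits),
    digits, round(high, digits)
  )
}

format_p <- function(p, alpha = 0.05, digits = 2) {
  ifelse(p < alpha, sprintf("<%.2f", alpha), sprintf("%.*f", digits, p))
}
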