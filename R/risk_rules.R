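#' Risk-factor specifications
#'
#' A risk factor is a named conjunction of binary predicates over drug
#' properties: high daily dose (>= 100 mg), high lipophilicity
#' (logP >= 3) and extensive hepatic metabolism (>= 50%, or inferred
#' when < 20% of the drug is excreted unchanged in urine). All
#' thresholds are inclusive. The Rule-of-Two (RO2) is the dose+logP
#' conjunction.
#'
#' @param name Display name for reports.
#' @param components Non-empty subset of `c("dose", "logp",
#'   "metabolism")`; the factor is positive only when every component is.
#' @param dose_threshold_mg Daily dose cut-off in milligrams.
#' @param logp_threshold Lipophilicity cut-off on the logP scale.
#' @param metabolism_threshold Hepatic-metabolism fraction cut-off.
#' @param urinary_fallback_threshold When the metabolism fraction is
#'   unknown, a fraction excreted unchanged in urine strictly below this
#'   value is taken to imply extensive metabolism.
#' @return A `risk_factor` object.
#' @export
risk_factor <- function(name, components,
                        dose_threshold_mg = 100,
                        logp_threshold = 3,
                        metabolism_threshold = 0.5,
                        urinary_fallback_threshold = 0.2) {
  if (!length(components)) {
    abort_dili("A risk factor needs at least one component.", "dili_spec_error")
  }
  components <- match.arg(
    components, c("dose", "logp", "metabolism"),
    several.ok = TRUE
  )
  thresholds <- c(
    dose_threshold_mg, logp_threshold,
    metabolism_threshold, urinary_fallback_threshold
  )
  if (any(!is.finite(thresholds)) || dose_threshold_mg <= 0) {
    abort_dili("Risk-factor thresholds must be finite (dose > 0).",
               "dili_spec_error")
  }
  structure(
    list(
      name = name,
      components = components,
      dose_threshold_mg = dose_threshold_mg,
      logp_threshold = logp_threshold,
      metabolism_threshold = metabolism_threshold,
      urinary_fallback_threshold = urinary_fallback_threshold
    ),
    class = "risk_factor"
  )
}

#' @export
print.risk_factor <- function(x, ...) {
  cat(sprintf(
    "<risk_factor> %s: %s\n", x$name, paste(x$components, collapse = " AND ")
  ))
  invisible(x)
}

#' Built-in risk factors
#'
#' Constructors for the factors analysed in the DILI risk tables:
#' `ro2_factor()` (dose AND logP, the Rule-of-Two), the single
#' components, and the metabolism+dose conjunction. Thresholds default
#' to dose >= 100 mg, logP >= 3 and metabolism >= 0.5, and may be
#' overridden via `...` (passed to [risk_factor()]).
#'
#' @param ... Threshold overrides passed to [risk_factor()].
#' @return A `risk_factor`.
#' @name builtin_factors
NULL

#' @rdname builtin_factors
#' @export
ro2_factor <- function(...) {
  risk_factor("RO2 (dose >= 100 mg and logP >= 3)", c("dose", "logp"), ...)
}

#' @rdname builtin_factors
#' @export
dose_factor <- function(...) {
  risk_factor("Daily dose >= 100 mg", "dose", ...)
}

#' @rdname builtin_factors
#' @export
logp_factor <- function(...) {
  risk_factor("logP >= 3", "logp", ...)
}

#' @rdname builtin_factors
#' @export
metabolism_factor <- function(...) {
  risk_factor("Hepatic metabolism >= 50%", "metabolism", ...)
}

#' @rdname builtin_factors
#' @export
metabolism_dose_factor <- function(...) {
  risk_factor(
    "Hepatic metabolism >= 50% and dose >= 100 mg",
    c("metabolism", "dose"), ...
  )
}

#' Look up built-in risk factors by short key
#'
#' @param keys Character vector drawn from `"ro2"`, `"dose"`, `"logp"`,
#'   `"metabolism"`, `"metabolism-dose"`.
#' @param ... Threshold overrides applied to every factor.
#' @return Named list of `risk_factor` objects.
#' @export
builtin_risk_factors <- function(keys = c("ro2", "logp", "dose"), ...) {
  ctors <- list(
    ro2 = ro2_factor, dose = dose_factor, logp = logp_factor,
    metabolism = metabolism_factor, `metabolism-dose` = metabolism_dose_factor
  )
  bad <- setdiff(keys, names(ctors))
  if (length(bad)) {
    abort_dili(
      sprintf("Unknown factor key(s): %s.", paste(bad, collapse = ", ")),
      "dili_spec_error"
    )
  }
  lapply(rlang::set_names(keys), function(k) ctors[[k]](...))
}

#' Component risk calls
#'
#' Vectorised three-valued predicates: each returns `"positive"`,
#' `"negative"` or `"undetermined"` per element. `"undetermined"` arises
#' only from missing input (and, for metabolism, a urinary value that
#' does not trigger the fallback).
#'
#' @param daily_dose_mg,logp,metabolism_fraction,urinary_unchanged_fraction
#'   Numeric vectors, `NA` for missing.
#' @param spec A [risk_factor()] supplying thresholds.
#' @return Character vector of calls.
#' @name risk_calls
NULL

#' @rdname risk_calls
#' @export
is_high_dose <- function(daily_dose_mg, spec = ro2_factor()) {
  if (any(daily_dose_mg < 0, na.rm = TRUE)) {
    abort_dili("Negative daily dose.", "dili_validation_error")
  }
  dplyr::case_when(
    is.na(daily_dose_mg) ~ "undetermined",
    daily_dose_mg >= spec$dose_threshold_mg ~ "positive",
    .default = "negative"
  )
}

#' @rdname risk_calls
#' @export
is_high_logp <- function(logp, spec = ro2_factor()) {
  dplyr::case_when(
    is.na(logp) ~ "undetermined",
    logp >= spec$logp_threshold ~ "positive",
    .default = "negative"
  )
}

#' @rdname risk_calls
#' @export
is_extensive_metabolism <- function(metabolism_fraction,
                                    urinary_unchanged_fraction = NA_real_,
                                    spec = metabolism_factor()) {
  n <- max(length(metabolism_fraction), length(urinary_unchanged_fraction))
  met <- rep_len(metabolism_fraction, n)
  uri <- rep_len(urinary_unchanged_fraction, n)
  dplyr::case_when(
    !is.na(met) & met >= spec$metabolism_threshold ~ "positive",
    !is.na(met) ~ "negative",
    # metabolism unknown: low unchanged excretion implies extensive metabolism
    !is.na(uri) & uri < spec$urinary_fallback_threshold ~ "positive",
    .default = "undetermined"
  )
}

#' Evaluate a risk factor over drug records
#'
#' Three-valued conjunction of the factor's component calls: positive
#' when every component is positive; negative as soon as any component
#' is definitely negative (even if another is undetermined — a drug
#' below the dose cut-off cannot be RO2-positive whatever its logP);
#' undetermined otherwise.
#'
#' @param data A [drug_table()] or any data frame with the property
#'   columns the factor's components need.
#' @param spec A [risk_factor()].
#' @return Character vector of `"positive"`, `"negative"`,
#'   `"undetermined"`, one per row of `data`.
#' @export
evaluate_factor <- function(data, spec) {
  calls <- list()
  if ("dose" %in% spec$components) {
    calls$dose <- is_high_dose(data$daily_dose_mg, spec)
  }
  if ("logp" %in% spec$components) {
    calls$logp <- is_high_logp(data$logp, spec)
  }
  if ("metabolism" %in% spec$components) {
    calls$metabolism <- is_extensive_metabolism(
      data$metabolism_fraction,
      data$urinary_unchanged_fraction %||% NA_real_,
      spec
    )
  }
  combine_calls(calls)
}

# Conjunction over parallel call vectors under Kleene three-valued logic.
combine_calls <- function(calls) {
  m <- do.call(cbind, calls)
  any_negative <- rowSums(m == "negative") > 0
  any_undet <- rowSums(m == "undetermined") > 0
  dplyr::case_when(
    any_negative ~ "negative",
    any_undet ~ "undetermined",
    .default = "positive"
  )
}
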