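#' Drug tables
#'
#' A drug table is a tibble with one row per drug, the four canonical
#' property columns (`daily_dose_mg`, `logp`, `metabolism_fraction`,
#' `urinary_unchanged_fraction`, all numeric with `NA` for missing),
#' and one character label column per annotation source holding
#' `"positive"`, `"negative"` or `"absent"`. `"absent"` means the source
#' did not annotate the drug; ambiguously annotated drugs are treated as
#' absent, not negative, so they never enter an analysis. The declared
#' source names are kept in the `"sources"` attribute and can be read
#' with [dili_sources()].
#'
#' @param data A data frame with a `drug_id` column, optionally the
#'   property columns (missing ones are added as all-`NA`), and one
#'   column per declared source. Label columns may use `NA` for absent.
#' @param sources Character vector of annotation source names; each must
#'   be a column of `data`.
#' @return A validated `drug_table` (a tibble subclass).
#' @examples
#' drug_table(
#'   tibble::tibble(
#'     drug_id = c("amiodarone", "aspirin"),
#'     daily_dose_mg = c(600, 100),
#'     logp = c(7.6, 1.2),
#'     chen = c("positive", "negative")
#'   ),
#'   sources = "chen"
#' )
#' @export
drug_table <- function(data, sources = character()) {
  data <- tibble::as_tibble(data)
  if (!"drug_id" %in% names(data)) {
    abort_dili("`data` must have a `drug_id` column.", "dili_schema_error")
  }
  for (f in PROPERTY_FIELDS) {
    if (!f %in% names(data)) data[[f]] <- NA_real_
  }
  for (s in sources) {
    if (!s %in% names(data)) {
      abort_dili(
        sprintf("Declared source '%s' is not a column of `data`.", s),
        "dili_schema_error"
      )
    }
    lab <- as.character(data[[s]])
    lab[is.na(lab)] <- "absent"
    data[[s]] <- lab
  }
  data <- data[, c("drug_id", PROPERTY_FIELDS, sources)]
  validate_drug_table(data, sources)
  new_drug_table(data, sources)
}

new_drug_table <- function(data, sources) {
  tibble::new_tibble(
    data,
    sources = as.character(sources),
    class = "drug_table"
  )
}

validate_drug_table <- function(data, sources) {
  problems <- character()
  flag <- function(rows, what) {
    if (length(rows)) {
      sprintf("row %s: %s", paste(rows, collapse = ", "), what)
    } else {
      character()
    }
  }
  id <- as.character(data$drug_id)
  problems <- c(
    problems,
    flag(which(is.na(id) | id == ""), "empty drug_id"),
    flag(which(duplicated(id)), "duplicate drug_id")
  )
  dose <- data$daily_dose_mg
  problems <- c(
    problems,
    flag(which(!is.na(dose) & dose < 0), "negative daily_dose_mg")
  )
  for (f in c("metabolism_fraction", "urinary_unchanged_fraction")) {
    v <- data[[f]]
    problems <- c(
      problems,
      flag(which(!is.na(v) & (v < 0 | v > 1)), sprintf("%s outside [0, 1]", f))
    )
  }
  for (s in sources) {
    bad <- which(!data[[s]] %in% LABEL_LEVELS)
    problems <- c(
      problems,
      flag(bad, sprintf("label for source '%s' not positive/negative/absent", s))
    )
  }
  if (length(problems)) {
    abort_dili(
      c("Invalid drug table:", problems),
      "dili_validation_error"
    )
  }
  invisible(data)
}

#' @export
print.drug_table <- function(x, ...) {
  src <- dili_sources(x)
  cat(sprintf(
    "# A drug table: %d drugs, %d annotation source%s (%s)\n",
    nrow(x), length(src), if (length(src) == 1) "" else "s",
    paste(src, collapse = ", ")
  ))
  NextMethod()
}

#' Annotation sources declared by a drug table
#'
#' @param table A [drug_table()].
#' @return Character vector of source names, in declared order.
#' @export
dili_sources <- function(table) {
  src <- attr(table, "sources", exact = TRUE)
  if (is.null(src)) {
    abort_dili("Not a drug table: no `sources` attribute.", "dili_schema_error")
  }
  src
}

check_source <- function(table, source) {
  if (!source %in% dili_sources(table)) {
    abort_dili(
      sprintf(
        "Unknown source '%s'; declared sources: %s.",
        source, paste(dili_sources(table), collapse = ", ")
      ),
      "dili_schema_error"
    )
  }
  invisible(source)
}

#' Restrict a drug table to records usable by an analysis
#'
#' Keeps records that (a) have every required property field present and
#' (b) carry a determinate (non-absent) label from `source`. This is how
#' per-source analysis cohorts are formed: e.g. the dose/logP analyses
#' require `daily_dose_mg` and `logp`, while metabolism analyses require
#' `daily_dose_mg` together with a determinate extensive-metabolism
#' call. Row order is preserved and the operation is idempotent.
#'
#' @param table A [drug_table()].
#' @param required_fields Character vector drawn from the property
#'   columns plus `"metabolism_determinate"`, which requires that the
#'   extensive-metabolism predicate can be decided for the record
#'   (metabolism fraction present, or the urinary-excretion fallback
#'   applicable). May be empty.
#' @param source Source whose label must not be absent.
#' @param factor Risk-factor specification supplying the metabolism and
#'   urinary thresholds used by `"metabolism_determinate"`.
#' @return A `drug_table` with a subset of the rows.
#' @export
analysis_subset <- function(table, required_fields, source,
                            factor = ro2_factor()) {
  check_source(table, source)
  allowed <- c(PROPERTY_FIELDS, METABOLISM_DETERMINATE)
  bad <- setdiff(required_fields, allowed)
  if (length(bad)) {
    abort_dili(
      sprintf(
        "Unknown required field(s): %s. Allowed: %s.",
        paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
      ),
      "dili_schema_error"
    )
  }
  keep <- table[[source]] != "absent"
  for (f in intersect(required_fields, PROPERTY_FIELDS)) {
    keep <- keep & !is.na(table[[f]])
  }
  if (METABOLISM_DETERMINATE %in% required_fields) {
    call <- is_extensive_metabolism(
      table$metabolism_fraction, table$urinary_unchanged_fraction,
      spec = factor
    )
    keep <- keep & call != "undetermined"
  }
  new_drug_table(table[keep, , drop = FALSE], dili_sources(table))
}
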