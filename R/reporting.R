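#' Run the full risk-factor association analysis
#'
#' For every source x factor pair: form the analysis cohort with
#' [analysis_subset()], cross-tabulate, and compute the association
#' statistics. This reproduces the layout of the published association
#' tables — one block per factor, one row per annotation source.
#'
#' @param table A [drug_table()].
#' @param sources Sources to analyse; defaults to all declared.
#' @param factors Named list of [risk_factor()] objects (see
#'   [builtin_risk_factors()]). The lipophilicity block is
#'   `c("ro2", "logp", "dose")`, the metabolism block
#'   `c("metabolism-dose", "metabolism", "dose")`.
#' @param required_fields Fields every analysed record must have,
#'   passed to [analysis_subset()]. The default is the union of the
#'   fields needed by the requested factors (dose -> `daily_dose_mg`,
#'   logp -> `logp`, metabolism -> a determinate metabolism call), so
#'   all rows of a block share one cohort, as in the published tables.
#' @param ci_level Confidence level for the Wald intervals.
#' @return A `dili_report` tibble: one row per source x factor with
#'   `n_dili_positive`, `n_dili_negative`, cells `a`–`d`, `estimate`,
#'   `conf.low`, `conf.high`, `p.value`, `correction_applied` and the
#'   formatted `or_ci` / `p_display` strings.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_drugs = 400, seed = 7))
#' tbl <- add_consensus_source(cohort$table)
#' run_full_analysis(tbl, factors = builtin_risk_factors(c("ro2", "dose")))
#' @export
run_full_analysis <- function(table,
                              sources = dili_sources(table),
                              factors = builtin_risk_factors(
                                c("ro2", "logp", "dose")
                              ),
                              required_fields = NULL,
                              ci_level = 0.95) {
  if (is.null(names(factors))) {
    names(factors) <- vapply(factors, `[[`, "", "name")
  }
  required_fields <- required_fields %||% default_required_fields(factors)
  rows <- purrr::map(names(factors), function(fk) {
    spec <- factors[[fk]]
    purrr::map(sources, function(src) {
      cohort <- analysis_subset(table, required_fields, src, factor = spec)
      fit <- associate(cohort, src, spec, ci_level = ci_level)
      dplyr::bind_cols(
        tibble::tibble(factor_key = fk, n_cohort = nrow(cohort)),
        tidy(fit)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out <- rows |>
    dplyr::mutate(
      n_dili_positive = .data$a + .data$b,
      n_dili_negative = .data$c + .data$d,
      or_ci = format_or_ci(.data$estimate, .data$conf.low, .data$conf.high),
      p_display = format_p(.data$p.value),
      .after = "factor"
    )
  tibble::new_tibble(out, ci_level = ci_level, class = "dili_report")
}

default_required_fields <- function(factors) {
  comp <- unique(unlist(lapply(factors, `[[`, "components")))
  fields <- c(
    dose = "daily_dose_mg", logp = "logp",
    metabolism = METABOLISM_DETERMINATE
  )
  unname(fields[comp])
}

#' Write an association report to disk
#'
#' Emits one TSV per factor block (columns mirroring the published
#' table layout) and a machine-readable JSON with every full-precision
#' result. Re-running on identical input produces byte-identical files.
#'
#' @param report A `dili_report` from [run_full_analysis()].
#' @param dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_association_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (fk in unique(report$factor_key)) {
    block <- report |>
      dplyr::filter(.data$factor_key == fk) |>
      dplyr::select(
        "source", "factor", "n_dili_positive", "n_dili_negative",
        "a", "b", "c", "d", "or_ci", "p_display"
      )
    path <- file.path(dir, sprintf("association_%s.tsv", gsub("-", "_", fk)))
    readr::write_tsv(block, path, progress = FALSE)
    written <- c(written, path)
  }
  json_path <- file.path(dir, "associations.json")
  jsonlite::write_json(
    tibble::as_tibble(report),
    json_path,
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(written, json_path))
}

#' Published 2x2 association counts
#'
#' The cell counts, odds ratios, confidence intervals and p-value
#' statements printed in the published DILIrank risk-factor association
#' tables (lipophilicity block: 763 drugs with dose and logP;
#' metabolism block: 559 drugs with dose and metabolism data), one row
#' per annotation source x factor. The per-drug dataset itself is not
#' public, but every 2x2 table is, so the statistics are exactly
#' recomputable from these counts. `printed_or_consistent` records
#' whether the cross-product odds ratio of the printed counts rounds to
#' the printed odds ratio at 2 decimals; for six rows it does not, and
#' those printed values are treated as unreproducible as printed.
#'
#' @return Tibble with columns `analysis` (`lipophilicity` /
#'   `metabolism`), `factor_key`, `source`, cells `a`–`d`, `or_printed`,
#'   `ci_low_printed`, `ci_high_printed`, `p_printed`,
#'   `printed_or_consistent`.
#' @export
published_counts <- function() {
  path <- system.file(
    "extdata", "published_association_counts.csv",
    package = "dilirisk", mustWork = TRUE
  )
  readr::read_csv(
    path,
    col_types = readr::cols(
      analysis = readr::col_character(),
      factor_key = readr::col_character(),
      source = readr::col_character(),
      a = readr::col_integer(), b = readr::col_integer(),
      c = readr::col_integer(), d = readr::col_integer(),
      or_printed = readr::col_double(),
      ci_low_printed = readr::col_double(),
      ci_high_printed = readr::col_double(),
      p_printed = readr::col_character(),
      printed_or_consistent = readr::col_logical()
    ),
    progress = FALSE
  )
}

#' Recompute association statistics from published counts
#'
#' Applies [associate_counts()] to each row of [published_counts()]
#' (or a compatible tibble of cell counts).
#'
#' @param counts Tibble with columns `source`, `factor_key` and cells
#'   `a`–`d`; defaults to [published_counts()].
#' @param ci_level Confidence level.
#' @return `counts` with `estimate`, `conf.low`, `conf.high` and
#'   `p.value` columns appended.
#' @export
associate_published <- function(counts = published_counts(),
                                ci_level = 0.95) {
  stats <- purrr::pmap(
    counts[, c("a", "b", "c", "d")],
    function(a, b, c, d) {
      fit <- associate_counts(a, b, c, d, ci_level = ci_level)
      tibble::tibble(
        estimate = fit$estimate,
        conf.low = fit$conf.low,
        conf.high = fit$conf.high,
        p.value = fit$p.value
      )
    }
  ) |> purrr::list_rbind()
  dplyr::bind_cols(counts, stats)
}

#' Forest plot of association results
#'
#' Odds ratios with confidence intervals per source, faceted by factor,
#' on a log scale.
#'
#' @param object A `dili_report` from [run_full_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dili_report
#' @export
autoplot.dili_report <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$estimate, y = .data$source)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$factor_key)) +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
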