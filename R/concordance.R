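#' Cross-dataset concordance of rule calls
#'
#' For drugs with a determinate factor call, counts per drug how many
#' sources agree with the call: a rule-positive drug's concordance
#' level `k` is the number of sources labelling it DILI-positive; a
#' rule-negative drug's `k` is the number labelling it DILI-negative.
#' An absent label is simply non-concordant, so `k` runs over all
#' declared sources and a source that labels everything absent changes
#' no percentage. Reported as exact-`k` percentages of each group, the
#' quantity the rule-overlap bar charts display.
#'
#' @param table A [drug_table()].
#' @param sources Sources to count agreement over; defaults to all.
#' @param factor A [risk_factor()], by default the Rule-of-Two.
#' @return A `dili_concordance` tibble with columns `group`
#'   (`"factor_positive"` / `"factor_negative"`), `k` (0..number of
#'   sources), `n` and `percent` (of the group; each group sums to
#'   100 when non-empty). Group sizes are in the `"group_sizes"`
#'   attribute.
#' @export
ro2_concordance <- function(table, sources = dili_sources(table),
                            factor = ro2_factor()) {
  bad <- setdiff(sources, dili_sources(table))
  if (length(bad)) {
    abort_dili(
      sprintf("Unknown source(s): %s.", paste(bad, collapse = ", ")),
      "dili_schema_error"
    )
  }
  call <- evaluate_factor(table, factor)
  keep <- call != "undetermined"
  m <- as.matrix(tibble::as_tibble(table)[keep, sources, drop = FALSE])
  call <- call[keep]
  concordant <- ifelse(call == "positive", "positive", "negative")
  k <- rowSums(m == concordant)
  levels_k <- 0:length(sources)
  summarise_group <- function(group_call, group_name) {
    in_group <- call == group_call
    n_group <- sum(in_group)
    counts <- tabulate(k[in_group] + 1, nbins = length(levels_k))
    tibble::tibble(
      group = group_name,
      k = levels_k,
      n = counts,
      percent = if (n_group > 0) 100 * counts / n_group else rep(0, length(counts))
    )
  }
  pos <- summarise_group("positive", "factor_positive")
  neg <- summarise_group("negative", "factor_negative")
  out <- dplyr::bind_rows(pos, neg)
  tibble::new_tibble(
    out,
    group_sizes = c(
      factor_positive = sum(call == "positive"),
      factor_negative = sum(call == "negative")
    ),
    factor_name = factor$name,
    class = "dili_concordance"
  )
}

#' Plot a concordance summary
#'
#' Bar chart of the exact-`k` agreement percentages, rule-positives in
#' red and rule-negatives in green, highest agreement on the left.
#'
#' @param object A `dili_concordance` from [ro2_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dili_concordance
#' @export
autoplot.dili_concordance <- function(object, ...) {
  df <- tibble::as_tibble(object) |> dplyr::filter(.data$k > 0)
  sizes <- attr(object, "group_sizes", exact = TRUE)
  labs <- c(
    factor_positive = sprintf("rule positive (n = %d)", sizes[["factor_positive"]]),
    factor_negative = sprintf("rule negative (n = %d)", sizes[["factor_negative"]])
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$k, levels = rev(sort(unique(.data$k)))),
      y = .data$percent,
      fill = labs[.data$group]
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = stats::setNames(
      c("#c0392b", "#27ae60"), unname(labs)
    )) +
    ggplot2::labs(
      x = "number of concordant annotation sources",
      y = "% of group",
      fill = NULL,
      title = attr(object, "factor_name", exact = TRUE)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
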