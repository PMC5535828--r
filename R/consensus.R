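#' Consensus policy
#'
#' Majority vote over the available (non-absent) labels. Ties between
#' positives and negatives resolve to positive, because positive DILI
#' annotations rest on clinical evidence while negatives reflect only
#' the lack of it.
#'
#' @param tie_rule Tie-breaking rule; only `"positive"` is defined.
#' @param min_sources Minimum number of available annotations required
#'   before a consensus is emitted; below it the consensus is absent.
#' @return A `consensus_policy` object.
#' @export
consensus_policy <- function(tie_rule = "positive", min_sources = 1) {
  tie_rule <- match.arg(tie_rule, "positive")
  if (min_sources < 1) {
    abort_dili("`min_sources` must be >= 1.", "dili_spec_error")
  }
  structure(
    list(tie_rule = tie_rule, min_sources = as.integer(min_sources)),
    class = "consensus_policy"
  )
}

#' Majority-vote consensus of annotation labels
#'
#' @param labels Character vector of `"positive"`, `"negative"`,
#'   `"absent"` — one drug's label across sources, in any order.
#' @param policy A [consensus_policy()].
#' @return A single label: the majority of the available annotations,
#'   ties to positive; `"absent"` when fewer than `min_sources`
#'   annotations are available.
#' @examples
#' consensus_label(c("positive", "positive", "negative")) # "positive"
#' consensus_label(c("positive", "negative"))             # tie -> "positive"
#' consensus_label(c("absent", "absent"))                 # "absent"
#' @export
consensus_label <- function(labels, policy = consensus_policy()) {
  bad <- setdiff(labels, LABEL_LEVELS)
  if (length(bad)) {
    abort_dili(
      sprintf("Invalid label(s): %s.", paste(unique(bad), collapse = ", ")),
      "dili_validation_error"
    )
  }
  n_pos <- sum(labels == "positive")
  n_neg <- sum(labels == "negative")
  if (n_pos + n_neg < policy$min_sources) {
    "absent"
  } else if (n_pos >= n_neg) {
    "positive"
  } else {
    "negative"
  }
}

#' Append a consensus annotation source to a drug table
#'
#' Adds one source whose per-drug label is [consensus_label()] over the
#' table's existing sources.
#'
#' @param table A [drug_table()].
#' @param policy A [consensus_policy()].
#' @param name Name of the new source; must not collide with an
#'   existing one.
#' @return A `drug_table` with `length(dili_sources(table)) + 1` sources.
#' @export
add_consensus_source <- function(table, policy = consensus_policy(),
                                 name = "consensus") {
  src <- dili_sources(table)
  if (name %in% src || name %in% c("drug_id", PROPERTY_FIELDS)) {
    abort_dili(
      sprintf("Source name '%s' already in use.", name),
      "dili_schema_error"
    )
  }
  m <- as.matrix(tibble::as_tibble(table)[, src, drop = FALSE])
  n_pos <- rowSums(m == "positive")
  n_neg <- rowSums(m == "negative")
  out <- tibble::as_tibble(table)
  out[[name]] <- dplyr::case_when(
    n_pos + n_neg < policy$min_sources ~ "absent",
    n_pos >= n_neg ~ "positive",
    .default = "negative"
  )
  new_drug_table(out, c(src, name))
}

#' Dataset-membership (Venn) summary
#'
#' Counts drugs by the exact subset of sources that annotate them
#' (label not absent, regardless of polarity), the quantity a Venn
#' diagram of the annotation datasets displays.
#'
#' @param table A [drug_table()].
#' @param sources Sources to consider; defaults to all declared sources.
#' @return A `membership_summary`: list with `per_subset` (tibble with
#'   `subset` — source names joined by `"+"` in declared order — `k`
#'   and `count`, only non-empty subsets), `per_level` (tibble `k`,
#'   `count` with `count[k]` the number of drugs annotated by exactly
#'   `k` sources), `n_annotated`, `n_total` and `sources`.
#' @export
membership_summary <- function(table, sources = dili_sources(table)) {
  bad <- setdiff(sources, dili_sources(table))
  if (length(bad)) {
    abort_dili(
      sprintf("Unknown source(s): %s.", paste(bad, collapse = ", ")),
      "dili_schema_error"
    )
  }
  m <- as.matrix(tibble::as_tibble(table)[, sources, drop = FALSE]) != "absent"
  key <- apply(m, 1, function(row) paste(sources[row], collapse = "+"))
  k <- rowSums(m)
  annotated <- k > 0
  per_subset <- tibble::tibble(subset = key[annotated], k = k[annotated]) |>
    dplyr::count(.data$subset, .data$k, name = "count") |>
    dplyr::arrange(.data$k, .data$subset)
  per_level <- tibble::tibble(k = k[annotated]) |>
    dplyr::count(.data$k, name = "count") |>
    dplyr::arrange(.data$k)
  structure(
    list(
      per_subset = per_subset,
      per_level = per_level,
      n_annotated = sum(annotated),
      n_total = nrow(table),
      sources = sources
    ),
    class = "membership_summary"
  )
}

#' @export
print.membership_summary <- function(x, ...) {
  cat(sprintf(
    "Membership over %d sources: %d of %d drugs annotated by >= 1 source\n",
    length(x$sources), x$n_annotated, x$n_total
  ))
  print(x$per_level)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a membership summary
#'
#' @param x A [membership_summary()].
#' @param ... Unused.
#' @return The `per_subset` tibble (`subset`, `k`, `count`).
#' @method tidy membership_summary
#' @export
tidy.membership_summary <- function(x, ...) x$per_subset
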