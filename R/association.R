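#' 2x2 contingency table of DILI status by risk factor
#'
#' Cell layout follows the published association tables: rows are the
#' DILI classes, columns the factor calls. `a` = DILI-positive &
#' factor-positive, `b` = DILI-positive & factor-negative, `c` =
#' DILI-negative & factor-positive, `d` = DILI-negative &
#' factor-negative.
#'
#' @param a,b,c,d Non-negative integer counts; the total must be >= 1.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort_dili("Cells must be non-negative integers.", "dili_validation_error")
  }
  if (sum(cells) < 1) {
    abort_dili("Empty 2x2 table.", "dili_stat_error")
  }
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(
    c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
    dimnames = list(
      c("DILI positive", "DILI negative"),
      c("factor positive", "factor negative")
    )
  )
  print(m)
  invisible(x)
}

#' Cross-tabulate a drug table against a risk factor
#'
#' Counts only records with a determinate DILI label from `source`
#' (positive or negative) and a determinate factor call; records with
#' an absent label or an undetermined call contribute nothing.
#'
#' @param table A [drug_table()].
#' @param source Annotation source providing the DILI labels.
#' @param factor A [risk_factor()].
#' @return A [contingency_2x2()] (possibly all-zero cells are reported
#'   as such via an error from downstream statistics, not here —
#'   except that a table with no counted record at all is returned as
#'   a degenerate `contingency_2x2` with total 0 refused by
#'   [contingency_2x2()] semantics; see Details).
#' @details A fully empty cross-tabulation is represented by counts
#'   `(0, 0, 0, 0)`; downstream statistics refuse it with an
#'   undefined-statistic error.
#' @export
build_table <- function(table, source, factor) {
  check_source(table, source)
  label <- table[[source]]
  call <- evaluate_factor(table, factor)
  keep <- label != "absent" & call != "undetermined"
  lab <- label[keep]
  cl <- call[keep]
  structure(
    list(
      a = sum(lab == "positive" & cl == "positive"),
      b = sum(lab == "positive" & cl == "negative"),
      c = sum(lab == "negative" & cl == "positive"),
      d = sum(lab == "negative" & cl == "negative")
    ),
    class = "contingency_2x2"
  )
}

cells_of <- function(t) c(a = t$a, b = t$b, c = t$c, d = t$d)

# Cells used for the OR and Wald CI: Haldane-Anscombe +0.5 on all four
# cells when any cell is zero.
or_cells <- function(t) {
  cells <- cells_of(t)
  if ((cells["a"] + cells["b"]) < 1 || (cells["c"] + cells["d"]) < 1) {
    abort_dili(
      "Undefined statistic: a DILI class has no records.",
      "dili_stat_error"
    )
  }
  correction <- any(cells == 0)
  if (correction) cells <- cells + 0.5
  list(cells = cells, correction = correction)
}

#' Sample odds ratio of a 2x2 table
#'
#' The unconditional cross-product ratio `(a*d) / (b*c)`. If any cell
#' is zero, the Haldane-Anscombe correction (+0.5 on all four cells) is
#' applied and flagged in the `"correction"` attribute.
#'
#' @param t A [contingency_2x2()].
#' @return Positive number with logical attribute `"correction"`.
#' @export
sample_odds_ratio <- function(t) {
  oc <- or_cells(t)
  or <- (oc$cells["a"] * oc$cells["d"]) / (oc$cells["b"] * oc$cells["c"])
  structure(unname(or), correction = oc$correction)
}

#' Wald confidence interval for the odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, computed on the
#' corrected cells whenever the zero-cell correction is in force.
#'
#' @param t A [contingency_2x2()].
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
wald_ci <- function(t, level = 0.95) {
  if (level <= 0 || level >= 1) {
    abort_dili("`level` must be in (0, 1).", "dili_spec_error")
  }
  oc <- or_cells(t)
  or <- (oc$cells["a"] * oc$cells["d"]) / (oc$cells["b"] * oc$cells["c"])
  se <- sqrt(sum(1 / oc$cells))
  z <- stats::qnorm((1 + level) / 2)
  unname(exp(log(or) + c(-1, 1) * z * se))
}

#' Odds ratio from a single-covariate logistic fit
#'
#' Fits `logit P(DILI+) = b0 + b1 * factor` by Newton iterations on the
#' grouped log-likelihood, run until the score norm drops below 1e-10,
#' and returns `exp(b1)`. For one binary covariate this maximum
#' likelihood estimate coincides with the cross-product ratio; the fit
#' is kept as an independent route to the same estimand.
#'
#' @param t A [contingency_2x2()] with no zero cell.
#' @return The fitted odds ratio.
#' @export
logistic_or <- function(t) {
  cells <- cells_of(t)
  if (any(cells == 0)) {
    abort_dili(
      paste(
        "Zero cell: the logistic MLE does not exist (separation).",
        "Use sample_odds_ratio(), which applies the +0.5 correction."
      ),
      "dili_stat_error"
    )
  }
  # grouped data: x = 1 (factor positive): a successes of a + c;
  #               x = 0 (factor negative): b successes of b + d
  x <- c(1, 0)
  y <- c(t$a, t$b)
  n <- c(t$a + t$c, t$b + t$d)
  beta <- c(0, 0)
  for (iter in seq_len(100)) {
    eta <- beta[1] + beta[2] * x
    p <- stats::plogis(eta)
    score <- c(sum(y - n * p), sum((y - n * p) * x))
    if (max(abs(score)) < 1e-10) break
    w <- n * p * (1 - p)
    info <- matrix(
      c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)),
      2, 2
    )
    beta <- beta + solve(info, score)
  }
  unname(exp(beta[2]))
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' With the margins fixed, enumerates every feasible table and sums the
#' hypergeometric probabilities of those no more probable than the
#' observed table (minimum-likelihood two-sided definition). A relative
#' tolerance of 1e-7 guards against floating-point exclusion of tied
#' tables. Probabilities are evaluated through log-factorials.
#'
#' @param t A [contingency_2x2()].
#' @return The p-value, clamped to `[0, 1]`.
#' @export
fisher_exact_two_sided <- function(t) {
  n <- t$a + t$b + t$c + t$d
  if (n < 1) {
    abort_dili("Empty 2x2 table.", "dili_stat_error")
  }
  m <- t$a + t$b # DILI-positive margin
  k <- t$a + t$c # factor-positive margin
  support <- max(0, m + k - n):min(m, k)
  # log P(A = x) under the hypergeometric null, via log-factorials
  lf <- lgamma(seq_len(n + 1)) # lf[i + 1] = log(i!)
  logfact <- function(i) lf[i + 1]
  logp <- function(x) {
    logfact(m) - logfact(x) - logfact(m - x) +
      logfact(n - m) - logfact(k - x) - logfact(n - m - (k - x)) -
      (logfact(n) - logfact(k) - logfact(n - k))
  }
  lp <- logp(support)
  obs <- logp(t$a)
  p <- sum(exp(lp[lp <= obs + log1p(1e-7)]))
  min(max(p, 0), 1)
}

#' Association between a DILI annotation and a risk factor
#'
#' The full per-row analysis behind the association tables: subset-free
#' cross-tabulation ([build_table()]), sample odds ratio with zero-cell
#' correction, Wald confidence interval and two-sided Fisher exact
#' test, bundled with provenance.
#'
#' @param table A [drug_table()].
#' @param source Annotation source for the DILI labels.
#' @param factor A [risk_factor()].
#' @param ci_level Confidence level for the Wald interval.
#' @return A `dili_association` object; see [tidy.dili_association()].
#' @examples
#' tbl <- drug_table(
#'   tibble::tibble(
#'     drug_id = sprintf("d%02d", 1:8),
#'     daily_dose_mg = c(200, 500, 150, 10, 300, 20, 5, 50),
#'     logp = c(4, 3.5, 5, 1, 4.2, 0.5, 2, 1.5),
#'     chen = c(rep("positive", 4), rep("negative", 4))
#'   ),
#'   sources = "chen"
#' )
#' associate(tbl, "chen", ro2_factor())
#' @export
associate <- function(table, source, factor, ci_level = 0.95) {
  xt <- build_table(table, source, factor)
  res <- associate_counts(
    xt$a, xt$b, xt$c, xt$d,
    ci_level = ci_level, source = source, factor_name = factor$name
  )
  res$n_dropped <- nrow(table) - (xt$a + xt$b + xt$c + xt$d)
  res
}

#' Association statistics straight from 2x2 cell counts
#'
#' Used when only the cross-tabulated counts are available (as for the
#' published association tables, which print every 2x2 table but not
#' the per-drug data).
#'
#' @param a,b,c,d Cell counts as in [contingency_2x2()].
#' @param ci_level Confidence level for the Wald interval.
#' @param source,factor_name Provenance tags carried into the result.
#' @return A `dili_association` object.
#' @export
associate_counts <- function(a, b, c, d, ci_level = 0.95,
                             source = NA_character_,
                             factor_name = NA_character_) {
  xt <- contingency_2x2(a, b, c, d)
  or <- sample_odds_ratio(xt)
  ci <- wald_ci(xt, ci_level)
  structure(
    list(
      table = xt,
      estimate = as.numeric(or),
      conf.low = ci[1],
      conf.high = ci[2],
      ci_level = ci_level,
      p.value = fisher_exact_two_sided(xt),
      n_dili_positive = xt$a + xt$b,
      n_dili_negative = xt$c + xt$d,
      correction_applied = attr(or, "correction"),
      or_method = "sample_cross_product",
      ci_method = "wald_log_or",
      p_method = "fisher_exact_two_sided",
      source = source,
      factor = factor_name
    ),
    class = "dili_association"
  )
}

#' @export
print.dili_association <- function(x, ...) {
  cat("DILI risk-factor association\n")
  if (!is.na(x$factor)) cat("  factor:", x$factor, "\n")
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  cat(sprintf(
    "  DILI+ n = %d, DILI- n = %d%s\n",
    x$n_dili_positive, x$n_dili_negative,
    if (x$correction_applied) "  [zero cell: +0.5 correction]" else ""
  ))
  cat(sprintf(
    "  OR (%.0f%% CI) = %s, Fisher p = %s\n",
    100 * x$ci_level,
    format_or_ci(x$estimate, x$conf.low, x$conf.high),
    format_p(x$p.value)
  ))
  invisible(x)
}

#' Tidy an association result
#'
#' @param x A `dili_association` from [associate()].
#' @param ... Unused.
#' @return One-row tibble: `source`, `factor`, cells `a`–`d`, `estimate`
#'   (odds ratio), `conf.low`, `conf.high`, `p.value`,
#'   `correction_applied`.
#' @method tidy dili_association
#' @export
tidy.dili_association <- function(x, ...) {
  tibble::tibble(
    source = x$source,
    factor = x$factor,
    a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    estimate = x$estimate,
    conf.low = x$conf.low,
    conf.high = x$conf.high,
    p.value = x$p.value,
    correction_applied = x$correction_applied
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row model summary of an association result
#'
#' @param x A `dili_association`.
#' @param ... Unused.
#' @return Tibble with class sizes, methods and the confidence level.
#' @method glance dili_association
#' @export
glance.dili_association <- function(x, ...) {
  tibble::tibble(
    n_dili_positive = x$n_dili_positive,
    n_dili_negative = x$n_dili_negative,
    n_used = x$n_dili_positive + x$n_dili_negative,
    ci_level = x$ci_level,
    or_method = x$or_method,
    ci_method = x$ci_method,
    p_method = x$p_method
  )
}
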