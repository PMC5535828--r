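test_that("build_table counts labels against factor calls", {
  # per-drug records engineered to give the published Chen dose counts
  n <- c(a = 139, b = 33, c = 70, d = 103)
  df <- tibble::tibble(
    drug_id = sprintf("d%03d", 1:sum(n)),
    daily_dose_mg = rep(c(200, 50, 200, 50), n),
    chen = rep(c("positive", "positive", "negative", "negative"), n)
  )
  xt <- build_table(drug_table(df, "chen"), "chen", dose_factor())
  expect_equal(unlist(xt[c("a", "b", "c", "d")]), n)
})

test_that("records with absent labels or undetermined calls are dropped", {
  tbl <- toy_table()
  xt <- build_table(tbl, "chen", ro2_factor())
  # alpha (pos, RO2+), charlie (pos, RO2+), echo (neg, RO2-);
  # bravo is RO2-negative by dose short-circuit despite missing logp
  expect_equal(unlist(xt[c("a", "b", "c", "d")]),
               c(a = 2, b = 0, c = 0, d = 2))
  all_undet <- drug_table(
    tibble::tibble(drug_id = "x", chen = "positive"), "chen"
  )
  xt0 <- build_table(all_undet, "chen", ro2_factor())
  expect_equal(sum(unlist(xt0[c("a", "b", "c", "d")])), 0)
  expect_error(sample_odds_ratio(xt0), class = "dili_stat_error")
  expect_error(build_table(tbl, "greene", ro2_factor()),
               class = "dili_schema_error")
})

test_that("sample odds ratio is the cross-product, corrected on zeros", {
  expect_equal(
    round(as.numeric(sample_odds_ratio(contingency_2x2(51, 123, 6, 59))), 2),
    4.08
  )
  flat <- sample_odds_ratio(contingency_2x2(5, 5, 5, 5))
  expect_equal(as.numeric(flat), 1)
  expect_false(attr(flat, "correction"))
  corrected <- sample_odds_ratio(contingency_2x2(1, 1, 0, 1))
  expect_equal(as.numeric(corrected), 3) # (1.5 * 1.5) / (1.5 * 0.5)
  expect_true(attr(corrected, "correction"))
  expect_error(sample_odds_ratio(contingency_2x2(0, 0, 3, 4)),
               class = "dili_stat_error")
})

test_that("odds-ratio symmetries hold", {
  withr::with_seed(5, {
    for (i in 1:50) {
      cells <- sample(1:40, 4, TRUE)
      t0 <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
      # simultaneous row and column swap leaves the OR unchanged
      t_both <- contingency_2x2(cells[4], cells[3], cells[2], cells[1])
      expect_equal(as.numeric(sample_odds_ratio(t0)),
                   as.numeric(sample_odds_ratio(t_both)))
      # a single row swap maps the OR to its reciprocal
      t_row <- contingency_2x2(cells[3], cells[4], cells[1], cells[2])
      expect_equal(as.numeric(sample_odds_ratio(t_row)),
                   1 / as.numeric(sample_odds_ratio(t0)))
    }
  })
  # increasing a strictly increases the OR
  ors <- sapply(5:10, function(a) sample_odds_ratio(contingency_2x2(a, 7, 3, 9)))
  expect_true(all(diff(ors) > 0))
})

test_that("Wald interval matches the closed form and nests in level", {
  # symmetric table: interval symmetric about 1 on the log scale
  ci <- wald_ci(contingency_2x2(5, 5, 5, 5))
  expect_equal(ci[1], 1 / ci[2])
  # direct-formula oracle
  t1 <- contingency_2x2(51, 123, 6, 59)
  or <- (51 * 59) / (123 * 6)
  se <- sqrt(1 / 51 + 1 / 123 + 1 / 6 + 1 / 59)
  want <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  expect_equal(wald_ci(t1, 0.95), want, tolerance = 1e-10)
  ci95 <- wald_ci(t1, 0.95)
  ci99 <- wald_ci(t1, 0.99)
  expect_true(ci99[1] < ci95[1] && ci95[2] < ci99[2])
  # zero cell: computed on the corrected cells, flagged upstream
  expect_silent(wald_ci(contingency_2x2(1, 1, 0, 1)))
})

test_that("logistic fit reproduces the cross-product odds ratio", {
  expect_equal(logistic_or(contingency_2x2(51, 123, 6, 59)),
               as.numeric(sample_odds_ratio(contingency_2x2(51, 123, 6, 59))),
               tolerance = 1e-8)
  expect_equal(logistic_or(contingency_2x2(5, 5, 5, 5)), 1, tolerance = 1e-10)
  expect_equal(round(logistic_or(contingency_2x2(42, 110, 3, 43)), 2), 5.47)
  expect_error(logistic_or(contingency_2x2(1, 1, 0, 1)),
               class = "dili_stat_error")
})

test_that("logistic fit agrees with glm on random tables", {
  withr::with_seed(21, {
    for (i in 1:20) {
      cells <- sample(1:50, 4, TRUE)
      t0 <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
      fit <- stats::glm(
        cbind(c(cells[1], cells[2]), c(cells[3], cells[4])) ~ c(1, 0),
        family = stats::binomial()
      )
      expect_equal(logistic_or(t0), unname(exp(coef(fit)[2])),
                   tolerance = 1e-6)
    }
  })
})

test_that("Fisher test matches stats::fisher.test on small tables", {
  # exhaustive over all tables with total <= 12
  total_max <- 12
  worst <- 0
  for (a in 0:total_max) {
    for (b in 0:(total_max - a)) {
      for (c in 0:(total_max - a - b)) {
        for (d in 0:(total_max - a - b - c)) {
          if (a + b + c + d < 1) next
          p <- fisher_exact_two_sided(contingency_2x2(a, b, c, d))
          want <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
          worst <- max(worst, abs(p - min(want, 1)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
  # and on random larger tables
  withr::with_seed(77, {
    worst_big <- max(vapply(1:100, function(i) {
      cells <- sample(0:60, 4, TRUE)
      if (sum(cells) == 0) cells[1] <- 1
      p <- fisher_exact_two_sided(do.call(contingency_2x2, as.list(cells)))
      want <- stats::fisher.test(matrix(c(cells[1], cells[3],
                                          cells[2], cells[4]), 2))$p.value
      abs(p - min(want, 1))
    }, 0))
    expect_lt(worst_big, 1e-12)
  })
})

test_that("Fisher examples: flat table, tiny diagonal, degenerate margins", {
  expect_equal(fisher_exact_two_sided(contingency_2x2(5, 5, 5, 5)), 1)
  # feasible a in {0, 1, 2} with probabilities {1/6, 4/6, 1/6}
  expect_equal(fisher_exact_two_sided(contingency_2x2(2, 0, 0, 2)), 1 / 3,
               tolerance = 1e-12)
  # a margin of zero leaves a single feasible table
  expect_equal(fisher_exact_two_sided(contingency_2x2(0, 0, 3, 4)), 1)
})

test_that("associate composes the pipeline with provenance", {
  tbl <- random_table(200, n_sources = 1, seed = 3)
  res <- associate(tbl, "s1", ro2_factor())
  expect_s3_class(res, "dili_association")
  td <- tidy(res)
  expect_equal(td$estimate,
               as.numeric(sample_odds_ratio(res$table)))
  expect_equal(td$p.value, fisher_exact_two_sided(res$table))
  expect_equal(glance(res)$n_used,
               res$table$a + res$table$b + res$table$c + res$table$d)
  one <- drug_table(
    tibble::tibble(drug_id = "x", daily_dose_mg = 200, logp = 4,
                   chen = "positive"),
    "chen"
  )
  expect_error(associate(one, "chen", ro2_factor()), class = "dili_stat_error")
})
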