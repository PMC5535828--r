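test_that("a seed fully determines the cohort", {
  p <- cohort_params(n_drugs = 300, seed = 42)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_equal(c1, c2)
  c3 <- generate_cohort(cohort_params(n_drugs = 300, seed = 43))
  expect_false(identical(
    tibble::as_tibble(c1$table), tibble::as_tibble(c3$table)
  ))
  # generation must not disturb the caller's random stream
  withr::with_seed(1, x1 <- runif(1))
  withr::with_seed(1, {
    invisible(generate_cohort(p))
    x2 <- runif(1)
  })
  expect_equal(x1, x2)
})

test_that("perfect sources reproduce the latent status exactly", {
  params <- cohort_params(
    n_drugs = 500, seed = 9,
    sources = tibble::tibble(
      name = c("u", "v"), sensitivity = 1, specificity = 1, coverage = 1
    ),
    missing_rate = c(daily_dose_mg = 0, logp = 0,
                     metabolism_fraction = 0, urinary_unchanged_fraction = 0)
  )
  cohort <- generate_cohort(params)
  want <- ifelse(cohort$truth$dili_status, "positive", "negative")
  expect_equal(cohort$table$u, want)
  expect_equal(cohort$table$v, want)
})

test_that("factor-positivity frequencies converge to the analytic marginals", {
  params <- cohort_params(
    n_drugs = 20000, seed = 5,
    missing_rate = c(daily_dose_mg = 0, logp = 0,
                     metabolism_fraction = 0, urinary_unchanged_fraction = 0)
  )
  cohort <- generate_cohort(params)
  tbl <- cohort$table
  n <- nrow(tbl)
  tol <- function(p) 4 * sqrt(p * (1 - p) / n)
  p_logp <- 1 - pnorm(3, 2, 1.8)
  expect_equal(mean(tbl$logp >= 3), p_logp, tolerance = tol(p_logp) / p_logp)
  p_dose <- 4 / 8 # levels {100, 200, 500, 1000} of 8, uniform
  expect_equal(mean(tbl$daily_dose_mg >= 100), p_dose,
               tolerance = tol(p_dose) / p_dose)
  p_met <- 1 - pbeta(0.5, 2, 2)
  expect_equal(mean(tbl$metabolism_fraction >= 0.5), p_met,
               tolerance = tol(p_met) / p_met)
})

test_that("membership counts match the multinomial expectation", {
  params <- cohort_params(n_drugs = 5000, seed = 31)
  cohort <- generate_cohort(params)
  ms <- membership_summary(cohort$table)
  src <- params$sources
  n <- params$n_drugs
  for (bits in 1:(2^nrow(src) - 1)) {
    sel <- as.logical(bitwAnd(bits, 2^(seq_len(nrow(src)) - 1)))
    prob <- prod(ifelse(sel, src$coverage, 1 - src$coverage))
    key <- paste(src$name[sel], collapse = "+")
    got <- ms$per_subset$count[ms$per_subset$subset == key]
    got <- if (length(got)) got else 0L
    expect_lt(abs(got - n * prob), 3 * sqrt(n * prob * (1 - prob)) + 1e-9)
  }
})

test_that("a null cohort estimates an RO2 odds ratio near one", {
  cohort <- generate_cohort(ro2_only_params(or = 1, n = 5000, seed = 77))
  fit <- associate(cohort$table, "truth", ro2_factor(), ci_level = 0.99)
  expect_true(fit$conf.low <= 1 && 1 <= fit$conf.high)
})

test_that("parameter recovery reports the generative odds ratio", {
  cohort <- generate_cohort(ro2_only_params(or = 5, n = 2000, seed = 13))
  rec <- recover_parameters(cohort$table, cohort$truth, ro2_factor(),
                            source = "truth")
  expect_equal(rec$generative_or, 5)
  expect_gt(rec$estimate, 3.5)
  expect_lt(rec$estimate, 7.0)
  expect_true(rec$ci_covers)
  # ground-truth labelling route agrees with the perfect source
  rec2 <- recover_parameters(cohort$table, cohort$truth, ro2_factor())
  expect_equal(rec2$estimate, rec$estimate)
})

test_that("consensus over noisy sources beats the worst single source", {
  n_rep <- 50
  errs <- purrr::map(seq_len(n_rep), function(r) {
    params <- cohort_params(
      n_drugs = 800, seed = 1000 + r,
      effect_logits = c(dose = 0, logp = 0, metabolism = 0,
                        dose_logp = log(5), dose_metabolism = 0),
      sources = tibble::tibble(
        name = paste0("s", 1:5),
        sensitivity = 0.9, specificity = 0.9, coverage = 1
      ),
      missing_rate = c(daily_dose_mg = 0, logp = 0,
                       metabolism_fraction = 0,
                       urinary_unchanged_fraction = 0)
    )
    cohort <- generate_cohort(params)
    tbl <- add_consensus_source(cohort$table)
    per_source <- vapply(paste0("s", 1:5), function(s) {
      abs(recover_parameters(tbl, cohort$truth, ro2_factor(),
                             source = s)$log_or_error)
    }, 0)
    tibble::tibble(
      consensus = abs(recover_parameters(tbl, cohort$truth, ro2_factor(),
                                         source = "consensus")$log_or_error),
      worst = max(per_source)
    )
  }) |> purrr::list_rbind()
  expect_lt(mean(errs$consensus), mean(errs$worst))
})

test_that("invalid generative parameters are rejected", {
  expect_error(cohort_params(n_drugs = 0), class = "dili_param_error")
  expect_error(
    cohort_params(sources = tibble::tibble(
      name = "s", sensitivity = 1.2, specificity = 0.9, coverage = 1
    )),
    class = "dili_param_error"
  )
  expect_error(
    cohort_params(missing_rate = c(daily_dose_mg = 1)),
    class = "dili_param_error"
  )
  expect_error(
    cohort_params(effect_logits = c(dose = 1)),
    class = "dili_param_error"
  )
})
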