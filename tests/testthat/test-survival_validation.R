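make_cohort <- function(time, event, expression = seq_along(time)) {
  survival_cohort(data.frame(
    sample_id = sprintf("s%03d", seq_along(time)),
    time = time, event = event, expression = expression))
}

test_that("cohort splitting is seeded, exact and exhaustive", {
  co <- make_cohort(rexp(150, 0.05) + 1, rbinom(150, 1, 0.8))
  sp <- split_cohort(co, seed = 5)
  expect_equal(nrow(sp$training), 100L)
  expect_equal(nrow(sp$validation), 50L)
  sp2 <- split_cohort(co, seed = 5)
  expect_identical(sp$training$sample_id, sp2$training$sample_id)
  # partition property over many seeds
  for (s in 1:100) {
    spx <- split_cohort(co, seed = s)
    ids <- c(spx$training$sample_id, spx$validation$sample_id)
    expect_equal(sort(ids), sort(co$sample_id))
    expect_length(intersect(spx$training$sample_id,
                            spx$validation$sample_id), 0L)
  }
  expect_error(split_cohort(co, fractions = c(0.5, 0.4)),
               class = "mimicscreen_config_error")
  expect_error(split_cohort(co[1:4, ]),
               class = "mimicscreen_config_error")
})

test_that("Kaplan-Meier estimates match hand tabulation and empirical survival", {
  # no censoring: S = empirical survival, median by the <= 0.5 rule
  km <- km_curve(make_cohort(c(1, 2, 3, 4), rep(1, 4)))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median_survival, 2)

  # all censored: curve stays at 1, median undefined
  km0 <- km_curve(make_cohort(c(2, 5, 7), rep(0, 3)))
  expect_length(km0$time, 0L)
  expect_true(is.na(km0$median_survival))

  # mixed 5-row fixture against a hand product-limit tabulation
  time <- c(2, 3, 3, 5, 8)
  event <- c(1, 0, 1, 1, 0)
  km5 <- km_curve(make_cohort(time, event))
  oracle <- tabulate_km(time, event)
  expect_equal(km5$time, oracle$time)
  expect_equal(km5$surv, oracle$surv)

  # larger random fixture, still censoring-aware
  set.seed(12)
  tt <- round(rexp(40, 0.1), 2)
  ee <- rbinom(40, 1, 0.7)
  kmr <- km_curve(make_cohort(tt, ee))
  oracler <- tabulate_km(tt, ee)
  expect_equal(kmr$surv, oracler$surv)
  expect_true(all(diff(kmr$surv) <= 0))

  expect_error(km_curve(make_cohort(numeric(0), integer(0))),
               class = "mimicscreen_empty_error")
  expect_error(km_curve(data.frame(sample_id = "a", time = -1, event = 1,
                                   expression = 0)),
               class = "mimicscreen_validation_error")
})

test_that("median recovery: planted exponential median within 10% at n = 500", {
  sim <- simulate_survival_cohort(
    survival_sim_config(n_patients = 500, censoring_rate = 0,
                        hazard_ratio = 1), seed = 99)
  km <- km_curve(sim$cohort)
  expect_lt(abs(km$median_survival - sim$truth$median_low) /
              sim$truth$median_low, 0.1)
})

test_that("log-rank statistic matches hand-computed O/E/V tables", {
  g1 <- make_cohort(c(1, 2, 3), rep(1, 3))
  g2 <- make_cohort(c(4, 5, 6), rep(1, 3))
  lr <- logrank_test(g1, g2)
  expect_equal(lr$chi_square,
               tabulate_logrank(g1$time, g1$event, g2$time, g2$event))
  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(g1, g1)
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p, 1)
  # label symmetry
  lr_sw <- logrank_test(g2, g1)
  expect_equal(lr_sw$chi_square, lr$chi_square)
  # censored mixed fixture against the tabulation oracle
  set.seed(7)
  t1 <- round(rexp(25, 0.08), 1); e1 <- rbinom(25, 1, 0.8)
  t2 <- round(rexp(25, 0.16), 1); e2 <- rbinom(25, 1, 0.8)
  lrm <- logrank_test(make_cohort(t1, e1), make_cohort(t2, e2))
  expect_equal(lrm$chi_square, tabulate_logrank(t1, e1, t2, e2),
               tolerance = 1e-10)
  expect_error(logrank_test(g1[0, ], g2),
               class = "mimicscreen_validation_error")
})

test_that("log-rank holds its nominal type-I error rate", {
  n_sim <- 600L
  seeds <- mimicscreen:::derive_seeds(207, n_sim)
  rej <- 0L
  for (i in seq_len(n_sim)) {
    sim <- simulate_survival_cohort(
      survival_sim_config(n_patients = 200, hazard_ratio = 1,
                          censoring_rate = 0.02), seed = seeds[i])
    co <- sim$cohort
    hi <- co$expression > median(co$expression)
    if (logrank_test(co[hi, ], co[!hi, ])$p < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_sim
  # nominal 0.05 within 3 binomial SEs at this replicate count
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("the cutoff scan finds planted effects and rejects degenerate input", {
  sim <- simulate_survival_cohort(
    survival_sim_config(n_patients = 400, hazard_ratio = 3,
                        threshold_percentile = 60), seed = 13)
  scan <- cutoff_scan(sim$cohort)
  expect_true(all(scan$candidates$percentile >= 25 &
                    scan$candidates$percentile <= 75))
  expect_true(all(scan$candidates$selected[!is.na(scan$candidates$p)] ==
                    (scan$candidates$p[!is.na(scan$candidates$p)] < 0.05)))
  expect_lte(abs(scan$best - 60), 10)
  # dichotomization convention: high = strictly above the quantile value
  i40 <- which(scan$candidates$percentile == 40)
  cut40 <- scan$candidates$cutoff_value[i40]
  expect_equal(scan$candidates$n_high[i40],
               sum(sim$cohort$expression > cut40))
  const <- make_cohort(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(2, 6))
  expect_error(cutoff_scan(const), class = "mimicscreen_degenerate_error")
})

test_that("training multiplicity inflates selection while validation controls it", {
  n_rep <- 250L
  seeds <- mimicscreen:::derive_seeds(501, n_rep)
  any_selected <- 0L
  n_validated <- 0L
  n_with_selection <- 0L
  for (i in seq_len(n_rep)) {
    sim <- simulate_survival_cohort(
      survival_sim_config(n_patients = 150, hazard_ratio = 1,
                          censoring_rate = 0.02), seed = seeds[i])
    sp <- split_cohort(sim$cohort, seed = seeds[i])
    scan <- tryCatch(cutoff_scan(sp$training),
                     mimicscreen_degenerate_error = function(e) NULL)
    if (is.null(scan)) next
    sel <- scan$candidates[scan$candidates$selected, , drop = FALSE]
    if (nrow(sel) == 0L) next
    any_selected <- any_selected + 1L
    best <- sel[which.min(sel$p), ]
    val <- tryCatch(validate_cutoff(sp$validation, best$cutoff_value),
                    mimicscreen_degenerate_error = function(e) NULL)
    if (is.null(val)) next
    n_with_selection <- n_with_selection + 1L
    if (val$p < 0.05) n_validated <- n_validated + 1L
  }
  # the uncorrected scan selects far more often than alpha (documented
  # multiplicity of the procedure, measured rather than corrected)
  expect_gt(any_selected / n_rep, 0.10)
  # but the held-out confirmation runs at the nominal rate
  rate <- n_validated / n_with_selection
  expect_lt(abs(rate - 0.05),
            3 * sqrt(0.05 * 0.95 / n_with_selection))
})

test_that("validated cutoffs reproduce planted group medians", {
  sim <- simulate_survival_cohort(
    survival_sim_config(n_patients = 600, hazard_ratio = 3,
                        threshold_percentile = 50,
                        censoring_rate = 0), seed = 41)
  sp <- split_cohort(sim$cohort, seed = 2)
  scan <- cutoff_scan(sp$training)
  best <- scan$candidates[which.min(scan$candidates$p), ]
  val <- validate_cutoff(sp$validation, best$cutoff_value)
  expect_lt(val$p, 0.05)
  # planted high group has the 3x hazard, so the shorter median
  expect_lt(val$median_high, val$median_low)
  expect_lt(abs(val$median_low - sim$truth$median_low) /
              sim$truth$median_low, 0.35)
  expect_lt(abs(val$median_high - sim$truth$median_high) /
              sim$truth$median_high, 0.35)
  # strong consistent effect validates on the training data itself
  expect_lt(validate_cutoff(sp$training, best$cutoff_value)$p, 0.05)
  # cutoff below every validation expression empties a group
  expect_error(
    validate_cutoff(sp$validation,
                    min(sp$validation$expression) - 10),
    class = "mimicscreen_degenerate_error")
})
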