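test_that("median dichotomization uses a strict greater-than", {
  r <- dichotomize_by_median(data.frame(gloh = c(5, 9.9, 12)))
  expect_equal(attr(r, "median_gloh"), 9.9)
  expect_equal(as.character(r$group), c("low", "low", "high"))
  # all-distinct even n splits exactly in half
  r2 <- dichotomize_by_median(data.frame(gloh = c(1, 3, 7, 9, 11, 20)))
  expect_equal(unname(table(r2$group)["high"]), 3L)
  expect_error(dichotomize_by_median(data.frame(gloh = rep(4, 5))),
               class = "lohscape_error_single_group")
  expect_error(dichotomize_by_median(data.frame(gloh = 1)),
               class = "lohscape_error_invalid_argument")
})

test_that("KM estimator: hand-computed values and the ECDF identity", {
  # all events, no censoring
  km <- km_estimate(data.frame(time = 1:3, event = TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # mixed censoring, 6 records, 2 censored: hand product over risk sets
  rec <- data.frame(time = c(1, 2, 2.5, 3, 4, 5),
                    event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  km2 <- km_estimate(rec)
  hand <- hand_km(rec$time, rec$event)
  expect_equal(km2$surv[km2$n_event > 0], hand$surv)
  expect_equal(hand$surv, c(5 / 6, 5 / 6 * 4 / 5, 5 / 6 * 4 / 5 * 2 / 3,
                            5 / 6 * 4 / 5 * 2 / 3 * 0))
  # no censoring: KM equals 1 - ECDF at every time
  withr::with_seed(31, {
    tt <- rexp(200)
    km3 <- km_estimate(data.frame(time = tt, event = TRUE))
    expect_equal(km3$surv, 1 - ecdf(tt)(km3$time), tolerance = 1e-12)
    expect_true(all(diff(km3$surv) <= 1e-12))
    expect_equal(max(km3$surv), 1 - 1 / 200)
  })
  expect_error(km_estimate(data.frame(time = 1:3, event = FALSE)),
               class = "lohscape_error_no_events")
})

test_that("log-rank: identical groups, relabeling invariance", {
  rec <- data.frame(time = rep(c(1, 2, 3, 5, 8), 2), event = TRUE,
                    group = rep(c("a", "b"), each = 5))
  lr <- logrank_test(rec)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  withr::with_seed(37, {
    rec2 <- data.frame(time = rexp(60), event = runif(60) < 0.8,
                       group = rep(c("a", "b"), 30))
    swapped <- rec2
    swapped$group <- ifelse(rec2$group == "a", "b", "a")
    expect_equal(logrank_test(rec2)$chisq, logrank_test(swapped)$chisq)
  })
  expect_error(logrank_test(rec[rec$group == "a", ]),
               class = "lohscape_error_invalid_argument")
})

test_that("Cox fit: brute-force partial likelihood oracle; tie methods", {
  withr::with_seed(41, {
    n <- 30
    rec <- data.frame(time = round(rexp(n), 6), # no ties
                      event = runif(n) < 0.7,
                      x = rep(0:1, n / 2))
    cx <- cox_fit(rec, "x")
    # oracle: maximize the enumerated partial likelihood on a fine grid
    grid <- seq(-3, 3, by = 1e-3)
    ll <- vapply(grid, function(b)
      bf_cox_loglik(rec$time, rec$event, rec$x, b), numeric(1))
    expect_lt(abs(cx$terms$coef - grid[which.max(ll)]), 2e-3)
    # Efron and Breslow agree when there are no ties
    cb <- cox_fit(rec, "x", ties = "breslow")
    expect_equal(cx$terms$coef, cb$terms$coef, tolerance = 1e-8)
  })
  expect_error(cox_fit(data.frame(time = 1:4, event = TRUE, x = 1), "x"),
               class = "lohscape_error_invalid_argument")
  expect_error(cox_fit(data.frame(time = 1:4, event = FALSE, x = rep(0:1, 2)),
                       "x"),
               class = "lohscape_error_no_events")
})

test_that("Cox coverage: null covariate CI covers 1 in ~95% of replicates", {
  withr::with_seed(43, {
    cover <- 0L
    for (i in 1:200) {
      rec <- data.frame(time = rexp(120, 0.05), event = TRUE,
                        x = rep(0:1, 60))
      cx <- cox_fit(rec, "x")
      if (cx$terms$ci_low <= 1 && 1 <= cx$terms$ci_high) cover <- cover + 1L
    }
    expect_gt(cover / 200, 0.90)
    expect_lt(cover / 200, 0.99)
  })
})

test_that("planted HR 0.31 is recovered within 3 SE at n = 1000", {
  co <- simulate_cohort(cohort_spec(n_samples = 1000, seed = 47))
  sv <- simulate_survival(co, list(baseline_hazard = log(2) / 36,
                                   hr_high = 0.31, censoring_rate = 0.2),
                          seed = 47)
  cx <- cox_fit(sv, "group")
  se <- (log(cx$terms$ci_high) - log(cx$terms$ci_low)) / (2 * 1.96)
  expect_lt(abs(cx$terms$coef - log(0.31)), 3 * se)
})
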