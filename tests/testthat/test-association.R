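mk_matrix <- function(n, ...) {
  cols <- list(...)
  M <- matrix(0L, n, length(cols), dimnames = list(NULL, names(cols)))
  for (k in names(cols)) M[cols[[k]], k] <- 1L
  M
}

test_that("HR group assignment follows the precedence rule", {
  M <- mk_matrix(6,
    "BRCA2:homozygous_deletion" = c(1, 2),
    "ATM:missense" = c(2, 3),
    "RAD51B:homozygous_deletion" = c(3, 4),
    "FBXW7:amplification" = 5)
  grp <- suppressWarnings(assign_hr_groups(M))
  expect_equal(as.character(grp),
               c("BRCA2_homdel", "BRCA2_homdel", "non_BRCA2_homdel",
                 "non_BRCA2_homdel", "HR_intact", "HR_intact"))
  # group sizes partition the cohort
  expect_equal(sum(table(grp)), 6)
  # empty HR list -> everyone intact
  expect_true(all(assign_hr_groups(M, character(0)) == "HR_intact"))
  expect_warning(assign_hr_groups(M, c("BRCA2", "NOTAGENE")), "NOTAGENE")
})

test_that("group_contrast: degenerate and identity-adjustment cases", {
  x <- rep(5, 40)
  g <- rep(c("HR_intact", "HR_mutation"), each = 20)
  gc <- group_contrast(x, g)
  expect_equal(gc$anova_f, 0)
  expect_equal(gc$anova_p, 1)
  expect_equal(gc$comparisons$p_adj, 1)
  # two groups: adjusted p equals the plain Welch p exactly
  withr::with_seed(1, {
    y <- c(rnorm(30), rnorm(25, 1))
    g2 <- rep(c("HR_intact", "BRCA2_homdel"), c(30, 25))
    gc2 <- group_contrast(y, g2)
    w <- t.test(y[g2 == "BRCA2_homdel"], y[g2 == "HR_intact"])
    expect_equal(gc2$comparisons$p_adj, w$p.value, tolerance = 1e-9)
  })
  expect_error(group_contrast(1:3, rep("a", 3)),
               class = "lohscape_error_invalid_argument")
})

test_that("group_contrast power/level at the published group sizes", {
  ns <- c(HR_intact = 1451, HR_mutation = 125, non_BRCA2_homdel = 48,
          BRCA2_homdel = 34)
  g <- factor(rep(names(ns), ns), levels = names(ns))
  hit_b2 <- 0L; false_other <- 0L
  withr::with_seed(11, {
    for (i in 1:500) {
      y <- rnorm(sum(ns), 12.9, 7) + 6 * (g == "BRCA2_homdel")
      gc <- group_contrast(y, g, mc_draws = 2000L, seed = i)
      p <- gc$comparisons$p_adj
      names(p) <- gc$comparisons$comparison
      if (p[["BRCA2_homdel vs HR_intact"]] < 0.01) hit_b2 <- hit_b2 + 1L
      if (min(p[c("HR_mutation vs HR_intact",
                  "non_BRCA2_homdel vs HR_intact")]) < 0.01)
        false_other <- false_other + 1L
    }
  })
  expect_gte(hit_b2 / 500, 0.90)
  expect_lte(false_other / 500, 0.10)
})

test_that("univariate screen: exact noiseless recovery and lm oracle", {
  n <- 400
  M <- mk_matrix(n, "K:amplification" = 1:40, "L:missense" = 21:80)
  y <- 10 + 5 * M[, 1] + 0 * M[, 2]
  scr <- univariate_screen(y, M)
  expect_equal(scr$estimate[1], 5, tolerance = 1e-12)
  expect_lt(scr$ci_high[1] - scr$ci_low[1], 1e-8)
  # oracle: stats::lm per key on a noisy response
  withr::with_seed(5, {
    y2 <- y + rnorm(n, 0, 3)
    scr2 <- univariate_screen(y2, M)
    for (j in 1:2) {
      fit <- lm(y2 ~ M[, j])
      expect_equal(scr2$estimate[j], unname(coef(fit)[2]), tolerance = 1e-9)
      expect_equal(scr2$p_value[j],
                   summary(fit)$coefficients[2, 4], tolerance = 1e-9)
      expect_equal(unlist(scr2[j, c("ci_low", "ci_high")], use.names = FALSE),
                   unname(confint(fit)[2, ]), tolerance = 1e-9)
    }
  })
  expect_error(univariate_screen(rep(1, n), M),
               class = "lohscape_error_undefined_fit")
})

test_that("screen properties: Bonferroni dominance and idempotence", {
  co <- simulate_cohort(cohort_spec(n_samples = 800, seed = 21))
  scr <- univariate_screen(co)
  expect_true(all(scr$q_value >= scr$p_value - 1e-15))
  expect_true(all(scr$q_value <= 1))
  expect_equal(attr(scr, "m"), nrow(scr))
  # re-running on the candidate subset with m unchanged reproduces q-values
  sub <- univariate_screen(co$samples$gloh,
                           co$alterations[, scr$key, drop = FALSE])
  expect_equal(sub$q_value, scr$q_value, tolerance = 1e-12)
})

test_that("multivariate fit: exact orthogonal effects and duplicate drop", {
  n <- 300
  M <- mk_matrix(n, "A:amplification" = 1:50, "B:missense" = 51:100)
  ut <- rep(c(TRUE, FALSE), length.out = n)
  y <- 10 + 4 * M[, 1] + 1.2 * ut
  fit <- suppressWarnings(multivariate_fit(y, M, uterine = ut))
  est <- setNames(fit$estimate, fit$term)
  expect_equal(unname(est["A:amplification"]), 4, tolerance = 1e-9)
  expect_equal(unname(est["uterine"]), 1.2, tolerance = 1e-9)
  withr::with_seed(8, {
    y3 <- y + rnorm(n, 0, 2)
    fit3 <- multivariate_fit(y3, M, uterine = ut)
    # OLS oracle: normal equations
    ora <- ols_oracle(y3, cbind(M, ut))
    expect_equal(fit3$estimate, ora, tolerance = 1e-9)
    # duplicated column dropped; result identical to deduplicated design
    M2 <- cbind(M, "A2:amplification" = M[, 1])
    expect_warning(fit4 <- multivariate_fit(y3, M2, uterine = ut),
                   "duplicated|collinear")
    expect_equal(setNames(fit4$estimate, fit4$term)[fit3$term],
                 setNames(fit3$estimate, fit3$term), tolerance = 1e-9)
  })
})

test_that("multivariate fit separates confounded effects (marginal is biased)", {
  # BRCA2 deletion enriched in uterine samples; planted effects 6.13 / 0.86
  cover_joint <- 0L
  bias_marg <- numeric(100)
  withr::with_seed(13, {
    for (i in 1:100) {
      n <- 1658
      ut <- runif(n) < 0.4
      b2 <- rbinom(n, 1, ifelse(ut, 0.05, 0.01))
      y <- rlnorm(n, 2.4, 0.5) + 6.13 * b2 + 0.86 * ut
      M <- cbind("BRCA2:homozygous_deletion" = b2)
      fit <- multivariate_fit(y, M, uterine = ut)
      r <- fit[fit$term == "BRCA2:homozygous_deletion", ]
      if (r$ci_low <= 6.13 && 6.13 <= r$ci_high) cover_joint <- cover_joint + 1L
      bias_marg[i] <- unname(coef(lm(y ~ b2))[2]) - 6.13
    }
  })
  expect_gte(cover_joint / 100, 0.90)
  expect_gt(mean(bias_marg), 0.1)  # marginal fit absorbs the uterine shift
})

test_that("differential prevalence: conjunction rule, power, exact fallback", {
  withr::with_seed(17, {
    n_u <- 651; n_n <- 1007
    ut <- rep(c(TRUE, FALSE), c(n_u, n_n))
    # identical prevalence -> not significant
    M0 <- cbind("G:missense" = rbinom(n_u + n_n, 1, 0.2))
    d0 <- differential_prevalence(M0, ut)
    expect_false(d0$significant)
    # planted delta = 0.15 detected in >= 95% of 200 replicates
    hits <- 0L
    for (i in 1:200) {
      M <- cbind("G:missense" = rbinom(n_u + n_n, 1, ifelse(ut, 0.30, 0.15)))
      if (differential_prevalence(M, ut)$significant) hits <- hits + 1L
    }
    expect_gte(hits / 200, 0.95)
  })
  # delta below 0.10 is never significant however small p is
  big <- rep(c(TRUE, FALSE), c(5000, 5000))
  Mb <- cbind("G:missense" = as.integer(c(rep(1, 450), rep(0, 4550),
                                          rep(1, 0), rep(0, 5000))))
  db <- differential_prevalence(Mb, big)
  expect_lt(db$p_value, 1e-10)
  expect_lt(abs(db$delta), 0.10)
  expect_false(db$significant)
  # sparse key (expected cell count < 1) falls back to the exact test
  Ms <- mk_matrix(60, "R:truncation" = 1)
  expect_warning(ds <- differential_prevalence(Ms, rep(c(TRUE, FALSE), 30)),
                 "exact")
  expect_equal(ds$test, "exact")
  expect_error(differential_prevalence(Ms, rep(TRUE, 60)),
               class = "lohscape_error_invalid_argument")
})

test_that("mutual exclusivity: oracle p, direction and capped odds ratio", {
  # never co-occurring keys
  M <- mk_matrix(2000, "A:homozygous_deletion" = 1:200,
                 "B:homozygous_deletion" = 201:400)
  mx <- mutual_exclusivity(M)
  expect_equal(mx$direction, "exclusive")
  expect_lt(mx$p_value, 1e-4)
  # p matches direct hypergeometric enumeration
  expect_equal(mx$p_value, hyper_fisher_p(0, 200, 200, 1600),
               tolerance = 1e-9)
  withr::with_seed(23, {
    for (i in 1:20) {
      a <- rbinom(300, 1, 0.2); b <- rbinom(300, 1, 0.3)
      Mi <- cbind("A:missense" = a, "B:missense" = b)
      got <- mutual_exclusivity(Mi)$p_value
      tab <- table(factor(a, 0:1), factor(b, 0:1))
      expect_equal(got,
                   hyper_fisher_p(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1]),
                   tolerance = 1e-6)
    }
  })
  # strict subset: co-occurring with capped odds ratio
  M2 <- mk_matrix(500, "A:amplification" = 1:50, "B:amplification" = 1:100)
  mx2 <- mutual_exclusivity(M2)
  expect_equal(mx2$direction, "co_occurring")
  expect_lte(mx2$odds_ratio, 1e6)
  expect_warning(
    empty <- mutual_exclusivity(M2, list(c("A:amplification", "ZZ:missense"))),
    "absent")
  expect_equal(nrow(empty), 0)
})

test_that("independent keys give a calibrated exclusivity test", {
  withr::with_seed(29, {
    rej <- 0L
    for (i in 1:200) {
      Mi <- cbind("A:missense" = rbinom(400, 1, 0.15),
                  "B:missense" = rbinom(400, 1, 0.15))
      if (mutual_exclusivity(Mi)$p_value < 0.05) rej <- rej + 1L
    }
    expect_lte(rej / 200, 0.07)  # Fisher is conservative under the null
  })
})
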