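test_that("simulate_sample: BAF behaviour at fixed points", {
  g <- toy_genome()
  panel <- make_snp_panel(g, 3000, seed = 1)
  dip <- diploid_planted(g)
  s <- simulate_sample(g, panel, dip, purity = 1, depth_mean = 100, seed = 2)
  baf <- s$snp_obs$alt_count / s$snp_obs$depth
  expect_lt(abs(mean(baf, na.rm = TRUE) - 0.5), 0.02)  # symmetry
  expect_equal(s$gloh_true, 0)
  # fixed allele: (Ci=2, Mi=0) at purity 1 on chromosome 2 tail
  pl <- toy_planted()
  s2 <- simulate_sample(g, panel, pl, purity = 1, depth_mean = 100, seed = 3)
  sel <- s2$snp_obs$chrom == 2 & s2$snp_obs$pos >= 50e6
  baf2 <- s2$snp_obs$alt_count[sel] / s2$snp_obs$depth[sel]
  expect_true(all(baf2 < 0.05 | baf2 > 0.95))
})

test_that("simulate_sample matches the closed-form purity-mixture BAF", {
  g <- toy_genome()
  panel <- make_snp_panel(g, 3000, seed = 4)
  # hemizygous loss on half of each p arm: BAF* = (1-p)/(p + 2(1-p)) = 0.4/1.4
  pl <- do.call(rbind, lapply(g$chrom, function(ch) {
    cen <- g$centromere[ch]; L <- g$length[ch]
    data.frame(chrom = ch, start = c(0, cen / 2), end = c(cen / 2, L),
               Ci = c(1L, 2L), Mi = c(0L, 1L))
  }))
  s <- simulate_sample(g, panel, pl, purity = 0.6, depth_mean = 200, seed = 5)
  in_loh <- s$snp_obs$pos < g$centromere[s$snp_obs$chrom] / 2
  baf <- (s$snp_obs$alt_count / s$snp_obs$depth)[in_loh]
  fold <- pmin(baf, 1 - baf)
  target <- 0.4 / 1.4
  se <- sqrt(target * (1 - target) / 200 / length(fold))
  expect_lt(abs(mean(fold) - target), 4 * se + 0.002)
  expect_equal(s$gloh_true, planted_gloh(pl, g)$percent_gloh)
  expect_equal(s$gloh_true,
               100 * sum(g$centromere / 2) / sum(g$length))
})

test_that("simulate_sample validates inputs and is deterministic", {
  g <- toy_genome()
  panel <- make_snp_panel(g, 200, seed = 1)
  dip <- diploid_planted(g)
  expect_error(simulate_sample(g, panel, dip, purity = 0, seed = 1),
               class = "lohscape_error_invalid_argument")
  expect_error(simulate_sample(g, panel, dip, purity = 1.2, seed = 1),
               class = "lohscape_error_invalid_argument")
  gap <- dip; gap$end[1] <- gap$end[1] - 10
  expect_error(simulate_sample(g, panel, gap, purity = 1, seed = 1),
               class = "lohscape_error_invalid_argument")
  a <- simulate_sample(g, panel, dip, purity = 0.8, seed = 9)
  b <- simulate_sample(g, panel, dip, purity = 0.8, seed = 9)
  expect_identical(a, b)
})

test_that("gloh_true comes from the shared scoring formula", {
  g <- default_genome()
  pl <- plant_segments(g, 30, seed = 11)
  panel <- make_snp_panel(g, 300, seed = 1)
  s <- simulate_sample(g, panel, pl, purity = 0.9, seed = 1)
  expect_identical(s$gloh_true, planted_gloh(pl, g)$percent_gloh)
})

test_that("simulate_cohort: degenerate, moment-matched and prevalence", {
  # degenerate distribution
  sp <- cohort_spec(n_samples = 100, mu = log(12), sigma = 1e-6,
                    alterations = data.frame(gene = "BRCA2",
                                             alt_class = "homozygous_deletion",
                                             prevalence = 0, effect = 0),
                    uterine_effect = 0, seed = 1)
  co <- simulate_cohort(sp)
  expect_true(all(abs(co$samples$gloh - 12) < 1e-4))
  # moment fidelity at n = 50,000 (no alterations, no uterine effect)
  sp2 <- cohort_spec(n_samples = 50000,
                     alterations = data.frame(gene = "BRCA2",
                                              alt_class = "homozygous_deletion",
                                              prevalence = 0.021, effect = 0),
                     uterine_effect = 0, seed = 2)
  co2 <- simulate_cohort(sp2)
  expect_lt(abs(mean(co2$samples$gloh) - 12.9), 0.2)
  expect_lt(abs(sd(co2$samples$gloh) - 6.9), 3 * 6.9 / sqrt(2 * 50000))
  # prevalence within binomial error
  prev <- mean(co2$alterations[, "BRCA2:homozygous_deletion"])
  expect_lt(abs(prev - 0.021), 0.003)
  # invalid prevalence
  expect_error(cohort_spec(alterations = data.frame(
    gene = "X", alt_class = "missense", prevalence = 1.2, effect = 0)),
    class = "lohscape_error_invalid_argument")
})

test_that("cohort generator is deterministic and honors exclusivity", {
  sp <- cohort_spec(n_samples = 500, seed = 7,
                    exclusive_pairs = list(c("CDKN2A:homozygous_deletion",
                                             "RB1:homozygous_deletion")))
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(a$samples, b$samples)
  expect_identical(a$alterations, b$alterations)
  both <- a$alterations[, "CDKN2A:homozygous_deletion"] &
    a$alterations[, "RB1:homozygous_deletion"]
  expect_equal(sum(both), 0)
})

test_that("simulate_survival: censoring extremes and errors", {
  co <- simulate_cohort(cohort_spec(n_samples = 60, seed = 3))
  sv0 <- simulate_survival(co, list(baseline_hazard = 0.02, hr_high = 1,
                                    censoring_rate = 0), seed = 4)
  expect_true(all(sv0$event))
  sv1 <- simulate_survival(co, list(baseline_hazard = 0.02, hr_high = 1,
                                    censoring_rate = 1), seed = 4)
  expect_false(any(sv1$event))
  expect_error(logrank_test(sv1), class = "lohscape_error_no_events")
  expect_error(simulate_survival(co, list(baseline_hazard = -1,
                                          hr_high = 0.31,
                                          censoring_rate = 0)),
               class = "lohscape_error_invalid_argument")
  expect_error(simulate_survival(co$samples[0, ]),
               class = "lohscape_error_invalid_argument")
})

test_that("gloh_lognormal_params moment-matches", {
  p <- gloh_lognormal_params(12.9, 6.9)
  expect_equal(exp(p$mu + p$sigma^2 / 2), 12.9, tolerance = 1e-12)
  m2 <- (exp(p$sigma^2) - 1) * exp(2 * p$mu + p$sigma^2)
  expect_equal(sqrt(m2), 6.9, tolerance = 1e-9)
})
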