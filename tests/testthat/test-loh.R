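test_that("LOH rule: Ci != 0 and Mi == 0", {
  expect_false(call_loh(2L, 1L))
  expect_true(call_loh(1L, 0L))
  expect_true(call_loh(2L, 0L))   # copy-neutral LOH counts
  expect_false(call_loh(0L, 0L))  # homozygous deletion is not LOH
})

mk_segs <- function(chrom, start, end, loh, n_snps = 50L, margin = Inf) {
  data.frame(chrom = chrom, start = start, end = end, n_snps = n_snps,
             is_loh = loh, margin = margin)
}

two_chrom_genome <- function() {
  g <- data.frame(chrom = 1:2, length = c(100, 100), centromere = c(50, 50))
  class(g) <- c("loh_genome", "data.frame")
  g
}

test_that("whole-chromosome and arm exclusions at the 90% threshold", {
  g <- two_chrom_genome()
  # 100% of chromosome 1 in LOH -> excluded
  s <- apply_exclusions(mk_segs(1, 0, 100, TRUE), g)
  expect_true(s$excluded)
  expect_equal(s$exclusion_reason, "whole_chrom_or_arm")
  # 89% of the p arm, 44.5% of the chromosome -> retained
  s2 <- apply_exclusions(
    mk_segs(1, c(0, 44.5), c(44.5, 100), c(TRUE, FALSE)), g)
  expect_false(any(s2$excluded))
  # exactly 90% of an arm -> excluded (threshold inclusive)
  s3 <- apply_exclusions(mk_segs(1, c(0, 45), c(45, 100), c(TRUE, FALSE)), g)
  expect_identical(s3$exclusion_reason, c("whole_chrom_or_arm", "none"))
  expect_error(apply_exclusions(mk_segs(1, 0, 100, TRUE), NULL),
               class = "lohscape_error_invalid_argument")
})

test_that("worked exclusion example: 100 x 30 / 105", {
  g <- two_chrom_genome()
  segs <- rbind(mk_segs(1, c(0, 95), c(95, 100), c(TRUE, FALSE)),
                mk_segs(2, c(0, 30), c(30, 100), c(TRUE, FALSE)))
  segs <- apply_exclusions(segs, g)
  res <- compute_percent_gloh(segs)
  expect_equal(res$percent_gloh, 100 * 30 / 105, tolerance = 1e-12)
  expect_equal(res$len_excluded_arm, 95)
})

test_that("split invariance: re-splitting an LOH run never changes flags", {
  g <- two_chrom_genome()
  base <- rbind(mk_segs(1, c(0, 48), c(48, 100), c(TRUE, FALSE)),
                mk_segs(2, c(0, 60, 92), c(60, 92, 100),
                        c(FALSE, TRUE, FALSE)))
  ref <- compute_percent_gloh(apply_exclusions(base, g))
  withr::with_seed(99, {
    for (i in 1:20) {
      # randomly split every segment into 1-4 pieces with identical state
      pieces <- lapply(seq_len(nrow(base)), function(j) {
        k <- sample(1:4, 1)
        cuts <- sort(c(base$start[j], base$end[j],
                       runif(k - 1, base$start[j], base$end[j])))
        mk_segs(base$chrom[j], head(cuts, -1), cuts[-1], base$is_loh[j])
      })
      segs <- do.call(rbind, pieces)
      segs <- segs[order(segs$chrom, segs$start), ]
      res <- compute_percent_gloh(apply_exclusions(segs, g))
      expect_equal(res$percent_gloh, ref$percent_gloh, tolerance = 1e-9)
    }
  })
  # a whole-arm run split in two halves is still excluded after merging
  halves <- rbind(mk_segs(1, c(0, 25), c(25, 50), TRUE),
                  mk_segs(1, 50, 100, FALSE))
  s <- apply_exclusions(halves, g)
  expect_identical(s$exclusion_reason,
                   c("whole_chrom_or_arm", "whole_chrom_or_arm", "none"))
})

test_that("ambiguous exclusions: low SNP support or low margin", {
  g <- two_chrom_genome()
  segs <- mk_segs(1, c(0, 20, 60), c(20, 60, 100), c(TRUE, FALSE, TRUE),
                  n_snps = c(3L, 50L, 50L), margin = c(Inf, Inf, 0.01))
  s <- apply_exclusions(segs, g)
  expect_identical(s$exclusion_reason, c("ambiguous", "none", "ambiguous"))
  res <- compute_percent_gloh(s)
  expect_equal(res$percent_gloh, 0)
  expect_equal(res$len_excluded_ambiguous, 60)
})

test_that("score formula, bounds and bookkeeping close exactly", {
  g <- two_chrom_genome()
  # trivial: LOH on [0,40) of a single 100-unit chromosome -> 40%
  s <- apply_exclusions(mk_segs(1, c(0, 40), c(40, 100), c(TRUE, FALSE)), g)
  expect_equal(compute_percent_gloh(s)$percent_gloh, 40)
  withr::with_seed(7, {
    for (i in 1:25) {
      # random tilings with random states
      segs <- do.call(rbind, lapply(1:2, function(ch) {
        cuts <- sort(c(0, 100, runif(sample(1:6, 1), 0, 100)))
        mk_segs(ch, head(cuts, -1), cuts[-1],
                sample(c(TRUE, FALSE), length(cuts) - 1, TRUE),
                n_snps = sample(c(3L, 50L), length(cuts) - 1, TRUE))
      }))
      segs <- apply_exclusions(segs, g)
      res <- tryCatch(compute_percent_gloh(segs),
                      lohscape_error_undefined_score = function(e) NULL)
      if (is.null(res)) next
      expect_gte(res$percent_gloh, 0)
      expect_lte(res$percent_gloh, 100)
      # conservation: included + excluded = genome length
      expect_equal(res$total_len_included + res$len_excluded_arm +
                     res$len_excluded_ambiguous, 200, tolerance = 1e-9)
    }
  })
})

test_that("adding LOH to an included het region never lowers the score", {
  # holds provided the addition does not push an LOH run over the 90%
  # chromosome/arm exclusion span (the flipped region here covers 80% of
  # the chr2 p arm, below the threshold)
  g <- two_chrom_genome()
  base <- rbind(mk_segs(1, c(0, 30, 60), c(30, 60, 100),
                        c(TRUE, FALSE, FALSE)),
                mk_segs(2, c(0, 40), c(40, 100), FALSE))
  before <- compute_percent_gloh(apply_exclusions(base, g))$percent_gloh
  flipped <- base
  flipped$is_loh[4] <- TRUE  # chr2 [0, 40)
  after <- compute_percent_gloh(apply_exclusions(flipped, g))$percent_gloh
  expect_gte(after, before)
  expect_equal(after, 100 * 70 / 200)
})

test_that("undefined score and QC failure are classed errors", {
  g <- two_chrom_genome()
  all_loh <- rbind(mk_segs(1, 0, 100, TRUE), mk_segs(2, 0, 100, TRUE))
  expect_error(compute_percent_gloh(apply_exclusions(all_loh, g)),
               class = "lohscape_error_undefined_score")
  prof <- structure(list(qc_pass = FALSE, qc_reason = "low_tumor_content",
                         segments = NULL), class = "tumor_profile")
  err <- tryCatch(compute_percent_gloh(prof), error = identity)
  expect_s3_class(err, "lohscape_error_qc_failure")
  expect_equal(err$qc_reason, "low_tumor_content")
})
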