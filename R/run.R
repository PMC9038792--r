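#' Engine configuration
#'
#' Thresholds and knobs of the per-sample gLOH engine, all documented proxies
#' for an unpublished commercial pipeline (see the methods vignette).
#'
#' @param penalty changepoint penalty; `NULL` = `3 * log(n)` per chromosome.
#' @param min_snps minimum SNPs per segment for fitting/confident calls.
#' @param margin_threshold ambiguity threshold on the (Ci, Mi) margin.
#' @param arm_span_threshold whole-chromosome/arm exclusion span (0.90).
#' @param Ci_max largest modelled total copy number.
#' @param purity_qc_min fitted/implied purity below this fails QC as
#'   `low_tumor_content` (default 0.20).
#' @param aneuploid_frac_min genome fraction in a non-(2,1) state below which
#'   (absent allelic-imbalance evidence) QC fails as `low_aneuploidy`.
#' @param imbalance_z z-score for calling a segment's allelic imbalance or
#'   log-ratio deviation significant (default 4).
#' @param qc_override if `TRUE`, a score is still computed for QC-failed
#'   samples (reported alongside the failure reason).
#' @return named list of class `gloh_config`.
#' @export
gloh_config <- function(penalty = NULL, min_snps = 5L,
                        margin_threshold = 0.05, arm_span_threshold = 0.90,
                        Ci_max = 8L, purity_qc_min = 0.20,
                        aneuploid_frac_min = 0.02, imbalance_z = 4,
                        qc_override = FALSE) {
  structure(list(penalty = penalty, min_snps = as.integer(min_snps),
                 margin_threshold = margin_threshold,
                 arm_span_threshold = arm_span_threshold,
                 Ci_max = as.integer(Ci_max),
                 purity_qc_min = purity_qc_min,
                 aneuploid_frac_min = aneuploid_frac_min,
                 imbalance_z = imbalance_z,
                 qc_override = isTRUE(qc_override)),
            class = "gloh_config")
}

#' Score percent gLOH for one tumor sample
#'
#' End-to-end composition of the engine: log-ratio profile against the
#' process-matched reference, joint segmentation, QC (tumor content and
#' aneuploidy evidence), purity/ploidy grid fit, per-segment (Ci, Mi)
#' assignment, LOH calling, exclusions, and the percent-gLOH formula.
#'
#' @param snp_obs data.frame with `chrom`, `pos`, `depth`, `alt_count` and
#'   either a `ref_depth` column or the `ref_depth` argument.
#' @param genome genome model (default [default_genome()]).
#' @param config engine configuration from [gloh_config()].
#' @param sample_id label used in reports and error context.
#' @param ref_depth optional reference depths (vector or scalar) overriding
#'   `snp_obs$ref_depth`.
#' @return list of class `gloh_run`: `sample_id`, `profile` (a
#'   `tumor_profile`: `segments`, `purity`, `psi`, `qc_pass`, `qc_reason`,
#'   `n_sites`) and `result` (a `gloh_result`, or `NULL` when QC failed and
#'   `qc_override` is off).
#' @export
#' @examples
#' g <- default_genome()
#' s <- simulate_sample(g, make_snp_panel(g, 1500, 1),
#'                      plant_segments(g, 25, 1), purity = 0.7,
#'                      depth_mean = 250, seed = 5)
#' r <- run_gloh(s$snp_obs, g, sample_id = "demo")
#' c(true = s$gloh_true, est = r$result$percent_gloh)
run_gloh <- function(snp_obs, genome = default_genome(),
                     config = gloh_config(), sample_id = "sample",
                     ref_depth = NULL) {
  need <- c("chrom", "pos", "depth", "alt_count")
  if (!is.data.frame(snp_obs) || !all(need %in% names(snp_obs)))
    stop_invalid(paste0("[", sample_id, "] snp_obs needs columns ",
                        paste(need, collapse = ", ")))
  rd <- ref_depth %||% snp_obs$ref_depth
  if (is.null(rd))
    abort(paste0("[", sample_id, "] no reference depths supplied"),
          "lohscape_error_missing_reference")
  lr <- compute_log_ratio_profile(snp_obs$depth, rd)
  baf <- ifelse(snp_obs$depth > 0, snp_obs$alt_count / snp_obs$depth, NA_real_)
  sites <- data.frame(chrom = snp_obs$chrom, pos = snp_obs$pos,
                      lr = lr, baf = baf, depth = snp_obs$depth)
  segs <- segment_profile(sites, genome, penalty = config$penalty,
                          min_snps = config$min_snps)

  # evidence z-scores per segment
  z_fb <- with(segs, (0.5 - baf_fold) * sqrt(n_snps) / pmax(fb_sd, 1e-6))
  fb_sig <- !is.na(z_fb) & z_fb > config$imbalance_z &
    (0.5 - segs$baf_fold) > 0.02 & segs$n_snps >= config$min_snps
  z_lr <- with(segs, abs(mean_log_ratio) * sqrt(n_snps) / pmax(lr_sd, 1e-6))
  lr_sig <- !is.na(z_lr) & z_lr > config$imbalance_z &
    abs(segs$mean_log_ratio) > 0.05 & segs$n_snps >= config$min_snps

  qc_reason <- "none"
  if (any(fb_sig)) {
    # purity implied by the strongest imbalance under the most purity-
    # generous interpretation (hemizygous loss)
    b <- min(segs$baf_fold[fb_sig])
    p_implied <- (1 - 2 * b) / (1 - b)
    if (p_implied < config$purity_qc_min) qc_reason <- "low_tumor_content"
  } else if (!any(lr_sig)) {
    qc_reason <- "low_aneuploidy"
  }

  fit <- tryCatch(
    fit_purity_ploidy(segs, min_snps = config$min_snps,
                      Ci_max = config$Ci_max),
    lohscape_error_unestimable = function(e) NULL)
  if (is.null(fit)) {
    fit <- list(purity = NA_real_, psi = NA_real_)
    if (qc_reason == "none") qc_reason <- "low_tumor_content"
  } else if (qc_reason == "none" && fit$purity < config$purity_qc_min) {
    qc_reason <- "low_tumor_content"
  }

  segs <- assign_states(segs, purity = fit$purity %||% 1,
                        psi = fit$psi %||% 2, Ci_max = config$Ci_max,
                        lr_offset = fit$lr_offset %||% 0)
  if (qc_reason == "none") {
    w <- as.numeric(segs$end - segs$start)
    aneu <- !is.na(segs$Ci) & !(segs$Ci == 2L & segs$Mi == 1L)
    if (sum(w[aneu]) / sum(w) < config$aneuploid_frac_min && !any(fb_sig))
      qc_reason <- "low_aneuploidy"
  }
  segs$is_loh <- call_loh(segs$Ci, segs$Mi)
  segs$is_loh[is.na(segs$Ci)] <- FALSE
  segs <- apply_exclusions(segs, genome,
                           arm_span_threshold = config$arm_span_threshold,
                           min_snps = config$min_snps,
                           margin_threshold = config$margin_threshold)
  profile <- structure(list(sample_id = sample_id, segments = segs,
                            purity = fit$purity, psi = fit$psi,
                            qc_pass = qc_reason == "none",
                            qc_reason = qc_reason,
                            n_sites = nrow(snp_obs)),
                       class = "tumor_profile")
  result <- if (profile$qc_pass || config$qc_override)
    compute_percent_gloh(segs) else NULL
  structure(list(sample_id = sample_id, profile = profile, result = result),
            class = "gloh_run")
}

#' @export
print.tumor_profile <- function(x, ...) {
  cat(sprintf("tumor profile '%s': %d segments, purity %.2f, ploidy %.1f\n",
              x$sample_id, nrow(x$segments), x$purity, x$psi))
  cat(sprintf("  QC: %s\n", if (x$qc_pass) "pass" else x$qc_reason))
  invisible(x)
}

#' @export
print.gloh_run <- function(x, ...) {
  print(x$profile)
  if (!is.null(x$result)) print(x$result) else cat("  no score (QC fail)\n")
  invisible(x)
}
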