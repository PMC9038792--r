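#' Call loss of heterozygosity for segments
#'
#' A segment is in LOH when its total copy number is non-zero and its minor
#' allele count is zero (`Ci != 0 & Mi == 0`). Homozygous deletion
#' (`Ci = 0`) is not LOH under this rule; copy-neutral LOH (`Ci = 2,
#' Mi = 0`) is.
#'
#' @param Ci,Mi integer vectors (or a `cn_segments` data.frame as first
#'   argument).
#' @return logical vector.
#' @export
#' @examples
#' call_loh(c(2, 1, 2, 0), c(1, 0, 0, 0))  # FALSE TRUE TRUE FALSE
call_loh <- function(Ci, Mi = NULL) {
  if (is.data.frame(Ci)) { Mi <- Ci$Mi; Ci <- Ci$Ci }
  Ci != 0L & Mi == 0L
}

#' Flag segments excluded from the percent-gLOH calculation
#'
#' Two exclusion classes are applied, removing length from both numerator
#' and denominator of the score:
#' * `whole_chrom_or_arm` - adjacent LOH segments are first merged into
#'   maximal LOH runs; a run covering at least `arm_span_threshold` (default
#'   90%) of its chromosome, or of either chromosome arm it overlaps, is
#'   excluded in full. Such events usually arise through non-HRD mechanisms.
#' * `ambiguous` - segments whose LOH state is not trustworthy: fewer than
#'   `min_snps` SNPs or a state-assignment confidence margin below
#'   `margin_threshold`.
#'
#' @param segs `cn_segments` data.frame with `is_loh` called (and optionally
#'   `margin`; missing margins are treated as confident).
#' @param genome genome model supplying chromosome/arm definitions.
#' @param arm_span_threshold fraction of a chromosome or arm an LOH run must
#'   span to be excluded (default 0.90).
#' @param min_snps ambiguity threshold on SNP support (default 5).
#' @param margin_threshold ambiguity threshold on the (Ci, Mi) confidence
#'   margin, in SNP-weighted cost units (default 0.05).
#' @return `segs` with logical `excluded` and `exclusion_reason` (one of
#'   "none", "whole_chrom_or_arm", "ambiguous").
#' @export
apply_exclusions <- function(segs, genome, arm_span_threshold = 0.90,
                             min_snps = 5L, margin_threshold = 0.05) {
  if (is.null(genome)) stop_invalid("genome with arm definitions is required")
  validate_genome(genome)
  if (is.null(segs$is_loh)) stop_invalid("segments need an is_loh column")
  margin <- segs$margin %||% rep(Inf, nrow(segs))
  margin[is.na(margin)] <- 0
  excluded <- rep(FALSE, nrow(segs))
  reason <- rep("none", nrow(segs))
  arms <- arm_table(genome)
  for (ch in unique(segs$chrom)) {
    sel <- which(segs$chrom == ch)
    sel <- sel[order(segs$start[sel])]
    loh <- segs$is_loh[sel] %in% TRUE
    if (!any(loh)) next
    runs <- rle(loh)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    chrom_len <- genome$length[genome$chrom == ch]
    ca <- arms[arms$chrom == ch, ]
    for (r in which(runs$values)) {
      ridx <- sel[starts[r]:ends[r]]
      r0 <- min(segs$start[ridx]); r1 <- max(segs$end[ridx])
      span_chrom <- (r1 - r0) / chrom_len
      span_arm <- max((pmin(r1, ca$end) - pmax(r0, ca$start)) / ca$length)
      if (span_chrom >= arm_span_threshold || span_arm >= arm_span_threshold) {
        excluded[ridx] <- TRUE
        reason[ridx] <- "whole_chrom_or_arm"
      }
    }
  }
  amb <- !excluded & (segs$n_snps < min_snps | margin < margin_threshold)
  excluded[amb] <- TRUE
  reason[amb] <- "ambiguous"
  segs$excluded <- excluded
  segs$exclusion_reason <- reason
  segs
}

#' Percent genomic LOH of a scored segment set
#'
#' `100 x` total length of non-excluded LOH segments divided by the total
#' length of non-excluded segments (autosomes only; the segment set is
#' assumed to tile the autosomes).
#'
#' @param x a `tumor_profile` (must have passed QC) or a `cn_segments`
#'   data.frame with `is_loh` and `excluded` columns.
#' @return list of class `gloh_result`: `percent_gloh`,
#'   `loh_len_included`, `total_len_included`, `len_excluded_arm`,
#'   `len_excluded_ambiguous`.
#' @export
#' @examples
#' segs <- data.frame(chrom = 1, start = c(0, 40), end = c(40, 100),
#'                    n_snps = 50, is_loh = c(TRUE, FALSE),
#'                    excluded = FALSE, exclusion_reason = "none")
#' compute_percent_gloh(segs)$percent_gloh  # 40
compute_percent_gloh <- function(x) {
  if (inherits(x, "tumor_profile")) {
    if (!isTRUE(x$qc_pass))
      abort(paste0("sample failed QC: ", x$qc_reason),
            "lohscape_error_qc_failure", qc_reason = x$qc_reason)
    x <- x$segments
  }
  if (is.null(x$excluded)) stop_invalid("segments need exclusion flags")
  len <- as.numeric(x$end - x$start)
  inc <- !x$excluded
  total <- sum(len[inc])
  if (total <= 0)
    abort("no genome length remains after exclusions; score undefined",
          "lohscape_error_undefined_score")
  loh_inc <- sum(len[inc & x$is_loh %in% TRUE])
  structure(list(
    percent_gloh = 100 * loh_inc / total,
    loh_len_included = loh_inc,
    total_len_included = total,
    len_excluded_arm = sum(len[x$exclusion_reason == "whole_chrom_or_arm"]),
    len_excluded_ambiguous = sum(len[x$exclusion_reason == "ambiguous"])),
    class = "gloh_result")
}

#' @export
print.gloh_result <- function(x, ...) {
  cat(sprintf("percent gLOH: %.2f%%\n", x$percent_gloh))
  cat(sprintf("  LOH length included:   %.0f bp\n", x$loh_len_included))
  cat(sprintf("  total length included: %.0f bp\n", x$total_len_included))
  cat(sprintf("  excluded (chrom/arm):  %.0f bp\n", x$len_excluded_arm))
  cat(sprintf("  excluded (ambiguous):  %.0f bp\n", x$len_excluded_ambiguous))
  invisible(x)
}

#' Ground-truth percent gLOH of a planted genome
#'
#' Applies the same LOH call, exclusion rules and percentage formula used by
#' the scoring engine directly to a planted segment table, so generator truth
#' and engine share one formula implementation.
#'
#' @param planted planted segments (`chrom`, `start`, `end`, `Ci`, `Mi`).
#' @param genome genome model.
#' @return a `gloh_result`.
#' @export
planted_gloh <- function(planted, genome) {
  segs <- planted
  segs$n_snps <- .Machine$integer.max
  segs$margin <- Inf
  segs$is_loh <- call_loh(segs$Ci, segs$Mi)
  segs <- apply_exclusions(segs, genome)
  compute_percent_gloh(segs)
}
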