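#' Median-centered log2 copy-ratio profile
#'
#' Normalizes tumor depth at each SNP site against a process-matched normal
#' reference depth and centers so the genome-wide median log-ratio is 0
#' (removing global scaling such as library size).
#'
#' @param tumor_depth integer vector of tumor depths per site.
#' @param reference_depth reference depths per site (recycled if length 1);
#'   must be positive and present for every site.
#' @return numeric vector of log-ratios; sites with zero tumor depth are
#'   returned as `NA` (flagged and omitted from centering).
#' @export
#' @examples
#' compute_log_ratio_profile(c(100, 200, 100), 100)
compute_log_ratio_profile <- function(tumor_depth, reference_depth) {
  if (length(reference_depth) == 1L)
    reference_depth <- rep(reference_depth, length(tumor_depth))
  if (length(reference_depth) != length(tumor_depth) ||
      anyNA(reference_depth))
    abort("every tumor site needs a matching reference depth",
          "lohscape_error_missing_reference")
  if (any(reference_depth <= 0))
    abort("reference depths must be positive",
          "lohscape_error_missing_reference")
  lr <- ifelse(tumor_depth > 0, log2(tumor_depth / reference_depth), NA_real_)
  lr - stats::median(lr, na.rm = TRUE)
}
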