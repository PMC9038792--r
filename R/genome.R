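#' Default toy hg-like genome model
#'
#' A coordinate-only model of the 22 autosomes: lengths proportional to
#' GRCh38 and approximate centromere positions splitting each chromosome into
#' p and q arms. No sequence is needed: the scoring pipeline only uses
#' coordinates, and arm definitions only feed the whole-chromosome/arm
#' exclusion rule. Sex chromosomes are deliberately absent (autosomes only).
#'
#' @param scale numeric; multiply all coordinates (default 1 = bp scale).
#' @return a `data.frame` of class `loh_genome` with columns `chrom`
#'   (integer 1..22), `length` and `centromere` (bp).
#' @export
#' @examples
#' g <- default_genome()
#' sum(as.numeric(g$length)) / 1e9  # ~2.88 Gb
default_genome <- function(scale = 1) {
  len_mb <- c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35, 145.14,
              138.39, 133.80, 135.09, 133.28, 114.36, 107.04, 101.99, 90.34,
              83.26, 80.37, 58.62, 64.44, 46.71, 50.82)
  cen_mb <- c(123.4, 93.9, 90.9, 50.0, 48.8, 59.8, 60.1, 45.2, 43.0, 39.8,
              53.4, 35.5, 17.7, 17.2, 19.0, 36.8, 25.1, 18.5, 26.2, 28.1,
              12.0, 15.0)
  g <- data.frame(chrom = 1:22,
                  length = round(len_mb * 1e6 * scale),
                  centromere = round(cen_mb * 1e6 * scale))
  class(g) <- c("loh_genome", "data.frame")
  validate_genome(g)
  g
}

#' Validate a genome model
#'
#' @param genome data.frame with columns `chrom`, `length`, `centromere`.
#' @return the genome, invisibly; errors if invalid.
#' @export
validate_genome <- function(genome) {
  need <- c("chrom", "length", "centromere")
  if (!all(need %in% names(genome)))
    stop_invalid("genome must have columns chrom, length, centromere")
  if (anyDuplicated(genome$chrom)) stop_invalid("duplicate chromosomes in genome")
  if (any(genome$length <= 0)) stop_invalid("chromosome lengths must be positive")
  if (any(genome$centromere <= 0 | genome$centromere >= genome$length))
    stop_invalid("centromere must lie strictly inside each chromosome")
  invisible(genome)
}

#' Chromosome-arm table for a genome model
#'
#' @param genome a genome model (see [default_genome()]).
#' @return data.frame with one row per arm: `chrom`, `arm` ("p"/"q"),
#'   `start`, `end` (0-based half-open), `length`.
#' @export
arm_table <- function(genome) {
  validate_genome(genome)
  rbind(
    data.frame(chrom = genome$chrom, arm = "p", start = 0,
               end = genome$centromere, length = genome$centromere),
    data.frame(chrom = genome$chrom, arm = "q", start = genome$centromere,
               end = genome$length, length = genome$length - genome$centromere)
  )
}

genome_length <- function(genome) sum(as.numeric(genome$length))
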