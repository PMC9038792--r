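#' Simulate a genome-wide polymorphic SNP panel
#'
#' Draws `n_snps` germline-heterozygous SNP sites approximately uniformly
#' across a genome model (density proportional to chromosome length),
#' guaranteeing at least one site on every arm whose length is at least one
#' tenth of the genome's mean arm length. Mirrors a targeted panel of >3,500
#' polymorphic SNPs used for LOH inference.
#'
#' @param genome a genome model (see [default_genome()]).
#' @param n_snps total number of sites (>= number of chromosomes).
#' @param seed integer seed; identical seed gives an identical panel.
#' @return data.frame of class `snp_panel` with columns `chrom`, `pos`
#'   (0-based), `het_in_normal` (all `TRUE`), sorted by (chrom, pos).
#' @export
#' @examples
#' panel <- make_snp_panel(default_genome(), 3500, seed = 7)
#' nrow(panel)
make_snp_panel <- function(genome, n_snps, seed = 1L) {
  validate_genome(genome)
  if (!is_num1(n_snps) || n_snps < nrow(genome))
    stop_invalid("n_snps must be >= the number of chromosomes")
  n_snps <- as.integer(n_snps)
  arms <- arm_table(genome)
  mean_arm <- mean(arms$length)
  with_seed(seed, {
    # one guaranteed site per sizable arm, remainder length-proportional
    big <- arms[arms$length >= mean_arm / 10, ]
    n_seed <- nrow(big)
    if (n_seed > n_snps) big <- big[seq_len(n_snps), ]
    seed_pos <- floor(big$start + stats::runif(nrow(big)) * big$length)
    n_rest <- n_snps - nrow(big)
    probs <- genome$length / sum(genome$length)
    counts <- stats::rmultinom(1, n_rest, probs)[, 1]
    chrom <- c(big$chrom, rep(genome$chrom, counts))
    pos <- c(seed_pos,
             floor(stats::runif(n_rest) * rep(genome$length, counts)))
    out <- data.frame(chrom = chrom, pos = pos, het_in_normal = TRUE)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("snp_panel", "data.frame")
    out
  })
}
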