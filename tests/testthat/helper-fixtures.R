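# Small fixtures built in code.

# Compact 4-chromosome genome for fast engine tests (100 Mb / 80 Mb / 60 Mb
# / 50 Mb with interior centromeres).
toy_genome <- function() {
  g <- data.frame(chrom = 1:4,
                  length = c(100e6, 80e6, 60e6, 50e6),
                  centromere = c(45e6, 30e6, 25e6, 20e6))
  class(g) <- c("loh_genome", "data.frame")
  g
}

# Planted genome on the toy genome with known states per chromosome.
toy_planted <- function() {
  rbind(
    data.frame(chrom = 1, start = c(0, 30e6, 60e6),
               end = c(30e6, 60e6, 100e6),
               Ci = c(2L, 1L, 2L), Mi = c(1L, 0L, 1L)),
    data.frame(chrom = 2, start = c(0, 50e6), end = c(50e6, 80e6),
               Ci = c(2L, 2L), Mi = c(1L, 0L)),
    data.frame(chrom = 3, start = c(0, 20e6), end = c(20e6, 60e6),
               Ci = c(3L, 2L), Mi = c(1L, 1L)),
    data.frame(chrom = 4, start = 0, end = 50e6, Ci = 2L, Mi = 1L))
}

diploid_planted <- function(genome) {
  data.frame(chrom = genome$chrom, start = 0, end = genome$length,
             Ci = 2L, Mi = 1L)
}

# Synthetic two-level site signal for segmentation tests.
step_signal <- function(n_left, n_right, gap, noise_sd = 0.15, seed = 1) {
  withr::with_seed(seed, {
    n <- n_left + n_right
    data.frame(
      chrom = 1L,
      pos = sort(sample.int(200e6, n)),
      lr = c(rnorm(n_left, 0, noise_sd), rnorm(n_right, gap, noise_sd)),
      baf = 0.5)
  })
}
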