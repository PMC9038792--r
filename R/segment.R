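## Penalized multiple-changepoint segmentation of the joint
## (log-ratio, folded-BAF) signal, via PELT with an L2 cost.

# Robust noise scale from successive differences within chromosomes:
# sd of diff(x) is sqrt(2)*sigma for iid noise, and the median |diff|
# of a N(0, s) variate is 0.6745 s.
robust_noise <- function(x, chrom) {
  d <- unlist(lapply(split(x, chrom), diff), use.names = FALSE)
  d <- d[is.finite(d)]
  if (!length(d)) return(1)
  s <- stats::median(abs(d)) / (0.6745 * sqrt(2))
  if (!is.finite(s) || s <= 0) 1 else s
}

# PELT on a 2-column standardized signal; returns changepoint indices
# (site index after which a breakpoint falls), possibly empty.
pelt_changepoints <- function(x1, x2, penalty) {
  n <- length(x1)
  if (n < 2L) return(integer(0))
  c1 <- c(0, cumsum(x1)); c1s <- c(0, cumsum(x1^2))
  c2 <- c(0, cumsum(x2)); c2s <- c(0, cumsum(x2^2))
  segcost <- function(a, b) { # vector a of segment starts, scalar end b
    m <- b - a + 1
    (c1s[b + 1] - c1s[a]) - (c1[b + 1] - c1[a])^2 / m +
      (c2s[b + 1] - c2s[a]) - (c2[b + 1] - c2[a])^2 / m
  }
  FF <- c(-penalty, rep(Inf, n))
  prev <- integer(n)
  cand <- 0L
  for (t in seq_len(n)) {
    costs <- FF[cand + 1L] + segcost(cand + 1L, t)
    k <- which.min(costs)
    FF[t + 1L] <- costs[k] + penalty
    prev[t] <- cand[k]
    keep <- costs <= FF[t + 1L] # K = 0 pruning, valid for subadditive SSE
    cand <- c(cand[keep], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- prev[t]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  cps
}

#' Segment a per-site copy-number signal into piecewise-constant regions
#'
#' Runs penalized changepoint detection (PELT, L2 cost) per chromosome on
#' the joint signal of log-ratio and folded B-allele frequency `|BAF - 0.5|`,
#' each standardized by a robust genome-wide noise estimate. Segment
#' boundaries fall at midpoints between flanking SNPs; the first/last
#' segment of each chromosome extends to the chromosome ends. Segments with
#' fewer than `min_snps` sites are merged into the neighbour with the closest
#' mean log-ratio.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `lr`
#'   (log-ratio; `NA` allowed, dropped), `baf` (alt-read fraction at
#'   heterozygous sites; `NA` dropped) and optionally `depth` (read depth,
#'   used to debias the segment folded-BAF summary: the raw RMS deviation of
#'   `baf` from 0.5 overestimates the true allelic imbalance by the binomial
#'   sampling variance `baf(1-baf)/depth`, which is subtracted before the
#'   square root).
#' @param genome optional genome model; chromosomes then span `[0, length)`
#'   and chromosomes without usable sites become single zero-SNP segments so
#'   the segmentation always tiles the genome.
#' @param penalty positive penalty per changepoint; default `3 * log(n)`
#'   per chromosome (BIC-style: two segment means plus one breakpoint).
#' @param min_snps minimum SNPs per reported segment (default 5; pass 1 to
#'   disable merging).
#' @return data.frame of class `cn_segments`: `chrom`, `start`, `end`,
#'   `n_snps`, `mean_log_ratio`, `baf_fold` (mean minor-allele frequency in
#'   `[0, 0.5]`, i.e. `0.5 - mean|baf - 0.5|`), `lr_sd`, `fb_sd` (per-site
#'   SDs used for evidence z-scores).
#' @export
segment_profile <- function(sites, genome = NULL, penalty = NULL,
                            min_snps = 5L) {
  if (!is.null(penalty) && penalty <= 0)
    stop_invalid("penalty must be positive")
  ok <- is.finite(sites$lr) & is.finite(sites$baf)
  s <- sites[ok, , drop = FALSE]
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  fb <- abs(s$baf - 0.5)
  # per-site binomial variance of baf, for the debiased segment summary
  bvar <- if (!is.null(s$depth)) s$baf * (1 - s$baf) / pmax(s$depth, 1)
          else rep(0, nrow(s))
  n1 <- robust_noise(s$lr, s$chrom)
  n2 <- robust_noise(fb, s$chrom)
  chroms <- if (!is.null(genome)) genome$chrom else sort(unique(s$chrom))
  out <- list()
  for (ch in chroms) {
    sel <- which(s$chrom == ch)
    chrom_len <- if (!is.null(genome)) genome$length[genome$chrom == ch]
                 else if (length(sel)) max(s$pos[sel]) + 1 else 1
    if (length(sel) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = 0, end = chrom_len, n_snps = 0L,
        mean_log_ratio = NA_real_, baf_fold = NA_real_,
        lr_sd = NA_real_, fb_sd = NA_real_)
      next
    }
    x1 <- s$lr[sel] / n1
    x2 <- fb[sel] / n2
    pen <- penalty %||% (3 * log(length(sel)))
    cps <- if (length(sel) >= 2L) pelt_changepoints(x1, x2, pen) else integer(0)
    bounds <- split_indices(cps, length(sel))
    bounds <- merge_short(bounds, s$lr[sel], min_snps)
    pos <- s$pos[sel]
    for (b in bounds) {
      i0 <- b[1]; i1 <- b[2]
      seg_start <- if (i0 == 1L) 0 else floor((pos[i0 - 1L] + pos[i0]) / 2)
      seg_end <- if (i1 == length(sel)) chrom_len
                 else floor((pos[i1] + pos[i1 + 1L]) / 2)
      li <- s$lr[sel][i0:i1]
      fi <- fb[sel][i0:i1]
      vi <- bvar[sel][i0:i1]
      delta <- sqrt(max(mean(fi^2) - mean(vi), 0))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = seg_start, end = seg_end, n_snps = i1 - i0 + 1L,
        mean_log_ratio = mean(li), baf_fold = 0.5 - delta,
        lr_sd = stats::sd(li), fb_sd = stats::sd(fi))
    }
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  class(segs) <- c("cn_segments", "data.frame")
  segs
}

# changepoint indices -> list of c(first, last) index pairs
split_indices <- function(cps, n) {
  starts <- c(1L, cps + 1L)
  ends <- c(cps, n)
  Map(c, starts, ends)
}

# merge segments shorter than min_snps into the neighbour whose mean
# log-ratio is closest
merge_short <- function(bounds, lr, min_snps) {
  if (min_snps <= 1L || length(bounds) <= 1L) return(bounds)
  repeat {
    sizes <- vapply(bounds, function(b) b[2] - b[1] + 1L, integer(1))
    small <- which(sizes < min_snps)
    if (!length(small) || length(bounds) == 1L) return(bounds)
    i <- small[which.min(sizes[small])]
    m_i <- mean(lr[bounds[[i]][1]:bounds[[i]][2]])
    nb <- c(if (i > 1L) i - 1L, if (i < length(bounds)) i + 1L)
    dm <- vapply(nb, function(j)
      abs(mean(lr[bounds[[j]][1]:bounds[[j]][2]]) - m_i), numeric(1))
    j <- nb[which.min(dm)]
    a <- min(i, j); b <- max(i, j)
    bounds[[a]] <- c(bounds[[a]][1], bounds[[b]][2])
    bounds[[b]] <- NULL
  }
}
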