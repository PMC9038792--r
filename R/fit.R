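## Purity/ploidy grid fit and per-segment allele-specific integer
## copy-number (Ci, Mi) estimation.

#' Model-expected log-ratio and folded BAF for copy-number states
#'
#' Forward model of what the assay observes for a segment with total copies
#' `Ci` and minor copies `Mi` in a tumor of purity `p` and mean ploidy `psi`:
#' log-ratio `log2((p*Ci + 2(1-p)) / (p*psi + 2(1-p)))` and minor-allele
#' (folded) BAF `(p*Mi + (1-p)) / (p*Ci + 2(1-p))`. The copy ratio is floored
#' at `ratio_floor` so a homozygous deletion at purity 1 stays finite; at
#' `Ci = 0` only normal cells contribute reads, so the expected folded BAF
#' is 0.5.
#'
#' @param Ci,Mi integer vectors of states.
#' @param purity tumor purity in (0, 1].
#' @param psi mean tumor ploidy.
#' @param ratio_floor floor on the expected copy ratio (default 0.01).
#' @return list with numeric vectors `lr` and `fb`.
#' @export
expected_cn_signal <- function(Ci, Mi, purity, psi, ratio_floor = 0.01) {
  p <- purity; q <- 1 - p
  denom <- p * Ci + 2 * q
  lr <- log2(pmax(denom / (p * psi + 2 * q), ratio_floor))
  fb <- ifelse(denom > 0, (p * Mi + q) / denom, 0.5)
  list(lr = lr, fb = fb)
}

# all (Ci, Mi) integer states with 0 <= Mi <= floor(Ci/2), Ci <= Ci_max
cn_state_grid <- function(Ci_max = 8L) {
  Ci <- rep(0:Ci_max, floor(0:Ci_max / 2) + 1L)
  Mi <- unlist(lapply(0:Ci_max, function(c) 0:(c %/% 2)))
  data.frame(Ci = Ci, Mi = Mi)
}

#' Estimate the allele-specific copy-number state of one segment
#'
#' Minimizes the SNP-count-weighted squared residual
#' `n_snps * ((lr - lr_exp)^2 + (fb - fb_exp)^2)` over the integer state grid
#' `0 <= Mi <= floor(Ci/2)`, `0 <= Ci <= Ci_max`. Ties are broken toward the
#' smaller `Ci`, then the larger `Mi` (conservative against over-calling
#' LOH). The returned `margin` (cost of the second-best state minus the
#' best) is the confidence used by the ambiguity exclusion.
#'
#' @param mean_log_ratio observed segment mean log-ratio.
#' @param baf_fold observed segment folded BAF on the minor-allele scale
#'   (0.5 = balanced heterozygous, 0 = fixed allele).
#' @param purity,psi fitted purity and ploidy.
#' @param n_snps SNP count weighting the cost (default 1).
#' @param Ci_max largest total copy number in the grid (default 8; higher
#'   amplifications are clipped, which cannot change LOH status).
#' @return list with `Ci`, `Mi`, `cost`, `margin`.
#' @export
#' @examples
#' estimate_allele_specific_cn(0, 0.5, purity = 1, psi = 2)      # (2, 1)
#' estimate_allele_specific_cn(-0.515, 0.2857, 0.6, 2)           # (1, 0)
estimate_allele_specific_cn <- function(mean_log_ratio, baf_fold, purity,
                                        psi, n_snps = 1L, Ci_max = 8L) {
  g <- cn_state_grid(Ci_max)
  e <- expected_cn_signal(g$Ci, g$Mi, purity, psi)
  cost <- n_snps * ((mean_log_ratio - e$lr)^2 + (baf_fold - e$fb)^2)
  ord <- order(cost, g$Ci, -g$Mi)
  best <- ord[1]
  list(Ci = g$Ci[best], Mi = g$Mi[best], cost = cost[best],
       margin = cost[ord[2]] - cost[best])
}

# vectorised over segments; returns segs with Ci, Mi, margin columns
assign_states <- function(segs, purity, psi, Ci_max = 8L, lr_offset = 0) {
  g <- cn_state_grid(Ci_max)
  e <- expected_cn_signal(g$Ci, g$Mi, purity, psi)
  lr <- segs$mean_log_ratio - lr_offset
  fb <- segs$baf_fold
  n <- segs$n_snps
  Ci <- Mi <- integer(nrow(segs))
  margin <- cost <- numeric(nrow(segs))
  D <- outer(lr, e$lr, "-")^2 + outer(fb, e$fb, "-")^2
  for (i in seq_len(nrow(segs))) {
    ci <- n[i] * D[i, ]
    if (!all(is.finite(ci))) { # zero-SNP or NA segment: unassignable
      Ci[i] <- NA_integer_; Mi[i] <- NA_integer_
      margin[i] <- 0; cost[i] <- NA_real_
      next
    }
    ord <- order(ci, g$Ci, -g$Mi)
    Ci[i] <- g$Ci[ord[1]]; Mi[i] <- g$Mi[ord[1]]
    cost[i] <- ci[ord[1]]; margin[i] <- ci[ord[2]] - ci[ord[1]]
  }
  segs$Ci <- Ci; segs$Mi <- Mi; segs$cost <- cost; segs$margin <- margin
  segs
}

#' Fit tumor purity and mean ploidy by grid search
#'
#' For each candidate on the grid purity in {0.10, 0.12, ..., 1.00} by
#' psi in {1.0, 1.1, ..., 6.0}, every segment is assigned its best integer
#' (Ci, Mi) state and candidates are ranked by the segment-length-weighted
#' mean squared error between observed and model-expected (log-ratio,
#' folded BAF). Two refinements make the fit identifiable in practice:
#' a per-candidate log-ratio offset (median centering of the observed
#' profile need not coincide with the candidate's expected scale), and two
#' regularization terms that break the classic scaled-solution degeneracy
#' (doubling every state while adjusting purity reproduces the same signal
#' shape): a self-consistency term pulling the candidate psi toward the
#' length-weighted mean of its own assigned states, and a small
#' diploid-parsimony term preferring the lowest-ploidy member of a
#' near-degenerate family. Residual exact ties break toward higher purity,
#' then lower psi.
#'
#' @param segs `cn_segments` data.frame (needs `mean_log_ratio`, `baf_fold`,
#'   `n_snps`, `start`, `end`).
#' @param min_snps segments with fewer SNPs are ignored during the fit.
#' @param purity_grid,psi_grid candidate grids.
#' @param Ci_max state-grid bound.
#' @param psi_consistency weight of `(implied psi - candidate psi)^2`
#'   (per-bp cost units; default 0.05).
#' @param diploid_prior weight of `(psi - 2)^2` (default 3e-4); orders of
#'   magnitude below genuine misfit, only active among degenerate ties.
#' @return list with `purity`, `psi`, `lr_offset`, `cost` (per-bp).
#' @export
fit_purity_ploidy <- function(segs, min_snps = 5L,
                              purity_grid = seq(0.10, 1.00, by = 0.02),
                              psi_grid = seq(1.0, 6.0, by = 0.1),
                              Ci_max = 8L, psi_consistency = 0.05,
                              diploid_prior = 3e-4) {
  use <- segs$n_snps >= min_snps & is.finite(segs$mean_log_ratio) &
    is.finite(segs$baf_fold)
  if (!any(use))
    abort("no segment has enough SNPs to fit purity/ploidy",
          "lohscape_error_unestimable")
  lr <- segs$mean_log_ratio[use]
  fb <- segs$baf_fold[use]
  w <- (segs$end - segs$start)[use]
  wsum <- sum(w)
  g <- cn_state_grid(Ci_max)
  cand <- expand.grid(purity = purity_grid, psi = psi_grid)
  costs <- offsets <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    e <- expected_cn_signal(g$Ci, g$Mi, cand$purity[k], cand$psi[k])
    Dlr <- outer(lr, e$lr, "-")
    Dfb <- outer(fb, e$fb, "-")^2
    D <- Dlr^2 + Dfb
    pick <- max.col(-D, ties.method = "first")
    # re-center: the observed profile is median-centered, not psi-scaled
    delta <- sum(w * Dlr[cbind(seq_along(pick), pick)]) / wsum
    D2 <- (Dlr - delta)^2 + Dfb
    pick <- max.col(-D2, ties.method = "first")
    fit_cost <- sum(w * D2[cbind(seq_along(pick), pick)]) / wsum
    psi_hat <- sum(w * g$Ci[pick]) / wsum
    costs[k] <- fit_cost + psi_consistency * (psi_hat - cand$psi[k])^2 +
      diploid_prior * (cand$psi[k] - 2)^2
    offsets[k] <- delta
  }
  best <- min(costs)
  tied <- which(costs <= best + 1e-9 * max(1, abs(best)))
  tied <- tied[order(-cand$purity[tied], cand$psi[tied])]
  k <- tied[1]
  list(purity = cand$purity[k], psi = cand$psi[k], lr_offset = offsets[k],
       cost = costs[k])
}
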