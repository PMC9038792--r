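# Independent oracles, deliberately coded differently from the package
# internals they check.

# Exhaustive O(n^2) optimal-partitioning changepoint oracle on the same
# standardized 2-d L2 cost and penalty as segment_profile/pelt.
dp_changepoints <- function(x1, x2, penalty) {
  n <- length(x1)
  sse <- function(v) sum((v - mean(v))^2)
  cost <- function(a, b) sse(x1[a:b]) + sse(x2[a:b])
  FF <- c(-penalty, rep(NA_real_, n))
  prev <- integer(n)
  for (t in seq_len(n)) {
    best <- Inf
    arg <- 0L
    for (s in 0:(t - 1L)) { # plain double loop, no pruning
      v <- FF[s + 1L] + cost(s + 1L, t) + penalty
      if (v < best) { best <- v; arg <- s }
    }
    FF[t + 1L] <- best
    prev[t] <- arg
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    if (prev[t] > 0L) cps <- c(prev[t], cps)
    t <- prev[t]
  }
  cps
}

# Brute-force (Ci, Mi) oracle: explicit double loop over the grid, same
# documented tie-break (smaller Ci, then larger Mi).
bf_state <- function(lr, fb, purity, psi, n_snps = 1, Ci_max = 8,
                     ratio_floor = 0.01) {
  best <- NULL
  p <- purity; q <- 1 - p
  for (Ci in 0:Ci_max) for (Mi in 0:(Ci %/% 2)) {
    den <- p * Ci + 2 * q
    elr <- log2(max(den / (p * psi + 2 * q), ratio_floor))
    efb <- if (den > 0) (p * Mi + q) / den else 0.5
    cost <- n_snps * ((lr - elr)^2 + (fb - efb)^2)
    better <- is.null(best) || cost < best$cost ||
      (cost == best$cost && (Ci < best$Ci ||
                               (Ci == best$Ci && Mi > best$Mi)))
    if (better) best <- list(Ci = Ci, Mi = Mi, cost = cost)
  }
  best
}

# Closed-form simple-OLS-free oracle: normal equations via solve().
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# Brute-force Cox partial likelihood for a single binary covariate,
# no ties: product over event times of exp(b x_i) / sum_{risk set} exp(b x_j).
bf_cox_loglik <- function(time, event, x, b) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

# Direct hypergeometric enumeration of the two-sided Fisher p-value for a
# 2x2 table (sum of probabilities <= observed probability).
hyper_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand product-limit estimator (no package calls).
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time[event])
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ut) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}
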