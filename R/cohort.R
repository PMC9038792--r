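## Cohort-level description of the gLOH distribution: ranked-curve
## inflection cutoff, gLOH-high classification, log-normal summary.

# centered moving average with partial windows at the edges
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  h <- w %/% 2L
  cs <- c(0, cumsum(x))
  n <- length(x)
  i0 <- pmax(seq_len(n) - h, 1L)
  i1 <- pmin(seq_len(n) + h, n)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

#' Inflection point of the ranked gLOH curve
#'
#' Sorts the scores ascending, smooths the rank-to-value curve with a
#' moving-average kernel, and takes first and second finite-difference
#' derivatives of the smoothed curve. The cutoff is the value at the
#' second-derivative zero-crossing nearest the first derivative's maximum.
#' When the first-derivative maximum sits at the end of the curve (the
#' ranked curve is convex to the end, as for a log-normal sample), the
#' crossing closest to the end is returned and `boundary` is `TRUE`. Raw
#' finite differences of sorted data form a step function whose second
#' derivative is almost never exactly zero, so smoothing is what makes the
#' rule computable; the bandwidth is reported in the result.
#'
#' @param gloh_values numeric vector (>= 50 values).
#' @param bandwidth smoothing window in ranks; default `max(5, n / 100)`.
#' @return list of class `inflection_result`: `cutoff_percent`,
#'   `rank_index`, `smoothing_bandwidth`, `boundary`.
#' @export
#' @examples
#' x <- 30 / (1 + exp(-10 * (seq(0.001, 0.999, length.out = 5000) - 0.5)))
#' find_inflection_point(x)$cutoff_percent  # ~15 (analytic inflection)
find_inflection_point <- function(gloh_values, bandwidth = NULL) {
  x <- gloh_values[is.finite(gloh_values)]
  n <- length(x)
  if (n < 50L)
    abort("need at least 50 values for a stable inflection",
          "lohscape_error_insufficient_data")
  rng <- diff(range(x))
  if (rng <= 0)
    abort("all values identical: no inflection", "lohscape_error_no_inflection")
  bw <- as.integer(bandwidth %||% max(5, round(n / 100)))
  if (bw %% 2L == 0L) bw <- bw + 1L
  ys <- moving_average(sort(x), bw)
  d1 <- moving_average(c(diff(ys)[1], diff(ys)), bw)
  # constant first derivative (linear ramp): no inflection exists; judge on
  # the interior, where the smoothing windows are complete
  inner <- seq(min(bw + 1L, n), max(n - bw, 1L))
  if (diff(range(d1[inner])) <= 1e-8 * max(abs(d1[inner]), 1e-12))
    abort("first derivative is constant: no inflection",
          "lohscape_error_no_inflection")
  d2 <- c(diff(d1)[1], diff(d1))
  interior <- seq(bw + 1L, n - 1L)
  cross <- interior[d2[interior] * d2[interior + 1L] < 0 |
                      d2[interior] == 0]
  imax <- which.max(d1)
  boundary <- imax >= n - bw
  if (!length(cross))
    abort("no zero-crossing of the second derivative",
          "lohscape_error_no_inflection")
  k <- cross[which.min(abs(cross - imax))]
  structure(list(cutoff_percent = ys[k], rank_index = k,
                 smoothing_bandwidth = bw, boundary = boundary),
            class = "inflection_result")
}

#' Classify samples as gLOH-high at a cutoff
#'
#' Values greater than or equal to the cutoff count as high (ties at the
#' cutoff are high).
#'
#' @param gloh_values numeric vector (non-empty).
#' @param cutoff finite cutoff on the percent scale (`Inf` allowed and gives
#'   0 high).
#' @return list of class `gloh_classification`: `cutoff`, `n_high`,
#'   `n_total`, `fraction_high`.
#' @export
#' @examples
#' classify_gloh_high(c(5, 14, 20), 14)$fraction_high  # 2/3
classify_gloh_high <- function(gloh_values, cutoff) {
  if (length(gloh_values) == 0L) stop_invalid("empty gLOH vector")
  if (is.na(cutoff)) stop_invalid("cutoff must not be NA")
  n_high <- sum(gloh_values >= cutoff)
  structure(list(cutoff = cutoff, n_high = n_high,
                 n_total = length(gloh_values),
                 fraction_high = n_high / length(gloh_values)),
            class = "gloh_classification")
}

#' Summary statistics and log-normal fit of a gLOH distribution
#'
#' Arithmetic mean and SD, maximum-likelihood log-normal parameters (zeros
#' shifted by `zero_offset` before the log), and a Kolmogorov-Smirnov
#' statistic of the log values against the fitted normal as a
#' goodness-of-fit indicator (parameters are estimated, so the p-value is
#' approximate and conservative only for gross departures).
#'
#' @param gloh_values numeric vector (>= 3 values).
#' @param zero_offset added to non-positive values before the log fit
#'   (default 0.1).
#' @return list: `mean`, `sd`, `mu`, `sigma`, `gof_stat`, `gof_p`, `n`.
#' @export
summarize_distribution <- function(gloh_values, zero_offset = 0.1) {
  x <- gloh_values[is.finite(gloh_values)]
  if (length(x) < 3L)
    abort("need at least 3 values", "lohscape_error_insufficient_data")
  lx <- log(ifelse(x <= 0, zero_offset, x))
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2)) # ML (1/n) estimate
  ks <- suppressWarnings(stats::ks.test(lx, "pnorm", mu, max(sigma, 1e-12)))
  list(mean = mean(x), sd = stats::sd(x), mu = mu, sigma = sigma,
       gof_stat = unname(ks$statistic), gof_p = ks$p.value, n = length(x))
}
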