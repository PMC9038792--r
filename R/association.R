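## Cohort association analyses: HR-pathway group contrasts, the
## pathway-agnostic univariate screen with Bonferroni q-values and a
## prevalence filter, the multivariate model with uterine status,
## uLMS vs non-uLMS differential prevalence, and mutual exclusivity.

#' Default homologous-recombination pathway gene list
#'
#' Genes repeatedly linked to HR deficiency and PARP-inhibitor response:
#' BRCA1/2, ATM, ATR, BRIP1, CHEK2, NBN, PALB2 and the RAD51 and FANC
#' families. User-overridable wherever a gene list is accepted.
#'
#' @return character vector of gene symbols.
#' @export
default_hr_genes <- function() {
  c("BRCA1", "BRCA2", "ATM", "ATR", "BRIP1", "CHEK2", "NBN", "PALB2",
    "RAD51", "RAD51B", "RAD51C", "RAD51D", "FANCA", "FANCC", "FANCD2",
    "FANCE", "FANCF", "FANCG", "FANCL")
}

as_alteration_matrix <- function(x) {
  if (inherits(x, "lms_cohort")) return(x$alterations)
  if (is.matrix(x)) return(x)
  stop_invalid("expected an lms_cohort or a sample-by-key indicator matrix")
}

key_gene <- function(keys) sub(":.*$", "", keys)
key_class <- function(keys) sub("^.*:", "", keys)

#' Assign samples to HR-pathway alteration groups
#'
#' Precedence: BRCA2 homozygous deletion > homozygous deletion of any other
#' HR gene > mutation (rearrangement/truncation/missense) in any HR gene >
#' HR intact. A sample carrying both a BRCA2 deletion and another HR
#' mutation is `BRCA2_homdel`. HR-gene amplifications do not count as
#' pathway mutations.
#'
#' @param cohort an `lms_cohort` or indicator matrix with "GENE:class"
#'   columns.
#' @param hr_genes character vector of HR-pathway genes; genes matching no
#'   alteration column raise a collapsed warning, not an error.
#' @return factor with levels `HR_intact`, `HR_mutation`,
#'   `non_BRCA2_homdel`, `BRCA2_homdel`.
#' @export
assign_hr_groups <- function(cohort, hr_genes = default_hr_genes()) {
  M <- as_alteration_matrix(cohort)
  keys <- colnames(M)
  genes <- key_gene(keys)
  classes <- key_class(keys)
  if (length(hr_genes)) {
    unknown <- setdiff(hr_genes, genes)
    if (length(unknown))
      warning("HR genes with no alteration data: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  mut_classes <- c("rearrangement", "truncation", "missense")
  has <- function(cols) if (any(cols)) rowSums(M[, cols, drop = FALSE]) > 0
                        else rep(FALSE, nrow(M))
  b2 <- has(genes == "BRCA2" & classes == "homozygous_deletion" &
              "BRCA2" %in% hr_genes)
  hd <- has(genes %in% hr_genes & genes != "BRCA2" &
              classes == "homozygous_deletion")
  mu <- has(genes %in% hr_genes & classes %in% mut_classes)
  grp <- rep("HR_intact", nrow(M))
  grp[mu] <- "HR_mutation"
  grp[hd] <- "non_BRCA2_homdel"
  grp[b2] <- "BRCA2_homdel"
  factor(grp, levels = c("HR_intact", "HR_mutation", "non_BRCA2_homdel",
                         "BRCA2_homdel"))
}

#' Compare gLOH across groups (ANOVA plus adjusted pairwise Welch tests)
#'
#' One-way ANOVA over all groups, then pairwise Welch t tests either against
#' a control group with a Dunnett-style adjustment, or between all pairs
#' with a Tukey-style adjustment. Both adjustments are computed by seeded
#' Monte-Carlo evaluation of the correlated max-|t| null of the Welch
#' statistics (deterministic given `seed`); with a single comparison the
#' adjustment is the identity and the unadjusted Welch p is returned.
#'
#' @param gloh numeric response.
#' @param groups factor of group labels.
#' @param control control-group label for Dunnett-style comparisons
#'   (default "HR_intact", or the first level if absent).
#' @param all_pairs if `TRUE`, Tukey-style all-pairs comparisons instead.
#' @param mc_draws Monte-Carlo draws for the adjustment (default 50000).
#' @param seed seed of the adjustment draws.
#' @return list of class `group_contrast`: `groups` (n/mean/sd per group),
#'   `anova_f`, `anova_p`, `comparisons` (estimate, t, df, p, p_adj),
#'   `method`.
#' @export
group_contrast <- function(gloh, groups, control = "HR_intact",
                           all_pairs = FALSE, mc_draws = 50000L,
                           seed = 20220425L) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2L) stop_invalid("need at least 2 groups")
  st <- data.frame(group = lev,
                   n = as.integer(table(groups)[lev]),
                   mean = tapply(gloh, groups, mean)[lev],
                   sd = tapply(gloh, groups, stats::sd)[lev])
  ok <- st$n >= 2L
  if (!all(ok))
    warning("groups with < 2 samples skipped: ",
            paste(st$group[!ok], collapse = ", "), call. = FALSE)
  if (sum(ok) < 2L) stop_invalid("need >= 2 groups with >= 2 samples")
  # classic one-way ANOVA
  gm <- mean(gloh)
  ssb <- sum(st$n * (st$mean - gm)^2)
  ssw <- sum(tapply(gloh, groups, function(x) sum((x - mean(x))^2)))
  df1 <- length(lev) - 1L
  df2 <- length(gloh) - length(lev)
  if (ssw <= 0) {
    f <- if (ssb <= 0) 0 else Inf
    p_anova <- if (ssb <= 0) 1 else 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p_anova <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  use <- st[ok, ]
  v <- use$sd^2 / use$n
  if (all_pairs) {
    idx <- utils::combn(nrow(use), 2)
    labs <- paste(use$group[idx[1, ]], "vs", use$group[idx[2, ]])
    est <- use$mean[idx[1, ]] - use$mean[idx[2, ]]
    vv <- v[idx[1, ]] + v[idx[2, ]]
    dfw <- vv^2 / (v[idx[1, ]]^2 / (use$n[idx[1, ]] - 1) +
                     v[idx[2, ]]^2 / (use$n[idx[2, ]] - 1))
    contr <- matrix(0, nrow(use), ncol(idx))
    for (j in seq_len(ncol(idx))) {
      contr[idx[1, j], j] <- 1; contr[idx[2, j], j] <- -1
    }
  } else {
    if (!control %in% use$group) control <- use$group[1]
    ci <- which(use$group == control)
    others <- setdiff(seq_len(nrow(use)), ci)
    labs <- paste(use$group[others], "vs", control)
    est <- use$mean[others] - use$mean[ci]
    vv <- v[others] + v[ci]
    dfw <- vv^2 / (v[others]^2 / (use$n[others] - 1) +
                     v[ci]^2 / (use$n[ci] - 1))
    contr <- matrix(0, nrow(use), length(others))
    for (j in seq_along(others)) {
      contr[others[j], j] <- 1; contr[ci, j] <- -1
    }
  }
  tstat <- ifelse(vv > 0, est / sqrt(vv),
                  ifelse(est == 0, 0, Inf * sign(est)))
  p_raw <- ifelse(is.finite(dfw) & dfw > 0,
                  2 * stats::pt(-abs(tstat), dfw),
                  ifelse(tstat == 0, 1, 0))
  k <- length(tstat)
  if (k == 1L || all(vv == 0)) {
    p_adj <- p_raw # identity adjustment (degenerate or single comparison)
  } else {
    p_adj <- with_seed(seed, {
      Z <- matrix(stats::rnorm(mc_draws * nrow(use)), mc_draws)
      Tn <- (Z %*% (contr * sqrt(v))) / rep(sqrt(pmax(vv, 1e-300)),
                                            each = mc_draws)
      mx <- do.call(pmax, as.data.frame(abs(Tn)))
      vapply(abs(tstat), function(t0) (1 + sum(mx >= t0)) / (mc_draws + 1),
             numeric(1))
    })
  }
  structure(list(groups = st, anova_f = f, anova_p = p_anova,
                 comparisons = data.frame(comparison = labs, estimate = est,
                                          t = tstat, df = dfw, p = p_raw,
                                          p_adj = pmin(p_adj, 1)),
                 method = if (all_pairs) "tukey_mc" else "dunnett_mc"),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.3g, p = %.3g\n", x$anova_f, x$anova_p))
  print(x$groups, row.names = FALSE)
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Univariate gene-alteration screen on gLOH
#'
#' Ordinary least squares of gLOH on each binary alteration indicator
#' separately (closed-form simple regression), Bonferroni q-values with
#' `m =` the number of keys actually tested (prevalence strictly between 0
#' and 1), and the candidate filter `q < q_threshold` and observed
#' `prevalence >= prevalence_threshold`.
#'
#' @param gloh numeric response (or an `lms_cohort`, in which case
#'   `alterations` is taken from it).
#' @param alterations sample-by-key indicator matrix.
#' @param q_threshold,prevalence_threshold candidate filter (defaults 0.1
#'   and 0.005).
#' @return data.frame of class `screen_result` (one row per tested key):
#'   `key`, `prevalence`, `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `q_value`, `candidate`; attribute `m` records the Bonferroni factor.
#' @export
univariate_screen <- function(gloh, alterations = NULL, q_threshold = 0.1,
                              prevalence_threshold = 0.005) {
  if (inherits(gloh, "lms_cohort")) {
    alterations <- alterations %||% gloh$alterations
    gloh <- gloh$samples$gloh
  }
  M <- as_alteration_matrix(alterations)
  n <- length(gloh)
  if (nrow(M) != n) stop_invalid("gloh and alteration matrix sizes differ")
  prev <- colMeans(M != 0)
  test <- prev > 0 & prev < 1
  if (!any(test)) stop_invalid("no testable keys (all prevalence 0 or 1)")
  M <- M[, test, drop = FALSE]
  prev <- prev[test]
  m <- ncol(M)
  ybar <- mean(gloh)
  syy <- sum((gloh - ybar)^2)
  if (syy <= 0)
    abort("gLOH is constant: regression undefined",
          "lohscape_error_undefined_fit")
  sx <- colSums(M)
  sxx <- colSums(M^2) - sx^2 / n
  sxy <- as.numeric(crossprod(M, gloh)) - sx * ybar
  b <- sxy / sxx
  sse <- pmax(syy - sxy^2 / sxx, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  tt <- b / se
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[se == 0] <- 0 # exact fit
  hw <- stats::qt(0.975, n - 2) * se
  q <- pmin(1, p * m)
  out <- data.frame(key = colnames(M), prevalence = prev, estimate = b,
                    ci_low = b - hw, ci_high = b + hw, p_value = p,
                    q_value = q,
                    candidate = q < q_threshold & prev >= prevalence_threshold,
                    row.names = NULL)
  attr(out, "m") <- m
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Multivariate linear model of gLOH on candidate alterations
#'
#' Joint ordinary least squares of gLOH on the selected alteration
#' indicators plus (by default) the uterine-disease indicator. Duplicated
#' and collinear columns are dropped with a warning before fitting (the
#' near-identical CDKN2A/CDKN2B deletion pair is the canonical case).
#'
#' @param gloh numeric response (or an `lms_cohort`).
#' @param alterations indicator matrix.
#' @param keys columns to include (default: all columns of `alterations`).
#' @param uterine logical vector; taken from the cohort if omitted.
#' @param include_uterine include the uterine indicator (default `TRUE`).
#' @return data.frame of class `multivariate_result`: `term`, `estimate`,
#'   `ci_low`, `ci_high`, `p_value`; attribute `dropped` lists removed
#'   columns.
#' @export
multivariate_fit <- function(gloh, alterations = NULL, keys = NULL,
                             uterine = NULL, include_uterine = TRUE) {
  if (inherits(gloh, "lms_cohort")) {
    alterations <- alterations %||% gloh$alterations
    uterine <- uterine %||% gloh$samples$uterine
    gloh <- gloh$samples$gloh
  }
  M <- as_alteration_matrix(alterations)
  keys <- keys %||% colnames(M)
  miss <- setdiff(keys, colnames(M))
  if (length(miss)) stop_invalid(paste0("unknown keys: ",
                                        paste(miss, collapse = ", ")))
  X <- M[, keys, drop = FALSE]
  if (include_uterine) {
    if (is.null(uterine)) stop_invalid("uterine indicator required")
    X <- cbind(X, uterine = as.integer(uterine))
  }
  dropped <- character(0)
  dup <- duplicated(t(X))
  if (any(dup)) {
    dropped <- colnames(X)[dup]
    warning("dropping duplicated design columns: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, !dup, drop = FALSE]
  }
  fit <- stats::lm(gloh ~ X)
  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    bad <- sub("^X", "", aliased)
    warning("dropping collinear design columns: ",
            paste(bad, collapse = ", "), call. = FALSE)
    dropped <- c(dropped, bad)
    X <- X[, setdiff(colnames(X), bad), drop = FALSE]
    fit <- stats::lm(gloh ~ X)
    if (anyNA(stats::coef(fit)))
      abort("design remains rank deficient after drops",
            "lohscape_error_singular_design")
  }
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(stats::confint(fit))
  terms <- sub("^X", "", rownames(sm))
  out <- data.frame(term = terms, estimate = sm[, 1],
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    p_value = sm[, 4], row.names = NULL)
  attr(out, "dropped") <- dropped
  class(out) <- c("multivariate_result", "data.frame")
  out
}

#' Differential alteration prevalence between uterine and non-uterine LMS
#'
#' Per key, a 2x2 chi-squared test (without continuity correction) of
#' alteration status against uterine status; an exact test replaces it with
#' a warning when any expected cell count is below 1. A key is significant
#' when the absolute prevalence difference exceeds `delta_threshold` (10
#' percentage points) and p is below `p_threshold` (5e-5, a Bonferroni-style
#' bound).
#'
#' @param cohort an `lms_cohort`, or an indicator matrix with `uterine`
#'   supplied.
#' @param uterine logical stratum indicator.
#' @param delta_threshold,p_threshold significance conjunction thresholds.
#' @return data.frame: `key`, `prev_uterine`, `prev_nonuterine`, `delta`,
#'   `p_value`, `test`, `significant`.
#' @export
differential_prevalence <- function(cohort, uterine = NULL,
                                    delta_threshold = 0.10,
                                    p_threshold = 5e-5) {
  if (inherits(cohort, "lms_cohort")) {
    uterine <- uterine %||% cohort$samples$uterine
  }
  M <- as_alteration_matrix(cohort)
  if (is.null(uterine) || length(uterine) != nrow(M))
    stop_invalid("uterine indicator of matching length required")
  uterine <- as.logical(uterine)
  if (!any(uterine) || all(uterine))
    stop_invalid("both uterine strata must be non-empty")
  res <- lapply(colnames(M), function(k) {
    x <- M[, k] != 0
    tab <- table(factor(x, c(FALSE, TRUE)), factor(uterine, c(FALSE, TRUE)))
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 1)) {
      warning("expected count < 1 for ", k, "; using exact test",
              call. = FALSE)
      p <- stats::fisher.test(tab)$p.value
      test <- "exact"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
      test <- "chisq"
    }
    pu <- mean(x[uterine]); pn <- mean(x[!uterine])
    data.frame(key = k, prev_uterine = pu, prev_nonuterine = pn,
               delta = pu - pn, p_value = p, test = test,
               significant = abs(pu - pn) > delta_threshold & p < p_threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mutual exclusivity / co-occurrence of alteration pairs
#'
#' Two-sided exact (Fisher) test on the 2x2 co-occurrence table of each key
#' pair. Direction is `exclusive` when the odds ratio is below 1 and
#' `co_occurring` above 1; infinite odds ratios (one key a subset of the
#' other) are reported as the capped sentinel `or_cap`.
#'
#' @param cohort an `lms_cohort` or indicator matrix.
#' @param pairs list of 2-element character vectors of keys; default all
#'   pairs of keys with non-zero prevalence.
#' @param or_cap cap for infinite odds ratios (default 1e6).
#' @return data.frame: `key_a`, `key_b`, `odds_ratio`, `p_value`,
#'   `direction`.
#' @export
mutual_exclusivity <- function(cohort, pairs = NULL, or_cap = 1e6) {
  M <- as_alteration_matrix(cohort)
  present <- colnames(M)[colSums(M != 0) > 0]
  auto <- is.null(pairs)
  if (is.null(pairs)) {
    if (length(present) < 2L) stop_invalid("need >= 2 keys with carriers")
    cb <- utils::combn(present, 2)
    pairs <- lapply(seq_len(ncol(cb)), function(j) cb[, j])
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% present)) {
      warning("pair skipped, key absent from cohort: ",
              paste(setdiff(pr, present), collapse = ", "), call. = FALSE)
      return(NULL)
    }
    a <- M[, pr[1]] != 0
    b <- M[, pr[2]] != 0
    tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
    ft <- stats::fisher.test(tab)
    or <- unname(ft$estimate)
    direction <- if (or < 1) "exclusive" else if (or > 1) "co_occurring"
                 else "independent"
    data.frame(key_a = pr[1], key_b = pr[2],
               odds_ratio = min(or, or_cap), p_value = ft$p.value,
               direction = direction)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    if (auto) stop_invalid("no testable pairs")
    # user-specified pairs that were all skipped: empty result, not an error
    return(data.frame(key_a = character(0), key_b = character(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      direction = character(0)))
  }
  rownames(out) <- NULL
  out
}
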