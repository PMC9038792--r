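## Clinical sub-cohort analysis: median-gLOH dichotomization, Kaplan-Meier
## curves, log-rank test and Cox proportional-hazards regression (backed by
## the survival package behind this module's interface).

#' Dichotomize records at the median gLOH
#'
#' Samples strictly above the median are `high`; ties at the median go
#' `low`.
#'
#' @param records data.frame with a `gloh` column (>= 2 rows).
#' @return `records` with a `group` factor (`low`/`high`) and attribute
#'   `median_gloh`.
#' @export
#' @examples
#' r <- dichotomize_by_median(data.frame(gloh = c(5, 9.9, 12)))
#' table(r$group); attr(r, "median_gloh")
dichotomize_by_median <- function(records) {
  if (nrow(records) < 2L) stop_invalid("need at least 2 records")
  med <- stats::median(records$gloh)
  if (diff(range(records$gloh)) == 0)
    abort("all gLOH values identical: cannot form two groups",
          "lohscape_error_single_group")
  records$group <- factor(ifelse(records$gloh > med, "high", "low"),
                          levels = c("low", "high"))
  attr(records, "median_gloh") <- med
  records
}

check_records <- function(records) {
  need <- c("time", "event")
  if (!all(need %in% names(records)))
    stop_invalid("records need time and event columns")
  if (any(records$time <= 0)) stop_invalid("times must be positive")
  invisible(records)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring and Greenwood standard
#' errors, optionally per group.
#'
#' @param records data.frame with `time`, `event` (logical/0-1) and
#'   optionally `group`.
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err` (Greenwood, on the survival scale).
#' @export
km_estimate <- function(records) {
  check_records(records)
  if (sum(records$event) < 1L)
    abort("no events: survival curve undefined", "lohscape_error_no_events")
  has_grp <- "group" %in% names(records)
  fml <- if (has_grp) survival::Surv(time, event) ~ group
         else survival::Surv(time, event) ~ 1
  fit <- survival::survfit(fml, data = records)
  grp <- if (has_grp)
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  else rep("all", length(fit$time))
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             std_err = fit$std.err * fit$surv)
}

#' Log-rank test between survival groups
#'
#' @param records data.frame with `time`, `event`, `group` (2 groups).
#' @return list: `chisq`, `df`, `p_value`, `observed`, `expected`.
#' @export
logrank_test <- function(records) {
  check_records(records)
  if (!"group" %in% names(records)) stop_invalid("records need a group column")
  g <- droplevels(as.factor(records$group))
  if (nlevels(g) < 2L) stop_invalid("log-rank needs two non-empty groups")
  if (sum(records$event) < 1L)
    abort("no events: log-rank undefined", "lohscape_error_no_events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = records)
  df <- length(sd$n) - 1L
  list(chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (Breslow
#' selectable), hazard ratios with Wald 95% confidence intervals. Monotone
#' likelihood (complete separation) and non-convergence are surfaced as a
#' `flag` rather than silently returned.
#'
#' @param records data.frame with `time`, `event` and the covariate columns.
#' @param covariates character vector of covariate column names (default
#'   `"group"`).
#' @param ties "efron" (default) or "breslow".
#' @return list of class `survival_fit`: `terms` (data.frame `term`, `coef`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`), `logrank_p` (score test),
#'   `n_events`, `flag`.
#' @export
cox_fit <- function(records, covariates = "group",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_records(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop_invalid(paste0("missing covariates: ",
                                        paste(miss, collapse = ", ")))
  if (sum(records$event) < 1L)
    abort("no events: Cox fit undefined", "lohscape_error_no_events")
  for (cv in covariates)
    if (length(unique(records[[cv]])) < 2L)
      stop_invalid(paste0("covariate '", cv, "' is constant"))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  flag <- "ok"
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        flag <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- data.frame(term = rownames(co), coef = co[, "coef"],
                      hr = exp(co[, "coef"]),
                      ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                      ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                      p_value = co[, "Pr(>|z|)"], row.names = NULL)
  structure(list(terms = terms, logrank_p = sm$sctest[["pvalue"]],
                 n_events = sum(records$event), flag = flag,
                 ties = ties),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties), %d events%s\n", x$ties, x$n_events,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  print(x$terms, row.names = FALSE)
  invisible(x)
}
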