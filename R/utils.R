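#' @keywords internal
"_PACKAGE"

## Classed conditions so callers/tests can match on error type rather than
## message text. All conditions carry class "lohscape_error".

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "lohscape_error"), ...))
}

stop_invalid <- function(msg, ...) abort(msg, "lohscape_error_invalid_argument", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the R random number generator locally, restoring any pre-existing
#' `.Random.seed` on exit, so seeded internals (e.g. Monte-Carlo multiplicity
#' adjustments) do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a top-level run seed
#'
#' All randomness in a pipeline run flows from one seed; each stage draws its
#' own sub-seed through this documented derivation so stages are individually
#' reproducible. Result stays inside the 32-bit signed integer range.
#'
#' @param seed top-level integer seed.
#' @param stage integer stage index (>= 0) or stage name from
#'   `c("simulate","gloh","cohort","associate","survive","report")`.
#' @return an integer seed.
#' @export
#' @examples
#' stage_seed(1, "cohort")
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, gloh = 2L, cohort = 3L, associate = 4L,
              survive = 5L, report = 6L)
  if (is.character(stage)) {
    if (!stage %in% names(stages)) stop_invalid(paste0("unknown stage: ", stage))
    stage <- stages[[stage]]
  }
  as.integer((as.numeric(seed) * 48271 + 77003 * as.numeric(stage)) %% 2147483647) + 1L
}

## weighted mean that tolerates zero-length input
wmean <- function(x, w) {
  if (length(x) == 0L) return(NA_real_)
  sum(x * w) / sum(w)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
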