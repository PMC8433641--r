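#' Summary statistics for replicate measurements
#'
#' Computes the n, mean, sample standard deviation and percent coefficient
#' of variation (%CV = 100 * sd / |mean|) of a numeric vector.  The %CV is
#' the repeatability metric used throughout assay validation (injection
#' repeatability, back-calculation precision, QC precision).
#'
#' All statistics are kept at full precision; rounding is a presentation
#' concern handled by the report renderers.  The standard deviation uses
#' the n - 1 denominator.
#'
#' @param values numeric vector, at least one finite value.
#' @return An object of class `sia_summary`: a list with elements `n`,
#'   `mean`, `sd`, `cv_percent` and `cv_defined`.  For `n = 1` the sd and
#'   %CV are `NA`; for `mean = 0` the %CV is undefined and flagged via
#'   `cv_defined = FALSE` rather than returned as infinity.
#' @examples
#' summarize_values(c(2.423, 2.430, 2.429, 2.428, 2.423))
#' @export
summarize_values <- function(values) {
  if (!is.numeric(values) || length(values) == 0) {
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("'values' must be finite and free of NA", call. = FALSE)
  }
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else NA_real_
  cv_defined <- m != 0 && n > 1
  cv <- if (cv_defined) 100 * s / abs(m) else NA_real_
  structure(
    list(n = n, mean = m, sd = s, cv_percent = cv, cv_defined = cv_defined),
    class = "sia_summary"
  )
}

#' @export
print.sia_summary <- function(x, digits = 4, ...) {
  cat(sprintf("n = %d, mean = %s, sd = %s, %%CV = %s\n",
              x$n, format(x$mean, digits = digits),
              format(x$sd, digits = digits),
              if (x$cv_defined) format(x$cv_percent, digits = digits)
              else "undefined"))
  invisible(x)
}

#' Percent recovery of a spiked or stored sample
#'
#' Recovery is the accuracy metric of the assay: the found concentration
#' expressed as a percentage of the added (nominal) concentration,
#' `100 * found / added`.
#'
#' @param added added (nominal) concentration, > 0.  Vectorised.
#' @param found found (measured) concentration.  Recycled against `added`.
#' @return A data frame of class `sia_recovery` with columns `added_conc`,
#'   `found_conc` and `recovery_percent`.
#' @examples
#' recovery(7.922, c(7.894, 8.146, 8.177))
#' @export
recovery <- function(added, found) {
  if (!is.numeric(added) || !is.numeric(found)) {
    stop("'added' and 'found' must be numeric", call. = FALSE)
  }
  if (any(!is.finite(added)) || any(added <= 0)) {
    stop("'added' concentrations must be finite and > 0", call. = FALSE)
  }
  d <- data.frame(added_conc = added, found_conc = found)
  d$recovery_percent <- 100 * d$found_conc / d$added_conc
  class(d) <- c("sia_recovery", "data.frame")
  d
}

#' Percent relative error against a nominal value
#'
#' Signed deviation of a back-calculated (found) concentration from its
#' nominal concentration, `%RE = 100 * (found - nominal) / nominal`.  This
#' is the deviation metric that drives weighting-factor selection for the
#' calibration model.
#'
#' @param found found / back-calculated concentration.  Vectorised.
#' @param nominal nominal concentration, > 0.  Recycled against `found`.
#' @return Numeric vector of signed percent relative errors.
#' @examples
#' percent_re(0.949, 1.000)  # -5.1
#' @export
percent_re <- function(found, nominal) {
  if (!is.numeric(found) || !is.numeric(nominal)) {
    stop("'found' and 'nominal' must be numeric", call. = FALSE)
  }
  if (any(!is.finite(nominal)) || any(nominal <= 0)) {
    stop("'nominal' concentrations must be finite and > 0", call. = FALSE)
  }
  100 * (found - nominal) / nominal
}

#' Acceptance rule for a validation metric
#'
#' A named one- or two-sided band against which an observed metric is
#' judged, e.g. recovery in 80--110% at the quantitation limit, or
#' injection %CV below 2%.  Bounds are inclusive: guideline bands are
#' phrased as "in the range of".
#'
#' @param metric_name label of the metric the rule constrains.
#' @param lower,upper numeric bounds; at least one must be given.
#' @param context optional label of where the rule applies (e.g. "LOQ").
#' @return Object of class `sia_rule`.
#' @seealso [check_rule()]
#' @export
acceptance_rule <- function(metric_name, lower = NULL, upper = NULL,
                            context = "") {
  if (is.null(lower) && is.null(upper)) {
    stop("an acceptance rule needs at least one bound", call. = FALSE)
  }
  if (!is.null(lower) && !is.null(upper) && lower > upper) {
    stop("'lower' must not exceed 'upper'", call. = FALSE)
  }
  structure(
    list(metric_name = as.character(metric_name),
         lower = if (is.null(lower)) NULL else as.numeric(lower),
         upper = if (is.null(upper)) NULL else as.numeric(upper),
         context = as.character(context)),
    class = "sia_rule"
  )
}

#' Evaluate an acceptance rule
#'
#' @param rule an [acceptance_rule()].
#' @param observed finite numeric scalar to test against the rule.
#' @return Object of class `sia_outcome` with elements `rule`, `observed`
#'   and `passed` (inclusive bound comparison).
#' @examples
#' check_rule(acceptance_rule("%recovery", 80, 110, "LOQ"), 92.5)
#' @export
check_rule <- function(rule, observed) {
  stopifnot(inherits(rule, "sia_rule"))
  if (!is.numeric(observed) || length(observed) != 1 || !is.finite(observed)) {
    stop("'observed' must be a single finite number", call. = FALSE)
  }
  ok <- TRUE
  if (!is.null(rule$lower)) ok <- ok && observed >= rule$lower
  if (!is.null(rule$upper)) ok <- ok && observed <= rule$upper
  structure(list(rule = rule, observed = observed, passed = ok),
            class = "sia_outcome")
}

#' @export
print.sia_outcome <- function(x, ...) {
  band <- paste0(
    if (!is.null(x$rule$lower)) sprintf(">= %g", x$rule$lower) else "",
    if (!is.null(x$rule$lower) && !is.null(x$rule$upper)) " and " else "",
    if (!is.null(x$rule$upper)) sprintf("<= %g", x$rule$upper) else ""
  )
  cat(sprintf("%s%s: observed %g (%s) -> %s\n", x$rule$metric_name,
              if (nzchar(x$rule$context)) paste0(" [", x$rule$context, "]")
              else "",
              x$observed, band, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

# round only for display; internal values stay at full precision
round_display <- function(x, digits) {
  ifelse(is.na(x), NA_real_, round(x, digits))
}
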