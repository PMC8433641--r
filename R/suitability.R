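#' USP theoretical plate count (half-height convention)
#'
#' `N = 5.54 * (retention_time / width_half_height)^2`.  Dimensionless
#' under any common rescaling of the two time inputs.
#'
#' @param retention_time retention time, min, > 0.  Vectorised.
#' @param width_half_height peak width at half height, min, > 0.
#' @return Plate count (numeric).
#' @examples
#' plate_count(2.427, 0.0503)
#' @export
plate_count <- function(retention_time, width_half_height) {
  if (any(!is.finite(retention_time)) || any(retention_time <= 0) ||
      any(!is.finite(width_half_height)) || any(width_half_height <= 0)) {
    stop("retention time and half-height width must be finite and > 0",
         call. = FALSE)
  }
  5.54 * (retention_time / width_half_height)^2
}

#' USP tailing factor
#'
#' `T = W_0.05 / (2 * f)`: full width at 5% of peak height over twice the
#' front half-width at the same height.  1.0 is a symmetric peak; values
#' above 1 indicate tailing.
#'
#' @param width_5pct full peak width at 5% height, min, > 0.
#' @param front_distance_5pct distance from the leading edge at 5% height
#'   to the peak apex, min, > 0 and not exceeding `width_5pct`.
#' @return Tailing factor (numeric).
#' @export
tailing_factor <- function(width_5pct, front_distance_5pct) {
  if (any(!is.finite(width_5pct)) || any(width_5pct <= 0) ||
      any(!is.finite(front_distance_5pct)) || any(front_distance_5pct <= 0)) {
    stop("widths must be finite and > 0", call. = FALSE)
  }
  if (any(front_distance_5pct > width_5pct)) {
    stop("front half-width cannot exceed the full width", call. = FALSE)
  }
  width_5pct / (2 * front_distance_5pct)
}

#' Chromatographic resolution between two peaks
#'
#' `Rs = 2 * (rt2 - rt1) / (w1 + w2)` with baseline widths (4 sigma for a
#' Gaussian peak).  Half-height widths may be used instead with
#' `convention = "half_height"`, which applies the USP factor 1.18 in
#' place of 2.
#'
#' @param rt1,rt2 retention times of the earlier and later peak, min,
#'   with `rt2 > rt1`.
#' @param w1,w2 peak widths, min, > 0 (baseline widths by default).
#' @param convention `"baseline"` (default) or `"half_height"`.
#' @return Resolution (numeric).
#' @export
resolution <- function(rt1, rt2, w1, w2,
                       convention = c("baseline", "half_height")) {
  convention <- match.arg(convention)
  if (any(rt2 <= rt1)) stop("'rt2' must exceed 'rt1'", call. = FALSE)
  if (any(w1 <= 0) || any(w2 <= 0)) stop("widths must be > 0", call. = FALSE)
  factor <- if (convention == "baseline") 2 else 1.18
  factor * (rt2 - rt1) / (w1 + w2)
}

#' Default system-suitability limits
#'
#' Injection %CV below 2%, tailing factor below 2, plate count above
#' 2000, resolution above 2 — the conventional limits for a validated
#' chromatographic assay.
#'
#' @param cv_max,tailing_max,plates_min,resolution_min numeric limits.
#' @return Named list of limits.
#' @export
suitability_limits <- function(cv_max = 2.0, tailing_max = 2.0,
                               plates_min = 2000, resolution_min = 2.0) {
  list(cv_max = cv_max, tailing_max = tailing_max,
       plates_min = plates_min, resolution_min = resolution_min)
}

#' System-suitability report for replicate injections
#'
#' Summarises the repeatability (retention-time and peak-area %CV) of a
#' set of replicate injections and judges it, together with the mean
#' tailing factor and plate count, against configurable limits.  Tailing
#' and plates are taken from the measured 5%-height / half-height widths
#' when those columns are present, or from instrument-reported `tailing`
#' / `plates` columns otherwise; if neither is available those checks are
#' skipped with a warning.
#'
#' @param injections data frame with one row per injection: columns
#'   `rt_min` and `area`, optional `w_half_min`, `w_5pct_min`,
#'   `f_5pct_min`, `tailing`, `plates`.
#' @param limits a [suitability_limits()] list.
#' @param min_injections minimum number of injections, default 5.
#' @param resolution_rs optional externally computed resolution to judge
#'   against the resolution limit.
#' @return Object of class `suitability_report` with the summary
#'   statistics, derived metrics and a list of `sia_outcome` verdicts.
#' @export
suitability_report <- function(injections, limits = suitability_limits(),
                               min_injections = 5, resolution_rs = NULL) {
  if (!is.data.frame(injections) ||
      !all(c("rt_min", "area") %in% names(injections))) {
    stop("'injections' needs columns rt_min and area", call. = FALSE)
  }
  if (nrow(injections) < min_injections) {
    stop(sprintf("need at least %d injections", min_injections), call. = FALSE)
  }
  rt_stats <- summarize_values(injections$rt_min)
  area_stats <- summarize_values(injections$area)

  tailing <- plates <- NA_real_
  if (all(c("w_5pct_min", "f_5pct_min") %in% names(injections))) {
    tailing <- mean(tailing_factor(injections$w_5pct_min,
                                   injections$f_5pct_min))
  } else if ("tailing" %in% names(injections)) {
    tailing <- mean(injections$tailing)
  }
  if ("w_half_min" %in% names(injections)) {
    plates <- mean(plate_count(injections$rt_min, injections$w_half_min))
  } else if ("plates" %in% names(injections)) {
    plates <- mean(injections$plates)
  }
  if (is.na(tailing) || is.na(plates)) {
    warning("peak width fields missing: tailing and/or plate verdicts omitted")
  }

  verdicts <- list(
    rt_cv = check_rule(acceptance_rule("retention time %CV",
                                       upper = limits$cv_max,
                                       context = "suitability"),
                       rt_stats$cv_percent),
    area_cv = check_rule(acceptance_rule("peak area %CV",
                                         upper = limits$cv_max,
                                         context = "suitability"),
                         area_stats$cv_percent)
  )
  if (!is.na(tailing)) {
    verdicts$tailing <- check_rule(
      acceptance_rule("tailing factor", upper = limits$tailing_max,
                      context = "suitability"), tailing)
  }
  if (!is.na(plates)) {
    verdicts$plates <- check_rule(
      acceptance_rule("plate count", lower = limits$plates_min,
                      context = "suitability"), plates)
  }
  if (!is.null(resolution_rs)) {
    verdicts$resolution <- check_rule(
      acceptance_rule("resolution", lower = limits$resolution_min,
                      context = "suitability"), resolution_rs)
  }
  structure(
    list(rt_stats = rt_stats, area_stats = area_stats,
         tailing = tailing, plates = plates,
         resolution = resolution_rs, n = nrow(injections),
         verdicts = verdicts,
         passed = all(vapply(verdicts, `[[`, logical(1), "passed"))),
    class = "suitability_report"
  )
}

#' @export
print.suitability_report <- function(x, ...) {
  cat(sprintf("System suitability (n = %d): %s\n", x$n,
              if (x$passed) "PASS" else "FAIL"))
  cat(sprintf("  retention time: mean %.4g min, %%CV %.2f\n",
              x$rt_stats$mean, x$rt_stats$cv_percent))
  cat(sprintf("  peak area:      mean %.6g, %%CV %.2f\n",
              x$area_stats$mean, x$area_stats$cv_percent))
  if (!is.na(x$tailing)) cat(sprintf("  tailing factor: %.3g\n", x$tailing))
  if (!is.na(x$plates)) cat(sprintf("  plate count:    %.0f\n", x$plates))
  if (!is.null(x$resolution)) cat(sprintf("  resolution:     %.3g\n", x$resolution))
  for (v in x$verdicts) print(v)
  invisible(x)
}

#' Percent of analyte remaining after a stress condition
#'
#' `100 * stressed / control` at equal nominal concentration.  Values may
#' exceed 100 (response drift); they are reported as computed, without
#' clamping.
#'
#' @param stressed_response response of the stressed sample.  Vectorised.
#' @param control_response response of the untreated control, > 0.
#' @return Percent remaining.
#' @export
percent_remaining <- function(stressed_response, control_response) {
  if (any(!is.finite(control_response)) || any(control_response <= 0)) {
    stop("control response must be finite and > 0", call. = FALSE)
  }
  100 * stressed_response / control_response
}

#' Forced-degradation bookkeeping table
#'
#' Assembles the percent-remaining column of a stress study from per
#' condition stressed and control responses.
#'
#' @param stress data frame with columns `condition`, `incubation_h`,
#'   `response`, `control_response`.
#' @return The input with a `remaining_percent` column appended, class
#'   `stress_table`.
#' @export
stress_table <- function(stress) {
  need <- c("condition", "incubation_h", "response", "control_response")
  if (!is.data.frame(stress) || !all(need %in% names(stress))) {
    stop("'stress' needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  stress$remaining_percent <- percent_remaining(stress$response,
                                                stress$control_response)
  class(stress) <- c("stress_table", "data.frame")
  stress
}

#' Robustness comparison across deliberate method variations
#'
#' Runs the suitability summaries per condition (e.g. mobile-phase
#' variations, column batches) and flags any condition violating the
#' suitability limits.
#'
#' @param variant_runs named list mapping condition label to an injection
#'   data frame as accepted by [suitability_report()].
#' @param limits a [suitability_limits()] list.
#' @param min_injections forwarded to [suitability_report()].
#' @return Object of class `robustness_table`: a data frame with one row
#'   per condition (`condition`, `rt_cv`, `area_cv`, `tailing`, `plates`,
#'   `passed`) plus the per-condition reports as attribute `reports`.
#' @export
robustness_table <- function(variant_runs, limits = suitability_limits(),
                             min_injections = 5) {
  if (!is.list(variant_runs) || length(variant_runs) < 2 ||
      is.null(names(variant_runs))) {
    stop("'variant_runs' must be a named list of >= 2 conditions", call. = FALSE)
  }
  reports <- lapply(variant_runs, suitability_report, limits = limits,
                    min_injections = min_injections)
  out <- data.frame(
    condition = names(variant_runs),
    rt_cv = vapply(reports, function(r) r$rt_stats$cv_percent, numeric(1)),
    area_cv = vapply(reports, function(r) r$area_stats$cv_percent, numeric(1)),
    tailing = vapply(reports, `[[`, numeric(1), "tailing"),
    plates = vapply(reports, `[[`, numeric(1), "plates"),
    passed = vapply(reports, `[[`, logical(1), "passed"),
    row.names = NULL
  )
  attr(out, "reports") <- reports
  class(out) <- c("robustness_table", "data.frame")
  out
}
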