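#' Estimate baseline noise from blank samples
#'
#' Noise amplitude of a blank (diluent) trace, either as the peak-to-peak
#' excursion (`max - min`) or the root-mean-square spread (sample sd).
#' The amplitude feeds the signal-to-noise ratios that define the
#' detection and quantitation limits.
#'
#' @param blank_values numeric vector of blank detector samples (>= 2).
#' @param method `"peak_to_peak"` (default) or `"rms"`.
#' @param window optional label of the blank region used.
#' @return Object of class `noise_estimate` with `method`, `amplitude`,
#'   `window` and a `degenerate` flag for a constant blank.
#' @export
estimate_noise <- function(blank_values, method = c("peak_to_peak", "rms"),
                           window = "") {
  method <- match.arg(method)
  if (!is.numeric(blank_values) || length(blank_values) < 2) {
    stop("need at least 2 blank samples", call. = FALSE)
  }
  amp <- switch(method,
                peak_to_peak = max(blank_values) - min(blank_values),
                rms = stats::sd(blank_values))
  structure(list(method = method, amplitude = amp,
                 window = as.character(window), degenerate = amp == 0),
            class = "noise_estimate")
}

#' Signal-to-noise ratio
#'
#' Under the peak-to-peak convention the pharmacopoeial form
#' `S/N = 2 * signal / amplitude` (signal height over half the
#' peak-to-peak noise) is used; under the rms convention
#' `S/N = signal / amplitude`.  The convention travels with the
#' [estimate_noise()] result.
#'
#' @param signal peak response (height or area in consistent units).
#' @param noise a [estimate_noise()] result with positive amplitude.
#' @return Object of class `sn_result` with `signal`, `noise`, `sn`,
#'   `convention`.
#' @export
signal_to_noise <- function(signal, noise) {
  stopifnot(inherits(noise, "noise_estimate"))
  if (noise$degenerate || noise$amplitude <= 0) {
    stop("noise amplitude must be > 0 (degenerate blank)", call. = FALSE)
  }
  if (any(signal <= 0)) {
    warning("non-positive signal; S/N reported as 0")
  }
  sn <- ifelse(signal <= 0, 0,
               switch(noise$method,
                      peak_to_peak = 2 * signal / noise$amplitude,
                      rms = signal / noise$amplitude))
  structure(list(signal = signal, noise = noise, sn = sn,
                 convention = noise$method),
            class = "sn_result")
}

#' Assess the limit of detection (LOD)
#'
#' The LOD concentration is accepted when the mean signal-to-noise ratio
#' of replicate injections is at least `sn_min` (conventionally 3) and
#' the injection precision (%CV of the responses) is below `cv_max`
#' (conventionally 15%).
#'
#' @param responses replicate peak responses at the LOD level (>= 3).
#' @param noise a [estimate_noise()] result.
#' @param conc the nominal LOD concentration, ug/mL.
#' @param sn_min,cv_max acceptance thresholds, defaults 3 and 15.
#' @return Object of class `lod_loq_assessment`.
#' @export
assess_lod <- function(responses, noise, conc, sn_min = 3, cv_max = 15) {
  if (length(responses) < 3) stop("need >= 3 injections", call. = FALSE)
  sn <- signal_to_noise(responses, noise)$sn
  stats <- summarize_values(responses)
  reasons <- character()
  if (mean(sn) < sn_min) {
    reasons <- c(reasons, sprintf("mean S/N %.3g < %g", mean(sn), sn_min))
  }
  if (!stats$cv_defined || stats$cv_percent >= cv_max) {
    reasons <- c(reasons, sprintf("response %%CV not below %g", cv_max))
  }
  structure(
    list(kind = "LOD", nominal_conc = conc, sn_values = sn,
         summary = stats, recoveries = NULL,
         verdict = length(reasons) == 0, reasons = reasons),
    class = "lod_loq_assessment"
  )
}

#' Assess the limit of quantitation (LOQ)
#'
#' The LOQ concentration is accepted when every stated criterion holds:
#' mean signal-to-noise at least `sn_min` (conventionally 10), mean
#' percent recovery inside `recovery_band` (conventionally 80--110%), and
#' %CV of the found concentrations below `cv_max` (conventionally 15%).
#'
#' @param added the nominal (added) LOQ concentration, ug/mL.
#' @param found replicate found concentrations at the LOQ (>= 3).
#' @param sn_values per-injection signal-to-noise ratios (instrument
#'   reported or computed via [signal_to_noise()]).
#' @param sn_min S/N threshold, default 10.
#' @param recovery_band inclusive recovery band in %, default `c(80, 110)`.
#' @param cv_max precision threshold in %, default 15.
#' @return Object of class `lod_loq_assessment` carrying the per-sample
#'   recoveries and the verdict with its reasons.
#' @export
assess_loq <- function(added, found, sn_values, sn_min = 10,
                       recovery_band = c(80, 110), cv_max = 15) {
  if (length(found) < 3) stop("need >= 3 injections", call. = FALSE)
  rec <- recovery(added, found)
  stats <- summarize_values(found)
  reasons <- character()
  if (mean(sn_values) < sn_min) {
    reasons <- c(reasons, sprintf("mean S/N %.3g < %g", mean(sn_values), sn_min))
  }
  mrec <- mean(rec$recovery_percent)
  if (mrec < recovery_band[1] || mrec > recovery_band[2]) {
    reasons <- c(reasons, sprintf("mean recovery %.3g%% outside %g-%g%%",
                                  mrec, recovery_band[1], recovery_band[2]))
  }
  if (!stats$cv_defined || stats$cv_percent >= cv_max) {
    reasons <- c(reasons, sprintf("found-concentration %%CV not below %g", cv_max))
  }
  structure(
    list(kind = "LOQ", nominal_conc = added, sn_values = sn_values,
         summary = stats, recoveries = rec,
         verdict = length(reasons) == 0, reasons = reasons),
    class = "lod_loq_assessment"
  )
}

#' @export
print.lod_loq_assessment <- function(x, ...) {
  cat(sprintf("%s assessment at %g ug/mL: %s\n", x$kind, x$nominal_conc,
              if (x$verdict) "accepted" else "rejected"))
  cat(sprintf("  mean S/N %.3g; %%CV %.3g\n", mean(x$sn_values),
              x$summary$cv_percent))
  if (!is.null(x$recoveries)) {
    cat(sprintf("  mean recovery %.4g%%\n",
                mean(x$recoveries$recovery_percent)))
  }
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}
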