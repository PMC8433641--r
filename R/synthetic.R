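#' Noise model for synthetic detector responses
#'
#' Gaussian noise whose standard deviation combines a proportional and an
#' additive component: `sd(y) = sqrt((cv * E[y])^2 + sd0^2)`.  A purely
#' proportional model (`sd0 = 0`) reproduces the roughly constant %CV
#' across concentration levels observed on real calibration tables, i.e.
#' heteroscedastic responses.
#'
#' @param kind `"proportional"`, `"additive"` or `"mixed"` (label only;
#'   the sd formula above always applies).
#' @param cv proportional component as a fraction, >= 0.
#' @param sd0 additive component in response units, >= 0.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("proportional", "additive", "mixed"),
                        cv = 0.02, sd0 = 0) {
  kind <- match.arg(kind)
  if (cv < 0 || sd0 < 0) stop("'cv' and 'sd0' must be >= 0", call. = FALSE)
  if (kind == "proportional") sd0 <- 0
  if (kind == "additive") cv <- 0
  structure(list(kind = kind, cv = cv, sd0 = sd0), class = "noise_model")
}

noise_sd <- function(noise, mu) sqrt((noise$cv * mu)^2 + noise$sd0^2)

# Named, independent substream per fixture kind so that adding a new
# fixture kind never perturbs draws of the existing ones.
stream_seed <- function(seed, kind) {
  offset <- c(calibration = 101L, decay = 211L, suitability = 307L,
              blank = 401L, qc = 503L)[[kind]]
  (as.integer(seed) + offset) %% .Machine$integer.max
}

# draw Gaussian responses around mu, resampling non-positive values
# (rather than clipping) so downstream log transforms stay valid
draw_positive <- function(mu, sd, max_tries = 100) {
  y <- stats::rnorm(length(mu), mu, sd)
  tries <- 0
  while (any(y <= 0) && tries < max_tries) {
    bad <- y <= 0
    y[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
    tries <- tries + 1
  }
  if (any(y <= 0)) stop("could not draw positive responses; noise too large",
                        call. = FALSE)
  attr(y, "resampled") <- tries
  y
}

#' Specification of a synthetic calibration experiment
#'
#' Defaults emulate a six-level, triplicate calibration of an ester
#' prodrug assay over 0.10--25 ug/mL with a slope near 7000 area units
#' per ug/mL, a small negative intercept and 2% proportional noise.
#'
#' @param levels concentration levels, ug/mL, distinct and > 0.
#' @param replicates replicates per level.
#' @param true_slope,true_intercept line parameters in response units.
#' @param noise a [noise_model()].
#' @param seed integer seed; every generated table is deterministic given
#'   the spec (including the seed).
#' @return Object of class `calibration_sim_spec`.
#' @export
calibration_sim_spec <- function(levels = c(0.10, 1, 3, 8, 15, 25),
                                 replicates = 3,
                                 true_slope = 7000, true_intercept = -60,
                                 noise = noise_model("proportional", cv = 0.02),
                                 seed = 1) {
  if (any(levels <= 0) || anyDuplicated(levels)) {
    stop("'levels' must be distinct and > 0", call. = FALSE)
  }
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  stopifnot(inherits(noise, "noise_model"))
  structure(list(levels = sort(levels), replicates = as.integer(replicates),
                 true_slope = true_slope, true_intercept = true_intercept,
                 noise = noise, seed = as.integer(seed)),
            class = "calibration_sim_spec")
}

#' Generate a synthetic calibration table
#'
#' Responses are `y = intercept + slope * x + e` with Gaussian noise per
#' the spec's [noise_model()]; non-positive draws are resampled.
#'
#' @param spec a [calibration_sim_spec()].
#' @return A [calibration_data()] object.
#' @export
gen_calibration <- function(spec) {
  stopifnot(inherits(spec, "calibration_sim_spec"))
  set.seed(stream_seed(spec$seed, "calibration"))
  conc <- rep(spec$levels, each = spec$replicates)
  mu <- spec$true_intercept + spec$true_slope * conc
  if (any(mu <= 0)) {
    stop("true line gives non-positive mean response at the lowest level",
         call. = FALSE)
  }
  y <- draw_positive(mu, noise_sd(spec$noise, mu))
  calibration_data(conc, as.numeric(y),
                   replicate = rep(seq_len(spec$replicates),
                                   times = length(spec$levels)))
}

#' Specification of a synthetic degradation experiment
#'
#' Defaults emulate a triplicate pseudo-first-order decay from
#' `C0 = 5` ug/mL sampled at 13 points over 24 h with 2% proportional
#' noise — the design of a buffer-stability kinetic run.
#'
#' @param c0 initial concentration, ug/mL.
#' @param k_true true rate constant (h^-1 for first order).
#' @param order rate-law order generating the decay.
#' @param times sampling grid, h.
#' @param replicates replicate count.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param condition condition label attached to the time courses.
#' @return Object of class `decay_sim_spec`.
#' @export
decay_sim_spec <- function(c0 = 5, k_true = 0.045,
                           order = c("first", "zero", "second"),
                           times = seq(0, 24, by = 2), replicates = 3,
                           noise = noise_model("proportional", cv = 0.02),
                           seed = 1, condition = "pH 1.2") {
  order <- match.arg(order)
  if (c0 <= 0 || k_true <= 0) stop("'c0' and 'k_true' must be > 0", call. = FALSE)
  if (length(times) < 3 || any(diff(times) <= 0)) {
    stop("'times' must be >= 3 strictly increasing values", call. = FALSE)
  }
  stopifnot(inherits(noise, "noise_model"))
  structure(list(c0 = c0, k_true = k_true, order = order, times = times,
                 replicates = as.integer(replicates), noise = noise,
                 seed = as.integer(seed), condition = condition),
            class = "decay_sim_spec")
}

decay_curve <- function(order, c0, k, t) {
  switch(order,
         first = c0 * exp(-k * t),
         zero = c0 - k * t,
         second = c0 / (1 + k * c0 * t))
}

#' Generate synthetic replicate degradation time courses
#'
#' Concentrations follow the closed form of the spec's order
#' (`C0 e^{-kt}`, `C0 - kt`, or `C0 / (1 + k C0 t)`) with Gaussian noise
#' per the [noise_model()]; non-positive draws are resampled.
#'
#' @param spec a [decay_sim_spec()].
#' @return List of [kinetic_timecourse()] objects, one per replicate.
#' @export
gen_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_sim_spec"))
  set.seed(stream_seed(spec$seed, "decay"))
  mu <- decay_curve(spec$order, spec$c0, spec$k_true, spec$times)
  if (any(mu <= 0)) {
    stop("true decay reaches non-positive concentration on the time grid",
         call. = FALSE)
  }
  lapply(seq_len(spec$replicates), function(r) {
    conc <- draw_positive(mu, noise_sd(spec$noise, mu))
    kinetic_timecourse(spec$times, as.numeric(conc),
                       condition = spec$condition, replicate = r)
  })
}

#' Specification of a synthetic system-suitability run
#'
#' Defaults emulate five replicate injections with retention time near
#' 2.43 min and peak area near 56,000 units, each with a %CV well below
#' the 2% suitability limit, and a slightly tailed peak shape giving a
#' plate count near 13,000.
#'
#' @param n_injections injection count.
#' @param rt_mean,rt_cv retention-time mean (min) and CV (fraction).
#' @param area_mean,area_cv peak-area mean and CV (fraction).
#' @param sigma_min Gaussian peak sigma, min.
#' @param tau_min exponential tailing time constant, min (0 = symmetric).
#' @param seed integer seed.
#' @return Object of class `suitability_sim_spec`.
#' @export
suitability_sim_spec <- function(n_injections = 5,
                                 rt_mean = 2.43, rt_cv = 0.0015,
                                 area_mean = 56000, area_cv = 0.003,
                                 sigma_min = 0.0214, tau_min = 0.004,
                                 seed = 1) {
  if (n_injections < 2) stop("need >= 2 injections", call. = FALSE)
  if (rt_cv < 0 || area_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  if (sigma_min <= 0 || tau_min < 0) {
    stop("'sigma_min' must be > 0 and 'tau_min' >= 0", call. = FALSE)
  }
  structure(list(n_injections = as.integer(n_injections),
                 rt_mean = rt_mean, rt_cv = rt_cv,
                 area_mean = area_mean, area_cv = area_cv,
                 sigma_min = sigma_min, tau_min = tau_min,
                 seed = as.integer(seed)),
            class = "suitability_sim_spec")
}

#' Sample a synthetic chromatographic peak on a time grid
#'
#' Gaussian peak, optionally convolved with an exponential decay
#' (exponentially modified Gaussian) to produce tailing, evaluated by the
#' closed-form EMG expression.  Used to give width and tailing
#' measurements a ground truth.
#'
#' @param t time grid, min.
#' @param rt peak (Gaussian centre) retention time, min.
#' @param sigma Gaussian sigma, min.
#' @param tau exponential tail constant, min; 0 gives a pure Gaussian.
#' @param area total peak area.
#' @return Numeric vector of detector response on `t`.
#' @export
peak_shape <- function(t, rt, sigma, tau = 0, area = 1) {
  if (tau <= 0) {
    return(area * stats::dnorm(t, rt, sigma))
  }
  # closed-form exponentially modified Gaussian; erfc via pnorm
  z <- (sigma / tau - (t - rt) / sigma) / sqrt(2)
  erfc <- 2 * stats::pnorm(-sqrt(2) * z)
  area / (2 * tau) * exp(sigma^2 / (2 * tau^2) - (t - rt) / tau) * erfc
}

#' Measure peak widths at fractional heights from a sampled trace
#'
#' Locates the apex and interpolates the crossing times at the requested
#' fraction of the peak height on each side, returning the full width and
#' the front (leading-edge to apex) distance.  This is the numerical
#' ground-truth oracle for the closed-form tailing/plate formulas.
#'
#' @param t time grid, min (fine enough to resolve the peak).
#' @param y response trace on `t`.
#' @param frac height fraction (0.5 for half height, 0.05 for 5% height).
#' @return List with `width`, `front`, `apex_time`, `apex_height`.
#' @export
measure_peak_width <- function(t, y, frac = 0.5) {
  i_apex <- which.max(y)
  h <- y[i_apex] * frac
  left <- right <- NA_real_
  if (i_apex > 1) {
    below <- which(y[seq_len(i_apex - 1)] <= h)
    if (length(below)) {
      i <- max(below)
      left <- t[i] + (h - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
    }
  }
  if (i_apex < length(y)) {
    after <- seq(i_apex + 1, length(y))
    below <- after[y[after] <= h]
    if (length(below)) {
      i <- min(below)
      right <- t[i - 1] + (h - y[i - 1]) * (t[i] - t[i - 1]) / (y[i] - y[i - 1])
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("peak not fully resolved on the grid at this height fraction",
         call. = FALSE)
  }
  list(width = right - left, front = t[i_apex] - left,
       apex_time = t[i_apex], apex_height = y[i_apex])
}

#' Generate synthetic replicate injections
#'
#' Draws per-injection retention times and areas and, from the sampled
#' synthetic peak shape, the measured half-height and 5%-height widths,
#' so that tailing factors and plate counts have a known ground truth.
#'
#' @param spec a [suitability_sim_spec()].
#' @return Data frame of injection records with columns `injection_id`,
#'   `rt_min`, `area`, `w_half_min`, `w_5pct_min`, `f_5pct_min`.
#' @export
gen_suitability <- function(spec) {
  stopifnot(inherits(spec, "suitability_sim_spec"))
  set.seed(stream_seed(spec$seed, "suitability"))
  n <- spec$n_injections
  rt <- stats::rnorm(n, spec$rt_mean, spec$rt_cv * spec$rt_mean)
  area <- stats::rnorm(n, spec$area_mean, spec$area_cv * spec$area_mean)
  rows <- lapply(seq_len(n), function(i) {
    span <- 8 * spec$sigma_min + 12 * spec$tau_min
    grid <- seq(rt[i] - span, rt[i] + span, length.out = 4001)
    y <- peak_shape(grid, rt[i], spec$sigma_min, spec$tau_min, area[i])
    w50 <- measure_peak_width(grid, y, 0.5)
    w05 <- measure_peak_width(grid, y, 0.05)
    data.frame(injection_id = i, rt_min = rt[i], area = area[i],
               w_half_min = w50$width, w_5pct_min = w05$width,
               f_5pct_min = w05$front)
  })
  do.call(rbind, rows)
}

#' Generate a blank (diluent) noise trace
#'
#' Zero-mean Gaussian detector samples, deterministic given the seed.
#'
#' @param n sample count, >= 2.
#' @param sd noise standard deviation in response units, >= 0.
#' @param seed integer seed.
#' @return Numeric vector of blank samples.
#' @export
gen_blank <- function(n, sd, seed = 1) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  set.seed(stream_seed(seed, "blank"))
  stats::rnorm(n, 0, sd)
}
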