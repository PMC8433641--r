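#' Construct a calibration data set
#'
#' Replicate (concentration, response) points spanning the calibration
#' range.  Concentrations must be strictly positive (a blank is not a
#' calibration point) and at least two distinct levels are required.
#'
#' @param conc nominal concentrations, ug/mL, all > 0.
#' @param response detector responses (integrated peak areas).
#' @param replicate optional replicate labels; defaults to the within-level
#'   running index.
#' @return A data frame of class `calibration_data` with columns
#'   `conc`, `response`, `replicate`.
#' @examples
#' calibration_data(rep(c(1, 5, 10), each = 3),
#'                  rep(c(1, 5, 10), each = 3) * 7000 + rnorm(9))
#' @export
calibration_data <- function(conc, response, replicate = NULL) {
  if (!is.numeric(conc) || !is.numeric(response) ||
      length(conc) != length(response) || length(conc) == 0) {
    stop("'conc' and 'response' must be numeric vectors of equal, positive length",
         call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all calibration concentrations must be finite and > 0 (x = 0 is not a calibration point)",
         call. = FALSE)
  }
  if (any(!is.finite(response))) {
    stop("all responses must be finite", call. = FALSE)
  }
  if (length(unique(conc)) < 2) {
    stop("calibration needs at least 2 distinct concentration levels",
         call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(conc), conc, FUN = seq_along)
  }
  d <- data.frame(conc = conc, response = response,
                  replicate = as.character(replicate))
  class(d) <- c("calibration_data", "data.frame")
  d
}

#' @export
print.calibration_data <- function(x, ...) {
  lv <- sort(unique(x$conc))
  cat(sprintf("Calibration data: %d points, %d levels (%g-%g ug/mL)\n",
              nrow(x), length(lv), min(lv), max(lv)))
  print.data.frame(x, ...)
  invisible(x)
}

# canonical weighting scheme names, in tie-break (parsimony) order
.sia_schemes <- c("unit", "1/x", "1/x^2")

match_scheme <- function(scheme) {
  s <- tolower(as.character(scheme))
  s[s %in% c("1", "none", "ols", "unit")] <- "unit"
  s[s %in% c("1/x", "inverse_x", "x")] <- "1/x"
  s[s %in% c("1/x^2", "1/x2", "inverse_x2", "x2", "x^2")] <- "1/x^2"
  if (!all(s %in% .sia_schemes)) {
    stop("unknown weighting scheme: ",
         paste(setdiff(s, .sia_schemes), collapse = ", "), call. = FALSE)
  }
  s
}

scheme_weights <- function(scheme, x) {
  switch(match_scheme(scheme),
         "unit" = rep(1, length(x)),
         "1/x" = 1 / x,
         "1/x^2" = 1 / x^2)
}

#' Upper quantile of the F distribution
#'
#' Convenience wrapper for the critical values used by the
#' homoscedasticity and lack-of-fit tests, e.g.
#' `f_critical(0.99, 2, 2) = 99.000`.
#'
#' @param p cumulative probability in (0, 1).
#' @param df1,df2 numerator / denominator degrees of freedom, >= 1.
#' @return The F quantile at cumulative probability `p`.
#' @export
f_critical <- function(p, df1, df2) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(df1 < 1) || any(df2 < 1)) {
    stop("degrees of freedom must be >= 1", call. = FALSE)
  }
  stats::qf(p, df1, df2)
}

#' Variance-ratio test for homoscedasticity of calibration responses
#'
#' Compares the response variances at the two extreme calibration levels.
#' The statistic is `F_cal = s2_high / s2_low` with sample variances; the
#' critical value is the F quantile at `1 - alpha` with
#' `(n_high - 1, n_low - 1)` degrees of freedom.  A calibration whose
#' F_cal exceeds the critical value is heteroscedastic and calls for
#' weighted least squares.
#'
#' @param group_low responses at the lowest concentration level (>= 2).
#' @param group_high responses at the highest concentration level (>= 2).
#' @param alpha significance level, default 0.01 (the conventional
#'   F(0.99) criterion for this test).
#' @return Object of class `homoscedasticity_test` with `sd_low`,
#'   `sd_high`, `f_cal`, `f_crit`, `df`, `alpha`, `homoscedastic` and a
#'   `degenerate` flag (zero variance in the denominator group).
#' @examples
#' homoscedasticity_test(c(643, 620, 633), c(177307, 173466, 184125))
#' @export
homoscedasticity_test <- function(group_low, group_high, alpha = 0.01) {
  if (length(group_low) < 2 || length(group_high) < 2) {
    stop("each group needs at least 2 replicate responses", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  v_low <- stats::var(group_low)
  v_high <- stats::var(group_high)
  df <- c(length(group_high) - 1L, length(group_low) - 1L)
  degenerate <- v_low == 0
  f_cal <- if (degenerate) NA_real_ else v_high / v_low
  f_crit <- f_critical(1 - alpha, df[1], df[2])
  structure(
    list(sd_low = sqrt(v_low), sd_high = sqrt(v_high),
         f_cal = f_cal, f_crit = f_crit, df = df, alpha = alpha,
         homoscedastic = if (degenerate) NA else f_cal <= f_crit,
         degenerate = degenerate),
    class = "homoscedasticity_test"
  )
}

#' @export
print.homoscedasticity_test <- function(x, ...) {
  cat("Homoscedasticity (variance-ratio) test\n")
  cat(sprintf("  sd(low) = %.4g, sd(high) = %.4g\n", x$sd_low, x$sd_high))
  if (x$degenerate) {
    cat("  degenerate: zero variance in the low group\n")
  } else {
    cat(sprintf("  F_cal = %.6g vs F_crit(%g; %d, %d) = %.4g -> %s\n",
                x$f_cal, 1 - x$alpha, x$df[1], x$df[2], x$f_crit,
                if (x$homoscedastic) "homoscedastic"
                else "heteroscedastic (use weighted least squares)"))
  }
  invisible(x)
}

#' Fit a (possibly weighted) straight-line calibration model
#'
#' Minimises `sum(w(x) * (y - a - b x)^2)` with `w(x)` = 1, 1/x or 1/x^2.
#' With unit weights this is ordinary least squares.  For weighted fits
#' the coefficient of determination is computed on weighted residuals
#' about the weighted mean response, which reduces to the ordinary r^2 in
#' the unit-weight case.
#'
#' @param data a [calibration_data()] object (or data frame with `conc`
#'   and `response` columns).
#' @param scheme weighting scheme: `"unit"`, `"1/x"` or `"1/x^2"`.
#' @return Object of class `calibration_fit` with `scheme`, `slope`,
#'   `intercept`, `r`, `r2`, `n`, `residuals`, `fitted`, `weights` and the
#'   underlying `lm` fit.
#' @export
fit_line <- function(data, scheme = "unit") {
  data <- as_calibration(data)
  if (nrow(data) < 3) stop("need at least 3 calibration points", call. = FALSE)
  if (length(unique(data$conc)) < 2) {
    stop("singular design: all concentrations identical", call. = FALSE)
  }
  scheme <- match_scheme(scheme)
  w <- scheme_weights(scheme, data$conc)
  fit <- stats::lm(response ~ conc, data = data, weights = w)
  co <- stats::coef(fit)
  # weighted r^2 about the weighted mean (ordinary r^2 for unit weights);
  # computed directly so that noiseless fits do not warn
  wm <- sum(w * data$response) / sum(w)
  ss_tot <- sum(w * (data$response - wm)^2)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / ss_tot
  structure(
    list(scheme = scheme,
         slope = unname(co["conc"]), intercept = unname(co["(Intercept)"]),
         r = sign(unname(co["conc"])) * sqrt(max(r2, 0)),
         r2 = r2, n = nrow(data),
         residuals = unname(stats::residuals(fit)),
         fitted = unname(stats::fitted(fit)),
         weights = w, lm = fit, data = data),
    class = "calibration_fit"
  )
}

as_calibration <- function(data) {
  if (inherits(data, "calibration_data")) return(data)
  if (is.data.frame(data) && all(c("conc", "response") %in% names(data))) {
    return(calibration_data(data$conc, data$response,
                            if ("replicate" %in% names(data)) data$replicate))
  }
  stop("'data' must be calibration_data or a data frame with conc/response",
       call. = FALSE)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (weighting %s): y = %.6g + %.6g x, r^2 = %.6f (n = %d)\n",
              x$scheme, x$intercept, x$slope, x$r2, x$n))
  invisible(x)
}

#' Back-calculate concentration from a detector response
#'
#' Inverts the calibration line: `conc = (response - intercept) / slope`.
#'
#' @param fit a [fit_line()] result.
#' @param response numeric responses (vectorised).
#' @return Back-calculated concentrations, ug/mL.
#' @export
back_calculate <- function(fit, response) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) stop("calibration slope is zero", call. = FALSE)
  (response - fit$intercept) / fit$slope
}

#' Per-level back-calculation table
#'
#' Back-calculates every calibration point, then per level reports the
#' mean back-calculated concentration, its signed %RE against the nominal
#' concentration, and the %CV across replicates.  The acceptance band on
#' the %RE is +/-`re_band_loq` at the lowest level (the quantitation
#' limit) and +/-`re_band_other` elsewhere.
#'
#' @param fit a [fit_line()] result.
#' @param data a [calibration_data()] object.
#' @param re_band_loq,re_band_other acceptance half-widths in %, defaults
#'   20 and 15.
#' @return Data frame of class `back_calc_table`: one row per level with
#'   `nominal`, `n`, `mean_back_calc`, `percent_re`, `cv_percent`,
#'   `re_band`, `within_band`.
#' @export
back_calc_table <- function(fit, data, re_band_loq = 20, re_band_other = 15) {
  data <- as_calibration(data)
  bc <- back_calculate(fit, data$response)
  lev <- sort(unique(data$conc))
  rows <- lapply(lev, function(lv) {
    b <- bc[data$conc == lv]
    m <- mean(b)
    data.frame(
      nominal = lv, n = length(b), mean_back_calc = m,
      percent_re = percent_re(m, lv),
      cv_percent = if (length(b) > 1) 100 * stats::sd(b) / abs(m) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out$re_band <- ifelse(out$nominal == min(lev), re_band_loq, re_band_other)
  out$within_band <- abs(out$percent_re) <= out$re_band
  class(out) <- c("back_calc_table", "data.frame")
  out
}

#' Select the calibration weighting factor by summed absolute %RE
#'
#' Fits each candidate weighting scheme to each replication curve (the
#' replicate-wise convention of weighted-calibration practice: one line
#' per replication, mirroring a replicated calibration table), back-
#' calculates every calibration point from its own replication's fit,
#' and sums the absolute %RE per scheme.  The scheme with the smallest
#' total is selected; ties break toward the simpler scheme in the order
#' unit < 1/x < 1/x^2.  Under noise whose spread grows proportionally
#' with concentration the 1/x^2 factor wins because it protects the low
#' end of the range, where relative errors of an unweighted fit are
#' largest.
#'
#' With `per_replicate = FALSE` (or when the data carry no replication) a
#' single pooled fit per scheme is used instead.  The replicate-wise
#' convention discriminates far better at small designs: the pooled fit
#' averages away the low-level shot noise that separates 1/x from 1/x^2.
#'
#' @param data a [calibration_data()] object.
#' @param schemes candidate schemes in tie-break order.
#' @param per_replicate fit each replication curve separately (default
#'   whenever every level is replicated)?
#' @return Object of class `weighting_selection`: `table` (one row per
#'   replication x scheme with slope, intercept, r, r2 and
#'   `sum_abs_re`), `totals` (per-scheme total sum |%RE|), `chosen`,
#'   `fits` (pooled per-scheme [fit_line()] results) and `chosen_fit`
#'   (the pooled fit under the chosen scheme, for downstream
#'   back-calculation).
#' @export
select_weighting <- function(data, schemes = c("unit", "1/x", "1/x^2"),
                             per_replicate = NULL) {
  data <- as_calibration(data)
  schemes <- match_scheme(schemes)
  if (length(schemes) < 1) stop("need at least one candidate scheme", call. = FALSE)
  reps <- split(seq_len(nrow(data)), data$replicate)
  complete <- all(vapply(reps, length, integer(1)) >= 3) && length(reps) >= 2
  if (is.null(per_replicate)) per_replicate <- complete
  if (per_replicate && !complete) {
    stop("per-replicate selection needs >= 2 replication curves of >= 3 points",
         call. = FALSE)
  }
  groups <- if (per_replicate) reps else list(all = seq_len(nrow(data)))

  rows <- list()
  sums <- stats::setNames(numeric(length(schemes)), schemes)
  for (g in names(groups)) {
    idx <- groups[[g]]
    sub <- calibration_data(data$conc[idx], data$response[idx])
    for (s in schemes) {
      f <- fit_line(sub, s)
      sre <- sum(abs(percent_re(back_calculate(f, sub$response), sub$conc)))
      sums[s] <- sums[s] + sre
      rows[[length(rows) + 1L]] <- data.frame(
        replication = g, scheme = s, slope = f$slope,
        intercept = f$intercept, r = f$r, r2 = f$r2, sum_abs_re = sre)
    }
  }
  tab <- do.call(rbind, rows)
  row.names(tab) <- NULL
  chosen <- schemes[which.min(sums)]  # first minimum = simplest on ties
  fits <- lapply(schemes, function(s) fit_line(data, s))
  names(fits) <- schemes
  structure(list(table = tab, totals = sums, chosen = chosen, fits = fits,
                 chosen_fit = fits[[chosen]],
                 per_replicate = per_replicate),
            class = "weighting_selection")
}

#' @export
print.weighting_selection <- function(x, digits = 6, ...) {
  cat(sprintf("Weighting-factor selection by %s sum |%%RE| of back-calculation\n",
              if (x$per_replicate) "replicate-wise" else "pooled"))
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("  chosen: %s (minimum total sum |%%RE| = %.4g)\n", x$chosen,
              min(x$totals)))
  invisible(x)
}

#' Lack-of-fit test for the straight-line calibration model
#'
#' Decomposes the residual sum of squares of the fitted line into
#' lack-of-fit (level means about the line, `df = levels - 2`) and pure
#' error (replicates about their level means, `df = n - levels`)
#' components, in the fit's weight metric.  The statistic
#' `F = MS_lof / MS_pe` is compared to the F quantile at `1 - alpha`.
#'
#' @param data a [calibration_data()] object with replication in at least
#'   one level and >= 3 levels.
#' @param fit the [fit_line()] result under test.
#' @param alpha significance level, default 0.05.
#' @return Object of class `lof_test` with the sums of squares, degrees of
#'   freedom, `f_lof`, `f_crit` and the `linear_ok` verdict.
#' @export
lack_of_fit <- function(data, fit, alpha = 0.05) {
  data <- as_calibration(data)
  stopifnot(inherits(fit, "calibration_fit"))
  lev <- unique(data$conc)
  n <- nrow(data)
  if (length(lev) < 3) stop("lack-of-fit needs >= 3 levels", call. = FALSE)
  if (n - length(lev) < 1) {
    stop("pure error unavailable: no replicated level", call. = FALSE)
  }
  w <- scheme_weights(fit$scheme, data$conc)
  pred <- fit$intercept + fit$slope * data$conc
  level_mean <- stats::ave(data$response, data$conc)
  ss_pe <- sum(w * (data$response - level_mean)^2)
  ss_lof <- sum(w * (level_mean - pred)^2)
  df_lof <- length(lev) - 2L
  df_pe <- n - length(lev)
  ms_pe <- ss_pe / df_pe
  # noiseless data make both components vanish to rounding error
  eps <- 1e-12 * max(sum(w * data$response^2), 1)
  f_lof <- if (ms_pe <= eps / df_pe) {
    if (ss_lof <= eps) 0 else Inf
  } else (ss_lof / df_lof) / ms_pe
  f_crit <- f_critical(1 - alpha, df_lof, df_pe)
  structure(
    list(ss_lack_of_fit = ss_lof, ss_pure_error = ss_pe,
         ss_residual = sum(w * (data$response - pred)^2),
         df_lof = df_lof, df_pe = df_pe,
         f_lof = f_lof, f_crit = f_crit, alpha = alpha,
         linear_ok = f_lof <= f_crit),
    class = "lof_test"
  )
}

#' @export
print.lof_test <- function(x, ...) {
  cat("Lack-of-fit test\n")
  cat(sprintf("  SS_lof = %.6g (df %d), SS_pe = %.6g (df %d)\n",
              x$ss_lack_of_fit, x$df_lof, x$ss_pure_error, x$df_pe))
  cat(sprintf("  F = %.4g vs F_crit(%g) = %.4g -> %s\n", x$f_lof,
              1 - x$alpha, x$f_crit,
              if (x$linear_ok) "straight line adequate" else "lack of fit"))
  invisible(x)
}

#' Regression ANOVA and coefficient significance
#'
#' Standard errors from the (weighted) least-squares covariance, two-sided
#' t tests of slope != 0 and intercept != 0, and the regression F
#' statistic `MS_regression / MS_residual`.  A valid calibration has a
#' slope significantly different from zero and an intercept that is not.
#'
#' Noiseless data make the residual mean square vanish; such fits are
#' flagged `degenerate` (the t statistics are not meaningful there).
#'
#' @param data a [calibration_data()] object.
#' @param fit the [fit_line()] result.
#' @return Object of class `regression_anova` with `f_reg`, `p_slope`,
#'   `p_intercept`, `se_slope`, `se_intercept`, `df_residual`,
#'   `degenerate`.
#' @export
regression_anova <- function(data, fit) {
  data <- as_calibration(data)
  stopifnot(inherits(fit, "calibration_fit"))
  if (nrow(data) < 3) stop("need n >= 3 for regression ANOVA", call. = FALSE)
  sm <- suppressWarnings(summary(fit$lm))  # degeneracy flagged below
  co <- sm$coefficients
  w <- fit$weights
  y <- data$conc * fit$slope + fit$intercept
  ss_res <- sum(w * (data$response - y)^2)
  wm <- sum(w * data$response) / sum(w)
  ss_tot <- sum(w * (data$response - wm)^2)
  ss_reg <- ss_tot - ss_res
  df_res <- fit$n - 2L
  degenerate <- ss_res <= 1e-12 * max(ss_tot, 1)
  f_reg <- if (ss_res == 0) Inf else (ss_reg / 1) / (ss_res / df_res)
  structure(
    list(f_reg = f_reg,
         p_slope = unname(co["conc", "Pr(>|t|)"]),
         p_intercept = unname(co["(Intercept)", "Pr(>|t|)"]),
         se_slope = unname(co["conc", "Std. Error"]),
         se_intercept = unname(co["(Intercept)", "Std. Error"]),
         df_residual = df_res, degenerate = degenerate),
    class = "regression_anova"
  )
}

#' @export
print.regression_anova <- function(x, ...) {
  cat("Regression ANOVA\n")
  if (x$degenerate) cat("  (degenerate: residual variance ~ 0)\n")
  cat(sprintf("  F_reg = %.6g; slope p = %.3g (se %.4g); intercept p = %.3g (se %.4g)\n",
              x$f_reg, x$p_slope, x$se_slope, x$p_intercept, x$se_intercept))
  invisible(x)
}
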