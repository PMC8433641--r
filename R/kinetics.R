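#' Construct a degradation time course
#'
#' One replicate's concentration-versus-time series under a single
#' condition (buffer pH, temperature).
#'
#' @param time_h sampling times, h, non-negative and strictly increasing.
#' @param conc measured concentrations, ug/mL.
#' @param condition condition label, e.g. `"pH 1.2"`.
#' @param replicate replicate label.
#' @return Data frame of class `kinetic_timecourse` with columns
#'   `condition`, `replicate`, `time_h`, `conc`.
#' @export
kinetic_timecourse <- function(time_h, conc, condition = "condition",
                               replicate = "1") {
  if (length(time_h) != length(conc) || length(time_h) < 3) {
    stop("need >= 3 matched (time, concentration) points", call. = FALSE)
  }
  if (any(time_h < 0) || any(diff(time_h) <= 0)) {
    stop("'time_h' must be non-negative and strictly increasing", call. = FALSE)
  }
  d <- data.frame(condition = as.character(condition),
                  replicate = as.character(replicate),
                  time_h = time_h, conc = conc)
  class(d) <- c("kinetic_timecourse", "data.frame")
  d
}

.sia_orders <- c("zero", "first", "second")

order_transform <- function(order, conc) {
  switch(order, zero = conc, first = log(conc), second = 1 / conc)
}

#' Fit a rate law of given order to a degradation time course
#'
#' Ordinary least squares of the order's transformed concentration on
#' time: C for zero order, ln C for (pseudo-)first order, 1/C for second
#' order.  The rate constant is `-slope` for zero/first order and
#' `+slope` for second order; r^2 is that of the transformed regression.
#'
#' First- and second-order transforms require positive concentrations;
#' by default points at or below zero (complete degradation) are dropped
#' with a warning (`on_nonpositive = "error"` aborts instead, naming the
#' offending point).
#'
#' @param tc a [kinetic_timecourse()] (or data frame with `time_h`,
#'   `conc`).
#' @param order `"zero"`, `"first"` or `"second"`.
#' @param on_nonpositive `"drop"` (default) or `"error"`.
#' @return Object of class `kinetic_fit` with `order`, `k`, `c0_est`,
#'   `r2`, `slope`, `intercept`, `n`, `condition`, `replicate`.
#' @examples
#' tc <- kinetic_timecourse(seq(0, 24, 2), 5 * exp(-0.045 * seq(0, 24, 2)))
#' fit_order(tc, "first")
#' @export
fit_order <- function(tc, order = c("first", "zero", "second"),
                      on_nonpositive = c("drop", "error")) {
  order <- match.arg(order)
  on_nonpositive <- match.arg(on_nonpositive)
  if (!is.data.frame(tc) || !all(c("time_h", "conc") %in% names(tc))) {
    stop("'tc' needs columns time_h and conc", call. = FALSE)
  }
  t <- tc$time_h
  c_obs <- tc$conc
  if (order != "zero" && any(c_obs <= 0)) {
    bad <- which(c_obs <= 0)
    if (on_nonpositive == "error") {
      stop(sprintf("non-positive concentration at time %g h (point %d) invalid for %s-order transform",
                   t[bad[1]], bad[1], order), call. = FALSE)
    }
    warning(sprintf("dropping %d non-positive concentration(s) for the %s-order transform",
                    length(bad), order))
    t <- t[-bad]
    c_obs <- c_obs[-bad]
  }
  if (length(t) < 3) {
    stop("fewer than 3 usable points for the kinetic fit", call. = FALSE)
  }
  y <- order_transform(order, c_obs)
  fit <- stats::lm(y ~ t)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  slope <- unname(stats::coef(fit)["t"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  k <- if (order == "second") slope else -slope
  c0 <- switch(order, zero = intercept, first = exp(intercept),
               second = 1 / intercept)
  structure(
    list(order = order, k = k, c0_est = c0,
         r2 = r2,
         slope = slope, intercept = intercept, n = length(t),
         condition = if ("condition" %in% names(tc)) tc$condition[1] else NA,
         replicate = if ("replicate" %in% names(tc)) tc$replicate[1] else NA),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s-order fit: k = %.6g, C0 = %.4g ug/mL, r^2 = %.4f (n = %d)\n",
              x$order, x$k, x$c0_est, x$r2, x$n))
  invisible(x)
}

#' Degradation half-life
#'
#' `t1/2 = ln 2 / k` (first order), `C0 / (2 k)` (zero order) or
#' `1 / (k C0)` (second order).
#'
#' @param k rate constant, > 0.  Units: h^-1 (first),
#'   ug mL^-1 h^-1 (zero), mL ug^-1 h^-1 (second).
#' @param order rate-law order.
#' @param c0 initial concentration, required (and > 0) for zero and
#'   second order.
#' @return Half-life in hours.
#' @examples
#' half_life(0.045)  # 15.40 h
#' @export
half_life <- function(k, order = c("first", "zero", "second"), c0 = NULL) {
  order <- match.arg(order)
  if (any(k <= 0)) stop("'k' must be > 0", call. = FALSE)
  if (order == "first") return(log(2) / k)
  if (is.null(c0) || any(c0 <= 0)) {
    stop(sprintf("'c0' > 0 required for %s-order half-life", order),
         call. = FALSE)
  }
  switch(order, zero = c0 / (2 * k), second = 1 / (k * c0))
}

#' Aggregate replicate kinetic fits of one condition
#'
#' The replicate-aggregation convention: each replicate is fitted
#' separately, and both the rate constant and the half-life are averaged
#' across replicates (mean +/- sample sd).  Because the half-life is a
#' convex function of k, `mean(ln2 / k_i)` exceeds `ln2 / mean(k_i)`
#' (Jensen); the per-replicate convention is the one that reproduces
#' replicate-averaged kinetic tables.
#'
#' @param fits list of [fit_order()] results sharing condition and order.
#' @return Object of class `kinetic_summary` with `condition`, `order`,
#'   `k_mean`, `k_sd`, `t_half_mean`, `t_half_sd`, `n_replicates`.
#'   With a single replicate the sds are `NA`.
#' @export
summarize_kinetics <- function(fits) {
  if (!is.list(fits) || length(fits) < 1 ||
      !all(vapply(fits, inherits, logical(1), "kinetic_fit"))) {
    stop("'fits' must be a non-empty list of kinetic_fit objects", call. = FALSE)
  }
  orders <- unique(vapply(fits, `[[`, character(1), "order"))
  if (length(orders) != 1) stop("fits must share one order", call. = FALSE)
  conds <- unique(vapply(fits, function(f) as.character(f$condition), character(1)))
  if (length(conds) != 1) stop("fits must share one condition", call. = FALSE)
  ks <- vapply(fits, `[[`, numeric(1), "k")
  th <- vapply(fits, function(f) half_life(f$k, f$order, f$c0_est), numeric(1))
  n <- length(fits)
  structure(
    list(condition = conds, order = orders,
         k_mean = mean(ks), k_sd = if (n > 1) stats::sd(ks) else NA_real_,
         t_half_mean = mean(th),
         t_half_sd = if (n > 1) stats::sd(th) else NA_real_,
         k_values = ks, t_half_values = th, n_replicates = n),
    class = "kinetic_summary"
  )
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat(sprintf("%s (%s order, n = %d): k = %.4g +/- %.2g h^-1, t1/2 = %.4g +/- %.2g h\n",
              x$condition, x$order, x$n_replicates, x$k_mean,
              x$k_sd, x$t_half_mean, x$t_half_sd))
  invisible(x)
}

#' Select the rate-law order by mean r-squared across replicates
#'
#' Fits every replicate time course under each candidate order, averages
#' the r^2 of the transformed regressions per order, and selects the
#' order with the highest mean r^2 (ties break toward the lower order).
#' Returns the per-order r^2 table, the chosen-order fits and their
#' [summarize_kinetics()] aggregate.
#'
#' @param tcs either a list of [kinetic_timecourse()] objects or a single
#'   data frame with columns `condition`, `replicate`, `time_h`, `conc`
#'   (split by replicate internally).  All must share one condition.
#' @param orders candidate orders, default all three.
#' @param on_nonpositive forwarded to [fit_order()].
#' @return Object of class `order_selection` with `r2_table` (order x
#'   mean r^2), `chosen_order`, `fits` (chosen order, per replicate) and
#'   `summary`.
#' @export
select_order <- function(tcs, orders = c("zero", "first", "second"),
                         on_nonpositive = "drop") {
  orders <- match.arg(orders, .sia_orders, several.ok = TRUE)
  if (is.data.frame(tcs)) {
    if (!all(c("replicate", "time_h", "conc") %in% names(tcs))) {
      stop("data frame form needs columns replicate, time_h, conc", call. = FALSE)
    }
    tcs <- split(tcs, tcs$replicate)
  }
  if (length(tcs) < 1) stop("need at least one replicate", call. = FALSE)
  all_fits <- lapply(orders, function(o) {
    lapply(tcs, fit_order, order = o, on_nonpositive = on_nonpositive)
  })
  names(all_fits) <- orders
  mean_r2 <- vapply(all_fits, function(fl) {
    mean(vapply(fl, `[[`, numeric(1), "r2"))
  }, numeric(1))
  # ties break toward the lower order: scan in zero < first < second order
  ord_rank <- orders[order(match(orders, .sia_orders))]
  chosen <- ord_rank[which.max(mean_r2[ord_rank])]
  fits <- all_fits[[chosen]]
  structure(
    list(r2_table = data.frame(order = orders, mean_r2 = unname(mean_r2)),
         chosen_order = chosen, fits = fits,
         summary = summarize_kinetics(unname(fits))),
    class = "order_selection"
  )
}

#' @export
print.order_selection <- function(x, ...) {
  cat("Kinetic order selection (mean r^2 across replicates)\n")
  print(format(x$r2_table, digits = 4), row.names = FALSE)
  cat(sprintf("  chosen: %s order\n", x$chosen_order))
  print(x$summary)
  invisible(x)
}
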