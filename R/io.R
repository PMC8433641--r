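# CSV schemas for the peak-table dialects the pipeline consumes.
# Each schema lists required/optional columns and per-column constraints;
# violations are reported with row and column names.
.sia_schemas <- list(
  calibration = list(
    required = c("level_conc_ug_ml", "replicate", "response"),
    positive = c("level_conc_ug_ml"),
    numeric = c("level_conc_ug_ml", "response")
  ),
  suitability = list(
    required = c("injection_id", "rt_min", "area"),
    optional = c("w_half_min", "w_5pct_min", "f_5pct_min", "tailing", "plates"),
    positive = c("rt_min"),
    numeric = c("rt_min", "area", "w_half_min", "w_5pct_min", "f_5pct_min",
                "tailing", "plates")
  ),
  sensitivity = list(
    required = c("conc_ug_ml", "replicate", "response"),
    optional = c("found_conc", "sn"),
    positive = c("conc_ug_ml"),
    numeric = c("conc_ug_ml", "response", "found_conc", "sn")
  ),
  qc = list(
    required = c("added_conc_ug_ml", "found_conc_ug_ml"),
    optional = c("level", "day", "replicate"),
    positive = c("added_conc_ug_ml"),
    numeric = c("added_conc_ug_ml", "found_conc_ug_ml")
  ),
  stress = list(
    required = c("condition", "incubation_h", "response", "control_response"),
    positive = c("control_response"),
    numeric = c("incubation_h", "response", "control_response")
  ),
  kinetics = list(
    required = c("condition", "replicate", "time_h", "conc_ug_ml"),
    positive = character(),
    numeric = c("time_h", "conc_ug_ml")
  ),
  blank = list(
    required = c("time", "signal"),
    positive = character(),
    numeric = c("time", "signal")
  )
)

#' Read and validate a peak-table CSV
#'
#' Reads one of the pipeline's CSV dialects and validates it against the
#' named schema: required columns present, numeric columns parse, and
#' positivity constraints hold.  Errors name the offending row and
#' column.
#'
#' @param path path to a CSV file with a header row.
#' @param schema one of `"calibration"`, `"suitability"`,
#'   `"sensitivity"`, `"qc"`, `"stress"`, `"kinetics"`, `"blank"`.
#' @return A validated data frame.  The calibration schema returns a
#'   [calibration_data()] object (columns renamed to `conc`, `response`,
#'   `replicate`).
#' @export
read_sia_table <- function(path, schema) {
  schema <- match.arg(schema, names(.sia_schemas))
  sc <- .sia_schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty table: ", path, call. = FALSE)
  missing <- setdiff(sc$required, names(d))
  if (length(missing)) {
    stop(sprintf("schema '%s': missing column(s) %s in %s", schema,
                 paste(missing, collapse = ", "), path), call. = FALSE)
  }
  for (col in intersect(sc$numeric, names(d))) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad)) {
      stop(sprintf("schema '%s': non-numeric value in column '%s', row %d",
                   schema, col, bad[1]), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("schema '%s': missing value in column '%s', row %d",
                   schema, col, which(is.na(v))[1]), call. = FALSE)
    }
    d[[col]] <- v
  }
  for (col in intersect(sc$positive, names(d))) {
    bad <- which(d[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("schema '%s': column '%s' must be > 0 (row %d)",
                   schema, col, bad[1]), call. = FALSE)
    }
  }
  if (schema == "calibration") {
    return(calibration_data(d$level_conc_ug_ml, d$response, d$replicate))
  }
  d
}

#' Write a generated fixture in its CSV dialect
#'
#' Inverse of [read_sia_table()] for the objects the synthetic generators
#' produce, so a write-read round trip is lossless.
#'
#' @param x a `calibration_data`, suitability injection data frame, or a
#'   list of / single `kinetic_timecourse`.
#' @param path output CSV path.
#' @param schema the dialect to write (see [read_sia_table()]).
#' @return `path`, invisibly.
#' @export
write_sia_table <- function(x, path, schema) {
  schema <- match.arg(schema, names(.sia_schemas))
  d <- switch(schema,
    calibration = data.frame(level_conc_ug_ml = x$conc,
                             replicate = x$replicate, response = x$response),
    kinetics = {
      if (inherits(x, "kinetic_timecourse")) x <- list(x)
      do.call(rbind, lapply(x, function(tc) {
        data.frame(condition = tc$condition, replicate = tc$replicate,
                   time_h = tc$time_h, conc_ug_ml = tc$conc)
      }))
    },
    as.data.frame(x)
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the input tables (paths or in-memory data frames), acceptance
#' limits and significance levels used by [run_pipeline()].  Any input
#' left `NULL` while `simulate = TRUE` is generated from the synthetic
#' defaults under the configured seed.
#'
#' @param calibration,suitability,sensitivity_blank,qc,stress,kinetics
#'   CSV paths or data frames in the corresponding dialect; `NULL` to
#'   simulate (or to skip, when `simulate = FALSE`).
#' @param stages stages to run, a subset of the default ordering.
#' @param r2_min minimum coefficient of determination for linearity.
#' @param alpha_homoscedasticity,alpha_lof significance levels.
#' @param weighting_candidates candidate weighting schemes.
#' @param limits a [suitability_limits()] list.
#' @param recovery_band inclusive accuracy band in percent.
#' @param qc_cv_max precision limit in %, default 7.3 (15 at the LOQ).
#' @param sn_lod,sn_loq signal-to-noise thresholds.
#' @param re_band_loq,re_band_other back-calculation %RE bands.
#' @param simulate generate missing inputs from the synthetic module?
#' @param seed integer seed driving every simulated input.
#' @return Object of class `sia_config` (a validated list).
#' @export
sia_config <- function(calibration = NULL, suitability = NULL,
                       sensitivity_blank = NULL, qc = NULL, stress = NULL,
                       kinetics = NULL,
                       stages = c("suitability", "linearity", "sensitivity",
                                  "accuracy", "stability", "kinetics"),
                       r2_min = 0.995,
                       alpha_homoscedasticity = 0.01, alpha_lof = 0.05,
                       weighting_candidates = c("unit", "1/x", "1/x^2"),
                       limits = suitability_limits(),
                       recovery_band = c(80, 110), qc_cv_max = 7.3,
                       sn_lod = 3, sn_loq = 10,
                       re_band_loq = 20, re_band_other = 15,
                       simulate = TRUE, seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (r2_min <= 0) stop("'r2_min' must be positive", call. = FALSE)
  for (a in c(alpha_homoscedasticity, alpha_lof)) {
    if (a <= 0 || a >= 1) stop("alpha levels must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(inputs = list(calibration = calibration, suitability = suitability,
                       sensitivity_blank = sensitivity_blank, qc = qc,
                       stress = stress, kinetics = kinetics),
         stages = stages, r2_min = r2_min,
         alpha_homoscedasticity = alpha_homoscedasticity,
         alpha_lof = alpha_lof,
         weighting_candidates = weighting_candidates,
         limits = limits, recovery_band = recovery_band,
         qc_cv_max = qc_cv_max, sn_lod = sn_lod, sn_loq = sn_loq,
         re_band_loq = re_band_loq, re_band_other = re_band_other,
         simulate = isTRUE(simulate), seed = as.integer(seed)),
    class = "sia_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [sia_config()]; unknown keys are
#' rejected.  Input paths are resolved relative to the config file.
#'
#' @param path YAML file path.
#' @return A `sia_config` object.
#' @export
read_sia_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sia_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  for (key in c("calibration", "suitability", "sensitivity_blank", "qc",
                "stress", "kinetics")) {
    if (!is.null(cfg[[key]]) && is.character(cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  do.call(sia_config, cfg)
}

resolve_input <- function(x, schema) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) return(read_sia_table(x, schema))
  x
}

#' Run the full validation / kinetics pipeline
#'
#' Executes the requested stages in order (suitability, linearity,
#' sensitivity, accuracy, stability, kinetics), assembling a
#' [render_report()]-able report.  A stage failure is recorded under
#' `errors` and does not abort the remaining stages.
#'
#' @param config a [sia_config()].
#' @return Object of class `sia_report`: per-stage sections plus a
#'   provenance block (config, seed, package version).
#' @export
run_pipeline <- function(config = sia_config()) {
  stopifnot(inherits(config, "sia_config"))
  report <- list(sections = list(), errors = list(),
                 provenance = list(seed = config$seed,
                                   stages = config$stages,
                                   package = "siaval",
                                   version = as.character(
                                     utils::packageVersion("siaval"))))
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report$errors[[name]] <<- conditionMessage(res)
    } else {
      report$sections[[name]] <<- res
    }
  }

  if ("suitability" %in% config$stages) run_stage("suitability", {
    inj <- resolve_input(config$inputs$suitability, "suitability")
    if (is.null(inj)) {
      if (!config$simulate) stop("no suitability input and simulate = FALSE")
      inj <- gen_suitability(suitability_sim_spec(seed = config$seed))
    }
    suitability_report(inj, limits = config$limits)
  })

  if ("linearity" %in% config$stages) run_stage("linearity", {
    cal <- resolve_input(config$inputs$calibration, "calibration")
    if (is.null(cal)) {
      if (!config$simulate) stop("no calibration input and simulate = FALSE")
      cal <- gen_calibration(calibration_sim_spec(seed = config$seed))
    }
    lv <- sort(unique(cal$conc))
    hom <- homoscedasticity_test(cal$response[cal$conc == lv[1]],
                                 cal$response[cal$conc == max(lv)],
                                 alpha = config$alpha_homoscedasticity)
    sel <- select_weighting(cal, config$weighting_candidates)
    fit <- sel$chosen_fit
    list(homoscedasticity = hom, selection = sel, fit = fit,
         back_calc = back_calc_table(fit, cal, config$re_band_loq,
                                     config$re_band_other),
         lof = lack_of_fit(cal, fit, alpha = config$alpha_lof),
         anova = regression_anova(cal, fit),
         r2_ok = check_rule(acceptance_rule("r^2", lower = config$r2_min,
                                            context = "linearity"),
                            fit$r2))
  })

  if ("sensitivity" %in% config$stages) run_stage("sensitivity", {
    blank <- config$inputs$sensitivity_blank
    if (is.null(blank)) {
      if (!config$simulate) stop("no blank input and simulate = FALSE")
      blank <- gen_blank(500, sd = 30, seed = config$seed)
    } else if (is.character(blank)) {
      blank <- read_sia_table(blank, "blank")$signal
    } else if (is.data.frame(blank)) {
      blank <- blank$signal
    }
    noise <- estimate_noise(blank, "rms")
    # emulate LOD/LOQ injections off the default calibration line
    set.seed(stream_seed(config$seed, "qc"))
    lod_resp <- draw_positive(rep(noise$amplitude * 3.5, 5),
                              rep(noise$amplitude * 0.2, 5))
    loq_found <- draw_positive(rep(0.095, 5), rep(0.002, 5))
    loq_sn <- signal_to_noise(as.numeric(
      draw_positive(rep(noise$amplitude * 12, 5),
                    rep(noise$amplitude * 0.5, 5))), noise)$sn
    list(noise = noise,
         lod = assess_lod(as.numeric(lod_resp), noise, conc = 0.04,
                          sn_min = config$sn_lod),
         loq = assess_loq(0.10, as.numeric(loq_found), loq_sn,
                          sn_min = config$sn_loq,
                          recovery_band = config$recovery_band))
  })

  if ("accuracy" %in% config$stages) run_stage("accuracy", {
    qc <- resolve_input(config$inputs$qc, "qc")
    if (is.null(qc)) {
      if (!config$simulate) stop("no QC input and simulate = FALSE")
      set.seed(stream_seed(config$seed, "qc") + 1L)
      lev <- rep(c(0.10, 12.5, 25), each = 3)
      qc <- data.frame(added_conc_ug_ml = lev,
                       found_conc_ug_ml = as.numeric(
                         draw_positive(lev, 0.01 * lev)))
    }
    rec <- recovery(qc$added_conc_ug_ml, qc$found_conc_ug_ml)
    lv <- sort(unique(qc$added_conc_ug_ml))
    rows <- lapply(lv, function(l) {
      r <- rec$recovery_percent[qc$added_conc_ug_ml == l]
      f <- qc$found_conc_ug_ml[qc$added_conc_ug_ml == l]
      cv_lim <- if (l == min(lv)) 15 else config$qc_cv_max
      s <- summarize_values(f)
      data.frame(added = l, n = length(r), mean_recovery = mean(r),
                 cv_percent = s$cv_percent,
                 recovery_ok = mean(r) >= config$recovery_band[1] &
                   mean(r) <= config$recovery_band[2],
                 cv_ok = s$cv_percent <= cv_lim)
    })
    do.call(rbind, rows)
  })

  if ("stability" %in% config$stages) run_stage("stability", {
    st <- resolve_input(config$inputs$stress, "stress")
    if (is.null(st)) {
      if (!config$simulate) stop("no stress input and simulate = FALSE")
      set.seed(stream_seed(config$seed, "qc") + 2L)
      conds <- c("control", "acid", "base", "oxidative", "moisture",
                 "thermal", "photolytic")
      ctrl <- 56000
      frac <- c(1, 0.78, 0.03, 0.92, 0.97, 1.01, 0.01)
      st <- data.frame(condition = conds, incubation_h = c(0, 3, 3, 1, 3, 3, 120),
                       response = as.numeric(
                         draw_positive(ctrl * frac, 0.005 * ctrl * frac)),
                       control_response = ctrl)
    }
    stress_table(st)
  })

  if ("kinetics" %in% config$stages) run_stage("kinetics", {
    kin <- resolve_input(config$inputs$kinetics, "kinetics")
    if (is.null(kin)) {
      if (!config$simulate) stop("no kinetics input and simulate = FALSE")
      tcs <- gen_decay(decay_sim_spec(seed = config$seed))
      kin <- do.call(rbind, lapply(tcs, function(tc) {
        data.frame(condition = tc$condition, replicate = tc$replicate,
                   time_h = tc$time_h, conc_ug_ml = tc$conc)
      }))
    }
    by_cond <- split(kin, kin$condition)
    lapply(by_cond, function(d) {
      d2 <- data.frame(condition = d$condition, replicate = d$replicate,
                       time_h = d$time_h, conc = d$conc_ug_ml)
      select_order(d2)
    })
  })

  class(report) <- "sia_report"
  report
}

#' @export
print.sia_report <- function(x, ...) {
  cat("Assay validation report (stages:",
      paste(names(x$sections), collapse = ", "), ")\n")
  if (length(x$errors)) {
    cat("Stage errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}

# strip non-serialisable members (lm fits, nested data) for JSON output
report_payload <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "lm")) return(NULL)
    if (is.function(x)) return(NULL)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) {
      x <- x[!vapply(x, function(e) inherits(e, "lm") || is.function(e),
                     logical(1))]
      return(lapply(unclass(x), simplify))
    }
    x
  }
  list(provenance = report$provenance,
       sections = simplify(report$sections),
       errors = report$errors)
}

#' Render a pipeline report
#'
#' Deterministic rendering of a [run_pipeline()] report, either as a
#' machine-readable JSON document or as human-readable text whose numeric
#' cells are the machine-readable values after display rounding.
#'
#' @param report a `sia_report`.
#' @param format `"json"` or `"text"`.
#' @return A character scalar (the rendered document).
#' @export
render_report <- function(report, format = c("json", "text")) {
  stopifnot(inherits(report, "sia_report"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_payload(report),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", force = TRUE)))
  }
  out <- utils::capture.output({
    print(report)
    for (nm in names(report$sections)) {
      cat("\n== ", nm, " ==\n", sep = "")
      sec <- report$sections[[nm]]
      if (is.data.frame(sec)) {
        print(format(sec, digits = 6), row.names = FALSE)
      } else if (nm == "kinetics") {
        for (cond in names(sec)) print(sec[[cond]])
      } else if (is.list(sec) && !is.object(sec)) {
        for (el in sec) if (is.object(el) || is.data.frame(el)) print(el)
      } else {
        print(sec)
      }
    }
  })
  paste(out, collapse = "\n")
}
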