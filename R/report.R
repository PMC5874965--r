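report_schema_version <- "1.0"

#' Validate an analysis configuration
#'
#' Builds the configuration object consumed by [run_full_analysis()] and the
#' command-line tool. Every field is checked against the preconditions of the
#' downstream operations; unknown fields are rejected.
#'
#' @param input Path to a QA log CSV ([read_qa_log()] dialect).
#' @param units,axes Optional selectors; default: every unit/axis present.
#' @param window_size Observations per analysis window (default 90).
#' @param action_limits_mm Numeric vector of symmetric action levels to
#'   assess capability at; default `c(1, 2)` for the +/-1 and +/-2 mm bands.
#' @param action_limit_mm The clinical action level used for point flags and
#'   verdicts; default 2.
#' @param alpha Normality-test significance level, in (0, 1).
#' @param baseline_reference Baseline value window means are compared to, mm.
#' @param drift_threshold_mm Center-line drift considered systematic.
#' @param out Optional path for the JSON report.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(input, units = NULL, axes = NULL,
                            window_size = 90L, action_limits_mm = c(1, 2),
                            action_limit_mm = 2, alpha = 0.05,
                            baseline_reference = 0, drift_threshold_mm = 0.5,
                            out = NULL) {
  if (!is.character(input) || length(input) != 1L) {
    stop("config: 'input' must be a single file path", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("config: 'alpha' must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(window_size) || window_size < 8) {
    stop("config: 'window_size' must be >= 8", call. = FALSE)
  }
  if (!is.numeric(action_limits_mm) || length(action_limits_mm) < 1L ||
      any(action_limits_mm <= 0)) {
    stop("config: 'action_limits_mm' must be positive", call. = FALSE)
  }
  if (!is.numeric(action_limit_mm) || action_limit_mm <= 0) {
    stop("config: 'action_limit_mm' must be positive", call. = FALSE)
  }
  if (!is.null(axes)) axes <- match.arg(axes, qa_axes, several.ok = TRUE)
  structure(
    list(input = input, units = units, axes = axes,
         window_size = as.integer(window_size),
         action_limits_mm = sort(action_limits_mm),
         action_limit_mm = action_limit_mm, alpha = alpha,
         baseline_reference = baseline_reference,
         drift_threshold_mm = drift_threshold_mm, out = out),
    class = "analysis_config"
  )
}

#' Load an analysis configuration from YAML or JSON
#'
#' Reads a config file whose keys are the arguments of [analysis_config()];
#' unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- setdiff(names(formals(analysis_config)), "")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, cfg)
}

window_report_to_list <- function(r) {
  list(
    window_index = r$window_index,
    start = r$start, end = r$end, n = r$n, partial = r$partial,
    cl = r$limits$center, ucl = r$limits$ucl, lcl = r$limits$lcl,
    mr_bar = r$limits$mr_bar, sigma_within = r$limits$sigma_within,
    mean_variation_mm = r$mean_variation_mm,
    n_beyond_spc = r$n_beyond_spc,
    n_beyond_action = r$n_beyond_action,
    ad = if (is.null(r$ad)) NULL else list(
      a2 = r$ad$a2, a2_star = r$ad$a2_star, p = r$ad$p_value, h = r$ad$h
    ),
    capability = lapply(r$capability, function(cap) list(
      lsl = cap$spec$lsl, usl = cap$spec$usl, cp = cap$cp, cpk = cap$cpk,
      sigma = cap$sigma, mean = cap$mean, acceptable = cap$acceptable
    ))
  )
}

#' Run the full windowed QA analysis over a measurement log
#'
#' Reads a QA log, and for every selected (unit, axis) runs the windowed
#' trend analysis -- individuals-chart limits and flags, Anderson-Darling
#' normality, capability at each configured action level, mean variation
#' from baseline -- plus a phase comparison of consecutive full windows to
#' detect systematic shifts. The report's overall recommendation is
#' `"within control"` only if no window shows control-limit or action-limit
#' violations and no consecutive-window comparison returns a
#' `systematic_shift` verdict; otherwise `"investigate"`.
#'
#' @param config An [analysis_config()] (or a path to a YAML/JSON config).
#' @return Object of class `qa_report`: a nested list (schema version,
#'   per-series window reports and verdicts, recommendation). If
#'   `config$out` is set the report is also written there as JSON.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  records <- read_qa_log(config$input, unit_filter = config$units,
                         axis_filter = config$axes)
  if (nrow(records) == 0L) {
    stop("no records match the configured selection", call. = FALSE)
  }
  specs <- lapply(config$action_limits_mm, function(a) spec_limits(-a, a))
  combos <- unique(records[c("unit_id", "axis")])
  combos <- combos[order(combos$unit_id, match(combos$axis, qa_axes)), ]

  series_reports <- lapply(seq_len(nrow(combos)), function(k) {
    unit <- combos$unit_id[k]
    axis <- combos$axis[k]
    series <- to_series(records, unit, axis)
    trend <- trend_analysis(series, window_size = config$window_size,
                            specs = specs,
                            baseline_reference = config$baseline_reference,
                            alpha = config$alpha,
                            action_limit_mm = config$action_limit_mm)
    full <- Filter(function(r) !r$partial, trend$reports)
    phase_verdicts <- if (length(full) >= 2L) {
      lapply(seq_len(length(full) - 1L), function(j) {
        a <- full[[j]]; b <- full[[j + 1L]]
        cmp <- compare_phases(
          qa_series(series$values[a$start:a$end], unit_id = unit, axis = axis),
          qa_series(series$values[b$start:b$end], unit_id = unit, axis = axis),
          specs = specs, drift_threshold_mm = config$drift_threshold_mm,
          action_limit_mm = config$action_limit_mm, alpha = config$alpha
        )
        list(window_a = a$window_index, window_b = b$window_index,
             delta_cl = cmp$delta_cl,
             limits_respected_in_b = cmp$limits_respected_in_b,
             verdict = cmp$verdict)
      })
    } else list()
    list(unit_id = unit, axis = axis, n = series$n,
         windows = lapply(trend$reports, window_report_to_list),
         phase_comparisons = phase_verdicts)
  })

  any_shift <- any(vapply(series_reports, function(sr) {
    any(vapply(sr$phase_comparisons, function(p) {
      p$verdict == "systematic_shift"
    }, logical(1)))
  }, logical(1)))
  any_flag <- any(vapply(series_reports, function(sr) {
    any(vapply(sr$windows, function(w) {
      w$n_beyond_spc > 0L || w$n_beyond_action > 0L
    }, logical(1)))
  }, logical(1)))

  report <- structure(
    list(
      schema_version = report_schema_version,
      input = config$input,
      window_size = config$window_size,
      action_limits_mm = config$action_limits_mm,
      alpha = config$alpha,
      series = series_reports,
      any_systematic_shift = any_shift,
      any_point_violation = any_flag,
      recommendation = if (any_shift || any_flag) "investigate" else "within control"
    ),
    class = "qa_report"
  )
  if (!is.null(config$out)) write_report_json(report, config$out)
  report
}

#' Write an analysis report as JSON
#'
#' @param report A `qa_report` from [run_full_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("QA analysis report (schema %s): %s\n", x$schema_version, x$input))
  cat(sprintf("  window size %d, action limits +/-%s mm, alpha %g\n",
              x$window_size, paste(x$action_limits_mm, collapse = "/"), x$alpha))
  for (sr in x$series) {
    n_shift <- sum(vapply(sr$phase_comparisons, function(p) {
      p$verdict == "systematic_shift"
    }, logical(1)))
    cat(sprintf("  %s %s: n = %d, %d window(s), %d systematic shift(s)\n",
                sr$unit_id, sr$axis, sr$n, length(sr$windows), n_shift))
  }
  cat("  recommendation:", x$recommendation, "\n")
  invisible(x)
}
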