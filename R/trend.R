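#' Partition a QA series into fixed-size analysis windows
#'
#' Slices a long measurement series into consecutive non-overlapping windows
#' of `window_size` observations -- at a daily measurement cadence, 90
#' observations correspond to a three-monthly review period. A trailing
#' partial window is returned flagged (attribute `"partial"`) so downstream
#' capability and normality analyses can exclude it.
#'
#' @param series A [qa_series].
#' @param window_size Observations per window, >= 8.
#' @return List of [qa_series]; each carries attributes `"window_index"`
#'   (1-based), `"start"` (1-based index of its first observation in the
#'   parent series) and `"partial"`.
#' @examples
#' s <- qa_series(rnorm(100))
#' lengths <- vapply(partition_windows(s, 90), function(w) w$n, integer(1))
#' lengths  # 90 and a partial 10
#' @export
partition_windows <- function(series, window_size = 90L) {
  series <- as_qa_series(series)
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      is.na(window_size) || window_size < 8) {
    stop("window_size must be an integer >= 8", call. = FALSE)
  }
  w <- as.integer(window_size)
  starts <- seq.int(1L, series$n, by = w)
  lapply(seq_along(starts), function(k) {
    i <- starts[k]
    j <- min(i + w - 1L, series$n)
    win <- qa_series(series$values[i:j], timestamps = series$timestamps[i:j],
                     unit_id = series$unit_id, axis = series$axis)
    attr(win, "window_index") <- k
    attr(win, "start") <- i
    attr(win, "partial") <- (j - i + 1L) < w
    win
  })
}

#' Full SPC analysis of one window
#'
#' Runs the individuals chart, the Anderson-Darling normality test and a
#' capability assessment at each configured action level on a single analysis
#' window, and reports the window mean's variation from the baseline
#' reference (0 mm by construction for offset data, since offsets are
#' deviations from baseline).
#'
#' @param window A [qa_series] with n >= 8, non-constant.
#' @param specs List of [spec_limits()] to assess capability against.
#' @param baseline_reference Reference value the window center line is
#'   compared to, mm.
#' @param alpha Significance level of the normality test.
#' @param action_limit_mm Clinical action level for point flags.
#' @return Object of class `window_report`: list with `window_index`,
#'   `start`, `end` (1-based inclusive), `n`, `partial`, `limits`
#'   ([spc_chart]), `ad` ([ad_test] or `NULL` for partial windows),
#'   `capability` (list of [capability_result], `NULL` for partial windows),
#'   `mean_variation_mm`, `n_beyond_spc`, `n_beyond_action`.
#' @export
analyze_window <- function(window, specs = list(spec_limits(-2, 2)),
                           baseline_reference = 0, alpha = 0.05,
                           action_limit_mm = 2) {
  window <- as_qa_series(window)
  if (inherits(specs, "spec_limits")) specs <- list(specs)
  if (window$n < 8L) {
    stop("analysis windows need at least 8 observations", call. = FALSE)
  }
  idx <- attr(window, "window_index")
  start <- attr(window, "start")
  partial <- isTRUE(attr(window, "partial"))
  chart <- spc_chart(window, action_limit_mm = action_limit_mm)
  # Partial trailing windows keep the chart but skip AD and capability: at
  # reduced n both become unstable.
  ad <- if (partial) NULL else ad_test(window, alpha = alpha)
  capability <- if (partial) NULL else lapply(specs, function(sp) {
    assess_capability(window, sp)
  })
  structure(
    list(
      window_index = if (is.null(idx)) 1L else idx,
      start = if (is.null(start)) 1L else start,
      end = (if (is.null(start)) 1L else start) + window$n - 1L,
      n = window$n,
      partial = partial,
      limits = chart,
      ad = ad,
      capability = capability,
      mean_variation_mm = chart$center - baseline_reference,
      n_beyond_spc = chart$counts$n_beyond_spc,
      n_beyond_action = chart$counts$n_beyond_action
    ),
    class = "window_report"
  )
}

#' @export
print.window_report <- function(x, ...) {
  cat(sprintf("Window %d [%d..%d], n = %d%s\n", x$window_index, x$start, x$end,
              x$n, if (x$partial) " (partial)" else ""))
  cat(sprintf("  CL %.4f  UCL %.4f  LCL %.4f (mm); mean variation %+.3f mm\n",
              x$limits$center, x$limits$ucl, x$limits$lcl, x$mean_variation_mm))
  if (!is.null(x$ad)) {
    cat(sprintf("  AD: A*^2 = %.3f, p = %.3g -> %s\n", x$ad$a2_star,
                x$ad$p_value, if (x$ad$h == 0L) "normal" else "not normal"))
  }
  for (cap in x$capability) {
    cat(sprintf("  [%g, %g] mm: cp %.3f, cpk %.3f (%s)\n", cap$spec$lsl,
                cap$spec$usl, cap$cp, cap$cpk,
                if (cap$acceptable) "acceptable" else "not acceptable"))
  }
  cat(sprintf("  beyond control limits: %d; beyond action limit: %d\n",
              x$n_beyond_spc, x$n_beyond_action))
  invisible(x)
}

#' Windowed trend analysis of a QA series
#'
#' Partitions the series into `window_size`-observation windows and runs
#' [analyze_window()] on each, giving the local (e.g. three-monthly) view of
#' chart limits, normality, capability and mean drift from baseline.
#'
#' @inheritParams analyze_window
#' @param series A [qa_series].
#' @param window_size Observations per window, default 90.
#' @return Object of class `qa_trend`: list of `window_report`s plus the
#'   series identity.
#' @export
trend_analysis <- function(series, window_size = 90L,
                           specs = list(spec_limits(-2, 2)),
                           baseline_reference = 0, alpha = 0.05,
                           action_limit_mm = 2) {
  series <- as_qa_series(series)
  windows <- partition_windows(series, window_size)
  reports <- lapply(windows, function(w) {
    tryCatch(
      analyze_window(w, specs = specs, baseline_reference = baseline_reference,
                     alpha = alpha, action_limit_mm = action_limit_mm),
      error = function(e) {
        stop(sprintf("window %d: %s", attr(w, "window_index"),
                     conditionMessage(e)), call. = FALSE)
      }
    )
  })
  structure(
    list(unit_id = series$unit_id, axis = series$axis, n = series$n,
         window_size = as.integer(window_size),
         baseline_reference = baseline_reference, reports = reports),
    class = "qa_trend"
  )
}

#' @export
print.qa_trend <- function(x, ...) {
  cat(sprintf("Windowed QA trend analysis: unit %s, axis %s, n = %d, window = %d\n",
              x$unit_id, x$axis, x$n, x$window_size))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Compare two measurement phases against a common set of limits
#'
#' Implements the retrospective pre/post-event comparison: control limits are
#' estimated from the `before` phase, the `after` phase is judged against
#' them, and the shift of the center line between phases is measured. The
#' verdict is `systematic_shift` when at least `shift_min_points` of the
#' after-phase points fall outside the before-phase limits, or when the
#' center line moved by more than `drift_threshold_mm`. A single
#' out-of-limit point is treated as an isolated setup error, not evidence of
#' a systematic change -- with ~90-observation phases a lone excursion beyond
#' estimated three-sigma limits is expected by chance in roughly a quarter of
#' in-control runs.
#'
#' @param before,after [qa_series] (or numeric vectors), each n >= 8.
#' @param specs List of [spec_limits()] forwarded to the per-phase reports.
#' @param drift_threshold_mm Center-line shift (mm) considered systematic;
#'   default 0.5 mm, the magnitude of gradual baseline drift seen over
#'   three-monthly periods.
#' @param shift_min_points Minimum number of after-phase points beyond the
#'   before-phase limits to call a systematic shift; default 2.
#' @param action_limit_mm Clinical action level for point flags.
#' @param alpha Normality-test level for the per-phase reports.
#' @return Object of class `phase_comparison`: list with `phase_a`/`phase_b`
#'   ([analyze_window()] reports), `delta_cl`, `limits_respected_in_b`
#'   (`TRUE` iff every after-phase point is inside the before-phase limits),
#'   `n_b_beyond_a_limits`, `verdict` (`"stable"` or `"systematic_shift"`).
#' @examples
#' set.seed(2)
#' pre <- qa_series(rnorm(90, 0, 0.3), axis = "IECZ")
#' post <- qa_series(rnorm(90, -1, 0.3), axis = "IECZ")
#' compare_phases(pre, post)$verdict
#' @export
compare_phases <- function(before, after, specs = list(spec_limits(-2, 2)),
                           drift_threshold_mm = 0.5, shift_min_points = 2L,
                           action_limit_mm = 2, alpha = 0.05) {
  before <- as_qa_series(before)
  after <- as_qa_series(after)
  if (before$n < 8L || after$n < 8L) {
    stop("both phases need at least 8 observations", call. = FALSE)
  }
  chart_a <- spc_chart(before, action_limit_mm = action_limit_mm)
  flags_b <- flag_points(after, chart_a, action_limit_mm = action_limit_mm)
  n_beyond <- sum(flags_b$beyond_spc != "none")
  delta_cl <- mean(after$values) - chart_a$center
  verdict <- if (n_beyond >= shift_min_points ||
                 abs(delta_cl) > drift_threshold_mm) {
    "systematic_shift"
  } else {
    "stable"
  }
  structure(
    list(
      phase_a = analyze_window(before, specs = specs, alpha = alpha,
                               action_limit_mm = action_limit_mm),
      phase_b = analyze_window(after, specs = specs, alpha = alpha,
                               action_limit_mm = action_limit_mm),
      flags_b_vs_a = flags_b,
      delta_cl = delta_cl,
      limits_respected_in_b = n_beyond == 0L,
      n_b_beyond_a_limits = n_beyond,
      drift_threshold_mm = drift_threshold_mm,
      shift_min_points = as.integer(shift_min_points),
      verdict = verdict
    ),
    class = "phase_comparison"
  )
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat("Phase comparison (limits from phase A)\n")
  cat(sprintf("  phase A: n = %d, CL %.4f; phase B: n = %d, CL %.4f\n",
              x$phase_a$n, x$phase_a$limits$center,
              x$phase_b$n, x$phase_b$limits$center))
  cat(sprintf("  delta CL = %+.4f mm (threshold %.2f mm)\n",
              x$delta_cl, x$drift_threshold_mm))
  cat(sprintf("  phase B points beyond phase A limits: %d (min for shift: %d)\n",
              x$n_b_beyond_a_limits, x$shift_min_points))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
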