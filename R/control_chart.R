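#' Expected-range bias constant d2
#'
#' The constant converting a mean range of `subgroup_size` consecutive
#' observations into an unbiased estimate of the process standard deviation:
#' `d2 = E[range of subgroup_size iid standard normals]`. For the moving
#' ranges of an individuals chart (`subgroup_size = 2`) the closed form is
#' `2/sqrt(pi)` (1.128 to three decimals); larger subgroup sizes are obtained
#' by numerical integration of
#' `E[range] = integral(1 - pnorm(x)^n - pnorm(-x)^n) dx`.
#'
#' @param subgroup_size Integer in 2..10.
#' @return The bias constant, a positive scalar.
#' @examples
#' d2_constant(2)          # 2/sqrt(pi) ~ 1.1284
#' round(d2_constant(3), 3)
#' @export
d2_constant <- function(subgroup_size) {
  if (length(subgroup_size) != 1L || is.na(subgroup_size) ||
      subgroup_size != as.integer(subgroup_size)) {
    stop("subgroup_size must be a single integer", call. = FALSE)
  }
  m <- as.integer(subgroup_size)
  if (m < 2L || m > 10L) {
    stop("subgroup_size must be between 2 and 10", call. = FALSE)
  }
  if (m == 2L) return(2 / sqrt(pi))
  stats::integrate(function(x) 1 - stats::pnorm(x)^m - stats::pnorm(-x)^m,
                   -Inf, Inf, rel.tol = 1e-12)$value
}

#' Moving ranges of a measurement series
#'
#' Computes `mR_i = |x_i - x_{i-1}|` for consecutive observations and their
#' arithmetic mean `mR_bar`, the short-term dispersion statistic of the
#' individuals chart (span fixed at 2 consecutive points).
#'
#' @param series A [qa_series] or numeric vector with at least 2 points.
#' @return A list with elements `mr` (length n-1), `mr_bar`, `span` (2).
#' @examples
#' moving_ranges(c(1, 3, 2))  # mr = 2, 1; mr_bar = 1.5
#' @export
moving_ranges <- function(series) {
  x <- if (inherits(series, "qa_series")) series$values else as.numeric(series)
  if (length(x) < 2L) {
    stop("at least 2 observations are required for moving ranges", call. = FALSE)
  }
  mr <- abs(diff(x))
  list(mr = mr, mr_bar = mean(mr), span = 2L)
}

#' Fit an individuals (X) control chart
#'
#' Fits the retrospective individuals chart for a QA measurement series:
#' center line `CL = mean(x)` and three-sigma control limits
#' `UCL/LCL = CL +/- 3 * mR_bar / (d2 * sqrt(n_sub))`, with the short-term
#' standard deviation estimated from the mean moving range as
#' `sigma_within = mR_bar / d2`. With subgroups of one observation
#' (`n_sub = 1`, the individuals chart) and moving ranges of two consecutive
#' points, `d2 = 2/sqrt(pi)` (1.128). Each point is flagged against the
#' control limits and against the clinical action limits
#' `+/- action_limit_mm` (strict inequalities: a point exactly on a limit is
#' in control).
#'
#' If `baseline` is supplied, limits are estimated from the baseline series
#' and the points of `x` are judged against them (phase-II style monitoring,
#' e.g. post-calibration surveillance); otherwise limits come from `x` itself
#' (phase-I, one global pass).
#'
#' @param x A [qa_series] or numeric vector of measurements (n >= 2).
#' @param baseline Optional [qa_series] or numeric vector from which to
#'   estimate the limits instead of `x`.
#' @param action_limit_mm Clinical action (tolerance) level in mm; points with
#'   `|x| > action_limit_mm` are flagged `beyond_action`. Default 2 mm.
#' @param n_sub Subgroup size entering the `sqrt(n)` of the limit formula;
#'   1 for individuals charts.
#' @param d2 Bias constant for the moving-range span; defaults to the exact
#'   `2/sqrt(pi)`.
#'
#' @return An object of class `spc_chart` with components `center`, `ucl`,
#'   `lcl`, `mr_bar`, `sigma_within`, `d2`, `n_sub`, `action_limit_mm`,
#'   `flags` (data frame: `index`, `value`, `beyond_spc`, `beyond_action`),
#'   `counts` (violations per category), `series`, and `baseline` (logical).
#'   Methods: [print.spc_chart()], [summary.spc_chart()], [plot.spc_chart()],
#'   [predict.spc_chart()], [residuals.spc_chart()], [coef.spc_chart()].
#' @examples
#' set.seed(1)
#' fit <- spc_chart(qa_series(rnorm(90, 0, 0.3), unit_id = "T1", axis = "IECZ"))
#' coef(fit)
#' summary(fit)
#' @export
spc_chart <- function(x, baseline = NULL, action_limit_mm = 2,
                      n_sub = 1L, d2 = d2_constant(2L)) {
  series <- as_qa_series(x)
  ref <- if (is.null(baseline)) series else as_qa_series(baseline)
  if (ref$n < 2L) {
    stop("at least 2 observations are required to estimate control limits",
         call. = FALSE)
  }
  if (!is.numeric(action_limit_mm) || action_limit_mm <= 0) {
    stop("action_limit_mm must be a positive number", call. = FALSE)
  }
  mrs <- moving_ranges(ref)
  center <- mean(ref$values)
  if (mrs$mr_bar == 0) {
    warning("constant series: moving ranges are all zero, ",
            "control limits collapse to the center line", call. = FALSE)
  }
  half_width <- 3 * mrs$mr_bar / (d2 * sqrt(n_sub))
  ucl <- center + half_width
  lcl <- center - half_width
  sigma_within <- mrs$mr_bar / d2

  flags <- flag_points(series, list(ucl = ucl, lcl = lcl),
                       action_limit_mm = action_limit_mm)
  structure(
    list(
      series = series,
      baseline = !is.null(baseline),
      center = center, ucl = ucl, lcl = lcl,
      mr = mrs$mr, mr_bar = mrs$mr_bar,
      d2 = d2, n_sub = n_sub,
      sigma_within = sigma_within,
      action_limit_mm = action_limit_mm,
      flags = flags,
      counts = violation_counts(flags)
    ),
    class = "spc_chart"
  )
}

#' Flag points against control and action limits
#'
#' Classifies every point of a series against three-sigma control limits
#' (`beyond_spc`: `none` / `above_UCL` / `below_LCL`) and against the
#' clinical action band `+/- action_limit_mm` (`beyond_action`: `none` /
#' `above_USL` / `below_LSL`). Violations use strict inequalities, so a
#' point exactly on a limit is in control.
#'
#' @param series A [qa_series] or numeric vector.
#' @param limits An `spc_chart` object or a list with elements `ucl`, `lcl`.
#' @param action_limit_mm Positive action level in mm.
#' @return Data frame with columns `index`, `value`, `beyond_spc`,
#'   `beyond_action`.
#' @export
flag_points <- function(series, limits, action_limit_mm = 2) {
  x <- if (inherits(series, "qa_series")) series$values else as.numeric(series)
  if (!is.numeric(action_limit_mm) || length(action_limit_mm) != 1L ||
      is.na(action_limit_mm) || action_limit_mm <= 0) {
    stop("action_limit_mm must be a positive number", call. = FALSE)
  }
  beyond_spc <- rep("none", length(x))
  beyond_spc[x > limits$ucl] <- "above_UCL"
  beyond_spc[x < limits$lcl] <- "below_LCL"
  beyond_action <- rep("none", length(x))
  beyond_action[x > action_limit_mm] <- "above_USL"
  beyond_action[x < -action_limit_mm] <- "below_LSL"
  data.frame(
    index = seq_along(x),
    value = x,
    beyond_spc = beyond_spc,
    beyond_action = beyond_action,
    stringsAsFactors = FALSE
  )
}

violation_counts <- function(flags) {
  list(
    n = nrow(flags),
    n_above_ucl = sum(flags$beyond_spc == "above_UCL"),
    n_below_lcl = sum(flags$beyond_spc == "below_LCL"),
    n_beyond_spc = sum(flags$beyond_spc != "none"),
    n_beyond_action = sum(flags$beyond_action != "none")
  )
}

#' @export
print.spc_chart <- function(x, digits = 4, ...) {
  cat(sprintf("Individuals X-chart: unit %s, axis %s, n = %d%s\n",
              x$series$unit_id, x$series$axis, x$series$n,
              if (x$baseline) " (limits from baseline series)" else ""))
  cat(sprintf("  CL  %s mm   UCL %s mm   LCL %s mm\n",
              format(x$center, digits = digits),
              format(x$ucl, digits = digits),
              format(x$lcl, digits = digits)))
  cat(sprintf("  mR_bar %s mm   sigma_within %s mm   (d2 = %.4f, n = %d)\n",
              format(x$mr_bar, digits = digits),
              format(x$sigma_within, digits = digits), x$d2, x$n_sub))
  cat(sprintf("  beyond control limits: %d   beyond +/-%g mm action limit: %d\n",
              x$counts$n_beyond_spc, x$action_limit_mm, x$counts$n_beyond_action))
  invisible(x)
}

#' @export
#' @method summary spc_chart
summary.spc_chart <- function(object, ...) {
  out <- list(
    unit_id = object$series$unit_id,
    axis = object$series$axis,
    n = object$series$n,
    center = object$center, ucl = object$ucl, lcl = object$lcl,
    mr_bar = object$mr_bar, sigma_within = object$sigma_within,
    sigma_overall = if (object$series$n > 1L) stats::sd(object$series$values) else NA_real_,
    action_limit_mm = object$action_limit_mm,
    counts = object$counts,
    violations = object$flags[object$flags$beyond_spc != "none" |
                                object$flags$beyond_action != "none", ,
                              drop = FALSE]
  )
  class(out) <- "summary.spc_chart"
  out
}

#' @export
print.summary.spc_chart <- function(x, ...) {
  cat(sprintf("Individuals X-chart summary: unit %s, axis %s, n = %d\n",
              x$unit_id, x$axis, x$n))
  cat(sprintf("  CL %.4f  UCL %.4f  LCL %.4f  (mm)\n", x$center, x$ucl, x$lcl))
  cat(sprintf("  sigma: within %.4f mm (mR_bar/d2), overall %.4f mm (sample SD)\n",
              x$sigma_within, x$sigma_overall))
  cat(sprintf("  out-of-control points: %d (%d above UCL, %d below LCL)\n",
              x$counts$n_beyond_spc, x$counts$n_above_ucl, x$counts$n_below_lcl))
  cat(sprintf("  beyond +/-%g mm action limit: %d\n",
              x$action_limit_mm, x$counts$n_beyond_action))
  if (nrow(x$violations)) {
    cat("  flagged points:\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.spc_chart <- function(object, ...) {
  c(CL = object$center, UCL = object$ucl, LCL = object$lcl)
}

#' @export
residuals.spc_chart <- function(object, ...) {
  object$series$values - object$center
}

#' Flag new observations against a fitted chart's limits
#'
#' @param object A fitted [spc_chart()].
#' @param newdata A [qa_series] or numeric vector of new measurements; if
#'   omitted, the fitted series' flags are returned.
#' @param ... Unused.
#' @return Data frame of point flags as in [flag_points()].
#' @export
#' @method predict spc_chart
predict.spc_chart <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$flags)
  flag_points(newdata, object, action_limit_mm = object$action_limit_mm)
}

#' Plot an individuals control chart
#'
#' Draws the measurement sequence with center line, UCL/LCL, and the
#' clinical action band; out-of-control points are highlighted.
#'
#' @param x A fitted [spc_chart()].
#' @param main Plot title; a default is built from the series identity.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
#' @method plot spc_chart
plot.spc_chart <- function(x, main = NULL, ...) {
  v <- x$series$values
  if (is.null(main)) {
    main <- sprintf("Individuals X-chart: %s %s", x$series$unit_id, x$series$axis)
  }
  ylim <- range(v, x$ucl, x$lcl, x$action_limit_mm, -x$action_limit_mm)
  graphics::plot(seq_along(v), v, type = "b", pch = 20, cex = 0.6,
                 xlab = "Observation", ylab = "Offset (mm)",
                 main = main, ylim = ylim, ...)
  graphics::abline(h = x$center, lwd = 2)
  graphics::abline(h = c(x$ucl, x$lcl), col = "red3")
  graphics::abline(h = c(-1, 1) * x$action_limit_mm, col = "blue", lty = 2)
  bad <- x$flags$beyond_spc != "none"
  if (any(bad)) graphics::points(which(bad), v[bad], col = "red3", pch = 19)
  invisible(x)
}
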