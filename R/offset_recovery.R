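#' Ordinary least-squares linearity fit
#'
#' Fits `response = intercept + slope * applied` by OLS and reports the
#' coefficient of determination, the summary used to verify that a detected
#' quantity (an offset component, the gantry phase angle, an energy delta)
#' responds linearly to the applied couch shift.
#'
#' @param applied Numeric vector of applied shifts, mm; at least 3 distinct
#'   values.
#' @param response Numeric vector of the same length.
#' @return Object of class `linearity_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @examples
#' fit_linearity(-5:5, 2 * (-5:5) + 1)  # slope 2, intercept 1, R^2 = 1
#' @export
fit_linearity <- function(applied, response) {
  applied <- as.numeric(applied)
  response <- as.numeric(response)
  if (length(applied) != length(response)) {
    stop("applied and response must have equal length", call. = FALSE)
  }
  ok <- is.finite(applied) & is.finite(response)
  applied <- applied[ok]
  response <- response[ok]
  if (length(unique(applied)) < 3L) {
    stop("degenerate design: at least 3 distinct applied values are required",
         call. = FALSE)
  }
  fit <- stats::lm(response ~ applied)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = min(max(r2, 0), 1),
         n_points = length(applied)),
    class = "linearity_fit"
  )
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): slope %.4f, intercept %.4f, R^2 = %.4f\n",
              x$n_points, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

detected_col <- c(IECX = "detected_x_mm", IECY = "detected_y_mm",
                  IECZ = "detected_z_mm")

## Mean detected offsets per (applied axis, applied value), replicates averaged.
average_replicates <- function(trials) {
  key <- interaction(trials$axis, trials$applied_mm, drop = TRUE)
  out <- do.call(rbind, lapply(split(trials, key), function(g) {
    data.frame(
      axis = g$axis[1L],
      applied_mm = g$applied_mm[1L],
      detected_x_mm = mean(g$detected_x_mm),
      detected_y_mm = mean(g$detected_y_mm),
      detected_z_mm = mean(g$detected_z_mm),
      n_replicates = nrow(g),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$axis, out$applied_mm), , drop = FALSE]
}

#' Applied-versus-detected offset recovery analysis
#'
#' For each axis along which shifts were applied, averages the replicate
#' measurements, computes the on-axis detection deviation
#' `detected_on_axis - applied` and its maximum magnitude across the applied
#' grid, judges it against the clinical tolerance, and screens the two
#' non-applied axes for cross-axis coupling (e.g. the couch's cobra motion
#' coupling vertical shifts into the longitudinal reading). A coupling is
#' reported for a target axis when, among applied magnitudes at or above
#' `coupling_floor_mm`, its mean detected magnitude exceeds three times the
#' measurement reproducibility -- below that it is indistinguishable from
#' read-to-read noise.
#'
#' @param trials Data frame of trials in the experiment dialect of
#'   [read_offset_experiment()].
#' @param tolerance_mm Action tolerance on the on-axis deviation; default 2.
#' @param coupling_floor_mm Minimum applied magnitude at which cross-axis
#'   coupling is considered detectable; default 2.
#' @param reproducibility_mm Measurement reproducibility; default 0.2.
#' @return Object of class `recovery_analysis`: a list with one
#'   `recovery_verdict` per applied axis (fields `axis`,
#'   `max_abs_deviation_mm`, `worst_applied_mm`, `within_action`,
#'   `deviation_by_applied`, `coupling_detected`).
#' @export
recovery_analysis <- function(trials, tolerance_mm = 2,
                              coupling_floor_mm = 2,
                              reproducibility_mm = 0.2) {
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0L) {
    stop("empty trial list: nothing to analyse", call. = FALSE)
  }
  if (!all(trials$axis %in% qa_axes)) {
    stop("trials contain unknown axes", call. = FALSE)
  }
  means <- average_replicates(trials)
  verdicts <- lapply(intersect(qa_axes, unique(means$axis)), function(ax) {
    g <- means[means$axis == ax, , drop = FALSE]
    dev <- g[[detected_col[[ax]]]] - g$applied_mm
    worst <- which.max(abs(dev))
    coupling <- do.call(rbind, lapply(setdiff(qa_axes, ax), function(target) {
      gated <- g[abs(g$applied_mm) >= coupling_floor_mm, , drop = FALSE]
      if (nrow(gated) == 0L) return(NULL)
      resp <- abs(gated[[detected_col[[target]]]])
      if (max(resp) <= 3 * reproducibility_mm) return(NULL)
      data.frame(source_axis = ax, target_axis = target,
                 magnitude_mm = max(resp), stringsAsFactors = FALSE)
    }))
    structure(
      list(
        axis = ax,
        max_abs_deviation_mm = abs(dev[worst]),
        worst_applied_mm = g$applied_mm[worst],
        within_action = abs(dev[worst]) <= tolerance_mm,
        deviation_by_applied = data.frame(applied_mm = g$applied_mm,
                                          deviation_mm = dev,
                                          n_replicates = g$n_replicates),
        coupling_detected = if (is.null(coupling)) {
          data.frame(source_axis = character(0), target_axis = character(0),
                     magnitude_mm = numeric(0))
        } else coupling
      ),
      class = "recovery_verdict"
    )
  })
  names(verdicts) <- vapply(verdicts, `[[`, character(1), "axis")
  structure(
    list(verdicts = verdicts, tolerance_mm = tolerance_mm,
         coupling_floor_mm = coupling_floor_mm,
         reproducibility_mm = reproducibility_mm),
    class = "recovery_analysis"
  )
}

#' @export
print.recovery_verdict <- function(x, ...) {
  cat(sprintf("%s applied: max |detected - applied| = %.3f mm at %+g mm (%s)\n",
              x$axis, x$max_abs_deviation_mm, x$worst_applied_mm,
              if (x$within_action) "within tolerance" else "BEYOND tolerance"))
  if (nrow(x$coupling_detected)) {
    for (k in seq_len(nrow(x$coupling_detected))) {
      cat(sprintf("  coupling %s -> %s: %.3f mm\n",
                  x$coupling_detected$source_axis[k],
                  x$coupling_detected$target_axis[k],
                  x$coupling_detected$magnitude_mm[k]))
    }
  }
  invisible(x)
}

#' @export
print.recovery_analysis <- function(x, ...) {
  cat(sprintf("Applied-vs-detected offset analysis (tolerance %.1f mm)\n",
              x$tolerance_mm))
  for (v in x$verdicts) print(v)
  invisible(x)
}

#' Cross-axis response matrix
#'
#' OLS slope of each detected coordinate against each applied axis: entry
#' (source, target) is the detected response on `target` per mm applied
#' along `source`. A faithful positioning system gives the identity matrix;
#' off-diagonal structure reveals mechanical coupling. Cells whose applied
#' design spans fewer than 2 distinct magnitudes are `NA` with a warning.
#'
#' @inheritParams recovery_analysis
#' @return 3x3 numeric matrix with [qa_axes] dimnames (rows = applied axis,
#'   columns = detected axis).
#' @export
cross_axis_matrix <- function(trials) {
  trials <- as.data.frame(trials)
  m <- matrix(NA_real_, 3L, 3L, dimnames = list(applied = qa_axes,
                                                detected = qa_axes))
  for (src in qa_axes) {
    g <- trials[trials$axis == src, , drop = FALSE]
    if (length(unique(g$applied_mm)) < 2L) {
      warning(sprintf("degenerate design for applied axis %s: fewer than 2 distinct applied values", src),
              call. = FALSE)
      next
    }
    for (tgt in qa_axes) {
      fit <- stats::lm(g[[detected_col[[tgt]]]] ~ g$applied_mm)
      m[src, tgt] <- unname(stats::coef(fit)[2L])
    }
  }
  m
}
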