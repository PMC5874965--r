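#' Specification (action) limits for capability analysis
#'
#' Clinical tolerances against which process capability is judged -- the
#' user-specified upper and lower levels. The couch-offset action level is
#' +/-2 mm, with +/-1 mm examined as a stricter alternative.
#'
#' @param lsl,usl Lower and upper limits in mm, `usl > lsl`.
#' @return Object of class `spec_limits`.
#' @examples
#' spec_limits(-2, 2)
#' @export
spec_limits <- function(lsl = -2, usl = 2) {
  if (!is.numeric(lsl) || !is.numeric(usl) || is.na(lsl) || is.na(usl) ||
      usl <= lsl) {
    stop("spec limits require usl > lsl", call. = FALSE)
  }
  structure(list(lsl = as.numeric(lsl), usl = as.numeric(usl)),
            class = "spec_limits")
}

#' @export
print.spec_limits <- function(x, ...) {
  cat(sprintf("Spec limits: [%g, %g] mm\n", x$lsl, x$usl))
  invisible(x)
}

#' Overall process standard deviation
#'
#' The sample standard deviation (n-1 denominator) of the measurement
#' series -- the dispersion of the data distribution that enters cp and cpk.
#' This is the overall SD, distinct from the within-subgroup estimate
#' `mR_bar/d2` reported by [spc_chart()].
#'
#' @param series A [qa_series] or numeric vector, n >= 2.
#' @return Positive scalar, mm.
#' @export
process_sigma <- function(series) {
  x <- if (inherits(series, "qa_series")) series$values else as.numeric(series)
  if (length(x) < 2L) stop("at least 2 observations are required", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    stop("constant series: zero variance, capability indices are undefined",
         call. = FALSE)
  }
  s
}

#' Process capability index cp
#'
#' `cp = (USL - LSL) / (6 * sigma)`: the specification width relative to the
#' six-sigma process spread. `cp = 1` means the dispersion exactly fills the
#' tolerance band; `cp > 1`, comfortably inside; `cp < 1`, too wide for the
#' chosen action level.
#'
#' @param spec A [spec_limits()].
#' @param sigma Process standard deviation, mm, > 0.
#' @return Non-negative scalar.
#' @export
cp_index <- function(spec, sigma) {
  stopifnot(inherits(spec, "spec_limits"))
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  (spec$usl - spec$lsl) / (6 * sigma)
}

#' Process acceptability index cpk
#'
#' `cpk = min((USL - mean) / (3 sigma), (mean - LSL) / (3 sigma))`: like cp
#' but penalizing an off-center process mean. `cpk = cp` exactly when the
#' mean sits at the specification midpoint; `cpk` can be negative when the
#' mean lies outside the limits.
#'
#' @inheritParams cp_index
#' @param mean Process mean, mm.
#' @return Scalar (may be negative).
#' @export
cpk_index <- function(spec, mean, sigma) {
  stopifnot(inherits(spec, "spec_limits"))
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  min((spec$usl - mean) / (3 * sigma), (mean - spec$lsl) / (3 * sigma))
}

#' Capability assessment of a measurement series
#'
#' Combines [process_sigma()], [cp_index()] and [cpk_index()] and classifies
#' the process as acceptable when both indices reach 1 -- dispersion inside
#' the action band and mean close enough to its center.
#'
#' @param series A [qa_series] or numeric vector, n >= 2, non-constant.
#' @param spec A [spec_limits()]; default the +/-2 mm action level.
#' @return Object of class `capability_result`: list with `cp`, `cpk`,
#'   `sigma`, `mean`, `spec`, `acceptable`, `n`.
#' @examples
#' set.seed(1)
#' assess_capability(rnorm(90, 0, 0.2), spec_limits(-2, 2))
#' @export
assess_capability <- function(series, spec = spec_limits(-2, 2)) {
  x <- if (inherits(series, "qa_series")) series$values else as.numeric(series)
  sigma <- process_sigma(x)
  m <- mean(x)
  cp <- cp_index(spec, sigma)
  cpk <- cpk_index(spec, m, sigma)
  structure(
    list(cp = cp, cpk = cpk, sigma = sigma, mean = m, spec = spec,
         acceptable = (cp >= 1 && cpk >= 1), n = length(x)),
    class = "capability_result"
  )
}

#' @export
print.capability_result <- function(x, ...) {
  cat(sprintf("Process capability vs [%g, %g] mm (n = %d)\n",
              x$spec$lsl, x$spec$usl, x$n))
  cat(sprintf("  mean %.4f mm, sigma %.4f mm\n", x$mean, x$sigma))
  cat(sprintf("  cp = %.3f, cpk = %.3f -> %s\n", x$cp, x$cpk,
              if (x$acceptable) "acceptable (both >= 1)" else "not acceptable"))
  invisible(x)
}
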