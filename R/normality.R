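#' Anderson-Darling goodness-of-fit statistic for normality
#'
#' Evaluates the Anderson-Darling statistic of a sample against a normal
#' distribution with the given mean and standard deviation:
#' `A^2 = -n - (1/n) * sum_{i=1..n} (2i-1) * [ln F(X_(i)) + ln(1 - F(X_(n+1-i)))]`
#' where `X_(1) <= ... <= X_(n)` is the ordered sample and `F` the normal
#' CDF. The statistic weights discrepancies in the distribution tails, which
#' is where setup-error outliers show up. CDF values are clamped to
#' `[1e-16, 1 - 1e-16]` before taking logarithms so extreme order statistics
#' cannot produce infinities.
#'
#' @param sample Numeric vector, n >= 2 (sorted internally; ties allowed).
#' @param distribution_mean,distribution_sd Parameters of the hypothesized
#'   normal distribution (`distribution_sd > 0`).
#' @return The statistic `A^2`, a non-negative scalar.
#' @seealso [ad_test()] for the composite test with estimated parameters.
#' @export
ad_statistic <- function(sample, distribution_mean, distribution_sd) {
  x <- as.numeric(sample)
  n <- length(x)
  if (n < 2L) stop("at least 2 observations are required", call. = FALSE)
  if (!is.numeric(distribution_sd) || distribution_sd <= 0) {
    stop("distribution_sd must be positive", call. = FALSE)
  }
  z <- sort(x)
  f <- stats::pnorm(z, mean = distribution_mean, sd = distribution_sd)
  f <- pmin(pmax(f, 1e-16), 1 - 1e-16)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(f) + log(1 - rev(f))))
}

## D'Agostino-Stephens p-value for the parameters-estimated (composite) case,
## applied to the small-sample-modified statistic.
ad_p_value <- function(a2_star) {
  a <- a2_star
  if (a < 0.2) {
    1 - exp(-13.436 + 101.14 * a - 223.73 * a^2)
  } else if (a < 0.34) {
    1 - exp(-8.318 + 42.796 * a - 59.938 * a^2)
  } else if (a < 0.6) {
    exp(0.9177 - 4.279 * a - 1.38 * a^2)
  } else if (a < 10) {
    exp(1.2937 - 5.709 * a + 0.0186 * a^2)
  } else {
    3.7e-24
  }
}

#' Anderson-Darling test of normality (composite null)
#'
#' Tests whether a QA measurement sample is normally distributed, with both
#' normal parameters estimated from the sample (mean and n-1 standard
#' deviation). The raw statistic from [ad_statistic()] receives Stephens'
#' small-sample modification `A*^2 = A^2 * (1 + 0.75/n + 2.25/n^2)` and is
#' mapped to a p-value through the standard piecewise-exponential
#' approximation for the all-parameters-estimated case. The decision `h` is
#' 1 (reject normality) when `p < alpha`, 0 otherwise.
#'
#' @param sample Numeric vector or [qa_series], n >= 8 (the p-value
#'   approximation is unreliable below that).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return An object of class `ad_test`: list with `a2`, `a2_star`,
#'   `p_value`, `alpha`, `h`, `n`, `mean_hat`, `sd_hat`.
#' @examples
#' set.seed(1)
#' ad_test(rnorm(90, 0, 0.3))
#' @export
ad_test <- function(sample, alpha = 0.05) {
  x <- if (inherits(sample, "qa_series")) sample$values else as.numeric(sample)
  n <- length(x)
  if (n < 8L) {
    stop("at least 8 observations are required for the AD normality test",
         call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  mean_hat <- mean(x)
  sd_hat <- stats::sd(x)
  if (sd_hat == 0) {
    stop("sample has zero variance; normality test is degenerate", call. = FALSE)
  }
  a2 <- ad_statistic(x, mean_hat, sd_hat)
  a2_star <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- min(max(ad_p_value(a2_star), 0), 1)
  structure(
    list(a2 = a2, a2_star = a2_star, p_value = p, alpha = alpha,
         h = as.integer(p < alpha), n = n,
         mean_hat = mean_hat, sd_hat = sd_hat),
    class = "ad_test"
  )
}

#' @export
print.ad_test <- function(x, ...) {
  cat("Anderson-Darling normality test (parameters estimated)\n")
  cat(sprintf("  n = %d, mean = %.4f, sd = %.4f\n", x$n, x$mean_hat, x$sd_hat))
  cat(sprintf("  A^2 = %.4f, A*^2 = %.4f, p = %.4g\n", x$a2, x$a2_star, x$p_value))
  cat(sprintf("  h = %d at alpha = %g: %s\n", x$h, x$alpha,
              if (x$h == 0L) "normal (fail to reject)" else "not normal (reject)"))
  invisible(x)
}

#' Normality decisions for a list of analysis windows
#'
#' Runs [ad_test()] on each window (e.g. the three-monthly slices from
#' [partition_windows()]), preserving order. Errors in individual windows are
#' re-raised with the window index attached.
#'
#' @param windows List of [qa_series] (or numeric vectors), each with n >= 8.
#' @param alpha Significance level shared by all windows.
#' @return List of `ad_test` objects, one per window.
#' @export
classify_windows_normality <- function(windows, alpha = 0.05) {
  lapply(seq_along(windows), function(k) {
    tryCatch(ad_test(windows[[k]], alpha = alpha), error = function(e) {
      stop(sprintf("window %d: %s", k, conditionMessage(e)), call. = FALSE)
    })
  })
}
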