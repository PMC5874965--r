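# Shared fixtures: everything is generated in code at test time.

make_series <- function(n = 90, mean = 0, sd = 0.3, seed = 1,
                        unit = "T1", axis = "IECX", ...) {
  generate_series(series_spec(unit_id = unit, axis = axis, n = n,
                              mean_mm = mean, sd_mm = sd, seed = seed, ...))$series
}

random_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    timestamp = format(as.Date("2013-01-01") + sort(sample.int(2000, n, replace = TRUE)),
                       "%Y-%m-%dT00:00:00"),
    unit_id = sample(c("T1", "T2"), n, replace = TRUE),
    axis = sample(qa_axes, n, replace = TRUE),
    offset_mm = round(runif(n, -5, 5), 4),
    energy_pct = ifelse(runif(n) < 0.3, NA, round(runif(n, -2, 2), 4)),
    output_pct = round(runif(n, -2, 2), 4),
    gantry_phase_deg = round(runif(n, -1, 1), 4),
    stringsAsFactors = FALSE
  )
}

# Literal term-by-term evaluation of the AD sum, kept deliberately naive and
# independent of the package implementation.
ad_brute <- function(x, mu, sigma) {
  x <- sort(x)
  n <- length(x)
  total <- 0
  for (i in seq_len(n)) {
    fi <- pnorm(x[i], mu, sigma)
    fr <- pnorm(x[n + 1 - i], mu, sigma)
    total <- total + (2 * i - 1) * (log(fi) + log(1 - fr))
  }
  -n - total / n
}

# Normal-equations OLS, independent of lm().
ols_brute <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}
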