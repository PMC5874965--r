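test_that("fit_linearity reproduces exact lines and degenerate cases", {
  x <- -5:5
  fit <- fit_linearity(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  flat <- fit_linearity(x, rep(3, 11))
  expect_equal(flat$r_squared, 0)

  expect_error(fit_linearity(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("fit_linearity matches the normal-equations oracle", {
  set.seed(81)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    y <- rnorm(n, 1 + 2 * x, 0.5)
    ours <- fit_linearity(x, y)
    ref <- ols_brute(x, y)
    expect_equal(ours$slope, ref$slope, tolerance = 1e-10)
    expect_equal(ours$intercept, ref$intercept, tolerance = 1e-10)
    expect_equal(ours$r_squared, ref$r_squared, tolerance = 1e-10)
  }
})

test_that("phase-angle responses built for R^2 ~ 0.996 fit at that level", {
  # noise SD solved from the R^2 definition on the applied grid, then simulated
  grid <- rep(c(-5, -2, -1, -0.5, 0.5, 1, 2, 5), each = 2)
  slope <- 1
  noise_sd <- sqrt(mean((slope * grid)^2) * (1 / 0.996 - 1))
  r2 <- vapply(1:40, function(s) {
    set.seed(900 + s)
    fit_linearity(grid, slope * grid + rnorm(length(grid), 0, noise_sd))$r_squared
  }, numeric(1))
  expect_equal(mean(r2), 0.996, tolerance = 0.01)
})

test_that("an ideal detector yields all-clear verdicts", {
  grid <- c(-5, -2, -1, -0.5, 0.5, 1, 2, 5)
  trials <- do.call(rbind, lapply(qa_axes, function(ax) {
    data.frame(axis = ax, applied_mm = grid,
               detected_x_mm = if (ax == "IECX") grid else 0,
               detected_y_mm = if (ax == "IECY") grid else 0,
               detected_z_mm = if (ax == "IECZ") grid else 0,
               replicate = 1L, stringsAsFactors = FALSE)
  }))
  res <- recovery_analysis(trials)
  for (v in res$verdicts) {
    expect_equal(v$max_abs_deviation_mm, 0)
    expect_true(v$within_action)
    expect_equal(nrow(v$coupling_detected), 0L)
  }
  expect_equal(unname(cross_axis_matrix(trials)), diag(3))
  expect_error(recovery_analysis(trials[0, ]), "empty")
})

test_that("cobra coupling of vertical into longitudinal is detected", {
  exp <- generate_experiment(experiment_spec(seed = 23))
  res <- recovery_analysis(exp$trials)
  cz <- res$verdicts$IECZ$coupling_detected
  expect_true(any(cz$source_axis == "IECZ" & cz$target_axis == "IECY"))
  mag <- cz$magnitude_mm[cz$target_axis == "IECY"]
  expect_equal(mag, 0.234 * 5, tolerance = 0.1)  # ~1.17 mm at 5 mm applied
  # lateral and longitudinal applied shifts show no coupling
  expect_equal(nrow(res$verdicts$IECX$coupling_detected), 0L)
  expect_equal(nrow(res$verdicts$IECY$coupling_detected), 0L)
})

test_that("the worst on-axis deviation sits on the vertical axis at 5 mm", {
  exp <- generate_experiment(experiment_spec(seed = 24))
  res <- recovery_analysis(exp$trials, tolerance_mm = 2)
  devs <- vapply(res$verdicts, `[[`, numeric(1), "max_abs_deviation_mm")
  expect_equal(names(which.max(devs)), "IECZ")
  z <- res$verdicts$IECZ
  expect_equal(abs(z$worst_applied_mm), 5)
  expect_equal(z$max_abs_deviation_mm, 1.19, tolerance = 0.15)
  expect_true(z$within_action)
})

test_that("cross-axis slopes recover the generator's coupling structure", {
  spec <- experiment_spec(coupling = data.frame(source = c("IECZ", "IECX"),
                                                target = c("IECY", "IECY"),
                                                slope = c(0.234, 0.05)),
                          seed = 25)
  m <- cross_axis_matrix(generate_experiment(spec)$trials)
  expect_lt(abs(m["IECZ", "IECY"] - 0.234), 0.03)
  expect_lt(abs(m["IECX", "IECY"] - 0.05), 0.03)
  expect_lt(abs(m["IECX", "IECX"] - 1), 0.03)
  expect_lt(abs(m["IECY", "IECZ"]), 0.03)

  # lateral shifts bounded to <= 0.3 mm off-axis response at 5 mm applied
  bounded <- experiment_spec(coupling = data.frame(source = "IECX",
                                                   target = c("IECY", "IECZ"),
                                                   slope = c(0.05, 0.05)),
                             replicates = 25, seed = 26)
  mb <- cross_axis_matrix(generate_experiment(bounded)$trials)
  expect_lte(abs(mb["IECX", "IECY"]), 0.06)
  expect_lte(abs(mb["IECX", "IECZ"]), 0.06)

  one_level <- data.frame(axis = "IECX", applied_mm = 1, detected_x_mm = 1,
                          detected_y_mm = 0, detected_z_mm = 0, replicate = 1L)
  warns <- capture_warnings(m1 <- cross_axis_matrix(one_level))
  expect_match(warns, "degenerate", all = TRUE)
  expect_true(all(is.na(m1["IECX", ])))
})

test_that("positive and negative applied offsets deviate symmetrically", {
  devs <- sapply(1:30, function(s) {
    exp <- generate_experiment(experiment_spec(seed = 700 + s))
    v <- recovery_analysis(exp$trials)$verdicts$IECZ$deviation_by_applied
    c(pos = v$deviation_mm[v$applied_mm == 5],
      neg = v$deviation_mm[v$applied_mm == -5])
  })
  # unbiased linear system: |dev(+5)| ~ |dev(-5)| within 3x reproducibility
  expect_lt(mean(abs(abs(devs["pos", ]) - abs(devs["neg", ]))), 3 * 0.2)
})

test_that("injected detection bias is recovered from replicate averages", {
  exp <- generate_experiment(experiment_spec(replicates = 25, seed = 27))
  z <- recovery_analysis(exp$trials)$verdicts$IECZ
  expect_equal(z$max_abs_deviation_mm, 1.19, tolerance = 0.1)
})
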