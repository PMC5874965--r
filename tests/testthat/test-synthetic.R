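test_that("generation is deterministic and leaves the caller's RNG alone", {
  sp <- series_spec(n = 200, mean_mm = -0.3, sd_mm = 0.4, outlier_rate = 0.02,
                    outlier_scale_mm = 1.5, seed = 31)
  expect_identical(generate_series(sp), generate_series(sp))

  set.seed(99)
  before <- .Random.seed
  invisible(generate_series(sp))
  expect_identical(.Random.seed, before)

  ex <- experiment_spec(seed = 32)
  expect_identical(generate_experiment(ex), generate_experiment(ex))
})

test_that("clean series match their spec distributionally", {
  out <- generate_series(series_spec(n = 10000, mean_mm = 0.2, sd_mm = 0.35,
                                     seed = 33))
  x <- out$series$values
  se_mean <- 0.35 / sqrt(10000)
  expect_lt(abs(mean(x) - 0.2), 3 * se_mean)
  expect_lt(abs(sd(x) - 0.35), 3 * 0.35 / sqrt(2 * 9999))
  expect_true(all(out$truth$in_control))
})

test_that("ground-truth annotations partition the observations", {
  out <- generate_series(series_spec(
    n = 300, sd_mm = 0.2, outlier_rate = 0.05, outlier_scale_mm = 2,
    fault_segments = list(fault_segment(100, 150, shift_mm = 1),
                          fault_segment(200, 240, drift_per_obs_mm = 0.02)),
    seed = 34
  ))
  tr <- out$truth
  expect_equal(nrow(tr), 300L)
  expect_equal(tr$in_control, !tr$outlier & !tr$contaminated & tr$fault_id == 0L)
  expect_equal(sort(unique(tr$fault_id)), c(0L, 1L, 2L))
  expect_equal(sum(tr$fault_id == 1L), 51L)
  # injected disturbances have the stated shape
  expect_true(all(tr$disturbance_mm[tr$fault_id == 1L] == 1))
  drift <- tr$disturbance_mm[tr$fault_id == 2L]
  expect_equal(drift, 0.02 * seq_along(drift))
})

test_that("setup-error outliers exceed 1 mm from the process mean", {
  out <- generate_series(series_spec(n = 2000, mean_mm = -0.5, sd_mm = 0.1,
                                     outlier_rate = 0.05,
                                     outlier_scale_mm = 1.2, seed = 35))
  dev <- abs(out$series$values[out$truth$outlier] - (-0.5))
  expect_true(all(dev > 1 & dev < 2.2))
  expect_equal(mean(out$truth$outlier), 0.05, tolerance = 0.3)
  expect_error(series_spec(outlier_rate = 0.1, outlier_scale_mm = 0.5),
               "exceed 1 mm")
})

test_that("spec validation rejects malformed inputs", {
  expect_error(series_spec(sd_mm = 0), "sd_mm")
  expect_error(series_spec(outlier_rate = 1), "outlier_rate")
  expect_error(series_spec(n = 50, fault_segments = list(
    fault_segment(40, 60, shift_mm = 1))), "past the series")
  expect_error(series_spec(n = 90, fault_segments = list(
    fault_segment(10, 30, shift_mm = 1),
    fault_segment(20, 40, shift_mm = 1))), "overlap")
  expect_error(fault_segment(5, 3, shift_mm = 1), "start <= end")
  expect_error(fault_segment(1, 10, shift_mm = 1, drift_per_obs_mm = 0.1),
               "exactly one")
  expect_error(experiment_spec(replicates = 0), "replicates")
})

test_that("a near-degenerate sd collapses the chart limits", {
  out <- generate_series(series_spec(n = 50, mean_mm = 0.5, sd_mm = 1e-9, seed = 36))
  fit <- spc_chart(out$series)
  expect_equal(fit$ucl, fit$lcl, tolerance = 1e-7)
  expect_equal(fit$center, 0.5, tolerance = 1e-8)
})

test_that("uniform-mixture contamination marks 20% of points", {
  out <- generate_series(series_spec(n = 90, sd_mm = 0.2,
                                     contamination = "uniform_mixture",
                                     seed = 37))
  expect_equal(sum(out$truth$contaminated), 18L)
  expect_true(all(abs(out$series$values[out$truth$contaminated]) <= 0.6 + 1e-12))
})

test_that("unit presets carry the per-axis process parameters", {
  for (u in c("T1", "T2")) {
    p <- qa_preset(u)
    expect_equal(p$axes$axis, qa_axes)
    expect_true(all(p$axes$sigma_mm > 0 & p$axes$sigma_mm < 0.57))
    expect_true(all(p$axes$ucl_mm > p$axes$cl_mm &
                      p$axes$cl_mm > p$axes$lcl_mm))
  }
  expect_equal(qa_preset("T1")$n_history, 1530L)
  expect_equal(qa_preset("T2")$n_history, 1388L)

  # preset-driven windows recover their center line and look normal
  h <- vapply(1:40, function(s) {
    out <- generate_series(preset_series_spec("T2", "IECZ", seed = s))
    stopifnot(abs(mean(out$series$values) - (-0.880)) < 0.25)
    ad_test(out$series)$h
  }, integer(1))
  expect_lte(mean(h), 0.15)  # h = 0 in ~95% of seeds
})
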