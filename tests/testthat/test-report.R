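write_demo_log <- function(path, specs) {
  recs <- do.call(rbind, lapply(specs, function(sp) {
    out <- generate_series(sp)
    data.frame(timestamp = out$series$timestamps, unit_id = sp$unit_id,
               axis = sp$axis, offset_mm = out$series$values,
               stringsAsFactors = FALSE)
  }))
  write_qa_log(recs, path)
}

test_that("config validation catches bad values and unknown keys", {
  expect_error(analysis_config(input = "x.csv", alpha = 1.5), "alpha")
  expect_error(analysis_config(input = "x.csv", window_size = 4), "window_size")
  expect_error(analysis_config(input = "x.csv", action_limits_mm = -1),
               "action_limits_mm")
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("input: x.csv", "frobnicate: 3"), cfg_file)
  expect_error(read_analysis_config(cfg_file), "unknown key.*frobnicate")
})

test_that("a clean preset log is within control at the action level", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_demo_log(tmp, list(preset_series_spec("T2", "IECX", n = 180, seed = 1),
                           preset_series_spec("T2", "IECY", n = 180, seed = 2)))
  out_json <- withr::local_tempfile(fileext = ".json")
  rep <- run_full_analysis(analysis_config(input = tmp, out = out_json))
  expect_s3_class(rep, "qa_report")
  expect_equal(rep$recommendation, "within control")
  expect_false(rep$any_systematic_shift)
  caps <- unlist(lapply(rep$series, function(sr) {
    lapply(sr$windows, function(w) {
      vapply(w$capability, function(cap) {
        if (cap$usl == 2) cap$acceptable else NA
      }, logical(1))
    })
  }))
  expect_true(all(stats::na.omit(caps)))  # all acceptable at +/-2 mm

  # report round-trips as JSON with a stable schema
  parsed <- jsonlite::read_json(out_json, simplifyVector = FALSE)
  expect_equal(parsed$schema_version, "1.0")
  expect_equal(parsed$recommendation, "within control")
  expect_equal(parsed$series[[1]]$windows[[1]]$cl,
               rep$series[[1]]$windows[[1]]$cl)
})

test_that("a tight action level exposes a wide vertical-axis process", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_demo_log(tmp, list(preset_series_spec("T2", "IECZ", n = 90, seed = 3)))
  rep <- run_full_analysis(analysis_config(input = tmp,
                                           action_limits_mm = c(1, 2)))
  caps <- rep$series[[1]]$windows[[1]]$capability
  cp1 <- caps[[which(vapply(caps, `[[`, numeric(1), "usl") == 1)]]$cp
  expect_lt(cp1, 1)  # 2/(6 * 0.542) < 1: +/-1 mm is too conservative
})

test_that("an encoder-fault drift drives the recommendation to investigate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  sp <- series_spec(unit_id = "T1", axis = "IECZ", n = 180, mean_mm = 0,
                    sd_mm = 0.25, seed = 4,
                    fault_segments = list(fault_segment(120, 180,
                                                        drift_per_obs_mm = -0.025)))
  write_demo_log(tmp, list(sp))
  rep <- run_full_analysis(analysis_config(input = tmp))
  expect_equal(rep$recommendation, "investigate")
  expect_true(rep$any_systematic_shift)
  verdicts <- vapply(rep$series[[1]]$phase_comparisons, `[[`, character(1),
                     "verdict")
  expect_true("systematic_shift" %in% verdicts)
})

test_that("selectors and empty selections behave", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_demo_log(tmp, list(preset_series_spec("T1", "IECX", n = 90, seed = 5),
                           preset_series_spec("T2", "IECX", n = 90, seed = 6)))
  rep <- run_full_analysis(analysis_config(input = tmp, units = "T1"))
  expect_length(rep$series, 1L)
  expect_equal(rep$series[[1]]$unit_id, "T1")
  expect_error(run_full_analysis(analysis_config(input = tmp, units = "T9")),
               "no records")
})

test_that("the CLI script dispatches over the installed package", {
  cli <- system.file("cli", "couchspc", package = "couchspc")
  expect_true(nzchar(cli))
  tmp <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".json")
  res <- system2("Rscript", c(cli, "simulate", "--preset", "T2", "--axis", "IECY",
                              "--n", "90", "--seed", "5", "--out", tmp))
  expect_equal(res, 0L)
  expect_equal(nrow(read_qa_log(tmp)), 90L)
  res <- system2("Rscript", c(cli, "chart", "--input", tmp, "--unit", "T2",
                              "--axis", "IECY", "--out", out))
  expect_equal(res, 0L)
  chart <- jsonlite::read_json(out, simplifyVector = TRUE)
  s <- to_series(read_qa_log(tmp), "T2", "IECY")
  expect_equal(chart$cl, mean(s$values))
})
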