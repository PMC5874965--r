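test_that("a well-formed log reads back in file order", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,unit_id,axis,offset_mm,energy_pct,output_pct,gantry_phase_deg",
    "2013-01-01T00:00:00,T1,IECX,0.100000,,,",
    "2013-01-02T00:00:00,T1,IECY,-0.250000,0.500000,,",
    "2013-01-03T00:00:00,T2,IECZ,1.000000,,,0.100000"
  ), tmp)
  recs <- read_qa_log(tmp)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$offset_mm, c(0.1, -0.25, 1))
  expect_equal(recs$axis, c("IECX", "IECY", "IECZ"))
  expect_true(is.na(recs$energy_pct[1]) && recs$energy_pct[2] == 0.5)
})

test_that("invalid rows are reported with their line numbers", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,unit_id,axis,offset_mm,energy_pct,output_pct,gantry_phase_deg",
    "2013-01-01T00:00:00,T1,IECX,0.1,,,",
    "2013-01-02T00:00:00,T1,IECX,0.2,,,",
    "2013-01-03T00:00:00,T1,IECQ,0.3,,,",   # line 4: bad axis
    "2013-01-04T00:00:00,T1,IECX,notanum,,,"  # line 5: bad offset
  ), tmp)
  expect_warning(recs <- read_qa_log(tmp), "line 4.*invalid axis")
  expect_equal(nrow(recs), 2L)
  expect_match(attr(recs, "problems")[2], "line 5")
  expect_error(read_qa_log(tmp, strict = TRUE), "line 4")
})

test_that("missing mandatory columns and sanity violations are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,unit_id,offset_mm", "2013-01-01T00:00:00,T1,0.1"), tmp)
  expect_error(read_qa_log(tmp), "axis")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,unit_id,axis,offset_mm,energy_pct,output_pct,gantry_phase_deg",
    "2013-01-01T00:00:00,T1,IECX,60.0,,,"
  ), tmp2)
  expect_warning(recs <- read_qa_log(tmp2), "sanity")
  expect_equal(nrow(recs), 0L)
})

test_that("write then read is the identity on all fields", {
  recs <- random_records(100, seed = 42)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_qa_log(recs, tmp)
  back <- read_qa_log(tmp)
  attr(back, "problems") <- NULL
  expect_identical(back, recs)
})

test_that("empty and single-record logs round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_qa_log(random_records(0), tmp)
  expect_equal(length(readLines(tmp)), 1L)  # header only
  write_qa_log(random_records(1, seed = 3), tmp)
  expect_equal(length(readLines(tmp)), 2L)
  expect_equal(nrow(read_qa_log(tmp)), 1L)
})

test_that("unit/axis filters select the matching records", {
  recs <- random_records(200, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_qa_log(recs, tmp)
  sub <- read_qa_log(tmp, unit_filter = "T1", axis_filter = "IECZ")
  expect_true(all(sub$unit_id == "T1" & sub$axis == "IECZ"))
  expect_equal(nrow(sub), sum(recs$unit_id == "T1" & recs$axis == "IECZ"))
})

test_that("to_series selects one unit/axis and sorts by timestamp", {
  recs <- data.frame(
    timestamp = c("2013-01-03T00:00:00", "2013-01-01T00:00:00",
                  "2013-01-02T00:00:00", "2013-01-01T00:00:00"),
    unit_id = c("T1", "T1", "T2", "T1"),
    axis = c("IECX", "IECX", "IECX", "IECX"),
    offset_mm = c(3, 1, 9, 2),
    stringsAsFactors = FALSE
  )
  s <- to_series(recs, "T1", "IECX")
  expect_equal(s$values, c(1, 2, 3))  # ties broken by input order
  expect_equal(s$n, 3L)
  expect_error(to_series(recs, "T9", "IECX"), "no records match")
})

test_that("a full synthetic unit history plumbs its observation count through", {
  n_hist <- qa_preset("T1")$n_history
  s <- make_series(n = n_hist, seed = 11)
  recs <- data.frame(timestamp = s$timestamps, unit_id = "T1", axis = "IECX",
                     offset_mm = s$values, stringsAsFactors = FALSE)
  expect_equal(to_series(recs, "T1", "IECX")$n, 1530L)
})

test_that("offset-experiment tables round-trip through their dialect", {
  exp <- generate_experiment(experiment_spec(seed = 9))
  trials <- exp$trials
  trials[c("applied_mm", "detected_x_mm", "detected_y_mm", "detected_z_mm",
           "energy_pct", "output_pct", "gantry_phase_deg")] <-
    lapply(trials[c("applied_mm", "detected_x_mm", "detected_y_mm",
                    "detected_z_mm", "energy_pct", "output_pct",
                    "gantry_phase_deg")], round, digits = 4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_offset_experiment(trials, tmp)
  expect_identical(read_offset_experiment(tmp), trials)
})
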