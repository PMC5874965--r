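## QA log CSV dialect: comma-separated, UTF-8, decimal point, header
##   timestamp,unit_id,axis,offset_mm,energy_pct,output_pct,gantry_phase_deg
## Optional columns may be empty. Offsets are serialized at 6 decimal places.

qa_log_columns <- c("timestamp", "unit_id", "axis", "offset_mm",
                    "energy_pct", "output_pct", "gantry_phase_deg")
qa_log_mandatory <- qa_log_columns[1:4]

experiment_columns <- c("axis", "applied_mm", "detected_x_mm", "detected_y_mm",
                        "detected_z_mm", "energy_pct", "output_pct",
                        "gantry_phase_deg", "replicate")

# Sanity bound: a couch offset beyond this is not a measurement, it is a
# corrupted row.
.offset_sanity_mm <- 50

#' Read a couch QA measurement log
#'
#' Parses a QA log in the package's CSV dialect (header
#' `timestamp,unit_id,axis,offset_mm,energy_pct,output_pct,gantry_phase_deg`;
#' the last three columns are optional and may be empty). Rows violating the
#' record invariants -- unknown axis, non-finite offset, |offset| >= 50 mm,
#' unparseable numerics -- are rejected and reported with their file line
#' numbers.
#'
#' @param path Path to the CSV file.
#' @param unit_filter,axis_filter Optional: keep only records for one unit
#'   and/or one axis.
#' @param strict If `TRUE`, any invalid row aborts the read; otherwise invalid
#'   rows are dropped with a warning listing line numbers, and the full
#'   problem table is attached as attribute `"problems"`.
#' @return A data frame of valid records in file order, with columns as in
#'   the dialect above (optional columns are `NA` where empty).
#' @seealso [write_qa_log()], [to_series()]
#' @export
read_qa_log <- function(path, unit_filter = NULL, axis_filter = NULL,
                        strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(qa_log_mandatory, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(qa_log_columns, names(raw))) raw[[col]] <- ""
  raw <- raw[qa_log_columns]

  n <- nrow(raw)
  lines <- seq_len(n) + 1L  # header is line 1
  problems <- character(0)
  problem_lines <- integer(0)
  note <- function(rows, msg) {
    problems <<- c(problems, sprintf("line %d: %s", lines[rows], msg))
    problem_lines <<- c(problem_lines, lines[rows])
  }

  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  offset <- num_or_na(raw$offset_mm)
  energy <- num_or_na(raw$energy_pct)
  output <- num_or_na(raw$output_pct)
  phase <- num_or_na(raw$gantry_phase_deg)

  bad <- rep(FALSE, n)
  mark <- function(rows, msg) {
    rows <- which(rows & !bad)
    if (length(rows)) { note(rows, msg); bad[rows] <<- TRUE }
  }
  mark(!(raw$axis %in% qa_axes),
       paste0("invalid axis (expected one of ", paste(qa_axes, collapse = "/"), ")"))
  mark(raw$offset_mm == "" | is.na(offset), "unparseable or missing offset_mm")
  mark(!is.na(offset) & (!is.finite(offset) | abs(offset) >= .offset_sanity_mm),
       sprintf("offset_mm outside sanity bound (|offset| < %g mm)", .offset_sanity_mm))
  mark(raw$energy_pct != "" & is.na(energy), "unparseable energy_pct")
  mark(raw$output_pct != "" & is.na(output), "unparseable output_pct")
  mark(raw$gantry_phase_deg != "" & is.na(phase), "unparseable gantry_phase_deg")
  mark(raw$timestamp == "", "missing timestamp")

  if (length(problems)) {
    ord <- order(problem_lines)
    problems <- problems[ord]
    if (strict) {
      stop("invalid QA log rows:\n  ", paste(problems, collapse = "\n  "),
           call. = FALSE)
    }
    warning("dropped ", sum(bad), " invalid row(s):\n  ",
            paste(problems, collapse = "\n  "), call. = FALSE)
  }

  records <- data.frame(
    timestamp = raw$timestamp,
    unit_id = raw$unit_id,
    axis = raw$axis,
    offset_mm = offset,
    energy_pct = energy,
    output_pct = output,
    gantry_phase_deg = phase,
    stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]
  if (!is.null(unit_filter)) {
    records <- records[records$unit_id %in% unit_filter, , drop = FALSE]
  }
  if (!is.null(axis_filter)) {
    axis_filter <- match.arg(axis_filter, qa_axes, several.ok = TRUE)
    records <- records[records$axis %in% axis_filter, , drop = FALSE]
  }
  rownames(records) <- NULL
  attr(records, "problems") <- problems
  records
}

#' Write a couch QA measurement log
#'
#' Serializes records to the package's CSV dialect. Numeric fields are
#' written with six decimal places, so `read_qa_log(write_qa_log(x))` is the
#' identity for values stated at that precision or coarser.
#'
#' @param records Data frame with the columns of [read_qa_log()]'s result
#'   (optional columns may be absent).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qa_log <- function(records, path) {
  records <- as.data.frame(records)
  for (col in setdiff(qa_log_columns, names(records))) records[[col]] <- NA_real_
  stopifnot(all(records$axis %in% qa_axes) | nrow(records) == 0L)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  out <- data.frame(
    timestamp = as.character(records$timestamp),
    unit_id = as.character(records$unit_id),
    axis = as.character(records$axis),
    offset_mm = fmt(records$offset_mm),
    energy_pct = fmt(records$energy_pct),
    output_pct = fmt(records$output_pct),
    gantry_phase_deg = fmt(records$gantry_phase_deg),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write an applied-offset experiment table
#'
#' The experiment dialect records one detected-offset measurement per row:
#' `axis,applied_mm,detected_x_mm,detected_y_mm,detected_z_mm,energy_pct,`
#' `output_pct,gantry_phase_deg,replicate`, where `axis` is the axis along
#' which the shift was applied and the three `detected_*` columns are the
#' offsets the detector reported on each coordinate.
#'
#' @param path CSV file path.
#' @return `read_offset_experiment()`: a data frame of trials;
#'   `write_offset_experiment()`: `path`, invisibly.
#' @export
read_offset_experiment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("axis", "applied_mm", "detected_x_mm",
                            "detected_y_mm", "detected_z_mm"), names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(experiment_columns, names(raw))) raw[[col]] <- ""
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  trials <- data.frame(
    axis = raw$axis,
    applied_mm = num(raw$applied_mm),
    detected_x_mm = num(raw$detected_x_mm),
    detected_y_mm = num(raw$detected_y_mm),
    detected_z_mm = num(raw$detected_z_mm),
    energy_pct = num(raw$energy_pct),
    output_pct = num(raw$output_pct),
    gantry_phase_deg = num(raw$gantry_phase_deg),
    replicate = {
      r <- num(raw$replicate)
      as.integer(ifelse(is.na(r), 1L, r))
    },
    stringsAsFactors = FALSE
  )
  bad <- !(trials$axis %in% qa_axes) | is.na(trials$applied_mm) |
    abs(trials$applied_mm) > 10 | trials$replicate < 1L
  if (any(bad)) {
    stop("invalid experiment rows at line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  trials
}

#' @rdname read_offset_experiment
#' @param trials Data frame of trials (columns as above).
#' @export
write_offset_experiment <- function(trials, path) {
  trials <- as.data.frame(trials)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  out <- data.frame(
    axis = as.character(trials$axis),
    applied_mm = fmt(trials$applied_mm),
    detected_x_mm = fmt(trials$detected_x_mm),
    detected_y_mm = fmt(trials$detected_y_mm),
    detected_z_mm = fmt(trials$detected_z_mm),
    energy_pct = fmt(trials$energy_pct),
    output_pct = fmt(trials$output_pct),
    gantry_phase_deg = fmt(trials$gantry_phase_deg),
    replicate = as.integer(trials$replicate),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
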