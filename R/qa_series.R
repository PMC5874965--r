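#' Couch axes of the fixed machine (IEC) coordinate system
#'
#' The three axes along which couch offsets are reported: `IECX` (patient
#' left), `IECY` (toward patient head), `IECZ` (patient anterior, i.e. the
#' vertical actuator axis).
#'
#' @format Character vector of length 3.
#' @export
qa_axes <- c("IECX", "IECY", "IECZ")

#' Construct an ordered QA measurement series
#'
#' A `qa_series` holds the ordered scalar offset measurements for one
#' (treatment unit, axis) pair -- the x_i that all control-chart, normality
#' and capability computations consume.
#'
#' @param values Numeric vector of measured offsets in mm (finite).
#' @param timestamps Optional character vector of ISO-8601 date-times,
#'   parallel to `values` and non-decreasing in lexical order. Defaults to a
#'   synthetic daily cadence.
#' @param unit_id Treatment unit identifier, e.g. `"T1"`.
#' @param axis One of [qa_axes].
#'
#' @return An object of class `qa_series`: a list with elements `values`,
#'   `timestamps`, `unit_id`, `axis`, `n`.
#' @examples
#' s <- qa_series(c(-0.1, 0.2, 0.05), unit_id = "T1", axis = "IECZ")
#' s$n
#' @export
qa_series <- function(values, timestamps = NULL, unit_id = "unit", axis = "IECX") {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a qa_series needs at least one observation", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("offset values must be finite", call. = FALSE)
  }
  axis <- match.arg(axis, qa_axes)
  if (is.null(timestamps)) {
    timestamps <- synth_timestamps(length(values))
  }
  timestamps <- as.character(timestamps)
  if (length(timestamps) != length(values)) {
    stop("timestamps and values must have equal length", call. = FALSE)
  }
  if (is.unsorted(timestamps)) {
    stop("timestamps must be non-decreasing", call. = FALSE)
  }
  structure(
    list(
      values = values,
      timestamps = timestamps,
      unit_id = as.character(unit_id)[1L],
      axis = axis,
      n = length(values)
    ),
    class = "qa_series"
  )
}

## Daily measurement cadence starting 2013-01-01; 90 observations ~ 3 months.
synth_timestamps <- function(n, start = "2013-01-01") {
  format(seq(as.Date(start), by = "1 day", length.out = n), "%Y-%m-%dT00:00:00")
}

#' @export
print.qa_series <- function(x, ...) {
  cat(sprintf(
    "QA series: unit %s, axis %s, n = %d\n  mean %.4f mm, sd %.4f mm, range [%.3f, %.3f] mm\n",
    x$unit_id, x$axis, x$n, mean(x$values),
    if (x$n > 1L) stats::sd(x$values) else NA_real_,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Coerce measurements to a qa_series
#'
#' @param x A numeric vector, `qa_series`, or QA-log data frame (see
#'   [read_qa_log()]).
#' @param ... Passed on to methods.
#' @return A `qa_series`.
#' @export
as_qa_series <- function(x, ...) UseMethod("as_qa_series")

#' @export
as_qa_series.qa_series <- function(x, ...) x

#' @rdname as_qa_series
#' @param unit_id,axis Series identity when coercing a bare numeric vector.
#' @param timestamps Optional timestamps when coercing a bare numeric vector.
#' @export
as_qa_series.numeric <- function(x, unit_id = "unit", axis = "IECX",
                                 timestamps = NULL, ...) {
  qa_series(x, timestamps = timestamps, unit_id = unit_id, axis = axis)
}

#' Extract one (unit, axis) series from QA-log records
#'
#' Selects the records matching `unit_id` and `axis` and orders them by
#' timestamp (lexical ISO ordering), ties broken by input order, yielding the
#' measurement series all downstream analyses operate on.
#'
#' @param records QA-log data frame as returned by [read_qa_log()].
#' @param unit_id Treatment unit to select.
#' @param axis Axis to select, one of [qa_axes].
#' @return A [qa_series].
#' @examples
#' recs <- data.frame(
#'   timestamp = c("2013-01-02T00:00:00", "2013-01-01T00:00:00"),
#'   unit_id = "T1", axis = "IECX", offset_mm = c(0.2, -0.1)
#' )
#' to_series(recs, "T1", "IECX")$values
#' @export
to_series <- function(records, unit_id, axis) {
  axis <- match.arg(axis, qa_axes)
  keep <- records$unit_id == unit_id & records$axis == axis
  if (!any(keep)) {
    stop(sprintf("no records match unit '%s', axis %s", unit_id, axis),
         call. = FALSE)
  }
  sel <- records[keep, , drop = FALSE]
  ord <- order(sel$timestamp, seq_len(nrow(sel)))  # stable
  sel <- sel[ord, , drop = FALSE]
  qa_series(sel$offset_mm, timestamps = sel$timestamp,
            unit_id = unit_id, axis = axis)
}
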