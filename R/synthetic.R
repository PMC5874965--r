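## Generators use R's default Mersenne-Twister RNG seeded through set.seed();
## the caller's RNG state is saved and restored around every draw.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Describe a fault segment for the series generator
#'
#' A sustained systematic disturbance over observation indices
#' `[start, end]` (1-based, inclusive): either a constant step `shift_mm`
#' (e.g. a miscalibrated encoder) or a linear drift accumulating
#' `drift_per_obs_mm` per observation (a degrading one).
#'
#' @param start,end 1-based inclusive observation indices, `start <= end`.
#' @param shift_mm Constant shift added over the segment (exclusive with
#'   `drift_per_obs_mm`).
#' @param drift_per_obs_mm Per-observation drift increment; the disturbance
#'   ramps from `drift_per_obs_mm` at `start` to
#'   `(end - start + 1) * drift_per_obs_mm` at `end`.
#' @return Object of class `fault_segment`.
#' @export
fault_segment <- function(start, end, shift_mm = NULL, drift_per_obs_mm = NULL) {
  if (is.null(shift_mm) == is.null(drift_per_obs_mm)) {
    stop("give exactly one of shift_mm or drift_per_obs_mm", call. = FALSE)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("fault segment requires 1 <= start <= end", call. = FALSE)
  }
  structure(
    list(start = start, end = end,
         type = if (is.null(shift_mm)) "drift" else "shift",
         magnitude = if (is.null(shift_mm)) drift_per_obs_mm else shift_mm),
    class = "fault_segment"
  )
}

#' Specification of a synthetic QA measurement series
#'
#' Describes the statistical structure of a simulated couch-offset log for
#' one (unit, axis): an in-control Gaussian core, sporadic setup-error
#' outliers (isolated points beyond 1 mm), sustained fault segments (steps or
#' drifts), and an optional uniform-mixture contamination that defeats
#' normality without moving the mean.
#'
#' @param unit_id,axis Series identity.
#' @param n Number of observations (90 per three-monthly window at a daily
#'   cadence).
#' @param mean_mm,sd_mm In-control process mean and SD, mm (`sd_mm > 0`).
#' @param outlier_rate Probability each point is replaced by a setup-error
#'   outlier, in `[0, 1)`.
#' @param outlier_scale_mm Lower edge of the outlier magnitude band; outliers
#'   are drawn `U(outlier_scale_mm, outlier_scale_mm + 1)` with random sign
#'   and must exceed 1 mm.
#' @param fault_segments List of [fault_segment()]s, non-overlapping, within
#'   `[1, n]`.
#' @param contamination `"none"` or `"uniform_mixture"` (20% of points
#'   replaced by `U(mean - 3 sd, mean + 3 sd)` draws).
#' @param seed Integer seed; output is fully reproducible from it.
#' @return Object of class `series_spec`.
#' @seealso [generate_series()], [preset_series_spec()]
#' @export
series_spec <- function(unit_id = "T1", axis = "IECX", n = 90L,
                        mean_mm = 0, sd_mm = 0.3,
                        outlier_rate = 0, outlier_scale_mm = 1.5,
                        fault_segments = list(),
                        contamination = c("none", "uniform_mixture"),
                        seed = 1L) {
  axis <- match.arg(axis, qa_axes)
  contamination <- match.arg(contamination)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (!is.numeric(sd_mm) || sd_mm <= 0) stop("sd_mm must be > 0", call. = FALSE)
  if (!is.numeric(outlier_rate) || outlier_rate < 0 || outlier_rate >= 1) {
    stop("outlier_rate must be in [0, 1)", call. = FALSE)
  }
  if (outlier_rate > 0 && outlier_scale_mm <= 1) {
    stop("setup-error outliers must exceed 1 mm (outlier_scale_mm > 1)",
         call. = FALSE)
  }
  if (inherits(fault_segments, "fault_segment")) {
    fault_segments <- list(fault_segments)
  }
  covered <- integer(0)
  for (seg in fault_segments) {
    stopifnot(inherits(seg, "fault_segment"))
    if (seg$end > n) stop("fault segment extends past the series", call. = FALSE)
    idx <- seg$start:seg$end
    if (any(idx %in% covered)) {
      stop("fault segments must not overlap", call. = FALSE)
    }
    covered <- c(covered, idx)
  }
  structure(
    list(unit_id = unit_id, axis = axis, n = n, mean_mm = mean_mm,
         sd_mm = sd_mm, outlier_rate = outlier_rate,
         outlier_scale_mm = outlier_scale_mm,
         fault_segments = fault_segments, contamination = contamination,
         seed = as.integer(seed)),
    class = "series_spec"
  )
}

#' Generate a synthetic QA measurement series with ground truth
#'
#' Draws the series described by a [series_spec()]: iid
#' `N(mean_mm, sd_mm^2)` base points; setup-error outliers replacing points
#' at `outlier_rate` with sign-random magnitudes
#' `U(outlier_scale, outlier_scale + 1)`; fault segments adding their step or
#' drift; uniform-mixture contamination replacing a fixed 20% of points with
#' `U(mean - 3 sd, mean + 3 sd)` draws. Timestamps are synthesized at a
#' daily cadence. Identical specs (including seed) give bit-identical
#' output; the caller's RNG state is untouched.
#'
#' @param spec A [series_spec()].
#' @return List with elements `series` (a [qa_series]) and `truth`, a data
#'   frame with one row per observation: `index`, `in_control`, `outlier`,
#'   `contaminated`, `fault_id` (0 = none), `disturbance_mm` (the injected
#'   fault offset).
#' @examples
#' out <- generate_series(series_spec(n = 90, mean_mm = -0.88, sd_mm = 0.542,
#'                                    axis = "IECZ", seed = 7))
#' spc_chart(out$series)
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  n <- spec$n
  with_seed(spec$seed, {
    x <- stats::rnorm(n, spec$mean_mm, spec$sd_mm)
    outlier <- rep(FALSE, n)
    if (spec$outlier_rate > 0) {
      outlier <- stats::runif(n) < spec$outlier_rate
      k <- sum(outlier)
      if (k > 0) {
        mag <- stats::runif(k, spec$outlier_scale_mm, spec$outlier_scale_mm + 1)
        sgn <- ifelse(stats::runif(k) < 0.5, -1, 1)
        x[outlier] <- spec$mean_mm + sgn * mag
      }
    }
    contaminated <- rep(FALSE, n)
    if (spec$contamination == "uniform_mixture") {
      k <- max(1L, floor(0.2 * n))
      contaminated[sample.int(n, k)] <- TRUE
      x[contaminated] <- stats::runif(k, spec$mean_mm - 3 * spec$sd_mm,
                                      spec$mean_mm + 3 * spec$sd_mm)
    }
    fault_id <- integer(n)
    disturbance <- numeric(n)
    for (s in seq_along(spec$fault_segments)) {
      seg <- spec$fault_segments[[s]]
      idx <- seg$start:seg$end
      disturbance[idx] <- if (seg$type == "shift") {
        seg$magnitude
      } else {
        seg$magnitude * seq_along(idx)
      }
      fault_id[idx] <- s
    }
    x <- x + disturbance
    list(
      series = qa_series(x, timestamps = synth_timestamps(n),
                         unit_id = spec$unit_id, axis = spec$axis),
      truth = data.frame(
        index = seq_len(n),
        in_control = !outlier & !contaminated & fault_id == 0L,
        outlier = outlier,
        contaminated = contaminated,
        fault_id = fault_id,
        disturbance_mm = disturbance
      )
    )
  })
}

## Three-monthly (90-observation) per-axis process parameters for the two
## treatment units, as estimated from their QA histories, plus each unit's
## 4-year observation count.
qa_unit_presets <- list(
  T1 = list(
    n_history = 1530L,
    axes = data.frame(
      axis = c("IECX", "IECY", "IECZ"),
      cl_mm = c(-0.062, -0.039, -0.366),
      sigma_mm = c(0.3436, 0.165, 0.377),
      ucl_mm = c(0.650, 0.3418, 0.566),
      lcl_mm = c(-0.775, -0.421, -1.298),
      ad_normal = c(FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE
    )
  ),
  T2 = list(
    n_history = 1388L,
    axes = data.frame(
      axis = c("IECX", "IECY", "IECZ"),
      cl_mm = c(0.046, 0.174, -0.880),
      sigma_mm = c(0.295, 0.171, 0.542),
      ucl_mm = c(0.818, 0.539, 0.236),
      lcl_mm = c(-0.725, -0.192, -1.996),
      ad_normal = c(TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
  )
)

#' Per-unit process parameter presets
#'
#' Returns the published three-monthly process summary for one treatment
#' unit: per-axis center line, overall SD, control limits and the normality
#' verdict of its 90-observation review window, plus the unit's 4-year
#' observation count. These parameterize [preset_series_spec()] so demo and
#' test data reproduce the units' qualitative behaviour.
#'
#' @param unit `"T1"` or `"T2"`.
#' @return List with elements `n_history` and `axes` (a data frame).
#' @export
qa_preset <- function(unit = c("T1", "T2")) {
  unit <- match.arg(unit)
  qa_unit_presets[[unit]]
}

#' Series spec built from a unit preset
#'
#' Convenience constructor: a [series_spec()] whose mean and SD are the
#' preset center line and overall sigma of the chosen unit and axis.
#'
#' @param unit `"T1"` or `"T2"`.
#' @param axis One of [qa_axes].
#' @param n Observations; default one 90-observation review window.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [series_spec()] (outliers, faults,
#'   contamination).
#' @return A [series_spec()].
#' @export
preset_series_spec <- function(unit = c("T1", "T2"), axis = "IECX", n = 90L,
                               seed = 1L, ...) {
  unit <- match.arg(unit)
  axis <- match.arg(axis, qa_axes)
  p <- qa_unit_presets[[unit]]$axes
  row <- p[p$axis == axis, ]
  series_spec(unit_id = unit, axis = axis, n = n,
              mean_mm = row$cl_mm, sd_mm = row$sigma_mm, seed = seed, ...)
}

#' Specification of a synthetic applied-offset experiment
#'
#' Describes the applied-versus-detected experiment the generator emulates:
#' shifts applied along each axis over a grid of magnitudes in both
#' directions, each repeated `replicates` times, with per-read detector noise
#' (`reproducibility_sd_mm`, default 0.2/3 so replicate spread is about
#' +/-0.2 mm), optional per-axis on-axis detection bias linear in the
#' applied shift, cross-axis coupling slopes (default: the cobra-motion
#' coupling of vertical into longitudinal, slope 0.234, i.e. 1.17 mm at
#' 5 mm), and a linear gantry-phase response to lateral shifts whose noise
#' level puts the phase-vs-applied fit near R^2 = 0.996.
#'
#' @param applied_grid_mm Applied shifts; default `+/- 0.5, 1, 2, 5` mm.
#' @param replicates Repeats per (axis, applied value); default 3.
#' @param reproducibility_sd_mm Per-read detector noise SD, mm.
#' @param on_axis_bias_slope Named numeric: bias per mm applied, by axis.
#'   Default `c(IECZ = 1.19/5)` (+1.19 mm detection bias at +5 mm applied on
#'   the vertical axis), others 0.
#' @param coupling Data frame with columns `source`, `target`, `slope`;
#'   default the Z-to-Y cobra coupling at slope 0.234.
#' @param phase_slope_deg_per_mm Gantry-phase response to IECX shifts,
#'   degrees per mm.
#' @param phase_noise_sd_deg Noise SD of the phase readout, degrees.
#' @param seed Integer seed.
#' @return Object of class `experiment_spec`.
#' @export
experiment_spec <- function(applied_grid_mm = c(-5, -2, -1, -0.5, 0.5, 1, 2, 5),
                            replicates = 3L,
                            reproducibility_sd_mm = 0.2 / 3,
                            on_axis_bias_slope = c(IECZ = 1.19 / 5),
                            coupling = data.frame(source = "IECZ",
                                                  target = "IECY",
                                                  slope = 0.234),
                            phase_slope_deg_per_mm = 1.0,
                            phase_noise_sd_deg = 0.17,
                            seed = 1L) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  if (!is.numeric(reproducibility_sd_mm) || reproducibility_sd_mm <= 0) {
    stop("reproducibility_sd_mm must be > 0", call. = FALSE)
  }
  if (any(abs(applied_grid_mm) > 10)) {
    stop("applied offsets beyond 10 mm are outside the sane experiment range",
         call. = FALSE)
  }
  bias <- c(IECX = 0, IECY = 0, IECZ = 0)
  bias[names(on_axis_bias_slope)] <- on_axis_bias_slope
  structure(
    list(applied_grid_mm = applied_grid_mm, replicates = replicates,
         reproducibility_sd_mm = reproducibility_sd_mm,
         on_axis_bias_slope = bias, coupling = coupling,
         phase_slope_deg_per_mm = phase_slope_deg_per_mm,
         phase_noise_sd_deg = phase_noise_sd_deg, seed = as.integer(seed)),
    class = "experiment_spec"
  )
}

#' Generate a synthetic applied-offset experiment with ground truth
#'
#' For every axis x applied value x replicate: the on-axis detected offset is
#' `applied + bias_slope[axis] * applied + noise`; each off-axis detected
#' offset is `coupling_slope * applied + noise` (zero slope where no coupling
#' is specified); the gantry phase responds linearly to IECX shifts; energy
#' and output deltas are pure noise carriers. Reproducible from the spec's
#' seed.
#'
#' @param spec An [experiment_spec()].
#' @return List with `trials` (data frame in the experiment dialect of
#'   [read_offset_experiment()]) and `truth` (the injected bias slopes and
#'   coupling table).
#' @examples
#' exp <- generate_experiment(experiment_spec(seed = 3))
#' recovery_analysis(exp$trials)
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  grid <- expand.grid(axis = qa_axes, applied_mm = spec$applied_grid_mm,
                      replicate = seq_len(spec$replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$axis, qa_axes), grid$applied_mm,
                     grid$replicate), , drop = FALSE]
  rownames(grid) <- NULL
  n <- nrow(grid)
  slope_matrix <- diag(3)
  dimnames(slope_matrix) <- list(source = qa_axes, detected = qa_axes)
  diag(slope_matrix) <- 1 + spec$on_axis_bias_slope[qa_axes]
  for (k in seq_len(nrow(spec$coupling))) {
    slope_matrix[spec$coupling$source[k], spec$coupling$target[k]] <-
      spec$coupling$slope[k]
  }
  with_seed(spec$seed, {
    detected <- sapply(qa_axes, function(tgt) {
      slope_matrix[cbind(grid$axis, tgt)] * grid$applied_mm +
        stats::rnorm(n, 0, spec$reproducibility_sd_mm)
    })
    phase <- ifelse(grid$axis == "IECX",
                    spec$phase_slope_deg_per_mm * grid$applied_mm, 0) +
      stats::rnorm(n, 0, spec$phase_noise_sd_deg)
    trials <- data.frame(
      axis = grid$axis,
      applied_mm = grid$applied_mm,
      detected_x_mm = detected[, "IECX"],
      detected_y_mm = detected[, "IECY"],
      detected_z_mm = detected[, "IECZ"],
      energy_pct = stats::rnorm(n, 0, 0.1),
      output_pct = stats::rnorm(n, 0, 0.2),
      gantry_phase_deg = phase,
      replicate = grid$replicate,
      stringsAsFactors = FALSE
    )
    list(trials = trials,
         truth = list(slope_matrix = slope_matrix,
                      on_axis_bias_slope = spec$on_axis_bias_slope,
                      coupling = spec$coupling,
                      phase_slope_deg_per_mm = spec$phase_slope_deg_per_mm))
  })
}
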