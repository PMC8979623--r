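#' Uniformly sampled calibrated signal
#'
#' The basic physical time-series container: values at a fixed sample rate
#' starting at `t0`, with a unit and a label.  Pressure is carried in mmHg,
#' Doppler velocity in cm/s, flow in mL/s and ECG in arbitrary units.
#'
#' @param values Numeric vector of physical values (finite, length >= 2).
#' @param rate Sample rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param unit Unit string.
#' @param label Human-readable label.
#' @return An object of class `pvz_signal`.
#' @export
calibrated_signal <- function(values, rate, t0 = 0, unit = "", label = "") {
  if (!is.numeric(values) || length(values) < 2) {
    pvz_stop("pvz_data_error", "signal needs at least 2 samples")
  }
  if (!all(is.finite(values))) {
    pvz_stop("pvz_data_error", "signal values must be finite")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    pvz_stop("pvz_data_error", "sample rate must be positive")
  }
  structure(
    list(values = as.numeric(values), rate = rate, t0 = t0,
         unit = unit, label = label),
    class = "pvz_signal"
  )
}

signal_times <- function(s) s$t0 + (seq_along(s$values) - 1) / s$rate

signal_duration <- function(s) (length(s$values) - 1) / s$rate

#' @export
print.pvz_signal <- function(x, ...) {
  cat(sprintf("<pvz_signal '%s': %d samples @ %g Hz, t0 = %g s, unit = %s>\n",
              x$label, length(x$values), x$rate, x$t0, x$unit))
  invisible(x)
}

new_raw_trace <- function(columns, rows) {
  structure(list(columns = as.integer(columns), rows = as.numeric(rows)),
            class = "pvz_trace")
}

#' Detect a bright line trace by column-wise centroid
#'
#' Scans every pixel column of the region and estimates the trace position as
#' the intensity-weighted centroid row of pixels at or above `threshold`,
#' giving sub-pixel (fractional-row) estimates.  Columns with no
#' super-threshold pixel are marked missing (`NA`).  Clinical displays draw
#' pressure and ECG traces near-white on a near-black background, so the
#' default threshold of 0.5 separates trace from background and gridlines.
#'
#' @param image A `pvz_capture`.
#' @param region A `pvz_region` with `trace_kind` `"line_trace"` or `"ecg"`.
#' @param threshold Normalised intensity threshold in `[0, 1]`.
#' @return A `pvz_trace`: 0-based `columns` and fractional `rows`
#'   (`NA` where undetected).
#' @export
detect_line_trace <- function(image, region, threshold = 0.5) {
  stopifnot(inherits(image, "pvz_capture"), inherits(region, "pvz_region"))
  if (!region$trace_kind %in% c("line_trace", "ecg")) {
    pvz_stop("pvz_config_error",
             "detect_line_trace requires a line_trace or ecg region, got '%s'",
             region$trace_kind)
  }
  check_region_in_image(region, image)
  cols <- region$left:(region$right - 1L)
  row0 <- region$top
  sub <- image$pixels[(region$top + 1L):region$bottom,
                      (region$left + 1L):region$right, drop = FALSE]
  mask <- sub >= threshold
  w <- sub * mask
  wsum <- colSums(w)
  # centroid in 0-based image rows; rows of `sub` are offset by region$top
  cent <- colSums(w * (seq_len(nrow(sub)) - 1L)) / wsum + row0
  cent[wsum == 0] <- NA_real_
  if (mean(is.na(cent)) > 0.5) {
    pvz_stop("pvz_detection_error", "trace not found in region")
  }
  new_raw_trace(cols, cent)
}

#' Trace a Doppler spectral envelope
#'
#' For each pixel column, finds the outermost super-threshold pixel row --
#' the row farthest from the zero-velocity baseline in the envelope
#' direction -- matching the maximum-velocity-edge semantics of a spectral
#' envelope (rather than the modal velocity at peak brightness).  The raw
#' per-column edge is then median-smoothed over a 5-column window to
#' suppress single-column speckle.  Columns with no super-threshold pixel
#' are marked missing.
#'
#' @inheritParams detect_line_trace
#' @param region A `pvz_region` with `trace_kind = "doppler_envelope"`,
#'   which fixes `baseline_row` and `envelope_direction`.
#' @return A `pvz_trace` of the smoothed envelope.
#' @export
detect_doppler_envelope <- function(image, region, threshold = 0.5) {
  stopifnot(inherits(image, "pvz_capture"), inherits(region, "pvz_region"))
  if (region$trace_kind != "doppler_envelope") {
    pvz_stop("pvz_config_error",
             "detect_doppler_envelope requires a doppler_envelope region")
  }
  check_region_in_image(region, image)
  cols <- region$left:(region$right - 1L)
  sub <- image$pixels[(region$top + 1L):region$bottom,
                      (region$left + 1L):region$right, drop = FALSE]
  upward <- region$envelope_direction == "above_baseline"
  edge <- apply(sub >= threshold, 2, function(m) {
    hit <- which(m)
    if (length(hit) == 0) return(NA_real_)
    if (upward) min(hit) - 1 else max(hit) - 1
  })
  edge <- edge + region$top
  if (mean(is.na(edge)) > 0.5) {
    pvz_stop("pvz_detection_error", "trace not found in region")
  }
  new_raw_trace(cols, rolling_median(edge, 5L))
}

# centered rolling median that tolerates NAs: the window shrinks
# symmetrically at the edges (an asymmetric window would bias steep
# envelope ramps) and skips missing neighbours; a missing center stays
# missing
rolling_median <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    hi <- min(h, i - 1L, n - i)
    win <- x[(i - hi):(i + hi)]
    out[i] <- stats::median(win, na.rm = TRUE)
  }
  out
}

#' Fill occlusion gaps in a raw trace
#'
#' Screen captures carry cursors and annotations that occlude short runs of
#' the trace.  Interior missing columns are linearly interpolated between
#' the nearest detected neighbours; leading and trailing missing columns are
#' dropped (extrapolating beyond the detected pixels would invent data).
#'
#' @param trace A `pvz_trace`, possibly with `NA` rows.
#' @return A gap-free `pvz_trace`, possibly shorter at the ends.
#' @export
fill_gaps <- function(trace) {
  stopifnot(inherits(trace, "pvz_trace"))
  det <- which(!is.na(trace$rows))
  if (length(det) < 2) {
    pvz_stop("pvz_detection_error",
             "fewer than 2 detected columns; cannot fill gaps")
  }
  keep <- det[1]:det[length(det)]
  cols <- trace$columns[keep]
  rows <- trace$rows[keep]
  if (anyNA(rows)) {
    rows <- stats::approx(cols[!is.na(rows)], rows[!is.na(rows)],
                          xout = cols, method = "linear")$y
  }
  new_raw_trace(cols, rows)
}

#' Map a pixel trace to physical time and value
#'
#' Applies the affine anchor maps of an [axis_calibration()] to a gap-free
#' trace, producing a (generally nonuniformly sampled) physical time series:
#' one `(time, value)` pair per pixel column.
#'
#' @param trace A gap-free `pvz_trace`.
#' @param cal A `pvz_calibration`.
#' @param label Label for the resulting signal.
#' @return An object of class `pvz_sampled` with fields `times`, `values`,
#'   `unit`, `label`; feed it to [resample_uniform()].
#' @export
calibrate_trace <- function(trace, cal, label = "") {
  stopifnot(inherits(trace, "pvz_trace"), inherits(cal, "pvz_calibration"))
  if (anyNA(trace$rows)) {
    pvz_stop("pvz_data_error", "trace has gaps; run fill_gaps() first")
  }
  structure(
    list(times = cal_time(cal, trace$columns),
         values = cal_value(cal, trace$rows),
         unit = cal$unit, label = label),
    class = "pvz_sampled"
  )
}

#' Resample onto a uniform grid
#'
#' Linearly interpolates a (possibly nonuniform) calibrated sample sequence
#' onto a uniform grid at `rate` spanning `[t_first, t_last]`.  Linear
#' interpolation cannot overshoot, so monotone segments keep their bounds.
#' The default 1000 Hz comfortably oversamples the sub-500 Hz content of a
#' clinical sweep.
#'
#' @param x A `pvz_sampled` (times + values) or an already-uniform
#'   `pvz_signal`.
#' @param rate Target sample rate in Hz.
#' @return A uniform `pvz_signal` at `rate`.
#' @export
resample_uniform <- function(x, rate = 1000) {
  if (inherits(x, "pvz_signal")) {
    x <- structure(list(times = signal_times(x), values = x$values,
                        unit = x$unit, label = x$label),
                   class = "pvz_sampled")
  }
  stopifnot(inherits(x, "pvz_sampled"))
  if (length(x$times) < 2) {
    pvz_stop("pvz_data_error", "need at least 2 samples to resample")
  }
  if (any(diff(x$times) <= 0)) {
    pvz_stop("pvz_data_error", "sample times must be strictly increasing")
  }
  t0 <- x$times[1]
  t1 <- x$times[length(x$times)]
  grid <- seq(t0, t1, by = 1 / rate)
  vals <- stats::approx(x$times, x$values, xout = grid, method = "linear")$y
  calibrated_signal(vals, rate = rate, t0 = t0, unit = x$unit, label = x$label)
}
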