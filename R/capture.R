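#' Load a screen capture as a grayscale image
#'
#' Reads a PNG or JPEG screen capture and converts it to a grayscale
#' intensity matrix in `[0, 1]`.  Colour images are converted with the
#' Rec. 709 luminance weights (0.2126 R + 0.7152 G + 0.0722 B); an alpha
#' channel, if present, is ignored.
#'
#' Pixel coordinates throughout the package are 0-based: pixel row `r`,
#' column `c` of the capture is `pixels[r + 1, c + 1]`, and rows increase
#' downward (image convention).
#'
#' @param path Path to a PNG or JPEG file.
#' @param kind Capture kind, one of `"pressure"`, `"doppler"`, `"ecg-only"`.
#' @return An object of class `pvz_capture` with fields `pixels`
#'   (height x width matrix of intensities in `[0, 1]`), `width`, `height`,
#'   `source_path` and `capture_kind`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(1, 50, 100), f)
#' cap <- load_capture(f, "pressure")
#' cap$width; cap$height
#' @export
load_capture <- function(path, kind = c("pressure", "doppler", "ecg-only")) {
  kind <- match.arg(kind)
  if (!file.exists(path) || dir.exists(path)) {
    pvz_stop("pvz_input_error", "capture image not found: '%s'", path)
  }
  if (file.size(path) == 0) {
    pvz_stop("pvz_input_error", "capture image is empty: '%s'", path)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      # fall back on content sniffing for extension-less files
      {
        magic <- readBin(path, "raw", n = 8)
        if (length(magic) >= 8 &&
            identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
          png::readPNG(path)
        } else {
          jpeg::readJPEG(path)
        }
      }
    ),
    error = function(e) {
      pvz_stop("pvz_input_error", "cannot decode capture image '%s': %s",
               path, conditionMessage(e))
    }
  )
  px <- to_grayscale(raw)
  if (nrow(px) < 2 || ncol(px) < 2) {
    pvz_stop("pvz_input_error", "capture image '%s' is smaller than 2x2", path)
  }
  structure(
    list(pixels = px, width = ncol(px), height = nrow(px),
         source_path = path, capture_kind = kind),
    class = "pvz_capture"
  )
}

# array from readPNG/readJPEG -> grayscale matrix via Rec.709 luminance
to_grayscale <- function(a) {
  if (is.matrix(a)) return(pmin(pmax(a, 0), 1))
  stopifnot(length(dim(a)) == 3)
  if (dim(a)[3] >= 3) {
    g <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  } else {
    g <- a[, , 1]  # gray + alpha
  }
  pmin(pmax(g, 0), 1)
}

#' @export
print.pvz_capture <- function(x, ...) {
  cat(sprintf("<pvz_capture %s: %d x %d px, '%s'>\n",
              x$capture_kind, x$width, x$height, x$source_path))
  invisible(x)
}

#' Define a rectangular region of interest on a capture
#'
#' Encodes the user's "point at the waveform" step: a half-open pixel
#' rectangle `[left, right) x [top, bottom)` (0-based) plus the kind of trace
#' expected inside it.  Doppler envelope regions additionally carry the pixel
#' row of the zero-velocity baseline and the side of the baseline the
#' envelope lies on.
#'
#' @param left,top,right,bottom 0-based pixel bounds, half-open.
#' @param trace_kind `"line_trace"`, `"doppler_envelope"` or `"ecg"`.
#' @param envelope_direction For Doppler regions: `"above_baseline"`
#'   (envelope at smaller row numbers than the baseline, i.e. towards the
#'   transducer) or `"below_baseline"`.
#' @param baseline_row 0-based pixel row of the zero-velocity line
#'   (Doppler regions only); must fall inside the rectangle.
#' @return An object of class `pvz_region`.
#' @export
region_spec <- function(left, top, right, bottom,
                        trace_kind = c("line_trace", "doppler_envelope", "ecg"),
                        envelope_direction = NULL, baseline_row = NULL) {
  trace_kind <- match.arg(trace_kind)
  for (v in list(left, top, right, bottom)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      pvz_stop("pvz_config_error", "region bounds must be non-negative integers")
    }
  }
  if (right <= left || bottom <= top) {
    pvz_stop("pvz_config_error",
             "region rectangle is empty: [%d, %d) x [%d, %d)",
             left, right, top, bottom)
  }
  if (trace_kind == "doppler_envelope") {
    if (is.null(baseline_row)) {
      pvz_stop("pvz_config_error",
               "doppler_envelope region requires baseline_row")
    }
    if (baseline_row < top || baseline_row >= bottom) {
      pvz_stop("pvz_config_error",
               "baseline_row %d outside region rows [%d, %d)",
               baseline_row, top, bottom)
    }
    envelope_direction <- match.arg(envelope_direction,
                                    c("above_baseline", "below_baseline"))
  }
  structure(
    list(left = as.integer(left), top = as.integer(top),
         right = as.integer(right), bottom = as.integer(bottom),
         trace_kind = trace_kind,
         envelope_direction = envelope_direction,
         baseline_row = if (!is.null(baseline_row)) as.integer(baseline_row)),
    class = "pvz_region"
  )
}

check_region_in_image <- function(region, image) {
  if (region$right > image$width || region$bottom > image$height) {
    pvz_stop("pvz_config_error",
             "region [%d, %d) x [%d, %d) exceeds image %d x %d",
             region$left, region$right, region$top, region$bottom,
             image$width, image$height)
  }
  invisible(region)
}

#' Axis calibration from two anchors per axis
#'
#' Maps pixel coordinates to physical coordinates by two affine anchor pairs
#' per axis: two pixel columns with their times in seconds, and two pixel
#' rows with their physical values.  Pixel rows increase downward, so the
#' y-scale is typically negative for quantities plotted upward; any nonzero
#' slope is accepted.
#'
#' @param x_px,x_time Two pixel columns and the times (s) they map to.
#' @param y_px,y_value Two pixel rows and the physical values they map to.
#' @param unit Unit of the calibrated values (e.g. `"mmHg"`, `"cm/s"`).
#' @return An object of class `pvz_calibration` carrying the affine
#'   coefficients `time = x_slope * column + x_intercept`,
#'   `value = y_slope * row + y_intercept`.
#' @examples
#' cal <- axis_calibration(c(0, 100), c(0, 1), c(0, 200), c(100, 0), "mmHg")
#' @export
axis_calibration <- function(x_px, x_time, y_px, y_value, unit) {
  stopifnot(length(x_px) == 2, length(x_time) == 2,
            length(y_px) == 2, length(y_value) == 2)
  if (x_px[1] == x_px[2] || y_px[1] == y_px[2]) {
    pvz_stop("pvz_config_error",
             "calibration anchors must have distinct pixel coordinates on each axis")
  }
  x_slope <- (x_time[2] - x_time[1]) / (x_px[2] - x_px[1])
  y_slope <- (y_value[2] - y_value[1]) / (y_px[2] - y_px[1])
  if (x_slope <= 0) {
    pvz_stop("pvz_config_error",
             "time axis calibration must be strictly increasing with pixel column")
  }
  if (y_slope == 0) {
    pvz_stop("pvz_config_error", "value axis calibration has zero scale")
  }
  structure(
    list(x_slope = x_slope, x_intercept = x_time[1] - x_slope * x_px[1],
         y_slope = y_slope, y_intercept = y_value[1] - y_slope * y_px[1],
         unit = as.character(unit),
         x_px = as.numeric(x_px), x_time = as.numeric(x_time),
         y_px = as.numeric(y_px), y_value = as.numeric(y_value)),
    class = "pvz_calibration"
  )
}

cal_time <- function(cal, column) cal$x_slope * column + cal$x_intercept
cal_value <- function(cal, row) cal$y_slope * row + cal$y_intercept
# inverses, used by the fixture renderer to place physical signals on pixels
cal_column <- function(cal, time) (time - cal$x_intercept) / cal$x_slope
cal_row <- function(cal, value) (value - cal$y_intercept) / cal$y_slope
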