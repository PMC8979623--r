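#' Rendering style for synthetic screen captures
#'
#' Controls how a fixture signal is drawn as a clinical-monitor-like image:
#' sweep speed in pixels per second, panel heights, trace/background/grid
#' intensities, and the Doppler speckle model.  Speckle emulates spectral
#' broadening: in-band pixels drop out (pepper) at `speckle_density`, and a
#' thin margin of `salt_margin_px` just outside the envelope gains bright
#' pixels (salt) at the same density.
#'
#' @param px_per_second Horizontal sweep speed, px/s.  The default matches
#'   a full-HD screen capture of a 6-8 s sweep (~250 px/s), the resolution
#'   regime in which a 5-column median suppresses speckle without blunting
#'   systolic peaks.
#' @param waveform_height,ecg_height Panel heights, px.
#' @param background,trace_intensity,grid_intensity,band_intensity
#'   Normalised intensities in `[0, 1]`; traces must sit above the
#'   detection threshold, grid below it.
#' @param grid_px Gridline spacing, px.
#' @param speckle_density Fraction of affected pixels (Doppler only).
#' @param salt_margin_px How far outside the envelope salt noise reaches.
#' @param value_margin_px Blank margin between the trace extremes and the
#'   panel edge.
#' @param max_width Widest drawable image, px.
#' @return An object of class `pvz_render_style`.
#' @export
render_style <- function(px_per_second = 250,
                         waveform_height = 300, ecg_height = 100,
                         background = 0.04, trace_intensity = 1.0,
                         grid_intensity = 0.22, band_intensity = 0.85,
                         grid_px = 50,
                         speckle_density = 0.1, salt_margin_px = 1,
                         value_margin_px = 15, max_width = 4000) {
  if (px_per_second <= 0) {
    pvz_stop("pvz_config_error", "px_per_second must be positive")
  }
  structure(
    list(px_per_second = px_per_second,
         waveform_height = as.integer(waveform_height),
         ecg_height = as.integer(ecg_height),
         background = background, trace_intensity = trace_intensity,
         grid_intensity = grid_intensity, band_intensity = band_intensity,
         grid_px = as.integer(grid_px),
         speckle_density = speckle_density,
         salt_margin_px = as.integer(salt_margin_px),
         value_margin_px = as.integer(value_margin_px),
         max_width = as.integer(max_width)),
    class = "pvz_render_style"
  )
}

# draw a sub-pixel path as an anti-aliased trace: the two pixels straddling
# the fractional row split the full intensity, so the intensity-weighted
# centroid recovers the path exactly; dim vertical connectors (below the
# detection threshold) keep steep traces visually continuous
draw_line_path <- function(img, cols1, rows0, intensity, connector) {
  h <- nrow(img)
  for (i in seq_along(cols1)) {
    r0 <- floor(rows0[i])
    f <- rows0[i] - r0
    if (r0 >= 0 && r0 < h) {
      img[r0 + 1, cols1[i]] <- max(img[r0 + 1, cols1[i]], intensity * (1 - f))
    }
    if (f > 0 && r0 + 1 >= 0 && r0 + 1 < h) {
      img[r0 + 2, cols1[i]] <- max(img[r0 + 2, cols1[i]], intensity * f)
    }
    if (i > 1) {
      lo <- ceiling(min(rows0[i - 1], rows0[i])) + 1
      hi <- floor(max(rows0[i - 1], rows0[i])) - 1
      if (hi >= lo && lo >= 0 && hi < h) {
        seg <- (lo:hi) + 1
        img[seg, cols1[i]] <- pmax(img[seg, cols1[i]], connector)
      }
    }
  }
  img
}

#' Render a fixture signal as a screen-capture image
#'
#' Draws the hemodynamic signal in a waveform panel and the ECG in a strip
#' below it, on a dark background with dim gridlines, exactly as the
#' digitizer expects to find them.  Pressure (and ECG) traces are
#' anti-aliased 1-2 px polylines; a Doppler spectrogram is a filled band
#' from the zero-velocity baseline up to the velocity envelope, with seeded
#' speckle.  The returned ground-truth bundle (true per-column pixel path,
#' true calibrations, R times) is what makes every digitizer test an exact
#' round trip.
#'
#' @param signal Waveform `pvz_signal` (pressure mmHg or velocity cm/s).
#' @param ecg ECG `pvz_signal` covering the same time span.
#' @param style A `pvz_render_style`.
#' @param kind `"pressure_trace"` or `"doppler_spectrogram"`.
#' @param seed Seed for the speckle noise.
#' @param r_times True R times to store in the ground truth.
#' @param path Optional PNG output path.
#' @return An object of class `pvz_render`: `capture` (a `pvz_capture`),
#'   `regions` (`waveform`, `ecg`), `calibrations` (`waveform`, `ecg`),
#'   and `truth` (`columns`, `waveform_rows`, `ecg_rows`, `r_times`).
#' @export
render_capture <- function(signal, ecg, style = render_style(),
                           kind = c("pressure_trace", "doppler_spectrogram"),
                           seed = 1, r_times = numeric(0), path = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(signal, "pvz_signal"), inherits(ecg, "pvz_signal"),
            inherits(style, "pvz_render_style"))
  duration <- min(signal_duration(signal), signal_duration(ecg))
  W <- floor(duration * style$px_per_second)
  if (W > style$max_width) {
    pvz_stop("pvz_render_error",
             "signal spans %d px at %g px/s, wider than max_width %d",
             W, style$px_per_second, style$max_width)
  }
  if (W < 10) {
    pvz_stop("pvz_render_error", "signal too short to render")
  }
  wh <- style$waveform_height
  eh <- style$ecg_height
  H <- wh + eh
  m <- style$value_margin_px
  img <- matrix(style$background, nrow = H, ncol = W)
  img[seq(1, H, by = style$grid_px), ] <- style$grid_intensity
  img[, seq(1, W, by = style$grid_px)] <- style$grid_intensity

  cols0 <- 0:(W - 1)
  t_col <- signal$t0 + cols0 / style$px_per_second
  v <- stats::approx(signal_times(signal), signal$values, xout = t_col)$y
  ve <- stats::approx(signal_times(ecg), ecg$values, xout = t_col)$y

  # waveform panel value -> row map (rows grow downward)
  if (kind == "doppler_spectrogram") {
    vmax <- max(v)
    if (vmax <= 0) pvz_stop("pvz_render_error", "velocity signal is non-positive")
    baseline_row <- wh - m
    ppu <- (wh - 2 * m) / vmax
    wave_cal <- axis_calibration(c(0, W - 1), c(t_col[1], t_col[W]),
                                 c(baseline_row, m), c(0, vmax), signal$unit)
  } else {
    vlo <- min(v); vhi <- max(v)
    if (vhi <= vlo) { vhi <- vlo + 1 }
    wave_cal <- axis_calibration(c(0, W - 1), c(t_col[1], t_col[W]),
                                 c(wh - m, m), c(vlo, vhi), signal$unit)
  }
  wave_rows <- cal_row(wave_cal, v)

  elo <- min(ve); ehi <- max(ve)
  if (ehi <= elo) ehi <- elo + 1
  ecg_cal <- axis_calibration(c(0, W - 1), c(t_col[1], t_col[W]),
                              c(H - 8, wh + 8), c(elo, ehi), ecg$unit)
  ecg_rows <- cal_row(ecg_cal, ve)

  if (kind == "pressure_trace") {
    img <- draw_line_path(img, cols0 + 1, wave_rows,
                          style$trace_intensity, 0.4 * style$trace_intensity)
  } else {
    baseline_row <- wh - m
    img <- with_seed(seed, {
      for (i in seq_along(cols0)) {
        rho <- wave_rows[i]
        r0 <- floor(rho)
        f <- rho - r0
        if (r0 + 1 <= baseline_row) {
          band <- (r0 + 1):baseline_row + 1
          img[band, i] <- style$band_intensity
          # in-band pepper dropouts; the first band row is the drawn
          # envelope boundary itself and stays solid
          interior <- band[-1]
          drop <- interior[stats::runif(length(interior)) < style$speckle_density]
          img[drop, i] <- stats::runif(length(drop), 0.05, 0.3)
        }
        if (r0 >= 0 && r0 < H) {
          img[r0 + 1, i] <- style$band_intensity * (1 - f)
        }
        # salt just outside the envelope edge (spectral broadening)
        if (style$salt_margin_px > 0) {
          marg <- max(0, r0 - style$salt_margin_px):max(0, r0 - 1)
          if (r0 >= 1) {
            salt <- marg[stats::runif(length(marg)) < style$speckle_density]
            img[salt + 1, i] <- pmax(img[salt + 1, i],
                                     stats::runif(length(salt), 0.7, 1.0))
          }
        }
      }
      img
    })
  }
  img <- draw_line_path(img, cols0 + 1, ecg_rows,
                        style$trace_intensity, 0.4 * style$trace_intensity)
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(path)) png::writePNG(img, path)

  capture_kind <- if (kind == "doppler_spectrogram") "doppler" else "pressure"
  capture <- structure(
    list(pixels = img, width = W, height = H,
         source_path = path %||% "<in-memory>", capture_kind = capture_kind),
    class = "pvz_capture"
  )
  wave_region <- if (kind == "doppler_spectrogram") {
    region_spec(0, 0, W, wh, "doppler_envelope",
                envelope_direction = "above_baseline",
                baseline_row = wh - m)
  } else {
    region_spec(0, 0, W, wh, "line_trace")
  }
  structure(
    list(capture = capture,
         regions = list(waveform = wave_region,
                        ecg = region_spec(0, wh, W, H, "ecg")),
         calibrations = list(waveform = wave_cal, ecg = ecg_cal),
         truth = list(columns = cols0, waveform_rows = wave_rows,
                      ecg_rows = ecg_rows, r_times = r_times,
                      px_per_second = style$px_per_second)),
    class = "pvz_render"
  )
}

#' Generate a complete synthetic study session on disk
#'
#' Builds the full oracle chain for one or more stages: a half-sine flow
#' pulse train, Windkessel pressure, synthetic ECGs, both captures rendered
#' as PNGs (independently simulated per capture, emulating asynchronous
#' acquisition), a ground-truth JSON bundle, and a ready-to-run session
#' config pointing at the images.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-stage and per-capture seeds derive from it.
#' @param stages Number of stages to generate.
#' @param heart_rate,stroke_volume,ejection_fraction,jitter Flow-pulse
#'   parameters (vectors recycled across stages).
#' @param rc,rp,compliance Windkessel parameters (recycled across stages).
#' @param pa_diameter_cm PA diameter used for the velocity rendering and
#'   written into the config.
#' @param duration Capture length, s.
#' @param noise If `FALSE`, Doppler speckle is disabled.
#' @param style A `pvz_render_style`.
#' @return Invisibly, a list with `config` (path to the session YAML),
#'   `truth` (per-stage Windkessel parameters and analytic impedance) and
#'   `stage_dirs`.
#' @export
render_fixture_session <- function(out_dir, seed = 1, stages = 1,
                                   heart_rate = 75, stroke_volume = 70,
                                   ejection_fraction = 0.35, jitter = 0.03,
                                   rc = 0.05, rp = 0.8, compliance = 3,
                                   pa_diameter_cm = 2.2, duration = 8,
                                   noise = TRUE, style = render_style()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!noise) style$speckle_density <- 0
  hr <- rep_len(heart_rate, stages)
  sv <- rep_len(stroke_volume, stages)
  ef <- rep_len(ejection_fraction, stages)
  jt <- rep_len(jitter, stages)
  rc <- rep_len(rc, stages)
  rp <- rep_len(rp, stages)
  cp <- rep_len(compliance, stages)
  dia <- rep_len(pa_diameter_cm, stages)

  stage_cfgs <- list()
  truth <- list()
  for (s in seq_len(stages)) {
    wk <- windkessel_params(rc[s], rp[s], cp[s])
    area <- csa_from_diameter(dia[s])$area
    base_seed <- (seed * 1000L + s * 10L) %% .Machine$integer.max

    # pressure capture: its own simulated run (asynchronous acquisition)
    simp <- simulate_flow(hr[s], sv[s], duration, ef[s], jt[s],
                          seed = base_seed + 1L)
    pressure <- apply_windkessel(simp$flow, wk)
    ecg_p <- simulate_ecg(hr[s], duration, r_times = simp$r_times)
    p_png <- file.path(out_dir, sprintf("stage%d_pressure.png", s))
    rp_render <- render_capture(pressure, ecg_p$ecg, style, "pressure_trace",
                                seed = base_seed + 2L,
                                r_times = simp$r_times, path = p_png)

    # doppler capture: independent run of the same physiology
    simd <- simulate_flow(hr[s], sv[s], duration, ef[s], jt[s],
                          seed = base_seed + 3L)
    velocity <- simd$flow
    velocity$values <- velocity$values / area
    velocity$unit <- "cm/s"
    velocity$label <- "simulated PA velocity"
    ecg_d <- simulate_ecg(hr[s], duration, r_times = simd$r_times)
    d_png <- file.path(out_dir, sprintf("stage%d_doppler.png", s))
    rd_render <- render_capture(velocity, ecg_d$ecg, style,
                                "doppler_spectrogram",
                                seed = base_seed + 4L,
                                r_times = simd$r_times, path = d_png)

    stage_cfgs[[s]] <- list(
      label = sprintf("stage%d", s),
      pa_diameter_cm = dia[s],
      pressure = capture_config_block(p_png, rp_render),
      doppler = capture_config_block(d_png, rd_render)
    )
    truth[[s]] <- list(
      label = sprintf("stage%d", s),
      windkessel = list(rc = rc[s], rp = rp[s], compliance = cp[s]),
      heart_rate = hr[s], stroke_volume = sv[s],
      pa_diameter_cm = dia[s],
      tpr = rc[s] + rp[s],
      analytic_modulus_h0_4 = vapply(0:4, function(k) {
        Mod(analytic_impedance(wk, k * hr[s] / 60))
      }, numeric(1))
    )
  }
  cfg_path <- file.path(out_dir, "session.yaml")
  yaml::write_yaml(list(schema_version = 1L, stages = stage_cfgs), cfg_path)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(list(config = cfg_path, truth = truth, out_dir = out_dir))
}

# serialize the regions/calibrations of a render into config-file form
capture_config_block <- function(image_path, render) {
  wr <- render$regions$waveform
  er <- render$regions$ecg
  wc <- render$calibrations$waveform
  ec <- render$calibrations$ecg
  reg <- function(r) {
    out <- list(left = r$left, top = r$top, right = r$right,
                bottom = r$bottom, trace_kind = r$trace_kind)
    if (!is.null(r$envelope_direction)) {
      out$envelope_direction <- r$envelope_direction
    }
    if (!is.null(r$baseline_row)) out$baseline_row <- r$baseline_row
    out
  }
  cal <- function(cc) {
    list(x_px = cc$x_px, x_time_s = cc$x_time,
         y_px = cc$y_px, y_value = cc$y_value, unit = cc$unit)
  }
  list(image = basename(image_path),
       waveform_region = reg(wr), ecg_region = reg(er),
       waveform_calibration = cal(wc), ecg_calibration = cal(ec))
}
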