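#' Load and validate a session config
#'
#' A session is a YAML file describing one or more study stages.  Each stage
#' pairs one pressure capture with one Doppler capture (pairing is explicit,
#' not inferred from timestamps: the captures are asynchronous by design)
#' plus the PA diameter in cm.  Each capture block names its image file
#' (relative paths resolve against the config file), one waveform region,
#' one ECG region, and the two-anchor axis calibrations for both; optional
#' fields are `include_beats` (0-based), `threshold`, `invert_ecg`.
#' The file must carry `schema_version: 1`.
#'
#' @param path Path to the YAML session config.
#' @return A list of validated stage configs (class `pvz_stage_config`),
#'   in file order.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) {
    pvz_stop("pvz_input_error", "session config not found: '%s'", path)
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    pvz_stop("pvz_config_error", "cannot parse session config '%s': %s",
             path, conditionMessage(e))
  })
  base_dir <- dirname(normalizePath(path))
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    pvz_stop("pvz_config_error", "schema_version: expected 1")
  }
  if (is.null(cfg$stages) || length(cfg$stages) == 0) {
    pvz_stop("pvz_config_error", "stages: at least one stage required")
  }
  lapply(seq_along(cfg$stages), function(i) {
    parse_stage(cfg$stages[[i]], sprintf("stages[%d]", i), base_dir)
  })
}

need_field <- function(x, name, where) {
  if (is.null(x[[name]])) {
    pvz_stop("pvz_config_error", "%s.%s: missing required field", where, name)
  }
  x[[name]]
}

parse_stage <- function(st, where, base_dir) {
  label <- as.character(need_field(st, "label", where))
  dia <- need_field(st, "pa_diameter_cm", where)
  if (!is.numeric(dia) || dia <= 0) {
    pvz_stop("pvz_config_error", "%s.pa_diameter_cm: must be positive", where)
  }
  tol <- st$hr_mismatch_tolerance %||% 0.10
  if (!is.numeric(tol) || tol <= 0 || tol >= 1) {
    pvz_stop("pvz_config_error",
             "%s.hr_mismatch_tolerance: must be in (0, 1)", where)
  }
  structure(
    list(label = label, pa_diameter_cm = dia, hr_mismatch_tolerance = tol,
         pressure = parse_capture(need_field(st, "pressure", where),
                                  paste0(where, ".pressure"), base_dir,
                                  expected = "line_trace"),
         doppler = parse_capture(need_field(st, "doppler", where),
                                 paste0(where, ".doppler"), base_dir,
                                 expected = "doppler_envelope")),
    class = "pvz_stage_config"
  )
}

parse_capture <- function(cc, where, base_dir, expected) {
  img <- as.character(need_field(cc, "image", where))
  if (!grepl("^(/|[A-Za-z]:)", img)) img <- file.path(base_dir, img)
  if (!file.exists(img)) {
    pvz_stop("pvz_input_error", "%s.image: file not found: '%s'", where, img)
  }
  parse_region <- function(r, rwhere) {
    tryCatch(
      region_spec(need_field(r, "left", rwhere), need_field(r, "top", rwhere),
                  need_field(r, "right", rwhere), need_field(r, "bottom", rwhere),
                  trace_kind = need_field(r, "trace_kind", rwhere),
                  envelope_direction = r$envelope_direction,
                  baseline_row = r$baseline_row),
      pvz_config_error = function(e) {
        pvz_stop("pvz_config_error", "%s: %s", rwhere, conditionMessage(e))
      })
  }
  parse_cal <- function(cl, cwhere) {
    tryCatch(
      axis_calibration(unlist(need_field(cl, "x_px", cwhere)),
                       unlist(need_field(cl, "x_time_s", cwhere)),
                       unlist(need_field(cl, "y_px", cwhere)),
                       unlist(need_field(cl, "y_value", cwhere)),
                       unit = need_field(cl, "unit", cwhere)),
      pvz_config_error = function(e) {
        pvz_stop("pvz_config_error", "%s: %s", cwhere, conditionMessage(e))
      })
  }
  wr <- parse_region(need_field(cc, "waveform_region", where),
                     paste0(where, ".waveform_region"))
  if (wr$trace_kind != expected) {
    pvz_stop("pvz_config_error",
             "%s.waveform_region.trace_kind: expected %s, got %s",
             where, expected, wr$trace_kind)
  }
  er <- parse_region(need_field(cc, "ecg_region", where),
                     paste0(where, ".ecg_region"))
  list(image = img,
       waveform_region = wr, ecg_region = er,
       waveform_calibration = parse_cal(
         need_field(cc, "waveform_calibration", where),
         paste0(where, ".waveform_calibration")),
       ecg_calibration = parse_cal(
         need_field(cc, "ecg_calibration", where),
         paste0(where, ".ecg_calibration")),
       include_beats = cc$include_beats,
       threshold = cc$threshold %||% 0.5,
       invert_ecg = isTRUE(cc$invert_ecg))
}

#' Check agreement of heart rates across asynchronous captures
#'
#' Because the pressure and Doppler captures are acquired minutes apart, a
#' composite spectrum is only meaningful when the two heart rates are
#' similar.  Mismatch beyond the tolerance produces a warning string, never
#' a hard failure (asynchronous pairing is the method's premise).
#'
#' @param hr_pressure,hr_doppler Heart rates, bpm (> 0).
#' @param tolerance Relative difference tolerated, as a fraction of the
#'   mean of the two rates.
#' @return `character(0)` on a pass, otherwise a one-element warning
#'   string.
#' @export
check_hr_match <- function(hr_pressure, hr_doppler, tolerance = 0.10) {
  if (hr_pressure <= 0 || hr_doppler <= 0) {
    pvz_stop("pvz_input_error", "heart rates must be positive")
  }
  rel <- abs(hr_pressure - hr_doppler) / mean(c(hr_pressure, hr_doppler))
  if (rel > tolerance) {
    sprintf(paste0("heart-rate mismatch: pressure %.1f bpm vs doppler %.1f bpm ",
                   "(%.1f%% > %.0f%% tolerance); composite spectrum may be biased"),
            hr_pressure, hr_doppler, 100 * rel, 100 * tolerance)
  } else {
    character(0)
  }
}

# digitize one capture: image -> calibrated waveform + ECG -> ARB
process_capture <- function(cap, capture_kind, stage_label,
                            rate = 1000, verbose = FALSE) {
  prefix <- sprintf("stage '%s', %s capture", stage_label, capture_kind)
  pvz_rethrow({
    img <- load_capture(cap$image, capture_kind)
    wave_trace <- if (cap$waveform_region$trace_kind == "doppler_envelope") {
      detect_doppler_envelope(img, cap$waveform_region, cap$threshold)
    } else {
      detect_line_trace(img, cap$waveform_region, cap$threshold)
    }
    wave <- resample_uniform(
      calibrate_trace(fill_gaps(wave_trace), cap$waveform_calibration,
                      label = capture_kind), rate)
    ecg_trace <- detect_line_trace(img, cap$ecg_region, cap$threshold)
    ecg <- resample_uniform(
      calibrate_trace(fill_gaps(ecg_trace), cap$ecg_calibration,
                      label = "ecg"), rate)
    if (cap$invert_ecg) ecg$values <- -ecg$values
    peaks <- detect_r_peaks(ecg)
    beats <- segment_beats(wave, peaks)
    if (!is.null(cap$include_beats)) {
      beats <- select_beats(beats, cap$include_beats)
    }
    arb <- average_beats(beats)
    if (verbose) {
      message(sprintf("[%s] %s: HR %.1f bpm, %d/%d beats, mean %.2f %s",
                      stage_label, capture_kind, peaks$heart_rate,
                      length(beats$included), length(beats$beats),
                      mean(arb$values), arb$unit))
    }
    list(arb = arb, heart_rate = peaks$heart_rate, peaks = peaks,
         beats = beats, waveform = wave, ecg = ecg)
  }, prefix)
}

#' Run the full pipeline for one stage
#'
#' Executes digitize -> calibrate -> resample -> R-peak detection -> beat
#' segmentation -> beat selection -> beat averaging for both captures,
#' converts velocity to flow through the PA cross-sectional area, decomposes
#' both ARBs into harmonics, forms the PVZ spectrum by harmonic index, and
#' derives TPR, Zc and Zs.  All intermediate artifacts are kept on the
#' result for audit.
#'
#' @param stage A `pvz_stage_config` from [load_session()].
#' @param n_harmonics Harmonics to compute above DC.
#' @param reliable_max Catheter-fidelity harmonic limit (metadata).
#' @param zc_range,zs_indices Passed to [derive_parameters()].
#' @param rate Resampling rate, Hz.
#' @param verbose Log per-step scalars to stderr.
#' @return An object of class `pvz_stage_result`: `label`, `spectrum`,
#'   `parameters`, `hr_pressure`, `hr_doppler`, `warnings`, `artifacts`.
#' @export
run_stage <- function(stage, n_harmonics = 10, reliable_max = 3,
                      zc_range = 2:4, zs_indices = c(1, 2),
                      rate = 1000, verbose = FALSE) {
  stopifnot(inherits(stage, "pvz_stage_config"))
  pres <- process_capture(stage$pressure, "pressure", stage$label,
                          rate, verbose)
  dopp <- process_capture(stage$doppler, "doppler", stage$label,
                          rate, verbose)
  cs <- csa_from_diameter(stage$pa_diameter_cm)
  flow_arb <- pvz_rethrow(flow_from_velocity(dopp$arb, cs),
                          sprintf("stage '%s', doppler capture", stage$label))
  p_h <- decompose_harmonics(pres$arb, n_harmonics)
  q_h <- decompose_harmonics(flow_arb, n_harmonics)
  spec <- compute_pvz(p_h, q_h, reliable_max)
  params <- derive_parameters(spec, zc_range, zs_indices)
  warnings <- check_hr_match(pres$heart_rate, dopp$heart_rate,
                             stage$hr_mismatch_tolerance)
  if (verbose) {
    message(sprintf("[%s] TPR %.4f, Zc %.4f, Zs %.4f mmHg·s/mL",
                    stage$label, params$tpr, params$zc, params$zs))
  }
  structure(
    list(label = stage$label, spectrum = spec, parameters = params,
         hr_pressure = pres$heart_rate, hr_doppler = dopp$heart_rate,
         warnings = warnings,
         artifacts = list(pressure = pres, doppler = dopp,
                          flow_arb = flow_arb, csa = cs,
                          pressure_harmonics = p_h, flow_harmonics = q_h)),
    class = "pvz_stage_result"
  )
}

#' @export
print.pvz_stage_result <- function(x, ...) {
  cat(sprintf("<pvz_stage_result '%s': HR %.1f/%.1f bpm%s>\n", x$label,
              x$hr_pressure, x$hr_doppler,
              if (length(x$warnings)) " [warnings]" else ""))
  print(x$parameters)
  invisible(x)
}

results_to_long <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    n <- r$spectrum$n_harmonics
    data.frame(
      stage = r$label,
      harmonic = 0:n,
      frequency_hz = (0:n) * r$spectrum$fundamental_hz_pressure,
      p_modulus = r$spectrum$p_modulus,
      q_modulus = r$spectrum$q_modulus,
      modulus = r$spectrum$modulus,
      phase_deg = c(NA_real_, r$spectrum$phase_deg),
      reliable = 0:n <= r$spectrum$reliable_max_harmonic,
      stringsAsFactors = FALSE
    )
  }))
}

#' Overlay PVZ spectra across stages
#'
#' Plots modulus-vs-harmonic and phase-vs-harmonic panels with one series
#' per stage, the standard way serial impedance measurements are compared.
#' Harmonics beyond the reliability limit of fluid-filled catheters are
#' shaded.
#'
#' @param results List of `pvz_stage_result`.
#' @param path Optional output image path (PNG/PDF via `ggsave`).
#' @return The ggplot object, invisibly.
#' @export
overlay_spectra <- function(results, path = NULL) {
  if (length(results) == 0) {
    pvz_stop("pvz_input_error", "no stage results to plot")
  }
  long <- results_to_long(results)
  df <- rbind(
    data.frame(stage = long$stage, harmonic = long$harmonic,
               value = long$modulus, panel = "Modulus (mmHg·s/mL)"),
    data.frame(stage = long$stage, harmonic = long$harmonic,
               value = long$phase_deg, panel = "Phase (°)")
  )
  df <- df[!is.na(df$value), ]
  rel_max <- min(vapply(results, function(r) r$spectrum$reliable_max_harmonic,
                        integer(1)))
  n_max <- max(df$harmonic)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$harmonic, y = .data$value,
                                        colour = .data$stage)) +
    ggplot2::annotate("rect", xmin = rel_max + 0.5, xmax = n_max + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 0:n_max) +
    ggplot2::labs(x = "Harmonic z(n)", y = NULL, colour = "Stage",
                  title = "Composite pulmonary vascular impedance",
                  subtitle = sprintf(
                    "shaded: beyond catheter-fidelity limit (harmonic %d)",
                    rel_max)) +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 6, dpi = 120)
  }
  invisible(p)
}

results_to_table <- function(results, alt_unit = "wood") {
  do.call(rbind, lapply(results, function(r) {
    p <- r$parameters
    df <- data.frame(
      stage = r$label,
      hr_pressure_bpm = r$hr_pressure,
      hr_doppler_bpm = r$hr_doppler,
      fundamental_hz = p$fundamental_hz,
      tpr_mmHg_s_ml = p$tpr, zc_mmHg_s_ml = p$zc, zs_mmHg_s_ml = p$zs,
      stringsAsFactors = FALSE
    )
    df[[paste0("tpr_", alt_unit)]] <- convert_impedance_units(p$tpr, alt_unit)
    df[[paste0("zc_", alt_unit)]] <- convert_impedance_units(p$zc, alt_unit)
    df[[paste0("zs_", alt_unit)]] <- convert_impedance_units(p$zs, alt_unit)
    df$warnings <- paste(r$warnings, collapse = "; ")
    df
  }))
}

#' Export stage parameters as a CSV table
#'
#' One row per stage: label, heart rates of both captures, fundamental
#' frequency, TPR, Zc and Zs in mmHg·s/mL plus a configured alternate
#' clinical unit, and any heart-rate-mismatch warnings.
#'
#' @param results List of `pvz_stage_result`.
#' @param path Output CSV path.
#' @param alt_unit Alternate unit column set: `"wood"` or `"dyn_s_cm5"`.
#' @return The exported data frame, invisibly.
#' @export
export_table <- function(results, path, alt_unit = "wood") {
  if (length(results) == 0) {
    pvz_stop("pvz_input_error", "no stage results to export")
  }
  df <- results_to_table(results, alt_unit)
  ok <- tryCatch({
    suppressWarnings(utils::write.csv(df, path, row.names = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pvz_stop("pvz_io_error", "cannot write table to '%s'", path)
  invisible(df)
}

#' Export per-harmonic spectra as a CSV table
#'
#' One row per stage and harmonic: index, frequency, |P|, |Q|, impedance
#' modulus, phase difference, and the catheter-reliability flag.
#'
#' @inheritParams export_table
#' @export
export_spectra <- function(results, path) {
  if (length(results) == 0) {
    pvz_stop("pvz_input_error", "no stage results to export")
  }
  df <- results_to_long(results)
  ok <- tryCatch({
    suppressWarnings(utils::write.csv(df, path, row.names = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pvz_stop("pvz_io_error", "cannot write table to '%s'", path)
  invisible(df)
}

#' Run a whole session and write all exports
#'
#' Convenience wrapper used by the command-line interface: loads the
#' config, runs every stage, and writes `parameters.csv`, `spectra.csv`,
#' `overlay.png` and `results.json` into `out_dir`.
#'
#' @param config Path to a session YAML (or a pre-loaded stage list).
#' @param out_dir Output directory, created if needed.
#' @param units Alternate unit for the parameter table.
#' @param ... Passed to [run_stage()] (`n_harmonics`, `zc_range`, ...).
#' @return List of `pvz_stage_result`, invisibly.
#' @export
run_session <- function(config, out_dir, units = "wood", ...) {
  stages <- if (is.character(config)) load_session(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- lapply(stages, run_stage, ...)
  export_table(results, file.path(out_dir, "parameters.csv"), units)
  export_spectra(results, file.path(out_dir, "spectra.csv"))
  overlay_spectra(results, file.path(out_dir, "overlay.png"))
  bundle <- lapply(results, function(r) {
    list(label = r$label,
         hr_pressure_bpm = r$hr_pressure, hr_doppler_bpm = r$hr_doppler,
         parameters = r$parameters[c("tpr", "zc", "zs", "fundamental_hz")],
         modulus = r$spectrum$modulus, phase_deg = r$spectrum$phase_deg,
         reliable_max_harmonic = r$spectrum$reliable_max_harmonic,
         warnings = r$warnings)
  })
  jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(results)
}
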