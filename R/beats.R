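#' Detect ECG R peaks
#'
#' Relative-threshold local-maxima detector: the ECG is detrended by
#' subtracting its median, candidate peaks are local maxima exceeding
#' `rel_threshold` times the peak detrended amplitude, and candidates are
#' accepted tallest-first subject to a refractory spacing (0.3 s by default,
#' i.e. up to 200 bpm).  The amplitude reference is the maximum rather than
#' a high percentile because R waves are narrow: on a clean strip they
#' occupy well under 5% of the samples, so any sample quantile tracks the
#' baseline, not the QRS.  The relative threshold makes detection invariant
#' to amplitude scaling; a config flag upstream inverts the lead for
#' negative R polarity.  Times are reported at sample resolution.
#'
#' @param ecg A uniform-rate `pvz_signal` of at least 2 s.
#' @param refractory Minimum spacing between accepted peaks, seconds.
#' @param rel_threshold Fraction of the peak detrended amplitude a
#'   candidate must exceed.
#' @return An object of class `pvz_rpeaks` with `peak_times` (s, strictly
#'   increasing), `mean_rr` (s) and `heart_rate` (bpm, `60 / mean_rr`).
#' @export
detect_r_peaks <- function(ecg, refractory = 0.3, rel_threshold = 0.6) {
  stopifnot(inherits(ecg, "pvz_signal"))
  if (signal_duration(ecg) < 2) {
    pvz_stop("pvz_data_error", "ECG shorter than 2 s; cannot segment beats")
  }
  x <- ecg$values - stats::median(ecg$values)
  amp <- max(x)
  thr <- rel_threshold * amp
  n <- length(x)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  cand <- which(is_max & x > thr & x > 0)
  if (length(cand) < 2) {
    pvz_stop("pvz_detection_error", "cannot segment beats: fewer than 2 R peaks")
  }
  cand <- cand[order(x[cand], decreasing = TRUE)]
  min_gap <- refractory * ecg$rate
  accepted <- integer(0)
  for (i in cand) {
    if (all(abs(accepted - i) >= min_gap)) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  if (length(accepted) < 2) {
    pvz_stop("pvz_detection_error", "cannot segment beats: fewer than 2 R peaks")
  }
  times <- ecg$t0 + (accepted - 1) / ecg$rate
  mean_rr <- mean(diff(times))
  structure(
    list(peak_times = times, mean_rr = mean_rr, heart_rate = 60 / mean_rr),
    class = "pvz_rpeaks"
  )
}

#' @export
print.pvz_rpeaks <- function(x, ...) {
  cat(sprintf("<pvz_rpeaks: %d peaks, HR %.1f bpm, mean R-R %.3f s>\n",
              length(x$peak_times), x$heart_rate, x$mean_rr))
  invisible(x)
}

#' Segment a signal into beats by R-R interval
#'
#' Cuts the co-captured hemodynamic signal into one beat per consecutive
#' R-peak pair `[R_i, R_{i+1})`, using the ECG as the shared clock.  Partial
#' cycles before the first and after the last usable R peak are discarded.
#' All beats start included; use [select_beats()] to exclude some.
#'
#' @param signal A uniform `pvz_signal` on the same time base as the ECG.
#' @param peaks A `pvz_rpeaks` from the same capture.
#' @return An object of class `pvz_beatset`: `beats` (each with `values`,
#'   `duration`, 0-based `index`), `rate`, `unit`, `included` (0-based).
#' @export
segment_beats <- function(signal, peaks) {
  stopifnot(inherits(signal, "pvz_signal"), inherits(peaks, "pvz_rpeaks"))
  n <- length(signal$values)
  idx <- round((peaks$peak_times - signal$t0) * signal$rate) + 1
  beats <- list()
  for (i in seq_len(length(idx) - 1)) {
    a <- idx[i]; b <- idx[i + 1]
    if (a < 1 || b - 1 > n) next  # beat not fully inside the signal span
    beats[[length(beats) + 1]] <- list(
      values = signal$values[a:(b - 1)],
      duration = peaks$peak_times[i + 1] - peaks$peak_times[i],
      index = length(beats)
    )
  }
  if (length(beats) == 0) {
    pvz_stop("pvz_detection_error",
             "cannot segment beats: no complete R-R cycle inside signal span")
  }
  structure(
    list(beats = beats, rate = signal$rate, unit = signal$unit,
         included = vapply(beats, `[[`, integer(1), "index")),
    class = "pvz_beatset"
  )
}

#' @export
print.pvz_beatset <- function(x, ...) {
  cat(sprintf("<pvz_beatset: %d beats (%d included) @ %g Hz, unit = %s>\n",
              length(x$beats), length(x$included), x$rate, x$unit))
  invisible(x)
}

#' Choose which beats enter the average
#'
#' Mirrors the investigator-driven beat selection of cardiac-output
#' calculations: inclusion is explicit, indices are 0-based, and the
#' original set is left unmodified.
#'
#' @param beats A `pvz_beatset`.
#' @param include Non-empty set of 0-based beat indices to include.
#' @return A new `pvz_beatset` with updated inclusion.
#' @export
select_beats <- function(beats, include) {
  stopifnot(inherits(beats, "pvz_beatset"))
  include <- unique(as.integer(include))
  avail <- vapply(beats$beats, `[[`, integer(1), "index")
  if (length(include) == 0) {
    pvz_stop("pvz_selection_error", "beat include list is empty")
  }
  if (!all(include %in% avail)) {
    bad <- setdiff(include, avail)
    pvz_stop("pvz_selection_error",
             "beat indices out of range: %s (available: 0..%d)",
             paste(bad, collapse = ", "), max(avail))
  }
  out <- beats
  out$included <- sort(include)
  out
}

#' Build the average representative beat (ARB)
#'
#' Each included beat is linearly time-normalised (resampled) to the length
#' implied by the mean included R-R interval, then the beats are averaged
#' point-wise.  Time normalisation keeps systolic/diastolic phase alignment
#' across beats of unequal length, which truncation to the shortest beat
#' would not.
#'
#' @param beats A `pvz_beatset` with at least one included beat.
#' @return An object of class `pvz_arb`: `values`, `rate`, `period` (s,
#'   mean included R-R), `n_beats`, `unit`.
#' @export
average_beats <- function(beats) {
  stopifnot(inherits(beats, "pvz_beatset"))
  sel <- beats$beats[vapply(beats$beats, `[[`, integer(1), "index") %in%
                       beats$included]
  if (length(sel) == 0) {
    pvz_stop("pvz_selection_error", "no beats included")
  }
  period <- mean(vapply(sel, `[[`, numeric(1), "duration"))
  L <- round(period * beats$rate)
  mat <- vapply(sel, function(b) {
    v <- b$values
    if (length(v) == L) return(v)
    stats::approx(seq(0, 1, length.out = length(v)), v,
                  xout = seq(0, 1, length.out = L))$y
  }, numeric(L))
  structure(
    list(values = rowMeans(mat), rate = beats$rate, period = period,
         n_beats = length(sel), unit = beats$unit),
    class = "pvz_arb"
  )
}

#' @export
print.pvz_arb <- function(x, ...) {
  cat(sprintf("<pvz_arb: period %.3f s (%d beats averaged) @ %g Hz, unit = %s>\n",
              x$period, x$n_beats, x$rate, x$unit))
  invisible(x)
}
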