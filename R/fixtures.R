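#' @keywords internal
# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Three-element Windkessel parameters
#'
#' The synthetic truth model: characteristic resistance `Rc` in series with
#' a parallel peripheral resistance `Rp` and compliance `C`.  Its input
#' impedance has the closed form `Z(f) = Rc + Rp / (1 + i 2 pi f Rp C)` --
#' the simplest model with a non-flat modulus and phase per harmonic, which
#' is what the impedance pipeline must recover.
#'
#' @param rc Characteristic resistance, mmHg·s/mL.
#' @param rp Peripheral resistance, mmHg·s/mL; physiology requires
#'   `rc < rp`.
#' @param compliance Arterial compliance, mL/mmHg.
#' @return An object of class `pvz_windkessel`.
#' @export
windkessel_params <- function(rc, rp, compliance) {
  if (!all(is.finite(c(rc, rp, compliance))) ||
      rc <= 0 || rp <= 0 || compliance <= 0) {
    pvz_stop("pvz_input_error", "Windkessel parameters must all be positive")
  }
  if (rc >= rp) {
    pvz_stop("pvz_input_error",
             "physiologic ordering requires Rc < Rp (got Rc = %g, Rp = %g)",
             rc, rp)
  }
  structure(list(rc = rc, rp = rp, compliance = compliance),
            class = "pvz_windkessel")
}

#' Analytic input impedance of the Windkessel
#'
#' `Z(f) = Rc + Rp / (1 + i 2 pi f Rp C)`.  At `f = 0` this is `Rc + Rp`
#' (total resistance); as `f` grows the modulus falls to the `Rc` plateau.
#'
#' @param wk A `pvz_windkessel`.
#' @param freq Frequency (or vector of frequencies), Hz, `>= 0`.
#' @return Complex impedance in mmHg·s/mL.
#' @export
analytic_impedance <- function(wk, freq) {
  stopifnot(inherits(wk, "pvz_windkessel"))
  if (any(freq < 0)) {
    pvz_stop("pvz_input_error", "frequency must be non-negative")
  }
  wk$rc + wk$rp / (1 + 1i * 2 * pi * freq * wk$rp * wk$compliance)
}

#' Simulate a pulsatile PA flow signal
#'
#' Per beat, a half-sine ejection pulse occupying `ejection_fraction` of the
#' cycle carries the full stroke volume (the discrete samples are normalised
#' so each beat's integral equals `stroke_volume` exactly); flow is zero in
#' diastole.  Beat lengths are jittered by the stated fraction (uniform,
#' seeded) to emulate sinus variability; the R-wave is taken at ejection
#' onset.
#'
#' @param heart_rate Mean heart rate, bpm, in `[30, 200]`.
#' @param stroke_volume mL per beat (> 0).
#' @param duration Signal length, s; must cover at least 3 beats.
#' @param ejection_fraction_of_cycle Fraction of the cycle spent ejecting,
#'   in `(0.1, 0.6)`.
#' @param jitter Beat-to-beat fractional R-R variation in `[0, 0.5)`.
#' @param seed RNG seed for the jitter.
#' @param rate Sample rate, Hz.
#' @return A list: `flow` (`pvz_signal`, mL/s), `r_times` (true R times, s,
#'   one per fully generated beat) and `beat_samples` (samples per beat).
#' @export
simulate_flow <- function(heart_rate, stroke_volume, duration,
                          ejection_fraction_of_cycle = 0.35,
                          jitter = 0, seed = 1, rate = 1000) {
  if (heart_rate < 30 || heart_rate > 200) {
    pvz_stop("pvz_input_error", "heart_rate must be in [30, 200] bpm")
  }
  if (stroke_volume <= 0) {
    pvz_stop("pvz_input_error", "stroke_volume must be positive")
  }
  if (ejection_fraction_of_cycle <= 0.1 || ejection_fraction_of_cycle >= 0.6) {
    pvz_stop("pvz_input_error", "ejection fraction of cycle must be in (0.1, 0.6)")
  }
  if (jitter < 0 || jitter >= 0.5) {
    pvz_stop("pvz_input_error", "jitter must be in [0, 0.5)")
  }
  t_beat <- 60 / heart_rate
  if (duration < 3 * t_beat) {
    pvz_stop("pvz_input_error", "duration must cover at least 3 beats")
  }
  n_beats <- ceiling(duration / ((1 - jitter) * t_beat)) + 1L
  mults <- with_seed(seed, 1 + jitter * stats::runif(n_beats, -1, 1))
  values <- numeric(0)
  r_times <- numeric(0)
  beat_samples <- integer(0)
  for (m in mults) {
    if (length(values) / rate >= duration) break
    n_i <- round(t_beat * m * rate)
    tau <- (0:(n_i - 1)) / rate
    ej <- ejection_fraction_of_cycle * n_i / rate
    q <- ifelse(tau < ej, sin(pi * tau / ej), 0)
    q <- q * stroke_volume / (sum(q) / rate)  # per-beat integral = SV exactly
    r_times <- c(r_times, length(values) / rate)
    values <- c(values, q)
    beat_samples <- c(beat_samples, n_i)
  }
  n_keep <- round(duration * rate)
  values <- values[seq_len(min(n_keep, length(values)))]
  list(
    flow = calibrated_signal(values, rate = rate, t0 = 0,
                             unit = "mL/s", label = "simulated PA flow"),
    r_times = r_times,
    beat_samples = beat_samples
  )
}

#' Synthesize Windkessel pressure from a flow signal
#'
#' Decomposes the full flow record with the FFT, multiplies each bin by the
#' analytic Windkessel impedance at that bin's true frequency (conjugate
#' symmetry keeps the result real), and reconstructs.  Synthesising in the
#' frequency domain makes the pressure exact in the band-limited sense --
#' no integrator truncation error enters the oracle.
#'
#' @param flow A uniform `pvz_signal` in mL/s, ideally periodic over its
#'   span.
#' @param wk A `pvz_windkessel`.
#' @return A `pvz_signal` in mmHg.
#' @export
apply_windkessel <- function(flow, wk) {
  stopifnot(inherits(wk, "pvz_windkessel"))
  if (!inherits(flow, "pvz_signal")) {
    pvz_stop("pvz_data_error", "apply_windkessel requires a uniform pvz_signal")
  }
  L <- length(flow$values)
  k <- 0:(L - 1)
  f <- ifelse(k <= L / 2, k, k - L) * flow$rate / L
  z <- analytic_impedance(wk, abs(f))
  z[f < 0] <- Conj(z[f < 0])
  p <- Re(stats::fft(stats::fft(flow$values) * z, inverse = TRUE)) / L
  calibrated_signal(p, rate = flow$rate, t0 = flow$t0,
                    unit = "mmHg", label = "simulated PA pressure")
}

#' Simulate an ECG strip
#'
#' Narrow Gaussian R spikes (about 20 ms full width at half maximum,
#' amplitude 1) at the given or computed R times, over a small-amplitude
#' sinusoidal baseline (<= 0.1), sufficient for R-peak detection tests.
#'
#' @param heart_rate bpm; sets default R spacing.
#' @param duration Signal length, s; must exceed two cycles.
#' @param r_times Optional explicit R times (s); defaults to a regular
#'   train starting at half a cycle.
#' @param rate Sample rate, Hz.
#' @return A list: `ecg` (`pvz_signal`, arbitrary units) and `r_times`.
#' @export
simulate_ecg <- function(heart_rate, duration, r_times = NULL, rate = 1000) {
  t_beat <- 60 / heart_rate
  if (duration <= 2 * t_beat) {
    pvz_stop("pvz_input_error", "duration must exceed two cardiac cycles")
  }
  if (is.null(r_times)) {
    r_times <- seq(t_beat / 2, duration, by = t_beat)
    r_times <- r_times[r_times < duration]
  }
  t <- (0:(round(duration * rate) - 1)) / rate
  v <- 0.05 * sin(2 * pi * 0.9 * t)  # baseline wander, well under spike height
  sigma <- 0.02 / (2 * sqrt(2 * log(2)))  # FWHM 20 ms
  for (r in r_times) {
    v <- v + exp(-(t - r)^2 / (2 * sigma^2))
  }
  list(
    ecg = calibrated_signal(v, rate = rate, t0 = 0,
                            unit = "a.u.", label = "simulated ECG"),
    r_times = r_times
  )
}
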