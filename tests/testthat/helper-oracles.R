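# Independent oracles and fixture builders shared across the suite.

# naive defining-sum DFT with one-sided physical-amplitude normalisation:
# amp[0] = mean, amp[k] = (2/L) sum_j x_j exp(-2 pi i k j / L)
naive_dft_amplitudes <- function(x, n_harmonics) {
  L <- length(x)
  j <- 0:(L - 1)
  amp <- complex(n_harmonics + 1)
  amp[1] <- complex(real = mean(x), imaginary = 0)
  for (k in seq_len(n_harmonics)) {
    amp[k + 1] <- (2 / L) * sum(x * exp(-2i * pi * k * j / L))
  }
  amp
}

# build an ARB object directly (bypasses beat detection for unit tests)
make_arb <- function(values, rate = 1000, unit = "mmHg", n_beats = 1) {
  structure(
    list(values = as.numeric(values), rate = rate,
         period = length(values) / rate, n_beats = n_beats, unit = unit),
    class = "pvz_arb"
  )
}

# ARB of mean + single cosine tone at harmonic 1
tone_arb <- function(mean_val, amp, phase_deg, L = 1000, rate = 1000,
                     unit = "mmHg") {
  j <- 0:(L - 1)
  make_arb(mean_val + amp * cos(2 * pi * j / L + phase_deg * pi / 180),
           rate = rate, unit = unit)
}

# R-peak series built from known times (bypasses the detector)
make_rpeaks <- function(times) {
  structure(list(peak_times = times, mean_rr = mean(diff(times)),
                 heart_rate = 60 / mean(diff(times))),
            class = "pvz_rpeaks")
}

# beat set of explicit same-rate beats (list of numeric vectors)
make_beatset <- function(beat_values, rate = 1000, unit = "mmHg") {
  beats <- lapply(seq_along(beat_values), function(i) {
    list(values = beat_values[[i]],
         duration = length(beat_values[[i]]) / rate,
         index = i - 1L)
  })
  structure(list(beats = beats, rate = rate, unit = unit,
                 included = seq_along(beat_values) - 1L),
            class = "pvz_beatset")
}

# write a grayscale matrix (values in [0,1]) as a temp PNG, return the path
write_gray_png <- function(mat) {
  f <- tempfile(fileext = ".png")
  png::writePNG(mat, f)
  f
}

# noiseless core pressure/flow ARB pair from the Windkessel truth model,
# cut at the true beat boundary (no detection, no images)
core_wk_pair <- function(wk, heart_rate = 60, stroke_volume = 70,
                         duration = 8, seed = 1, noise_sd_frac = 0,
                         ejection = 0.35) {
  sim <- simulate_flow(heart_rate, stroke_volume, duration,
                       ejection_fraction_of_cycle = ejection,
                       jitter = 0, seed = seed)
  pres <- apply_windkessel(sim$flow, wk)
  q <- sim$flow
  p <- pres
  if (noise_sd_frac > 0) {
    q$values <- q$values + stats::rnorm(length(q$values),
                                        sd = noise_sd_frac * diff(range(q$values)))
    p$values <- p$values + stats::rnorm(length(p$values),
                                        sd = noise_sd_frac * diff(range(p$values)))
  }
  pk <- make_rpeaks(sim$r_times)
  list(p_arb = average_beats(segment_beats(p, pk)),
       q_arb = average_beats(segment_beats(q, pk)),
       fundamental_hz = heart_rate / 60)
}
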