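#' Pulmonary-artery cross-sectional area from diameter
#'
#' Computes the circular cross-sectional area `pi * d^2 / 4` from the PA
#' diameter measured at the pulmonic valve (standard echo convention of a
#' circular cross-section).
#'
#' @param diameter PA diameter in cm (> 0).
#' @return An object of class `pvz_csa` with `diameter` (cm) and `area`
#'   (cm^2).
#' @examples
#' csa_from_diameter(2.0)$area  # 3.14159 cm^2
#' @export
csa_from_diameter <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1 ||
      !is.finite(diameter) || diameter <= 0) {
    pvz_stop("pvz_input_error", "PA diameter must be a positive number (cm)")
  }
  structure(list(diameter = diameter, area = pi * diameter^2 / 4),
            class = "pvz_csa")
}

#' Convert a velocity ARB to a flow ARB
#'
#' Flow is the sample-wise product of Doppler velocity and PA
#' cross-sectional area, `Q(t) = V(t) * CSA`, assuming a flat velocity
#' profile.  cm/s times cm^2 gives cm^3/s = mL/s.
#'
#' @param velocity A `pvz_arb` in cm/s.
#' @param cs A `pvz_csa`.
#' @return A `pvz_arb` in mL/s with period, rate and beat count preserved.
#' @export
flow_from_velocity <- function(velocity, cs) {
  stopifnot(inherits(velocity, "pvz_arb"), inherits(cs, "pvz_csa"))
  if (velocity$unit != "cm/s") {
    pvz_stop("pvz_unit_error",
             "velocity ARB must be in cm/s, got '%s'", velocity$unit)
  }
  out <- velocity
  out$values <- velocity$values * cs$area
  out$unit <- "mL/s"
  out
}

#' Fourier harmonic decomposition of an average beat
#'
#' Decomposes one period (the ARB) into harmonics of the fundamental
#' frequency `1 / period` via the FFT.  Harmonic 0 is the signal mean;
#' for `k >= 1` the complex amplitude is `(2/L) * sum_j x_j
#' exp(-2*pi*i*k*j/L)`, the one-sided normalisation under which
#' `|amplitude[k]|` is the physical cosine amplitude of harmonic `k`.
#'
#' @param beat A `pvz_arb` of length `L >= 2 * n_harmonics + 1`.
#' @param n_harmonics Number of harmonics above DC to retain.
#' @return An object of class `pvz_harmonics`: `fundamental_hz`,
#'   `amplitudes` (complex, harmonic 0..N; harmonic 0 purely real), `unit`,
#'   `n_harmonics`.
#' @export
decompose_harmonics <- function(beat, n_harmonics = 10) {
  stopifnot(inherits(beat, "pvz_arb"))
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1) {
    pvz_stop("pvz_input_error", "n_harmonics must be >= 1")
  }
  L <- length(beat$values)
  if (L < 2 * n_harmonics + 1) {
    pvz_stop("pvz_input_error",
             "beat of %d samples supports at most %d harmonics (need L >= 2N+1)",
             L, (L - 1) %/% 2)
  }
  F <- stats::fft(beat$values)
  amp <- c(complex(real = Re(F[1]) / L, imaginary = 0),
           2 * F[2:(n_harmonics + 1)] / L)
  structure(
    list(fundamental_hz = 1 / beat$period, amplitudes = amp,
         unit = beat$unit, n_harmonics = n_harmonics),
    class = "pvz_harmonics"
  )
}

# wrap degrees into (-180, 180]
wrap_phase_deg <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

#' Compute the PVZ spectrum from pressure and flow harmonics
#'
#' The pulmonary vascular impedance at harmonic `k` is the ratio of the
#' pressure harmonic to the flow harmonic *matched by harmonic index*, never
#' by absolute frequency: the captures are asynchronous, so their
#' fundamentals generally differ, and pairing by index is what makes the
#' composite spectrum well defined.  `modulus[0] = P(0)/Q(0)` is mean
#' pressure over mean flow (TPR); `phase_deg[k]` is the pressure phase minus
#' the flow phase, wrapped to `(-180, 180]` (negative low-harmonic phase
#' means flow leads pressure).
#'
#' @param p `pvz_harmonics` of the pressure ARB (mmHg).
#' @param q `pvz_harmonics` of the flow ARB (mL/s).
#' @param reliable_max Highest harmonic considered reliable given catheter
#'   fidelity; fluid-filled catheters support about 3.  Carried as metadata
#'   and plot shading; output is never truncated to it.
#' @return An object of class `pvz_spectrum`: `modulus` (mmHg·s/mL,
#'   harmonics 0..N), `phase_deg` (harmonics 1..N), `p_modulus`,
#'   `q_modulus`, both fundamentals, `reliable_max_harmonic`,
#'   `n_harmonics`.
#' @export
compute_pvz <- function(p, q, reliable_max = 3) {
  stopifnot(inherits(p, "pvz_harmonics"), inherits(q, "pvz_harmonics"))
  if (p$unit != "mmHg") {
    pvz_stop("pvz_unit_error", "pressure harmonics must be mmHg, got '%s'", p$unit)
  }
  if (q$unit != "mL/s") {
    pvz_stop("pvz_unit_error", "flow harmonics must be mL/s, got '%s'", q$unit)
  }
  n <- min(p$n_harmonics, q$n_harmonics)
  pk <- p$amplitudes[1:(n + 1)]
  qk <- q$amplitudes[1:(n + 1)]
  q0 <- Re(qk[1])
  if (q0 <= 0) {
    pvz_stop("pvz_data_error", "mean flow Q(0) must be positive, got %g", q0)
  }
  qmag <- Mod(qk)
  # distinguish true zero-harmonics (symmetric synthetic flows) from float
  # noise; |Q(0)| floors the reference so a pulseless flow is caught too
  degen <- which(qmag[-1] < 1e-12 * max(qmag[1], qmag[2]))
  if (length(degen) > 0) {
    pvz_stop("pvz_data_error",
             "flow harmonic %d is degenerate (|Q| ~ 0); impedance undefined there",
             degen[1])
  }
  modulus <- Mod(pk) / qmag
  phase <- wrap_phase_deg((Arg(pk[-1]) - Arg(qk[-1])) * 180 / pi)
  structure(
    list(modulus = modulus, phase_deg = phase,
         p_modulus = Mod(pk), q_modulus = qmag,
         fundamental_hz_pressure = p$fundamental_hz,
         fundamental_hz_flow = q$fundamental_hz,
         reliable_max_harmonic = as.integer(reliable_max),
         n_harmonics = n),
    class = "pvz_spectrum"
  )
}

#' @export
print.pvz_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pvz_spectrum: harmonics 0..%d, f1(P) %.3f Hz, f1(Q) %.3f Hz, reliable to %d>\n",
    x$n_harmonics, x$fundamental_hz_pressure, x$fundamental_hz_flow,
    x$reliable_max_harmonic))
  print(utils::head(data.frame(harmonic = 0:x$n_harmonics,
                               modulus = x$modulus,
                               phase_deg = c(NA, x$phase_deg)), 11))
  invisible(x)
}

#' Derive afterload parameters from a PVZ spectrum
#'
#' Total pulmonary resistance (TPR) is the impedance modulus at harmonic 0
#' (mean pressure over mean flow).  Characteristic impedance Zc is the
#' average of the moduli at harmonics 2-4, approximating the
#' high-frequency plateau; the stiffness index Zs is the sum of the moduli
#' at harmonics 1 and 2.  Both harmonic choices are overridable to suit
#' higher-fidelity pressure signals.
#'
#' @param spec A `pvz_spectrum` computed through the highest requested
#'   harmonic.
#' @param zc_range Harmonic indices averaged for Zc (default `2:4`).
#' @param zs_indices Two harmonic indices summed for Zs (default `c(1, 2)`).
#' @return An object of class `pvz_parameters`: `tpr`, `zc`, `zs`
#'   (mmHg·s/mL), `fundamental_hz`, `zc_harmonics`, `zs_harmonics`.
#' @examples
#' # modulus 3.0, 1.0, 0.6, 0.5, 0.4 at harmonics 0..4:
#' # TPR = 3.0, Zs = 1.0 + 0.6 = 1.6, Zc = mean(0.6, 0.5, 0.4) = 0.5
#' @export
derive_parameters <- function(spec, zc_range = 2:4, zs_indices = c(1, 2)) {
  stopifnot(inherits(spec, "pvz_spectrum"))
  zc_range <- as.integer(zc_range)
  zs_indices <- as.integer(zs_indices)
  if (length(zs_indices) != 2) {
    pvz_stop("pvz_range_error", "zs_indices must be exactly two harmonics")
  }
  need <- max(zc_range, zs_indices)
  if (any(c(zc_range, zs_indices) < 1) || need > spec$n_harmonics) {
    pvz_stop("pvz_range_error",
             "requested harmonic %d beyond computed spectrum (1..%d)",
             need, spec$n_harmonics)
  }
  structure(
    list(tpr = spec$modulus[1],
         zc = mean(spec$modulus[zc_range + 1]),
         zs = sum(spec$modulus[zs_indices + 1]),
         fundamental_hz = spec$fundamental_hz_pressure,
         zc_harmonics = zc_range, zs_harmonics = zs_indices),
    class = "pvz_parameters"
  )
}

#' @export
print.pvz_parameters <- function(x, ...) {
  cat(sprintf(
    "<pvz_parameters: TPR %.4f, Zc %.4f (harmonics %s), Zs %.4f (harmonics %s) mmHg·s/mL>\n",
    x$tpr, x$zc, paste(range(x$zc_harmonics), collapse = "-"),
    x$zs, paste(x$zs_harmonics, collapse = "+")))
  invisible(x)
}

#' Convert impedance/resistance units
#'
#' Converts a value in mmHg·s/mL to dyn·s·cm^-5 (x 1333.22) or Wood units
#' (mmHg·min/L, x 1000/60), the two clinical reporting conventions.
#'
#' @param value Finite non-negative value(s) in mmHg·s/mL.
#' @param target `"dyn_s_cm5"`, `"wood"` or `"mmHg_s_ml"` (identity).
#' @return Converted value(s).
#' @export
convert_impedance_units <- function(value,
                                    target = c("dyn_s_cm5", "wood", "mmHg_s_ml")) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    pvz_stop("pvz_input_error", "impedance value must be finite and non-negative")
  }
  if (length(target) != 1 ||
      !target %in% c("dyn_s_cm5", "wood", "mmHg_s_ml")) {
    pvz_stop("pvz_unit_error", "unknown impedance unit target: '%s'",
             paste(target, collapse = ","))
  }
  switch(target,
         dyn_s_cm5 = value * 1333.22,
         wood = value * 1000 / 60,
         mmHg_s_ml = value)
}
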