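test_that("cross-sectional area follows the circular convention", {
  expect_equal(csa_from_diameter(2.0)$area, pi, tolerance = 1e-9)
  expect_equal(csa_from_diameter(1.0)$area, pi / 4, tolerance = 1e-9)
  expect_error(csa_from_diameter(0), class = "pvz_input_error")
  expect_error(csa_from_diameter(-1), class = "pvz_input_error")
})

test_that("flow is velocity times area, with unit bookkeeping", {
  v <- make_arb(rep(50, 500), unit = "cm/s")
  cs <- csa_from_diameter(2 * sqrt(4 / pi))  # area = 4 cm^2
  q <- flow_from_velocity(v, cs)
  expect_equal(q$values, rep(200, 500))
  expect_equal(q$unit, "mL/s")
  expect_equal(q$period, v$period)

  zero <- make_arb(rep(0, 500), unit = "cm/s")
  expect_equal(flow_from_velocity(zero, cs)$values, rep(0, 500))

  half <- make_arb(100 * sin(pi * (0:499) / 500), unit = "cm/s")
  cs2 <- csa_from_diameter(2)  # pi cm^2
  expect_equal(max(flow_from_velocity(half, cs2)$values), 100 * pi,
               tolerance = 1e-4)

  wrong <- make_arb(rep(1, 500), unit = "m/s")
  expect_error(flow_from_velocity(wrong, cs), class = "pvz_unit_error")
})

test_that("harmonic decomposition matches constants and single tones", {
  const <- make_arb(rep(7.5, 600))
  h <- decompose_harmonics(const, 5)
  expect_equal(Re(h$amplitudes[1]), 7.5)
  expect_equal(Im(h$amplitudes[1]), 0)
  expect_lt(max(Mod(h$amplitudes[-1])), 1e-9)

  tone <- tone_arb(5, 3, -30, L = 1000)
  ht <- decompose_harmonics(tone, 8)
  expect_equal(Re(ht$amplitudes[1]), 5, tolerance = 1e-9)
  expect_equal(Mod(ht$amplitudes[2]), 3, tolerance = 1e-9)
  expect_equal(Arg(ht$amplitudes[2]) * 180 / pi, -30, tolerance = 1e-6)
  expect_lt(max(Mod(ht$amplitudes[3:9])), 1e-6)
  expect_equal(ht$fundamental_hz, 1.0)

  expect_error(decompose_harmonics(make_arb(rnorm(10)), 5),
               class = "pvz_input_error")
})

test_that("harmonic decomposition equals the naive defining-sum DFT", {
  set.seed(31)
  x <- rnorm(64)
  got <- decompose_harmonics(make_arb(x), 31)$amplitudes
  want <- naive_dft_amplitudes(x, 31)
  expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-9)

  for (L in c(3, 5, 17, 33, 100, 127)) {
    x <- rnorm(L)
    n <- (L - 1) %/% 2
    got <- decompose_harmonics(make_arb(x), n)$amplitudes
    want <- naive_dft_amplitudes(x, n)
    expect_lt(max(Mod(got - want)) / max(1e-12, max(Mod(want))), 1e-9)
  }
})

test_that("truncated harmonic series reconstructs a band-limited beat", {
  set.seed(5)
  L <- 100
  j <- 0:(L - 1)
  x <- 10 + 2 * cos(2 * pi * j / L + 0.4) + 1.3 * cos(2 * pi * 5 * j / L - 1) +
    0.5 * cos(2 * pi * 20 * j / L)
  h <- decompose_harmonics(make_arb(x), (L - 2L) %/% 2L)
  recon <- Re(h$amplitudes[1]) +
    Reduce(`+`, lapply(seq_len(h$n_harmonics), function(k) {
      Re(h$amplitudes[k + 1] * exp(2i * pi * k * j / L))
    }))
  expect_lt(sqrt(mean((recon - x)^2)), 1e-6)
})

test_that("compute_pvz forms modulus and phase-difference ratios by index", {
  # pure resistance: P = R * Q sample-wise
  q <- make_arb(200 + 60 * sin(2 * pi * (0:999) / 1000) +
                  20 * sin(4 * pi * (0:999) / 1000), unit = "mL/s")
  p <- q
  p$values <- 1.05 * q$values
  p$unit <- "mmHg"
  spec <- compute_pvz(decompose_harmonics(p, 2), decompose_harmonics(q, 2))
  expect_equal(spec$modulus, rep(1.05, 3), tolerance = 1e-9)
  expect_equal(spec$phase_deg, rep(0, 2), tolerance = 1e-6)

  # single tone: modulus ratio 2, phase difference -45 degrees
  pt <- tone_arb(10, 6, 0, unit = "mmHg")
  qt <- tone_arb(5, 3, 45, unit = "mL/s")
  s2 <- compute_pvz(decompose_harmonics(pt, 1), decompose_harmonics(qt, 1))
  expect_equal(s2$modulus[2], 2.0, tolerance = 1e-9)
  expect_equal(s2$phase_deg[1], -45, tolerance = 1e-6)
  expect_equal(s2$modulus[1], 10 / 5, tolerance = 1e-12)
})

test_that("PVZ moduli scale covariantly with pressure and flow", {
  set.seed(13)
  pair <- core_wk_pair(windkessel_params(0.06, 0.9, 2.5))
  ph <- decompose_harmonics(pair$p_arb, 5)
  qh <- decompose_harmonics(pair$q_arb, 5)
  base <- compute_pvz(ph, qh)
  a <- 2.7; b <- 0.4
  ph2 <- ph; ph2$amplitudes <- a * ph$amplitudes
  qh2 <- qh; qh2$amplitudes <- b * qh$amplitudes
  scaled <- compute_pvz(ph2, qh2)
  expect_equal(scaled$modulus, base$modulus * a / b, tolerance = 1e-12)
  expect_equal(scaled$phase_deg, base$phase_deg, tolerance = 1e-9)
})

test_that("pairing is by harmonic index, regardless of actual frequency", {
  pt <- tone_arb(10, 6, 20, L = 1000, unit = "mmHg")     # 1 Hz fundamental
  qt <- tone_arb(5, 3, -10, L = 750, unit = "mL/s")      # 1.33 Hz fundamental
  qt_same <- tone_arb(5, 3, -10, L = 1000, unit = "mL/s")
  s_diff <- compute_pvz(decompose_harmonics(pt, 1), decompose_harmonics(qt, 1))
  s_same <- compute_pvz(decompose_harmonics(pt, 1),
                        decompose_harmonics(qt_same, 1))
  expect_equal(s_diff$modulus, s_same$modulus, tolerance = 1e-9)
  expect_equal(s_diff$phase_deg, s_same$phase_deg, tolerance = 1e-6)
  # both fundamentals are preserved as metadata
  expect_equal(s_diff$fundamental_hz_pressure, 1.0)
  expect_equal(s_diff$fundamental_hz_flow, 1000 / 750)
})

test_that("compute_pvz flags degenerate flow harmonics and nonpositive mean flow", {
  p <- tone_arb(10, 6, 0, unit = "mmHg")
  q_flat <- make_arb(rep(100, 1000), unit = "mL/s")  # no harmonic content
  expect_error(compute_pvz(decompose_harmonics(p, 1),
                           decompose_harmonics(q_flat, 1)),
               class = "pvz_data_error")
  q_neg <- tone_arb(-5, 3, 0, unit = "mL/s")
  expect_error(compute_pvz(decompose_harmonics(p, 1),
                           decompose_harmonics(q_neg, 1)),
               class = "pvz_data_error")
})

test_that("derive_parameters applies the TPR / Zc / Zs definitions", {
  spec <- structure(
    list(modulus = c(3.0, 1.0, 0.6, 0.5, 0.4), phase_deg = rep(0, 4),
         p_modulus = rep(1, 5), q_modulus = rep(1, 5),
         fundamental_hz_pressure = 1.2, fundamental_hz_flow = 1.25,
         reliable_max_harmonic = 3L, n_harmonics = 4L),
    class = "pvz_spectrum"
  )
  par <- derive_parameters(spec)
  expect_equal(par$tpr, 3.0, tolerance = 1e-15)
  expect_equal(par$zs, 1.6, tolerance = 1e-15)
  expect_equal(par$zc, 0.5, tolerance = 1e-15)
  expect_equal(par$fundamental_hz, 1.2)

  flat <- spec
  flat$modulus <- rep(0.7, 5)
  pf <- derive_parameters(flat)
  expect_equal(pf$tpr, 0.7)
  expect_equal(pf$zc, 0.7)
  expect_equal(pf$zs, 1.4)

  expect_error(derive_parameters(spec, zc_range = 2:5),
               class = "pvz_range_error")
  # configurable harmonic choices
  alt <- derive_parameters(spec, zc_range = 2:3, zs_indices = c(1, 3))
  expect_equal(alt$zc, mean(c(0.6, 0.5)))
  expect_equal(alt$zs, 1.0 + 0.5)
})

test_that("impedance unit conversions follow clinical conventions", {
  expect_equal(convert_impedance_units(1.0, "dyn_s_cm5"), 1333.22)
  expect_equal(convert_impedance_units(1.0, "wood"), 1000 / 60)
  expect_equal(convert_impedance_units(0, "wood"), 0)
  expect_equal(convert_impedance_units(2.5, "mmHg_s_ml"), 2.5)
  expect_error(convert_impedance_units(1.0, "furlongs"),
               class = "pvz_unit_error")
  expect_error(convert_impedance_units(-1, "wood"), class = "pvz_input_error")
})

test_that("modulus at harmonic 0 is mean pressure over mean flow", {
  set.seed(17)
  pair <- core_wk_pair(windkessel_params(0.04, 0.7, 4), heart_rate = 80)
  spec <- compute_pvz(decompose_harmonics(pair$p_arb, 4),
                      decompose_harmonics(pair$q_arb, 4))
  expect_equal(spec$modulus[1],
               mean(pair$p_arb$values) / mean(pair$q_arb$values),
               tolerance = 1e-12)
})
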