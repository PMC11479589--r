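test_that("peak detection locates analytic maxima to sub-sample precision", {
  tt <- seq(0, 70, by = 0.01)
  pk <- detect_peaks(cos(2 * pi * tt / 17.5), tt, min_separation = 5)
  # interior maxima at 17.5, 35, 52.5 (endpoints are not local maxima)
  expect_equal(pk$time, c(17.5, 35, 52.5), tolerance = 1e-4)
  expect_equal(pk$height, rep(1, 3), tolerance = 1e-6)

  expect_equal(nrow(detect_peaks(rep(2, 100), seq_len(100))), 0)

  # prominence filter drops small ripples riding on the main oscillation
  sig <- cos(2 * pi * tt / 17.5) + 0.05 * cos(2 * pi * tt / 1.3)
  pk2 <- detect_peaks(sig, tt, min_separation = 0, min_prominence = 0.3)
  expect_equal(nrow(pk2), 3)
})

test_that("free-running simulation has uniform peak spacing after a cycle", {
  tr <- simulate_opto(opto_params(), light_constant("off"), t_end = 180,
                      dt = 0.005, record_dt = 0.01)
  pk <- detect_peaks(tr$states[, "y"], tr$times, min_separation = 5,
                     min_prominence = 0.2)
  gaps <- diff(pk$time[-1])
  expect_gt(length(gaps), 5)
  expect_lt(max(abs(gaps - mean(gaps))) / mean(gaps), 0.01)
})

test_that("natural period respects the model's time-rescaling symmetry", {
  T1 <- natural_period(opto_params())
  T2 <- natural_period(opto_params(alpha = 0.375, beta = 150),
                       t_end = 500)
  expect_equal(T2 / T1, 2, tolerance = 0.002)
  expect_error(natural_period(opto_params(), t_end = 20), "peaks")
})

test_that("phase shifts vanish without a pulse and are peak-index invariant", {
  p <- opto_params()
  expect_equal(phase_response(p, 0.2, beta_prime_pulse = 0), 0)

  # the shift measured at the 3rd and 5th post-pulse peaks agrees:
  # transients have decayed, so the shift is a property of the cycle
  for (phi in c(-0.3, 0.25)) {
    d3 <- phase_response(p, phi, k = 3)
    d5 <- phase_response(p, phi, k = 5)
    expect_lt(abs(wrap_phase(d3 - d5)), 0.02)
  }
})

test_that("pulses before the peak advance the clock, after it delay", {
  p <- opto_params()
  expect_gt(phase_response(p, -0.08), 0)
  expect_lt(phase_response(p, 0.3), 0)
})

test_that("circle map reproduces closed-form fixed points of a known PRC", {
  # synthetic sinusoidal PRC with known roots and slopes
  grid <- -0.5 + (0:63) / 64
  prc <- structure(list(phi = grid, delta_phi = -0.2 * sinpi(2 * grid),
                        tau = 2, beta_prime = 80, T0 = 17.5, k = 3),
                   class = "phase_response_curve")

  # TL = T0: fixed point at the PRC zero with negative slope (phi = 0);
  # the zero at +-0.5 has positive slope and must be rejected
  fp <- entrained_phase(prc, 17.5)
  expect_equal(fp$phi_star, 0, tolerance = 1e-3)
  expect_true(fp$stable)
  expect_equal(fp$slope, -0.4 * pi, tolerance = 0.01)

  # detuned: delta(phi*) = 1 - TL/T0 = 0.1 at phi* = -asin(0.5)/(2 pi)
  TL <- 0.9 * 17.5
  fp2 <- entrained_phase(prc, TL)
  expect_equal(fp2$phi_star, -asin(0.5) / (2 * pi), tolerance = 1e-3)

  # beyond the PRC range: no locking
  expect_error(entrained_phase(prc, 0.7 * 17.5),
               class = "optorep_outside_locking_range")

  # map iteration: pure rotation without a PRC response
  flat <- structure(list(phi = grid, delta_phi = rep(0, 64), tau = 2,
                         beta_prime = 80, T0 = 17.5, k = 3),
                    class = "phase_response_curve")
  expect_equal(circle_map_step(0.1, flat, 1.25 * 17.5),
               wrap_phase(0.1 + 0.25))

  # iteration converges to the stable fixed point
  phi <- 0.3
  for (i in 1:60) phi <- circle_map_step(phi, prc, 17.5)
  expect_equal(phi, 0, tolerance = 1e-3)
})

test_that("interpolated PRC is periodic and passes through its grid", {
  p <- opto_params()
  prc <- compute_prc(p, n_points = 16)
  expect_equal(prc_interp(prc, prc$phi), prc$delta_phi)
  expect_equal(prc_interp(prc, prc$phi + 1), prc$delta_phi)
})

test_that("an unentrained pulse train is flagged as drifting", {
  p <- opto_params()
  T0 <- natural_period(p)
  # no light reaches the cells: phases slip by the detuning every period
  dark <- opto_params(beta_prime_on = 0)
  TL <- 0.9 * T0
  tr <- simulate_opto(dark, light_pulse_train(0, TL, 2, 16),
                      t_end = 16 * TL, dt = 0.005, record_dt = 0.01)
  m <- measured_entrained_phase(tr, T0)
  expect_false(m$entrained)
  expect_true(is.na(m$phi_star))
})

test_that("PRC export writes the curve and its pulse metadata", {
  p <- opto_params()
  prc <- compute_prc(p, n_points = 16)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_prc_csv(prc, csv)
  df <- utils::read.csv(csv)
  expect_equal(df$delta_phi, prc$delta_phi)
  hdr <- jsonlite::read_json(paste0(csv, ".json"), simplifyVector = TRUE)
  expect_equal(hdr$tau, 2)
  expect_equal(hdr$beta_prime, 80)
  expect_equal(hdr$T0, prc$T0, tolerance = 1e-9)
})
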