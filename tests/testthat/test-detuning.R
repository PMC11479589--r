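test_that("periodogram finds pure and mixed tones at bin resolution", {
  dt <- 0.05
  tt <- seq(0, 350, by = dt)
  ps <- power_spectrum(cos(2 * pi * tt / 17.5), dt)
  res <- ps$frequency[1]
  expect_lt(abs(ps$frequency[which.max(ps$power)] - 1 / 17.5), res)

  two <- cos(2 * pi * tt / 17.5) + 0.4 * cos(2 * pi * tt / 6)
  ps2 <- power_spectrum(two, dt)
  expect_lt(abs(ps2$frequency[which.max(ps2$power)] - 1 / 17.5), res)

  expect_error(power_spectrum(1:5, dt), "too short")
})

test_that("dominant frequency prefers a strong subharmonic over a harmonic", {
  spec <- data.frame(frequency = c(0.05, 0.10, 0.15, 0.20),
                     power = c(30, 100, 2, 1))
  expect_equal(dominant_frequency(spec), 0.05)          # guard engages
  expect_equal(dominant_frequency(spec, harmonic_guard = FALSE), 0.10)
  weak <- data.frame(frequency = c(0.05, 0.10),
                     power = c(10, 100))                # below 25%: keep max
  expect_equal(dominant_frequency(weak), 0.10)
})

test_that("unforced and principally locked oscillators give the right ratio", {
  p <- opto_params()
  nu0 <- 1 / natural_period(p)

  # no forcing: the system keeps its own frequency, ratio = nu0/f
  free <- frequency_ratio(p, 1.3, beta_prime = 0, nu0 = nu0)
  expect_lt(abs(free$ratio - 1 / 1.3), free$resolution / free$f)

  # principal tongue: locked 1:1
  locked <- frequency_ratio(p, 1, beta_prime = 80, nu0 = nu0)
  expect_lt(abs(locked$ratio - 1), locked$resolution / locked$f)

  # spectral period agrees with peak-spacing period when locked
  TL <- 1 / nu0
  tr <- simulate_opto(opto_params(beta_prime_on = 80),
                      light_pulse_train(0, TL, 2, 40), t_end = 40 * TL,
                      dt = 0.005, record_dt = 0.05)
  keep <- tr$times >= 10 * TL
  pk <- detect_peaks(tr$states[keep, "y"], tr$times[keep],
                     min_separation = 5, min_prominence = 0.2)
  expect_lt(abs(1 / mean(diff(pk$time)) - locked$nu),
            locked$resolution)
})

test_that("frequency ratios are invariant under exact time rescaling", {
  p <- opto_params()
  nu0 <- 1 / natural_period(p)
  p2 <- opto_params(alpha = 1.5, beta = 600)
  r1 <- frequency_ratio(p, 2, beta_prime = 80, tau = 2, nu0 = nu0)
  r2 <- frequency_ratio(p2, 2, beta_prime = 160, tau = 1, nu0 = 2 * nu0,
                        dt = 0.0025, record_dt = 0.025)
  expect_lt(abs(r1$ratio - r2$ratio), 2 * r1$resolution / r1$f)
})

test_that("tongue surface labels locked cells and never the unforced row", {
  p <- opto_params()
  surf <- tongue_surface(p, f_grid = c(1, 2), beta_prime_grid = c(0, 80))
  expect_s3_class(surf, "tongue_surface")
  expect_equal(nrow(surf), 4)
  get <- function(f, b) surf[surf$f_over_nu0 == f & surf$beta_prime == b, ]
  expect_equal(get(1, 80)$label, "1")
  expect_equal(get(2, 80)$label, "1/2")
  expect_true(all(surf$label[surf$beta_prime == 0] == "unlocked"))
  expect_equal(get(2, 80)$ratio, 0.5, tolerance = 0.02)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_tongue_csv(surf, csv)
  expect_equal(utils::read.csv(csv)$ratio, surf$ratio)
  cfg <- jsonlite::read_json(paste0(csv, ".json"), simplifyVector = TRUE)
  expect_equal(cfg$beta_prime, c(0, 80))
})

test_that("half-frequency tongue: parity classes and their cancellation", {
  p <- opto_params()
  T0 <- natural_period(p)
  TL <- T0 / 2

  # identical synchronized cells share one parity: population stays at f/2
  same <- ensemble_spec(n_cells = 3, alpha_sd = 0, seed = 1)
  res_same <- alternate_peak_population(same, f_over_nu0 = 2,
                                        beta_prime = 80)
  expect_equal(length(unique(res_same$parity)), 1L)
  expect_lt(abs(res_same$dominant_frequency - res_same$f / 2),
            0.1 * res_same$f / 2)

  # opposite-parity pair: one cell shifted by one forcing period; their
  # mean oscillates at the forcing frequency, not f/2
  base <- simulate_opto(p, light_constant("off"), t_end = 8 * T0,
                        dt = 0.005, record_dt = 0.01)
  pk <- detect_peaks(base$states[, "y"], base$times, min_separation = 5,
                     min_prominence = 0.2)
  anchor <- pk$time[5]
  i1 <- which.min(abs(base$times - anchor))
  i2 <- which.min(abs(base$times - (anchor - TL)))
  forced <- opto_params(beta_prime_on = 80)
  prot <- light_pulse_train(0, TL, 2, 40)
  y1 <- simulate_opto(forced, prot, initial = base$states[i1, ],
                      t_end = 40 * TL, dt = 0.005,
                      record_dt = 0.05)$states[, "y"]
  y2 <- simulate_opto(forced, prot, initial = base$states[i2, ],
                      t_end = 40 * TL, dt = 0.005,
                      record_dt = 0.05)$states[, "y"]
  mixed <- (y1 + y2) / 2
  keep <- seq_along(mixed) > 10 * TL / 0.05
  f <- 1 / TL
  nu_mix <- dominant_frequency(power_spectrum(mixed[keep], 0.05))
  expect_lt(abs(nu_mix - f), 0.05 * f)
})
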