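test_that("compiled Euler stepper agrees with a plain-R oracle", {
  p <- opto_params()
  protocol <- light_pulse(1, 0.5)
  tr <- simulate_opto(p, protocol, initial = c(10, 20, 30, 5), t_end = 3,
                      dt = 0.01)
  bp <- evaluate_protocol(protocol, seq(0, 3 - 0.01, by = 0.01), p)
  oracle <- r_euler(c(10, 20, 30, 5), p, bp, 0.01)
  expect_equal(unname(tr$states), unname(oracle), tolerance = 1e-12)
})

test_that("x' relaxes on its closed form under constant light", {
  p <- opto_params()
  tr <- simulate_opto(p, light_constant("on"), t_end = 20, dt = 0.001,
                      record_dt = 0.01)
  expect_lt(relaxation_check(tr), 0.1)

  # starting exactly on the x' fixed point leaves only round-off
  fp <- green_fixed_point(p)
  tr2 <- simulate_opto(p, light_constant("on"), initial = fp, t_end = 10,
                       dt = 0.001, record_dt = 0.01)
  expect_lt(relaxation_check(tr2), 1e-8)

  # dark, empty cell: defect is exactly zero
  tr3 <- simulate_opto(p, light_constant("off"),
                       initial = c(0, 0, 400, 0), t_end = 10, dt = 0.005)
  expect_equal(relaxation_check(tr3), 0)

  expect_error(relaxation_check(
    simulate_opto(p, light_pulse(1, 2), t_end = 5, dt = 0.005)),
    "constant")
})

test_that("steady green light collapses the oscillation to its fixed point", {
  p <- opto_params()
  fp <- green_fixed_point(p)
  tr <- simulate_opto(p, light_constant("on"), initial = c(100, 50, 200, 0),
                      t_end = 10 / p$alpha, dt = 0.005, record_dt = 0.05)
  final <- tr$states[nrow(tr$states), ]
  expect_lt(max(abs(final - fp)), 0.01 * p$beta / p$alpha)
})

test_that("time-rescaling symmetry holds exactly for a power-of-two factor", {
  p <- opto_params()
  p2 <- opto_params(alpha = 2 * p$alpha, beta = 2 * p$beta, n = p$n,
                    beta_prime_on = 2 * p$beta_prime_on)
  # binary dt keeps every floating-point operation exactly rescalable
  dt <- 1 / 256
  a <- simulate_opto(p, t_end = 40, dt = dt, record_dt = 16 * dt)
  b <- simulate_opto(p2, t_end = 20, dt = dt / 2, record_dt = 8 * dt)
  expect_identical(a$states, b$states)
  # with a pulse: pulse times scale too
  a2 <- simulate_opto(p, light_pulse(10, 2), t_end = 40, dt = dt,
                      record_dt = 16 * dt)
  b2 <- simulate_opto(p2, light_pulse(5, 1), t_end = 20, dt = dt / 2,
                      record_dt = 8 * dt)
  expect_identical(a2$states, b2$states)
})

test_that("splitting a run and handing over the state changes nothing", {
  p <- opto_params(beta_prime_on = 80)
  protocol <- light_pulse_train(30, 18, 2, 3)
  dt <- 1 / 256  # binary step: the two grids align exactly
  whole <- simulate_opto(p, protocol, t_end = 80, dt = dt,
                         record_dt = 16 * dt)
  first <- simulate_opto(p, protocol, t_end = 40, dt = dt,
                         record_dt = 16 * dt)
  second <- simulate_opto(p, shift_protocol(protocol, -40),
                          initial = first$states[nrow(first$states), ],
                          t_end = 40, dt = dt, record_dt = 16 * dt)
  stitched <- rbind(first$states, second$states[-1L, ])
  expect_identical(unname(whole$states), unname(stitched))
})

test_that("grid refinement shifts the measured period only slightly", {
  p <- opto_params()
  t_coarse <- natural_period(p, t_end = 120, dt = 0.01)
  t_fine <- natural_period(p, t_end = 120, dt = 0.005)
  expect_lt(abs(t_coarse - t_fine) / t_fine, 0.005)
})

test_that("trajectories stay non-negative and export cleanly", {
  p <- opto_params()
  tr <- simulate_opto(p, light_pulse_train(0, 18, 2, 4), t_end = 80,
                      dt = 0.005, record_dt = 0.05)
  expect_true(all(tr$states >= 0))
  df <- as.data.frame(tr)
  expect_named(df, c("time_h", "x", "y", "z", "x_prime", "beta_prime"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  expect_equal(utils::read.csv(path)$y, df$y)
})

test_that("a diverging integration fails loudly, naming the first bad step", {
  # fractional Hill exponent + a huge step drives the state negative,
  # where the Hill term is undefined
  expect_error(
    simulate_opto(opto_params(n = 2.5), t_end = 100, dt = 10),
    "non-finite state at step")
})

test_that("limit-cycle components are identical up to a third-period shift", {
  tr <- simulate_opto(opto_params(), light_constant("off"), t_end = 150,
                      dt = 0.005, record_dt = 0.01)
  T0 <- natural_period(opto_params())
  peaks_of <- function(v) detect_peaks(tr$states[, v], tr$times,
                                       min_separation = 5,
                                       min_prominence = 0.2)$time
  py <- peaks_of("y"); px <- peaks_of("x"); pz <- peaks_of("z")
  late <- function(p) p[p > 3 * T0 & p < max(tr$times) - T0]
  # x peaks a third of a period after y, z a third after x
  lag_xy <- sapply(late(py), function(t) min((px - t)[px > t]))
  lag_zx <- sapply(late(px), function(t) min((pz - t)[pz > t]))
  expect_equal(mean(lag_xy), T0 / 3, tolerance = 0.02)
  expect_equal(mean(lag_zx), T0 / 3, tolerance = 0.02)
})
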