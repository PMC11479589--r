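test_that("growth-rate draws are reproducible, truncated and well-centred", {
  spec0 <- ensemble_spec(n_cells = 50, alpha_sd = 0, seed = 7)
  expect_equal(draw_growth_rates(spec0), rep(0.75, 50))

  spec <- ensemble_spec(n_cells = 200, seed = 11)
  expect_identical(draw_growth_rates(spec), draw_growth_rates(spec))
  expect_false(identical(draw_growth_rates(spec),
                         draw_growth_rates(ensemble_spec(n_cells = 200,
                                                         seed = 12))))

  # non-positive draws are redrawn even for an absurdly wide distribution
  wide <- ensemble_spec(n_cells = 500, alpha_mean = 0.1, alpha_sd = 0.5,
                        seed = 3)
  expect_true(all(draw_growth_rates(wide) > 0))

  # sample mean close to the population mean (standard error ~ 0.00034)
  big <- ensemble_spec(n_cells = 10000, seed = 5)
  expect_lt(abs(mean(draw_growth_rates(big)) - 0.75), 0.002)

  expect_error(ensemble_spec(alpha_sd = -0.1), "alpha_sd")
})

test_that("initial-condition modes produce the documented states", {
  spec_g <- ensemble_spec(n_cells = 4, alpha_sd = 0, seed = 1,
                          init_mode = "synchronized_green")
  sg <- initial_states(spec_g)
  expect_equal(unname(sg[1, ]), c(0, 0, 400, 0))

  spec_i <- ensemble_spec(n_cells = 4, alpha_sd = 0, seed = 1,
                          init_mode = "synchronized_iptg")
  si <- initial_states(spec_i)
  expect_equal(unname(si[3, ]), c(400, 400, 0, 0))

  # per-cell alpha scales the synchronized state
  spec_h <- ensemble_spec(n_cells = 6, seed = 2)
  a <- draw_growth_rates(spec_h)
  sh <- initial_states(spec_h, a)
  expect_equal(sh[, "z"], 300 / a)

  # random-phase states lie on (near) the limit cycle: all non-negative,
  # within the oscillation's range, and different across cells
  spec_r <- ensemble_spec(n_cells = 3, alpha_sd = 0, seed = 4,
                          init_mode = "random_phase")
  sr <- initial_states(spec_r)
  expect_true(all(sr >= 0))
  expect_true(all(sr[, c("x", "y", "z")] <= 450))
  expect_equal(sr[, "x_prime"], rep(0, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_gt(stats::sd(sr[, "y"]), 0)

  expect_error(ensemble_spec(init_mode = "frozen"))
})

test_that("population mean is the exact arithmetic mean of independent cells", {
  spec <- ensemble_spec(n_cells = 8, seed = 9)
  res <- simulate_ensemble(spec, light_constant("off"), t_end = 60)
  expect_equal(res$population_mean, rowMeans(res$y))
  # cell-count-weighted recombination of sub-ensembles is exact
  sub1 <- rowMeans(res$y[, 1:3])
  sub2 <- rowMeans(res$y[, 4:8])
  expect_equal((3 * sub1 + 5 * sub2) / 8, res$population_mean,
               tolerance = 1e-12)
})

test_that("identical cells stay synchronized; dispersed cells dephase", {
  same <- ensemble_spec(n_cells = 5, alpha_sd = 0, seed = 1)
  res_same <- simulate_ensemble(same, light_constant("off"), t_end = 150)
  expect_equal(periods_to_half_amplitude(res_same), Inf)

  mixed <- ensemble_spec(n_cells = 100, alpha_sd = 0.034, seed = 1)
  res_mixed <- simulate_ensemble(mixed, light_constant("off"), t_end = 180)
  n_half <- periods_to_half_amplitude(res_mixed)
  expect_true(is.finite(n_half))
  expect_lt(n_half, 5)
})

test_that("wider growth-rate dispersion never slows the dephasing", {
  vals <- vapply(c(0.01, 0.034, 0.071), function(s) {
    spec <- ensemble_spec(n_cells = 200, alpha_sd = s, seed = 21)
    periods_to_half_amplitude(
      simulate_ensemble(spec, light_constant("off"), t_end = 250))
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("a random-phase population averages to a nearly constant signal", {
  spec <- ensemble_spec(n_cells = 80, alpha_sd = 0.034, seed = 6,
                        init_mode = "random_phase")
  res <- simulate_ensemble(spec, light_constant("off"), t_end = 100)
  late <- res$times > 10
  flatness <- stats::sd(res$population_mean[late]) /
    stats::sd(res$y[late, 1])
  expect_lt(flatness, 0.3)
})

test_that("half-amplitude counter matches its closed-form oracle", {
  tt <- seq(0, 200, by = 0.05)
  T <- 17.5
  tau_d <- 2.5 * T / log(2)  # envelope halves at exactly 2.5 periods
  damped <- exp(-tt / tau_d) * cos(2 * pi * tt / T)
  expect_equal(periods_to_half_amplitude(damped, tt), 2.5, tolerance = 0.06)

  expect_equal(periods_to_half_amplitude(cos(2 * pi * tt / T), tt), Inf)
  expect_error(periods_to_half_amplitude(rep(1, length(tt)), tt), "peaks")
})

test_that("ensemble export writes long-format traces plus growth rates", {
  spec <- ensemble_spec(n_cells = 3, seed = 2)
  res <- simulate_ensemble(spec, light_constant("off"), t_end = 30)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(res, csv)
  df <- utils::read.csv(csv)
  expect_setequal(unique(df$cell_id), c("1", "2", "3", "mean"))
  expect_equal(nrow(df), 4 * length(res$times))
  side <- jsonlite::read_json(paste0(csv, ".json"), simplifyVector = TRUE)
  expect_equal(side$alphas, res$alphas, tolerance = 1e-12)
})
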