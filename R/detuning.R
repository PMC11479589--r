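#' Periodogram of a uniformly sampled signal
#'
#' Plain mean-subtracted periodogram (no taper, no padding): power at the
#' discrete Fourier frequencies `k / (n dt)` for `k = 1 .. floor(n/2)`. The
#' frequency resolution equals one over the signal duration. Signals here are
#' long and near-periodic, and only the location of the dominant peak is
#' consumed downstream, so no window is applied.
#'
#' @param signal Numeric vector (uniform sampling), length >= 16.
#' @param dt Sampling interval (h).
#' @return Data frame with columns `frequency` (1/h) and `power`.
#' @export
#' @examples
#' t <- seq(0, 350, by = 0.05)
#' ps <- power_spectrum(cos(2 * pi * t / 17.5), dt = 0.05)
#' ps$frequency[which.max(ps$power)]  # ~ 1/17.5
power_spectrum <- function(signal, dt) {
  stopifnot(is.numeric(signal), is.numeric(dt), dt > 0)
  n <- length(signal)
  if (n < 16L) stop("signal too short for a spectrum (need >= 16 samples)")
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  p <- Mod(stats::fft(signal - mean(signal)))^2 / n
  k <- seq_len(n %/% 2)
  data.frame(frequency = k / (n * dt), power = p[k + 1L])
}

#' Dominant spectral frequency
#'
#' Frequency of the maximum-power bin (the zero-frequency bin is excluded by
#' construction in [power_spectrum()]). A relaxation-shaped oscillation can
#' put substantial power into its second harmonic; when `harmonic_guard` is
#' on, the bin nearest half the arg-max frequency is preferred whenever it
#' carries at least 25% of the maximum power.
#'
#' @param spectrum A [power_spectrum()] data frame.
#' @param harmonic_guard Apply the subharmonic preference rule (default TRUE).
#' @return Dominant frequency (1/h).
#' @export
dominant_frequency <- function(spectrum, harmonic_guard = TRUE) {
  stopifnot(is.data.frame(spectrum),
            all(c("frequency", "power") %in% names(spectrum)))
  imax <- which.max(spectrum$power)
  f <- spectrum$frequency[imax]
  if (harmonic_guard) {
    ihalf <- which.min(abs(spectrum$frequency - f / 2))
    if (ihalf != imax &&
        spectrum$power[ihalf] >= 0.25 * spectrum$power[imax])
      f <- spectrum$frequency[ihalf]
  }
  f
}

#' Frequency-locking ratio of a forced optorepressilator
#'
#' Drives a single oscillator with a pulse train whose frequency is
#' `f_over_nu0` times the natural frequency nu0 = 1/T0, simulates
#' `n_periods` forcing periods, discards the first `n_discard`, and returns
#' the ratio of the dominant y-spectrum frequency to the forcing frequency.
#' Inside an Arnold tongue this ratio locks onto a rational value (1 on the
#' principal tongue, 1/2 when forced at twice the natural frequency, ...).
#'
#' @param params An [opto_params()]; the forcing amplitude below overrides
#'   its `beta_prime_on`.
#' @param f_over_nu0 Forcing frequency in units of the natural frequency.
#' @param beta_prime Forcing amplitude (1/h); 0 leaves the system free-running.
#' @param tau Pulse duration (h).
#' @param nu0 Natural frequency (1/h); measured via [natural_period()] when
#'   omitted.
#' @param n_periods Forcing periods simulated (>= 20 recommended).
#' @param n_discard Leading forcing periods dropped as transient.
#' @param dt Euler step (h).
#' @param record_dt Output sampling (h).
#' @return List with `nu` (dominant frequency, 1/h), `f` (forcing frequency),
#'   `ratio` (nu/f), `resolution` (spectral bin width, 1/h), and `spectrum`.
#' @export
frequency_ratio <- function(params, f_over_nu0, beta_prime = 80, tau = 2,
                            nu0 = NULL, n_periods = 40, n_discard = 10,
                            dt = 0.005, record_dt = 0.05) {
  params <- as_opto_params(params)
  stopifnot(f_over_nu0 > 0, beta_prime >= 0, tau > 0,
            n_periods > n_discard)
  if (is.null(nu0)) nu0 <- 1 / natural_period(params, dt = dt)
  f <- f_over_nu0 * nu0
  TL <- 1 / f
  if (tau >= TL)
    stop("pulse duration tau must be shorter than the forcing period")
  forced <- opto_params(params$alpha, params$beta, params$n,
                        beta_prime_on = beta_prime,
                        beta_prime_off = params$beta_prime_off)
  protocol <- if (beta_prime > 0)
    light_pulse_train(0, TL, tau, n_periods) else light_constant("off")
  tr <- simulate_opto(forced, protocol, t_end = n_periods * TL,
                      dt = dt, record_dt = record_dt)
  keep <- tr$times >= n_discard * TL
  sig <- tr$states[keep, "y"]
  ps <- power_spectrum(sig, dt = tr$record_dt)
  nu <- dominant_frequency(ps)
  list(nu = nu, f = f, ratio = nu / f,
       resolution = ps$frequency[1L], spectrum = ps)
}

#' Frequency-ratio surface over the forcing plane (Arnold tongues)
#'
#' Computes the locking ratio nu/f of a single forced oscillator on a grid of
#' forcing frequencies (in units of the natural frequency) and amplitudes
#' beta'. Grid cells whose ratio sits within `label_tol` of a low-order
#' rational p/q in {1, 1/2, 2, 3/2, 2/3} are labelled with that rational;
#' unforced cells (beta' = 0) are always labelled `"unlocked"`, since locking
#' requires forcing.
#'
#' @param params An [opto_params()].
#' @param f_grid Forcing frequencies, units of nu0.
#' @param beta_prime_grid Forcing amplitudes (1/h).
#' @param tau Pulse duration (h).
#' @param label_tol Plateau tolerance on |nu/f - p/q|.
#' @param ... Passed to [frequency_ratio()] (`n_periods`, `dt`, ...).
#' @return A `tongue_surface` data frame (long format) with columns
#'   `f_over_nu0`, `beta_prime`, `ratio`, `label`, and attributes `nu0` and
#'   `tau`.
#' @export
tongue_surface <- function(params, f_grid = seq(0.4, 2.4, by = 0.1),
                           beta_prime_grid = c(0, 10, 20, 40, 80, 120),
                           tau = 2, label_tol = 0.02, ...) {
  params <- as_opto_params(params)
  nu0 <- 1 / natural_period(params)
  rationals <- c("1" = 1, "1/2" = 1 / 2, "2" = 2, "3/2" = 3 / 2,
                 "2/3" = 2 / 3)
  grid <- expand.grid(f_over_nu0 = f_grid, beta_prime = beta_prime_grid)
  res <- vapply(seq_len(nrow(grid)), function(i) {
    frequency_ratio(params, grid$f_over_nu0[i],
                    beta_prime = grid$beta_prime[i], tau = tau,
                    nu0 = nu0, ...)$ratio
  }, numeric(1))
  lab <- vapply(seq_len(nrow(grid)), function(i) {
    if (grid$beta_prime[i] <= 0) return("unlocked")
    d <- abs(res[i] - rationals)
    if (min(d) < label_tol) names(rationals)[which.min(d)] else "unlocked"
  }, character(1))
  out <- data.frame(grid, ratio = res, label = lab)
  attr(out, "nu0") <- nu0
  attr(out, "tau") <- tau
  class(out) <- c("tongue_surface", "data.frame")
  out
}

#' Export a tongue surface
#'
#' Long-format CSV (`f_over_nu0`, `beta_prime`, `ratio`, `label`) plus a JSON
#' scan-configuration sidecar (`nu0`, `tau`, grids).
#'
#' @param surface A [tongue_surface()] result.
#' @param path CSV output file.
#' @param config_path JSON sidecar; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_tongue_csv <- function(surface, path,
                             config_path = paste0(path, ".json")) {
  stopifnot(inherits(surface, "tongue_surface"))
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  jsonlite::write_json(list(nu0 = attr(surface, "nu0"),
                            tau = attr(surface, "tau"),
                            f_over_nu0 = unique(surface$f_over_nu0),
                            beta_prime = unique(surface$beta_prime)),
                       config_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Population average on the half-frequency tongue
#'
#' On the nu/f = 1/2 tongue each cell peaks on every other light pulse, so a
#' cell is characterized by the parity (even/odd pulse index) of the pulses
#' at which its y peaks occur. Cells of opposite parity cancel in the
#' population mean: when both parities are populated the mean oscillates at
#' the forcing frequency f rather than at f/2.
#'
#' Cells whose post-transient peaks do not settle on a single parity (at
#' least `parity_majority` of peaks on one parity) are excluded with a
#' warning.
#'
#' @param spec An [ensemble_spec()].
#' @param f_over_nu0 Forcing frequency in units of the ensemble-mean natural
#'   frequency; about 2 for the half-frequency tongue.
#' @param beta_prime Forcing amplitude (1/h).
#' @param tau Pulse duration (h).
#' @param n_periods Forcing periods simulated.
#' @param n_discard Forcing periods discarded as transient.
#' @param parity_majority Fraction of peaks that must share a parity.
#' @param dt,record_dt Integration and output steps (h).
#' @return List with `times`, `population_mean` (over parity-classified
#'   cells), `parity` (0/1 per cell, NA for excluded cells), `n_excluded`,
#'   `f` (1/h), `TL` (h), and `dominant_frequency` of the mean trace (1/h).
#' @export
alternate_peak_population <- function(spec, f_over_nu0 = 2, beta_prime = 80,
                                      tau = 2, n_periods = 40,
                                      n_discard = 10,
                                      parity_majority = 0.9,
                                      dt = 0.005, record_dt = 0.05) {
  stopifnot(inherits(spec, "ensemble_spec"))
  p <- spec$params
  base <- opto_params(spec$alpha_mean, p$beta, p$n,
                      beta_prime_on = p$beta_prime_on,
                      beta_prime_off = p$beta_prime_off)
  T0 <- natural_period(base, dt = dt)
  TL <- T0 / f_over_nu0
  f <- 1 / TL
  forced_spec <- spec
  forced_spec$params <- opto_params(p$alpha, p$beta, p$n,
                                    beta_prime_on = beta_prime,
                                    beta_prime_off = p$beta_prime_off)
  protocol <- light_pulse_train(0, TL, tau, n_periods)
  res <- simulate_ensemble(forced_spec, protocol, t_end = n_periods * TL,
                           dt = dt, record_dt = record_dt)
  keep <- res$times >= n_discard * TL
  pulse_starts <- protocol$on_starts
  parity <- rep(NA_integer_, ncol(res$y))
  for (i in seq_len(ncol(res$y))) {
    pk <- detect_peaks(res$y[keep, i], res$times[keep],
                       min_separation = 0.5 * T0, min_prominence = 0.2)
    if (nrow(pk) < 3L) next
    idx <- vapply(pk$time, function(tp)
      which.min(abs(pulse_starts - tp)) - 1L, integer(1))
    par <- idx %% 2L
    tab <- table(par)
    if (max(tab) / length(par) >= parity_majority)
      parity[i] <- as.integer(names(tab)[which.max(tab)])
  }
  n_excluded <- sum(is.na(parity))
  if (n_excluded > 0L)
    warning(sprintf("%d unlocked cell(s) excluded from the parity average",
                    n_excluded))
  locked <- which(!is.na(parity))
  if (length(locked) == 0L) stop("no cells locked on the half-frequency tongue")
  mean_trace <- rowMeans(res$y[, locked, drop = FALSE])
  ps <- power_spectrum(mean_trace[keep], dt = record_dt)
  list(times = res$times, population_mean = mean_trace, parity = parity,
       n_excluded = n_excluded, f = f, TL = TL,
       dominant_frequency = dominant_frequency(ps))
}
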