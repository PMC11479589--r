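# shared fixtures: the calibrated parameter set and a plain-R Euler stepper
# used as an independent oracle for the compiled integrator

default_params <- function() opto_params()

# forward Euler in plain R, same left-endpoint beta' convention
r_euler <- function(init, params, beta_prime, dt) {
  s <- matrix(NA_real_, nrow = length(beta_prime) + 1L, ncol = 4L)
  s[1L, ] <- init
  for (k in seq_along(beta_prime)) {
    x <- s[k, 1L]; y <- s[k, 2L]; z <- s[k, 3L]; xp <- s[k, 4L]
    s[k + 1L, ] <- c(
      x + dt * (params$beta / (1 + z^params$n) - params$alpha * x),
      y + dt * (params$beta / (1 + (x + xp)^params$n) - params$alpha * y),
      z + dt * (params$beta / (1 + y^params$n) - params$alpha * z),
      xp + dt * (beta_prime[k] - params$alpha * xp))
  }
  s
}

# peak-swing envelope ratio over a time window: mean of the last `n_edge`
# peak-to-trough swings over the mean of the first `n_edge`
envelope_ratio <- function(signal, times, t_min = 0, t_max = Inf,
                           n_edge = 2) {
  keep <- times >= t_min & times <= t_max
  signal <- signal[keep]
  times <- times[keep]
  centred <- signal - mean(signal)
  pk <- detect_peaks(centred, times, min_separation = 5,
                     min_prominence = 0.02)
  tr <- detect_peaks(-centred, times, min_separation = 5,
                     min_prominence = 0.01)
  swing <- vapply(seq_len(nrow(pk)), function(i) {
    j <- which(tr$time > pk$time[i])[1L]
    if (is.na(j)) NA_real_ else pk$height[i] + tr$height[j]
  }, numeric(1))
  swing <- swing[!is.na(swing)]
  mean(utils::tail(swing, n_edge)) / mean(utils::head(swing, n_edge))
}
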