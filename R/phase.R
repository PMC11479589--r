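#' Detect peaks in a uniformly sampled signal
#'
#' Finds local maxima separated by at least `min_separation` hours whose
#' topographic prominence is at least `min_prominence` times the global
#' signal range. Peak times (and heights) are refined by parabolic
#' interpolation through the three samples around each maximum, so peak-time
#' resolution is much finer than the sampling interval.
#'
#' @param signal Numeric vector, uniformly sampled.
#' @param times Sampling times (h), strictly increasing, same length.
#' @param min_separation Minimum spacing between reported peaks (h).
#' @param min_prominence Minimum prominence as a fraction of the global
#'   (max - min) range.
#' @return A data frame with columns `time`, `height`, `index` (one row per
#'   peak, ordered by time); zero rows for flat or featureless signals.
#' @export
#' @examples
#' t <- seq(0, 70, by = 0.01)
#' detect_peaks(cos(2 * pi * t / 17.5), t, min_separation = 5)
detect_peaks <- function(signal, times, min_separation = 0,
                         min_prominence = 0) {
  stopifnot(is.numeric(signal), is.numeric(times),
            length(signal) == length(times), length(signal) >= 3L)
  empty <- data.frame(time = numeric(0), height = numeric(0),
                      index = integer(0))
  rng <- max(signal) - min(signal)
  if (!is.finite(rng) || rng == 0) return(empty)
  n <- length(signal)
  i <- 2:(n - 1L)
  cand <- i[signal[i] > signal[i - 1L] & signal[i] >= signal[i + 1L]]
  if (length(cand) == 0L) return(empty)

  prominence <- vapply(cand, function(j) {
    h <- signal[j]
    left <- if (j > 1L) {
      higher <- which(signal[seq_len(j - 1L)] > h)
      from <- if (length(higher)) max(higher) + 1L else 1L
      min(signal[from:(j - 1L)])
    } else h
    right <- if (j < n) {
      seg <- signal[(j + 1L):n]
      higher <- which(seg > h)
      upto <- if (length(higher)) min(higher) - 1L else length(seg)
      min(seg[seq_len(upto)])
    } else h
    h - max(left, right)
  }, numeric(1))
  keep <- prominence >= min_prominence * rng & prominence > 0
  cand <- cand[keep]
  if (length(cand) == 0L) return(empty)

  # enforce min_separation greedily, strongest peaks first
  if (min_separation > 0 && length(cand) > 1L) {
    o <- order(signal[cand], decreasing = TRUE)
    chosen <- integer(0)
    for (j in cand[o]) {
      if (all(abs(times[j] - times[chosen]) >= min_separation))
        chosen <- c(chosen, j)
    }
    cand <- sort(chosen)
  }

  dt <- times[2L] - times[1L]
  refine <- function(j) {
    a <- signal[j - 1L]; b <- signal[j]; cc <- signal[j + 1L]
    denom <- a - 2 * b + cc
    off <- if (denom < 0) 0.5 * (a - cc) / denom else 0
    off <- max(min(off, 0.5), -0.5)
    c(times[j] + off * dt, b - 0.25 * (a - cc) * off)
  }
  ref <- vapply(cand, refine, numeric(2))
  data.frame(time = ref[1L, ], height = ref[2L, ], index = cand)
}

#' Free-running oscillation period
#'
#' Simulates the optorepressilator under constant red light from the default
#' post-synchronization state and returns the mean peak-to-peak spacing of
#' the y (TetR) trace after discarding the first two cycles. With the default
#' parameters (alpha 0.75/h, beta 300/h, n 3) this is about 17.5 h.
#'
#' @param params An [opto_params()] (its `beta_prime_off` is the free-running
#'   light level; 0 by default).
#' @param t_end Simulation horizon (h); long enough for at least 4 peaks.
#' @param dt Euler step (h).
#' @param record_dt Output sampling (h).
#' @return Natural period T0 (h).
#' @export
#' @examples
#' \donttest{natural_period(opto_params())}
natural_period <- function(params, t_end = 250, dt = 0.005,
                           record_dt = 0.01) {
  params <- as_opto_params(params)
  tr <- simulate_opto(params, light_constant("off"), t_end = t_end,
                      dt = dt, record_dt = record_dt)
  pk <- detect_peaks(tr$states[, "y"], tr$times,
                     min_separation = 1, min_prominence = 0.2)
  if (nrow(pk) < 4L)
    stop("fewer than 4 y-peaks found; increase t_end")
  mean(diff(pk$time[-(1:2)]))
}

#' Wrap a phase to a standard interval
#'
#' `wrap_phase()` wraps to the signed interval `[-0.5, 0.5)` (phase 0 at the
#' y-expression peak, advances positive); `phase_mod1()` wraps to `[0, 1)`,
#' the convention in which the circle map is usually written. Both act
#' elementwise.
#'
#' @param phi Phase(s) in cycles.
#' @return Wrapped phase(s).
#' @export
wrap_phase <- function(phi) ((phi + 0.5) %% 1) - 0.5

#' @rdname wrap_phase
#' @export
phase_mod1 <- function(phi) phi %% 1

# Reference free-running run shared by phase_response() calls: natural
# period, reference peak list, the anchor peak the pulse phase is measured
# from, and the common horizon.
prepare_reference <- function(params, dt = 0.005, k = 3, record_dt = 0.01) {
  params <- as_opto_params(params)
  T0 <- natural_period(params, dt = dt, record_dt = record_dt)
  t_end <- (k + 9) * T0
  tr <- simulate_opto(params, light_constant("off"), t_end = t_end,
                      dt = dt, record_dt = record_dt)
  pk <- detect_peaks(tr$states[, "y"], tr$times,
                     min_separation = 0.25 * T0, min_prominence = 0.2)
  anchor <- pk$time[pk$time >= 3 * T0][1L]
  if (is.na(anchor)) stop("no established reference peak found")
  list(params = params, T0 = T0, ref_peaks = pk$time, anchor = anchor,
       t_end = t_end, dt = dt, record_dt = record_dt, k = k)
}

#' Phase shift produced by a single light pulse
#'
#' Measures the phase response of the free-running oscillator to one green
#' pulse of duration `tau` and amplitude `beta_prime_pulse`. The pulse starts
#' at phase `phi` (in cycles, 0 at a y peak, so `phi > 0` means the pulse
#' arrives after the peak). The shift is read off at the `k`-th y peak after
#' the pulse end, comparing perturbed against unperturbed peak times:
#' \deqn{\Delta\phi = (t^{ref}_k - t^{pert}_k)/T_0} wrapped to `[-0.5, 0.5)`,
#' so a phase advance is positive. By `k = 3` the post-pulse transient has
#' decayed and the result is independent of `k`.
#'
#' @param params An [opto_params()]; the pulse amplitude below overrides its
#'   `beta_prime_on`.
#' @param phi Pulse arrival phase (cycles), wrapped to `[-0.5, 0.5)`.
#' @param tau Pulse duration (h); default 2.
#' @param beta_prime_pulse Pulse amplitude (1/h); default 80.
#' @param dt Euler step (h).
#' @param k Peak index after the pulse at which the shift is measured.
#' @param ref Optional shared reference from repeated calls (internal use by
#'   [compute_prc()]).
#' @return Phase shift in cycles, in `[-0.5, 0.5)`.
#' @export
phase_response <- function(params, phi, tau = 2, beta_prime_pulse = 80,
                           dt = 0.005, k = 3, ref = NULL) {
  params <- as_opto_params(params)
  if (is.null(ref)) ref <- prepare_reference(params, dt = dt, k = k)
  phi <- wrap_phase(phi)
  t_pulse <- ref$anchor + phi * ref$T0
  if (t_pulse < ref$T0)
    stop("pulse scheduled before the reference cycle is established")
  if (beta_prime_pulse == 0) return(0)
  pulsed <- opto_params(params$alpha, params$beta, params$n,
                        beta_prime_on = beta_prime_pulse,
                        beta_prime_off = params$beta_prime_off)
  tr <- simulate_opto(pulsed, light_pulse(t_pulse, tau), t_end = ref$t_end,
                      dt = ref$dt, record_dt = ref$record_dt)
  pk <- detect_peaks(tr$states[, "y"], tr$times,
                     min_separation = 0.25 * ref$T0, min_prominence = 0.2)
  after_ref <- ref$ref_peaks[ref$ref_peaks > t_pulse + tau]
  after_pert <- pk$time[pk$time > t_pulse + tau]
  kk <- ref$k
  if (length(after_ref) < kk || length(after_pert) < kk)
    stop("trajectory too short to reach the measurement peak; increase t_end")
  wrap_phase((after_ref[kk] - after_pert[kk]) / ref$T0)
}

#' Phase response curve of the optorepressilator
#'
#' Evaluates [phase_response()] on a uniform grid of `n_points` pulse-arrival
#' phases covering `[-0.5, 0.5)`, sharing one free-running reference run.
#' With the default 2-h, 80/h pulse the curve crosses zero with negative
#' slope near phi = 0: pulses arriving before the y peak advance the clock,
#' pulses after it delay it, and the advance grows the earlier the pulse
#' arrives.
#'
#' Each individual shift is only defined modulo one cycle; the default pulse
#' resets strongly enough (type-0 resetting) that advances exceed half a
#' cycle for early-arriving pulses. The curve is therefore reported
#' branch-continuously — each grid value is the mod-1 representative closest
#' to its neighbour, anchored at the small wrapped shift near phi = 0 — so
#' its only discontinuity is the advance/delay crossover at the periodic
#' boundary. Apply [wrap_phase()] to `delta_phi` for the wrapped view; the
#' circle-map dynamics are identical modulo 1.
#'
#' @inheritParams phase_response
#' @param n_points Number of grid points (>= 8).
#' @return A `phase_response_curve`: list with `phi`, `delta_phi`, `tau`,
#'   `beta_prime`, `T0`.
#' @export
compute_prc <- function(params, tau = 2, beta_prime_pulse = 80,
                        n_points = 64, dt = 0.005, k = 3) {
  stopifnot(n_points >= 8)
  params <- as_opto_params(params)
  ref <- prepare_reference(params, dt = dt, k = k)
  phis <- -0.5 + (seq_len(n_points) - 1) / n_points
  dphis <- vapply(phis, function(p)
    phase_response(params, p, tau = tau,
                   beta_prime_pulse = beta_prime_pulse, ref = ref),
    numeric(1))
  # Each shift is defined modulo one cycle. The default 2-h, 80/h pulse
  # resets strongly (type-0): advances grow past half a cycle for early
  # pulses, so wrapping every point to [-0.5, 0.5) would cut the advance
  # branch with a spurious jump. Report the branch-continuous
  # representative (each value within half a cycle of its neighbour),
  # anchored at the small wrapped shift nearest phi = 0; the only remaining
  # discontinuity is the advance/delay crossover at the periodic boundary.
  for (i in seq_along(dphis)[-1L])
    dphis[i] <- dphis[i] - round(dphis[i] - dphis[i - 1L])
  i0 <- which.min(abs(phis))
  dphis <- dphis - round(dphis[i0] - wrap_phase(dphis[i0]))
  structure(list(phi = phis, delta_phi = dphis, tau = tau,
                 beta_prime = beta_prime_pulse, T0 = ref$T0, k = k),
            class = "phase_response_curve")
}

#' @export
print.phase_response_curve <- function(x, ...) {
  cat("Phase response curve: ", length(x$phi), " points, tau = ", x$tau,
      " h, beta' = ", x$beta_prime, " 1/h, T0 = ", round(x$T0, 3), " h\n",
      sep = "")
  invisible(x)
}

#' Interpolate a phase response curve
#'
#' Periodic linear interpolation of the sampled PRC; phases are wrapped to
#' `[-0.5, 0.5)` first.
#'
#' @param prc A [compute_prc()] result.
#' @param phi Phase(s) in cycles.
#' @return Interpolated phase shift(s) in cycles.
#' @export
prc_interp <- function(prc, phi) {
  stopifnot(inherits(prc, "phase_response_curve"))
  n <- length(prc$delta_phi)
  # periodic continuation: the value at +0.5 is the first grid value up to
  # the integer branch offset that keeps the curve continuous at the seam
  v_end <- prc$delta_phi[1L] +
    round(prc$delta_phi[n] - prc$delta_phi[1L])
  xs <- c(prc$phi, 0.5)
  ys <- c(prc$delta_phi, v_end)
  stats::approx(xs, ys, xout = wrap_phase(phi))$y
}

#' One step of the pulse-train circle map
#'
#' Under a train of identical pulses with period `TL`, the phase at which
#' successive pulses arrive follows the circle map
#' \deqn{\phi_{n+1} = \phi_n + T_L/T_0 - 1 + \Delta\phi(\phi_n),}
#' wrapped here to `[-0.5, 0.5)`.
#'
#' @param phi_n Current pulse-arrival phase(s) (cycles).
#' @param prc A [compute_prc()] result.
#' @param TL Forcing period (h).
#' @return Next phase(s), wrapped.
#' @export
circle_map_step <- function(phi_n, prc, TL) {
  stopifnot(inherits(prc, "phase_response_curve"), TL > 0)
  wrap_phase(phi_n + TL / prc$T0 - 1 + prc_interp(prc, phi_n))
}

#' Entrained phase predicted by the circle map
#'
#' Solves the fixed-point condition \deqn{\Delta\phi(\phi^*) = 1 - T_L/T_0}
#' on the interpolated PRC by bracketing sign changes and bisection. Because
#' a phase shift is defined modulo one cycle, the condition is solved mod 1:
#' crossings of the branch-continuous curve with the target shifted by an
#' integer count the same fixed points of the wrapped map. A fixed point is
#' a stable entrained state when the PRC slope there satisfies
#' `-2 < slope < 0`.
#'
#' @param prc A [compute_prc()] result.
#' @param TL Forcing period (h).
#' @param tol Bisection tolerance (cycles).
#' @return An `entrained_state`: list with `phi_star` (cycles), `slope`
#'   (d(delta phi)/d phi at the fixed point), `stable`, `TL`, `T0`. If no
#'   fixed point exists the detuning is outside the locking range and an
#'   error of class `optorep_outside_locking_range` is thrown.
#' @export
entrained_phase <- function(prc, TL, tol = 1e-4) {
  stopifnot(inherits(prc, "phase_response_curve"), TL > 0)
  target0 <- 1 - TL / prc$T0
  n <- length(prc$delta_phi)
  v_end <- prc$delta_phi[1L] +
    round(prc$delta_phi[n] - prc$delta_phi[1L])
  ph <- c(prc$phi, 0.5)
  dp <- c(prc$delta_phi, v_end)
  roots <- numeric(0)
  for (m in -1:1) {
    target <- target0 + m
    f <- function(p) prc_interp(prc, p) - target
    g <- dp - target
    for (i in seq_len(length(ph) - 1L)) {
      if (g[i] == 0) {
        roots <- c(roots, ph[i])
      } else if (g[i] * g[i + 1L] < 0) {
        lo <- ph[i]; hi <- ph[i + 1L]
        while (hi - lo > tol) {
          mid <- (lo + hi) / 2
          if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
        }
        roots <- c(roots, (lo + hi) / 2)
      }
    }
  }
  if (length(roots) == 0L) {
    cond <- structure(
      class = c("optorep_outside_locking_range", "error", "condition"),
      list(message = sprintf(
        "no entrained phase: 1 - TL/T0 = %.4f is outside the PRC range [%.4f, %.4f]",
        target, min(prc$delta_phi), max(prc$delta_phi)),
        call = sys.call(-1)))
    stop(cond)
  }
  h <- prc$phi[2L] - prc$phi[1L]
  slopes <- vapply(roots, function(r)
    (prc_interp(prc, r + h) - prc_interp(prc, r - h)) / (2 * h), numeric(1))
  stable <- slopes > -2 & slopes < 0
  if (sum(stable) > 1L)
    stop("multiple stable entrained phases found; PRC grid too coarse?")
  pick <- if (any(stable)) which(stable)[1L] else 1L
  structure(list(phi_star = wrap_phase(roots[pick]), slope = slopes[pick],
                 stable = stable[pick], TL = TL, T0 = prc$T0),
            class = "entrained_state")
}

#' @export
print.entrained_state <- function(x, ...) {
  cat("Entrained state: phi* = ", round(x$phi_star, 4), " cycles, slope = ",
      round(x$slope, 3), if (x$stable) " (stable)\n" else " (unstable)\n",
      sep = "")
  invisible(x)
}

#' Entrained phase measured from a forced trajectory
#'
#' For a trajectory driven by a pulse train, measures the phase difference
#' between pulse onsets and the nearest y peaks, averaged over the late
#' pulses (the first `n_discard` forcing periods are treated as transient).
#' Phases follow the PRC convention: `(t_pulse - t_peak)/T0`, wrapped to
#' `[-0.5, 0.5)`, positive when the pulse arrives after the peak.
#'
#' A trajectory whose pulse phase drifts monotonically instead of settling is
#' flagged as not entrained and no phase is returned.
#'
#' @param trajectory A [simulate_opto()] result under a pulse-train protocol.
#' @param T0 Natural period of the oscillator (h).
#' @param n_discard Forcing periods discarded as transient (>= 5 recommended).
#' @param drift_tol Total unwrapped phase change (cycles) across the retained
#'   pulses above which the trajectory is flagged as drifting.
#' @return List with `phi_star` (circular mean, cycles), `sd` (circular
#'   standard deviation across pulses), `entrained` (logical), `phases`
#'   (per-pulse), `n_pulses`.
#' @export
measured_entrained_phase <- function(trajectory, T0, n_discard = 5,
                                     drift_tol = 0.25) {
  stopifnot(inherits(trajectory, "trajectory"), T0 > 0)
  starts <- trajectory$protocol$on_starts
  if (length(starts) < n_discard + 3L)
    stop("need at least n_discard + 3 pulses to measure the entrained phase")
  pk <- detect_peaks(trajectory$states[, "y"], trajectory$times,
                     min_separation = 0.25 * T0, min_prominence = 0.1)
  if (nrow(pk) < 2L) stop("too few y peaks in the forced trajectory")
  late <- starts[-seq_len(n_discard)]
  late <- late[late < max(trajectory$times) - 0.1 * T0]
  phases <- vapply(late, function(tp) {
    wrap_phase((tp - pk$time[which.min(abs(pk$time - tp))]) / T0)
  }, numeric(1))
  # unwrap to detect monotone drift
  unwrapped <- cumsum(c(phases[1L], wrap_phase(diff(phases))))
  drift <- abs(unwrapped[length(unwrapped)] - unwrapped[1L])
  ang <- 2 * pi * phases
  mvec <- complex(real = mean(cos(ang)), imaginary = mean(sin(ang)))
  circ_sd <- sqrt(-2 * log(max(Mod(mvec), .Machine$double.eps))) / (2 * pi)
  entrained <- drift <= drift_tol
  list(phi_star = if (entrained) wrap_phase(Arg(mvec) / (2 * pi)) else NA_real_,
       sd = circ_sd, entrained = entrained, phases = phases,
       n_pulses = length(phases))
}

#' Export a phase response curve
#'
#' Writes the sampled curve as CSV (`phi`, `delta_phi`) plus a JSON sidecar
#' holding `tau`, `beta_prime` and `T0`.
#'
#' @param prc A [compute_prc()] result.
#' @param path CSV output file.
#' @param header_path JSON sidecar path; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_prc_csv <- function(prc, path, header_path = paste0(path, ".json")) {
  stopifnot(inherits(prc, "phase_response_curve"))
  utils::write.csv(data.frame(phi = prc$phi, delta_phi = prc$delta_phi),
                   path, row.names = FALSE)
  jsonlite::write_json(list(tau = prc$tau, beta_prime = prc$beta_prime,
                            T0 = prc$T0), header_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
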