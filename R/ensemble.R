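# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a heterogeneous oscillator population
#'
#' Describes an ensemble of independent (uncoupled) optorepressilators whose
#' growth rates alpha are drawn from a normal distribution, the dominant
#' source of cell-to-cell period variability. Plate-reader-like populations
#' use `alpha_sd = 0.034` 1/h; mother-machine populations show a wider spread,
#' `alpha_sd = 0.071` 1/h. Production rate, cooperativity and light response
#' are shared across cells.
#'
#' Initial-condition modes:
#' * `"synchronized_green"`: every cell starts at its green fixed point with
#'   the light-driven LacI reset, `(0, 0, beta/alpha_i, 0)` — the state just
#'   after a synchronizing green pulse.
#' * `"synchronized_iptg"`: the IPTG-arrested state `(beta/alpha_i,
#'   beta/alpha_i, 0, 0)` in which LacI is chemically inactivated and x, y
#'   accumulate while z decays.
#' * `"random_phase"`: each cell placed at a uniformly random phase along its
#'   own free-running limit cycle (after a discarded transient).
#'
#' @param n_cells Number of cells (>= 1).
#' @param alpha_mean Mean growth rate (1/h).
#' @param alpha_sd Growth-rate standard deviation (1/h), >= 0.
#' @param seed RNG seed controlling growth-rate draws and random phases.
#' @param params An [opto_params()] template shared by all cells (its `alpha`
#'   is replaced per cell).
#' @param init_mode One of `"synchronized_green"`, `"synchronized_iptg"`,
#'   `"random_phase"`.
#' @return An `ensemble_spec` object.
#' @export
#' @examples
#' ensemble_spec(n_cells = 50, alpha_sd = 0.071, seed = 7)
ensemble_spec <- function(n_cells = 200, alpha_mean = 0.75,
                          alpha_sd = 0.034, seed = 1,
                          params = opto_params(),
                          init_mode = c("synchronized_green",
                                        "synchronized_iptg",
                                        "random_phase")) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1,
            is.numeric(alpha_mean), alpha_mean > 0,
            is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(alpha_sd) || length(alpha_sd) != 1L || alpha_sd < 0)
    stop("alpha_sd must be a single number >= 0")
  init_mode <- match.arg(init_mode)
  params <- as_opto_params(params)
  structure(list(n_cells = as.integer(n_cells), alpha_mean = alpha_mean,
                 alpha_sd = alpha_sd, seed = as.integer(seed),
                 params = params, init_mode = init_mode),
            class = "ensemble_spec")
}

#' Draw per-cell growth rates
#'
#' Growth rates are i.i.d. normal with the spec's mean and standard
#' deviation; non-positive draws are redrawn (the normal tail below zero is
#' negligible at the shipped presets but must not produce unphysical cells).
#' Reproducible given the spec's seed.
#'
#' @param spec An [ensemble_spec()].
#' @return Numeric vector of `n_cells` growth rates (1/h), all positive.
#' @export
draw_growth_rates <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_seed(spec$seed, {
    a <- stats::rnorm(spec$n_cells, spec$alpha_mean, spec$alpha_sd)
    while (any(a <= 0))
      a[a <= 0] <- stats::rnorm(sum(a <= 0), spec$alpha_mean, spec$alpha_sd)
    a
  })
}

#' Per-cell initial states
#'
#' Builds the initial `(x, y, z, x_prime)` state of every cell according to
#' the spec's `init_mode` (see [ensemble_spec()]).
#'
#' @param spec An [ensemble_spec()].
#' @param alphas Optional growth rates; drawn from the spec when omitted.
#' @param dt Euler step used when sampling random phases (h).
#' @return A numeric matrix (`n_cells` x 4) with columns
#'   `x`, `y`, `z`, `x_prime`.
#' @export
initial_states <- function(spec, alphas = NULL, dt = 0.005) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (is.null(alphas)) alphas <- draw_growth_rates(spec)
  stopifnot(length(alphas) == spec$n_cells)
  p <- spec$params
  out <- switch(spec$init_mode,
    synchronized_green = cbind(0, 0, p$beta / alphas, 0),
    synchronized_iptg = cbind(p$beta / alphas, p$beta / alphas, 0, 0),
    random_phase = {
      # place each cell at a uniform random time along its own limit cycle,
      # after an 8-period transient from the synchronized state
      u <- with_seed(spec$seed + 1L, stats::runif(spec$n_cells))
      t(vapply(seq_len(spec$n_cells), function(i) {
        pi_ <- opto_params(alphas[i], p$beta, p$n,
                           beta_prime_on = p$beta_prime_on,
                           beta_prime_off = p$beta_prime_off)
        T_i <- 3 * log(p$beta / alphas[i]) / alphas[i]  # digital-limit scale
        tr <- simulate_opto(pi_, light_constant("off"),
                            t_end = 9 * T_i, dt = dt, record_dt = 0.01)
        pk <- detect_peaks(tr$states[, "y"], tr$times,
                           min_separation = 1, min_prominence = 0.2)
        late <- pk$time[pk$time >= 6 * T_i]
        t0 <- if (length(late) >= 2L) late[1L] else pk$time[nrow(pk) - 1L]
        period <- if (length(late) >= 2L) late[2L] - late[1L]
                  else diff(utils::tail(pk$time, 2L))
        j <- which.min(abs(tr$times - (t0 + u[i] * period)))
        tr$states[j, ]
      }, numeric(4)))
    })
  colnames(out) <- c("x", "y", "z", "x_prime")
  out
}

#' Simulate an uncoupled population of optorepressilators
#'
#' Integrates every cell independently on a common time grid (no cell-cell
#' coupling) and averages the reporter-proxy variable y across cells.
#'
#' @param spec An [ensemble_spec()].
#' @param protocol A light protocol applied identically to all cells.
#' @param t_end Horizon (h).
#' @param dt Euler step (h).
#' @param record_dt Output sampling (h); default 0.05 keeps long population
#'   runs compact.
#' @return An `ensemble_result`: list with `times`, `y` (time x cell matrix),
#'   `population_mean` (arithmetic mean of y across cells), `alphas`,
#'   `init`, `spec`, `protocol`.
#' @export
#' @examples
#' \donttest{
#' spec <- ensemble_spec(n_cells = 20, seed = 3)
#' res <- simulate_ensemble(spec, light_constant("off"), t_end = 120)
#' }
simulate_ensemble <- function(spec, protocol = light_constant("off"),
                              t_end, dt = 0.005, record_dt = 0.05) {
  stopifnot(inherits(spec, "ensemble_spec"),
            inherits(protocol, "light_protocol"))
  alphas <- draw_growth_rates(spec)
  init <- initial_states(spec, alphas, dt = dt)
  p <- spec$params
  y <- NULL
  times <- NULL
  for (i in seq_len(spec$n_cells)) {
    pi_ <- opto_params(alphas[i], p$beta, p$n,
                       beta_prime_on = p$beta_prime_on,
                       beta_prime_off = p$beta_prime_off)
    tr <- simulate_opto(pi_, protocol, initial = init[i, ], t_end = t_end,
                        dt = dt, record_dt = record_dt)
    if (is.null(y)) {
      times <- tr$times
      y <- matrix(NA_real_, nrow = length(times), ncol = spec$n_cells)
    }
    y[, i] <- tr$states[, "y"]
  }
  structure(list(times = times, y = y,
                 population_mean = rowMeans(y),
                 alphas = alphas, init = init,
                 spec = spec, protocol = protocol),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("Ensemble of ", ncol(x$y), " optorepressilators over ",
      max(x$times), " h (", x$spec$init_mode, " start)\n", sep = "")
  invisible(x)
}

#' Periods until the population signal damps to half amplitude
#'
#' Quantifies dephasing of an initially synchronized population: the
#' population-mean signal oscillates with an envelope that decays as cells
#' drift out of phase. The envelope is anchored at the successive maxima of
#' the baseline-subtracted mean signal; the amplitude at each maximum is the
#' full oscillation contrast there, peak height minus the following trough.
#' (For a near-sinusoidal signal this is proportional to the peak height
#' itself; for the sharply peaked repressilator waveform the peak tips smear
#' out much faster than the oscillation contrast, so the swing is the robust
#' measure.) Peaks whose swing is below 5% of the first swing are ignored as
#' noise. Returns the time at which the envelope first falls below half the
#' first amplitude (linearly interpolated between peaks), measured from the
#' start of the record — the synchronization instant — and divided by the
#' mean peak-to-peak period. A record that starts on an amplitude maximum
#' (the chemically synchronized release, where the reporter is maximal)
#' counts that boundary maximum as the reference peak, so the convention
#' agrees with reading the halving time off a measured trace. An undamped
#' signal returns `Inf` ("not reached").
#'
#' @param x An `ensemble_result` (its `population_mean` is used) or a numeric
#'   signal.
#' @param times Sampling times (h); taken from `x` when it is an
#'   `ensemble_result`.
#' @param min_separation Minimum peak spacing passed to [detect_peaks()] (h).
#' @return Number of periods (dimensionless), possibly `Inf`.
#' @export
periods_to_half_amplitude <- function(x, times = NULL, min_separation = 2) {
  if (inherits(x, "ensemble_result")) {
    times <- x$times
    signal <- x$population_mean
  } else {
    signal <- x
  }
  stopifnot(is.numeric(signal), is.numeric(times),
            length(signal) == length(times))
  centred <- signal - mean(signal)
  pk <- detect_peaks(centred, times, min_separation = min_separation,
                     min_prominence = 0.01)
  tr <- detect_peaks(-centred, times, min_separation = min_separation,
                     min_prominence = 0.005)
  if (nrow(pk) < 2L) stop("need at least 2 peaks to define an envelope")
  # a record starting on a maximum (synchronized release) anchors the
  # envelope at t = times[1]
  if (centred[1L] >= centred[2L] && centred[1L] > pk$height[1L] / 2 &&
      times[1L] < pk$time[1L] - min_separation)
    pk <- rbind(data.frame(time = times[1L], height = centred[1L],
                           index = 1L), pk)
  # oscillation swing at each maximum: peak height minus the next trough
  swing <- vapply(seq_len(nrow(pk)), function(i) {
    j <- which(tr$time > pk$time[i])[1L]
    if (is.na(j)) NA_real_ else pk$height[i] + tr$height[j]
  }, numeric(1))
  keep <- !is.na(swing)
  pk <- pk[keep, , drop = FALSE]
  swing <- swing[keep]
  if (length(swing) < 2L) stop("need at least 2 peaks to define an envelope")
  a1 <- swing[1L]
  keep <- swing >= 0.05 * a1
  pk <- pk[keep, , drop = FALSE]
  swing <- swing[keep]
  period <- mean(diff(pk$time))
  below <- which(swing < 0.5 * a1)
  if (length(below) == 0L) return(Inf)
  j <- below[1L]
  if (j == 1L) return(0)
  # linear interpolation of the envelope between the bracketing peaks
  h0 <- swing[j - 1L]; h1 <- swing[j]
  frac <- (h0 - 0.5 * a1) / (h0 - h1)
  t_half <- pk$time[j - 1L] + frac * (pk$time[j] - pk$time[j - 1L])
  (t_half - times[1L]) / period
}

#' Export an ensemble run
#'
#' Writes per-cell traces and the population mean as long-format CSV
#' (`cell_id`, `time_h`, `y`; the mean uses `cell_id = "mean"`), plus a JSON
#' sidecar with the drawn growth rates and the seed.
#'
#' @param result An `ensemble_result`.
#' @param path CSV output file.
#' @param sidecar_path JSON sidecar; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(result, path,
                               sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(result, "ensemble_result"))
  n <- ncol(result$y)
  long <- data.frame(
    cell_id = c(rep(as.character(seq_len(n)), each = length(result$times)),
                rep("mean", length(result$times))),
    time_h = c(rep(result$times, n), result$times),
    y = c(as.vector(result$y), result$population_mean))
  utils::write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(list(alphas = result$alphas,
                            seed = result$spec$seed,
                            n_cells = n,
                            init_mode = result$spec$init_mode),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
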