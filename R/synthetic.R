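#' Measurement model for synthetic fluorescence data
#'
#' Describes how an underlying simulation is observed: sampling interval,
#' additive Gaussian noise (scaled to the signal amplitude), an affine
#' fluorescence calibration, and the observation level. Two presets mirror
#' the study designs the generator emulates:
#' * [plate_reader_model()]: population-mean trace sampled every 2 h;
#' * [mother_machine_model()]: single-cell traces sampled every 0.15 h
#'   (9 min).
#'
#' @param sampling_interval Observation spacing (h), positive.
#' @param noise_sd Noise standard deviation as a fraction of the observed
#'   signal's half peak-to-peak amplitude; default 0.05.
#' @param gain Fluorescence units per K-unit, positive.
#' @param baseline Fluorescence offset.
#' @param level `"population"` (observe the mean) or `"single_cell"`
#'   (observe every cell).
#' @return A `measurement_model` object.
#' @export
measurement_model <- function(sampling_interval, noise_sd = 0.05, gain = 1,
                              baseline = 0,
                              level = c("population", "single_cell")) {
  stopifnot(is.numeric(sampling_interval), sampling_interval > 0,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(gain), gain > 0, is.numeric(baseline))
  level <- match.arg(level)
  structure(list(sampling_interval = sampling_interval, noise_sd = noise_sd,
                 gain = gain, baseline = baseline, level = level),
            class = "measurement_model")
}

#' @rdname measurement_model
#' @export
plate_reader_model <- function(noise_sd = 0.05, gain = 1, baseline = 0) {
  measurement_model(2, noise_sd, gain, baseline, level = "population")
}

#' @rdname measurement_model
#' @export
mother_machine_model <- function(noise_sd = 0.05, gain = 1, baseline = 0) {
  measurement_model(0.15, noise_sd, gain, baseline, level = "single_cell")
}

#' Generate a synthetic fluorescence dataset with known ground truth
#'
#' Simulates an ensemble, subsamples it at the measurement model's sampling
#' interval, and applies gain, baseline and additive Gaussian noise (with
#' standard deviation `noise_sd` times the half peak-to-peak amplitude of the
#' noiseless observed signal). The full noiseless simulation is kept as
#' ground truth, so every estimator in the package can be validated without
#' external data. Fully reproducible from `seed`.
#'
#' @param spec An [ensemble_spec()].
#' @param protocol A light protocol.
#' @param model A [measurement_model()].
#' @param t_end Horizon (h).
#' @param seed RNG seed for the measurement noise; defaults to the spec seed.
#' @param dt Euler step (h).
#' @return A `synthetic_dataset`: list with `times` (observation grid),
#'   `observed` (vector for population level, time x cell matrix for
#'   single-cell level), `truth` (the noiseless `ensemble_result` on a finer
#'   grid), `model`, `spec`, `protocol`, `seed`.
#' @export
#' @examples
#' \donttest{
#' ds <- generate_dataset(ensemble_spec(n_cells = 20, seed = 4),
#'                        light_constant("off"), plate_reader_model(),
#'                        t_end = 100)
#' }
generate_dataset <- function(spec, protocol, model, t_end,
                             seed = spec$seed, dt = 0.005) {
  stopifnot(inherits(spec, "ensemble_spec"),
            inherits(model, "measurement_model"))
  record_dt <- 0.05
  if (abs(model$sampling_interval / record_dt -
          round(model$sampling_interval / record_dt)) > 1e-9)
    record_dt <- model$sampling_interval
  truth <- simulate_ensemble(spec, protocol, t_end = t_end, dt = dt,
                             record_dt = record_dt)
  stride <- as.integer(round(model$sampling_interval / record_dt))
  idx <- seq(1L, length(truth$times), by = stride)
  times <- truth$times[idx]
  clean <- if (model$level == "population")
    truth$population_mean[idx] else truth$y[idx, , drop = FALSE]
  amp <- (max(clean) - min(clean)) / 2
  observed <- with_seed(seed, {
    noise <- stats::rnorm(length(clean), 0, model$noise_sd * amp * model$gain)
    model$gain * clean + model$baseline + noise
  })
  if (is.matrix(clean)) observed <- matrix(observed, nrow = nrow(clean))
  structure(list(times = times, observed = observed, truth = truth,
                 model = model, spec = spec, protocol = protocol,
                 seed = seed),
            class = "synthetic_dataset")
}

# period estimate from one observed trace: mean peak spacing, first peak
# discarded when enough peaks are available
period_from_signal <- function(signal, times, min_separation = 5,
                               min_prominence = 0.25) {
  pk <- detect_peaks(signal - mean(signal), times,
                     min_separation = min_separation,
                     min_prominence = min_prominence)
  if (nrow(pk) < 4L)
    stop("fewer than 4 peaks at the observation rate; period not recoverable")
  mean(diff(pk$time[-1L]))
}

#' Recover the oscillation period from a synthetic dataset
#'
#' Runs the package's peak-based period estimator on the noisy observed data
#' and reports it against the ground-truth period computed with the same
#' estimator on the noiseless, finely sampled truth. For single-cell data
#' both are per-cell estimates averaged across cells (each cell has its own
#' growth rate, hence its own period).
#'
#' @param dataset A [generate_dataset()] result.
#' @param min_separation Minimum peak spacing (h) for peak detection.
#' @return List with `estimate` (h), `truth` (h) and `rel_error`.
#' @export
recover_period <- function(dataset, min_separation = 5) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  tt <- dataset$truth
  if (dataset$model$level == "population") {
    est <- period_from_signal(dataset$observed, dataset$times,
                              min_separation = min_separation)
    tru <- period_from_signal(tt$population_mean, tt$times,
                              min_separation = min_separation)
  } else {
    n <- ncol(dataset$observed)
    est <- mean(vapply(seq_len(n), function(i)
      period_from_signal(dataset$observed[, i], dataset$times,
                         min_separation = min_separation), numeric(1)))
    tru <- mean(vapply(seq_len(n), function(i)
      period_from_signal(tt$y[, i], tt$times,
                         min_separation = min_separation), numeric(1)))
  }
  list(estimate = est, truth = tru, rel_error = abs(est - tru) / tru)
}

#' Export a synthetic dataset
#'
#' Long-format CSV (`time_h`, `cell_id` — `"mean"` for population-level
#' data —, `fluorescence`) plus a JSON ground-truth sidecar with the drawn
#' growth rates, seed and measurement model.
#'
#' @param dataset A [generate_dataset()] result.
#' @param path CSV output file.
#' @param sidecar_path JSON sidecar; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path,
                              sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (is.matrix(dataset$observed)) {
    n <- ncol(dataset$observed)
    df <- data.frame(
      time_h = rep(dataset$times, n),
      cell_id = rep(as.character(seq_len(n)), each = length(dataset$times)),
      fluorescence = as.vector(dataset$observed))
  } else {
    df <- data.frame(time_h = dataset$times, cell_id = "mean",
                     fluorescence = dataset$observed)
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(alphas = dataset$truth$alphas,
                            seed = dataset$seed,
                            model = unclass(dataset$model),
                            init_mode = dataset$spec$init_mode),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synthetic dataset CSV
#'
#' Reads the long-format dialect written by [write_dataset_csv()].
#'
#' @param path CSV file.
#' @return Data frame with columns `time_h`, `cell_id`, `fluorescence`.
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(cell_id = "character"))
  stopifnot(all(c("time_h", "cell_id", "fluorescence") %in% names(df)))
  df
}
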