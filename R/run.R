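#' Run a figure-level computation end to end
#'
#' Programmatic entry point behind the `inst/cli/optorep.R` command-line
#' script: each subcommand reproduces one complete analysis from a config
#' list and writes its artifacts plus a `manifest.json` (config, seed,
#' package version) to `out_dir`, so any run can be reproduced bit-for-bit
#' from its manifest.
#'
#' Subcommands and their config blocks (unknown keys are rejected; all blocks
#' optional unless noted):
#' * `"simulate"`: one cell under any protocol -> `trajectory.csv`. Blocks
#'   `model` (alpha, beta, n, beta_prime_on, beta_prime_off), `protocol`
#'   (kind = constant/pulse/train plus its fields), `t_end` (required).
#' * `"ensemble"`: population run -> `ensemble.csv` + sidecar. Blocks
#'   `model`, `protocol`, `ensemble` (n_cells, alpha_mean, alpha_sd,
#'   init_mode), `t_end`.
#' * `"prc"`: phase response curve -> `prc.csv` + JSON header. Block `prc`
#'   (tau, beta_prime, n_points).
#' * `"entrain"`: pulse-train run with measured and circle-map-predicted
#'   entrained phase -> `entrain.json`. Blocks `model`, `entrain`
#'   (tl_over_t0, tau, beta_prime, n_periods).
#' * `"tongues"`: frequency-ratio scan -> `tongues.csv` + config sidecar.
#'   Blocks `model`, `scan` (f_grid, beta_prime_grid, tau, n_periods).
#' * `"synth"`: synthetic dataset -> `dataset.csv` + ground-truth sidecar.
#'   Blocks `model`, `protocol`, `ensemble`, `measurement`
#'   (preset = plate_reader/mother_machine, noise_sd, gain, baseline),
#'   `t_end`.
#' * `"validate"`: runs the integrator self-checks (closed-form x'
#'   relaxation, green-collapse, time-rescaling) -> `validate.json`.
#'
#' @param command Subcommand name.
#' @param config Nested configuration list (for the script, parsed from a
#'   JSON file).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed applied to all stochastic stages.
#' @param dt Euler step (h).
#' @return Invisibly, a character vector of files written. Partial outputs
#'   are removed when a stage fails.
#' @export
run_command <- function(command, config = list(), out_dir, seed = 1,
                        dt = 0.005) {
  commands <- c("simulate", "ensemble", "prc", "entrain", "tongues",
                "synth", "validate")
  if (!is.character(command) || length(command) != 1L ||
      !command %in% commands)
    stop("unknown subcommand; expected one of: ",
         paste(commands, collapse = ", "))
  if (!is.list(config)) stop("config must be a list")
  known <- c("model", "protocol", "ensemble", "measurement", "scan",
             "prc", "entrain", "t_end")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  params <- config_params(config$model)
  switch(command,
    simulate = {
      t_end <- config_required(config, "t_end")
      protocol <- config_protocol(config$protocol)
      tr <- simulate_opto(params, protocol, t_end = t_end, dt = dt,
                          record_dt = max(dt, 0.05))
      write_trajectory_csv(tr, note(file.path(out_dir, "trajectory.csv")))
    },
    ensemble = {
      t_end <- config_required(config, "t_end")
      spec <- config_spec(config$ensemble, params, seed)
      res <- simulate_ensemble(spec, config_protocol(config$protocol),
                               t_end = t_end, dt = dt)
      write_ensemble_csv(res, note(file.path(out_dir, "ensemble.csv")),
                         note(file.path(out_dir, "ensemble.csv.json")))
    },
    prc = {
      cfg <- config_block(config$prc, list(tau = 2, beta_prime = 80,
                                           n_points = 64))
      prc <- compute_prc(params, tau = cfg$tau,
                         beta_prime_pulse = cfg$beta_prime,
                         n_points = cfg$n_points, dt = dt)
      write_prc_csv(prc, note(file.path(out_dir, "prc.csv")),
                    note(file.path(out_dir, "prc.csv.json")))
    },
    entrain = {
      cfg <- config_block(config$entrain,
                          list(tl_over_t0 = 1, tau = 2, beta_prime = 80,
                               n_periods = 18, n_points = 32))
      prc <- compute_prc(params, tau = cfg$tau,
                         beta_prime_pulse = cfg$beta_prime,
                         n_points = cfg$n_points, dt = dt)
      TL <- cfg$tl_over_t0 * prc$T0
      predicted <- tryCatch(entrained_phase(prc, TL),
                            optorep_outside_locking_range = function(e) NULL)
      forced <- opto_params(params$alpha, params$beta, params$n,
                            beta_prime_on = cfg$beta_prime,
                            beta_prime_off = params$beta_prime_off)
      tr <- simulate_opto(forced,
                          light_pulse_train(0, TL, cfg$tau, cfg$n_periods),
                          t_end = cfg$n_periods * TL, dt = dt,
                          record_dt = max(dt, 0.01))
      measured <- measured_entrained_phase(tr, prc$T0)
      report <- list(
        T0 = prc$T0, TL = TL,
        predicted = if (is.null(predicted)) NULL else
          list(phi_star = predicted$phi_star, slope = predicted$slope,
               stable = predicted$stable),
        outside_locking_range = is.null(predicted),
        measured = list(phi_star = measured$phi_star, sd = measured$sd,
                        entrained = measured$entrained,
                        n_pulses = measured$n_pulses))
      jsonlite::write_json(report, note(file.path(out_dir, "entrain.json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
    },
    tongues = {
      cfg <- config_block(config$scan,
                          list(f_grid = seq(0.4, 2.4, by = 0.1),
                               beta_prime_grid = c(0, 10, 20, 40, 80, 120),
                               tau = 2, n_periods = 40))
      surf <- tongue_surface(params, f_grid = cfg$f_grid,
                             beta_prime_grid = cfg$beta_prime_grid,
                             tau = cfg$tau, n_periods = cfg$n_periods,
                             dt = dt)
      write_tongue_csv(surf, note(file.path(out_dir, "tongues.csv")),
                       note(file.path(out_dir, "tongues.csv.json")))
    },
    synth = {
      t_end <- config_required(config, "t_end")
      spec <- config_spec(config$ensemble, params, seed)
      mcfg <- config_block(config$measurement,
                           list(preset = "plate_reader", noise_sd = 0.05,
                                gain = 1, baseline = 0))
      model <- switch(mcfg$preset,
        plate_reader = plate_reader_model(mcfg$noise_sd, mcfg$gain,
                                          mcfg$baseline),
        mother_machine = mother_machine_model(mcfg$noise_sd, mcfg$gain,
                                              mcfg$baseline),
        stop("measurement preset must be plate_reader or mother_machine"))
      ds <- generate_dataset(spec, config_protocol(config$protocol), model,
                             t_end = t_end, seed = seed, dt = dt)
      write_dataset_csv(ds, note(file.path(out_dir, "dataset.csv")),
                        note(file.path(out_dir, "dataset.csv.json")))
    },
    validate = {
      checks <- run_validation_suite(params, dt)
      jsonlite::write_json(checks, note(file.path(out_dir, "validate.json")),
                           auto_unbox = TRUE, digits = NA)
      if (!all(vapply(checks, `[[`, logical(1), "pass")))
        stop("validation suite failed; see validate.json")
    })

  manifest <- list(command = command, config = config, seed = seed, dt = dt,
                   package_version = as.character(
                     utils::packageVersion("optorep")))
  jsonlite::write_json(manifest, note(file.path(out_dir, "manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  invisible(written)
}

config_required <- function(config, key) {
  if (is.null(config[[key]]))
    stop("missing required config key: ", key)
  config[[key]]
}

config_block <- function(block, defaults) {
  if (is.null(block)) return(defaults)
  bad <- setdiff(names(block), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, block)
}

config_spec <- function(block, params, seed) {
  cfg <- config_block(block, list(n_cells = 200, alpha_mean = 0.75,
                                  alpha_sd = 0.034,
                                  init_mode = "synchronized_green"))
  ensemble_spec(n_cells = cfg$n_cells, alpha_mean = cfg$alpha_mean,
                alpha_sd = cfg$alpha_sd, seed = seed, params = params,
                init_mode = cfg$init_mode)
}

config_params <- function(block) {
  cfg <- config_block(block, list(alpha = 0.75, beta = 300, n = 3,
                                  beta_prime_on = 80, beta_prime_off = 0))
  opto_params(cfg$alpha, cfg$beta, cfg$n, cfg$beta_prime_on,
              cfg$beta_prime_off)
}

config_protocol <- function(block) {
  if (is.null(block)) return(light_constant("off"))
  kind <- if (is.null(block$kind)) stop("protocol block needs a 'kind'")
          else block$kind
  switch(kind,
    constant = light_constant(config_block(block, list(
      kind = kind, level = "off"))$level),
    pulse = {
      cfg <- config_block(block, list(kind = kind, t_start = 0, duration = 2))
      light_pulse(cfg$t_start, cfg$duration)
    },
    train = {
      cfg <- config_block(block, list(kind = kind, t_start = 0, period = 18,
                                      duration = 2, count = 10))
      light_pulse_train(cfg$t_start, cfg$period, cfg$duration, cfg$count)
    },
    stop("protocol kind must be constant, pulse or train"))
}

run_validation_suite <- function(params, dt) {
  # closed-form x' relaxation under constant green
  tr <- simulate_opto(params, light_constant("on"), t_end = 20, dt = 0.001,
                      record_dt = 0.01)
  defect <- relaxation_check(tr)
  # collapse to the green fixed point
  fp <- green_fixed_point(params)
  tr2 <- simulate_opto(params, light_constant("on"),
                       initial = c(100, 50, 200, 0),
                       t_end = 16 / params$alpha, dt = dt, record_dt = 0.05)
  gap <- max(abs(tr2$states[nrow(tr2$states), ] - fp))
  # exact time-rescaling symmetry with a power-of-two factor
  a <- simulate_opto(params, t_end = 40, dt = dt, record_dt = 10 * dt)
  p2 <- opto_params(2 * params$alpha, 2 * params$beta, params$n,
                    beta_prime_on = 2 * params$beta_prime_on,
                    beta_prime_off = 2 * params$beta_prime_off)
  b <- simulate_opto(p2, t_end = 20, dt = dt / 2, record_dt = 5 * dt)
  resc <- max(abs(a$states - b$states))
  list(
    relaxation_defect = list(value = defect, pass = defect < 0.1),
    green_collapse = list(value = gap,
                          pass = gap < 0.01 * params$beta / params$alpha),
    time_rescaling = list(value = resc, pass = resc == 0))
}
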