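#' Piecewise-constant light protocols
#'
#' A light protocol maps time to an illumination level, `"on"` (green light,
#' production rate `beta_prime_on`) or `"off"` (red light, `beta_prime_off`).
#' It is stored as an ordered set of non-overlapping "on" segments over
#' half-open intervals `[start, end)`; any time not covered is "off".
#'
#' * `light_constant("on")` / `light_constant("off")`: steady illumination.
#' * `light_pulse(t_start, duration)`: a single green pulse.
#' * `light_pulse_train(t_start, period, duration, count)`: `count` pulses of
#'   length `duration` starting at `t_start, t_start + period, ...`
#'   (`duration < period` required).
#'
#' @param level `"on"` or `"off"`.
#' @param t_start Start time of the (first) pulse (h).
#' @param duration Pulse duration tau (h), positive.
#' @param period Forcing period T_L (h), must exceed `duration`.
#' @param count Number of pulses (>= 1).
#' @return An object of class `light_protocol`.
#' @export
#' @examples
#' light_pulse_train(t_start = 0, period = 18, duration = 2, count = 5)
light_constant <- function(level = c("off", "on")) {
  level <- match.arg(level)
  if (level == "on")
    new_light_protocol(0, Inf, "constant on")
  else
    new_light_protocol(numeric(0), numeric(0), "constant off")
}

#' @rdname light_constant
#' @export
light_pulse <- function(t_start, duration) {
  stopifnot(is.numeric(t_start), length(t_start) == 1L, t_start >= 0,
            is.numeric(duration), length(duration) == 1L, duration > 0)
  new_light_protocol(t_start, t_start + duration, "single pulse")
}

#' @rdname light_constant
#' @export
light_pulse_train <- function(t_start, period, duration, count) {
  stopifnot(is.numeric(t_start), length(t_start) == 1L, t_start >= 0,
            is.numeric(period), length(period) == 1L, period > 0,
            is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(count), length(count) == 1L, count >= 1)
  if (duration >= period)
    stop("pulse duration must be shorter than the train period")
  starts <- t_start + period * seq_len(count) - period
  new_light_protocol(starts, starts + duration, "pulse train")
}

new_light_protocol <- function(on_starts, on_ends, kind) {
  stopifnot(length(on_starts) == length(on_ends),
            all(on_ends > on_starts))
  o <- order(on_starts)
  on_starts <- on_starts[o]
  on_ends <- on_ends[o]
  if (length(on_starts) > 1L &&
      any(on_starts[-1L] < on_ends[-length(on_ends)]))
    stop("light segments must not overlap")
  structure(list(on_starts = on_starts, on_ends = on_ends, kind = kind),
            class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  cat("Light protocol (", x$kind, "): ", length(x$on_starts),
      " green segment(s)\n", sep = "")
  invisible(x)
}

#' Green-light segments of a protocol
#'
#' @param protocol A `light_protocol`.
#' @return A data frame with columns `start`, `end`, `level` (always `"on"`);
#'   times outside these half-open intervals are `"off"`.
#' @export
protocol_segments <- function(protocol) {
  stopifnot(inherits(protocol, "light_protocol"))
  data.frame(start = protocol$on_starts, end = protocol$on_ends,
             level = rep("on", length(protocol$on_starts)))
}

#' Translate a protocol in time
#'
#' @param protocol A `light_protocol`.
#' @param by Time shift (h); segments move to later times for positive `by`.
#'   Segments ending at or before t = 0 after the shift are dropped; a segment
#'   straddling 0 is clipped.
#' @return A shifted `light_protocol`.
#' @export
shift_protocol <- function(protocol, by) {
  stopifnot(inherits(protocol, "light_protocol"),
            is.numeric(by), length(by) == 1L, is.finite(by))
  s <- protocol$on_starts + by
  e <- protocol$on_ends + by
  keep <- e > 0
  s <- pmax(s[keep], 0)
  e <- e[keep]
  new_light_protocol(s, e, protocol$kind)
}

# TRUE where t falls inside an "on" segment (vectorized, half-open intervals)
protocol_is_on <- function(protocol, t) {
  if (length(protocol$on_starts) == 0L) return(rep(FALSE, length(t)))
  idx <- findInterval(t, protocol$on_starts)
  on <- idx >= 1L
  on[on] <- t[on] < protocol$on_ends[idx[on]]
  on
}

#' Light-driven production rate at given times
#'
#' Maps a protocol and parameter set to the instantaneous production rate
#' beta'(t) of the light-inducible LacI: `beta_prime_on` inside an "on"
#' segment, `beta_prime_off` otherwise (half-open segment boundaries).
#'
#' @param protocol A `light_protocol`.
#' @param t Time or vector of times (h), non-negative.
#' @param params An [opto_params()].
#' @return Numeric vector of rates (1/h), one per element of `t`.
#' @export
#' @examples
#' p <- opto_params()
#' evaluate_protocol(light_pulse(10, 2), c(9.9, 10, 11.9, 12), p)
evaluate_protocol <- function(protocol, t, params) {
  stopifnot(inherits(protocol, "light_protocol"),
            inherits(params, "opto_params"),
            is.numeric(t), all(t >= 0))
  ifelse(protocol_is_on(protocol, t),
         params$beta_prime_on, params$beta_prime_off)
}

#' Read and write light protocols as JSON
#'
#' Protocols serialize as a JSON list of "on" segments (`start`, `end`,
#' `level`), with times in hours; `end` may be the string `"Inf"` for a
#' constant-on protocol.
#'
#' @param protocol A `light_protocol`.
#' @param path File path.
#' @return `read_protocol_json()` returns the protocol;
#'   `write_protocol_json()` returns `path` invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  seg <- protocol_segments(protocol)
  seg$end <- ifelse(is.finite(seg$end), seg$end, "Inf")
  jsonlite::write_json(list(kind = protocol$kind, segments = seg), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- obj$segments
  if (is.null(seg) || NROW(seg) == 0L)
    return(light_constant("off"))
  ends <- suppressWarnings(as.numeric(seg$end))
  ends[seg$end == "Inf"] <- Inf
  new_light_protocol(as.numeric(seg$start), ends,
                     if (is.null(obj$kind)) "custom" else obj$kind)
}
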