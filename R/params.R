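#' Kinetic parameters of the protein-only repressilator
#'
#' The three-gene ring model tracks repressor concentrations in units of the
#' dissociation constant K (the concentration that half-represses a promoter).
#' `alpha` is the effective protein decay rate set by dilution through cell
#' growth, `beta` the maximal production rate (K-units per hour), and `n` the
#' Hill cooperativity of repression.
#'
#' Defaults give a free-running period of about 17.5 h, the regime the model
#' is calibrated to.
#'
#' @param alpha Decay/dilution rate (1/h), must be positive.
#' @param beta Maximal production rate (1/h), must be positive.
#' @param n Hill coefficient (dimensionless), must be >= 1.
#' @return An object of class `repressilator_params`.
#' @export
#' @examples
#' repressilator_params()
#' repressilator_params(alpha = 0.5, beta = 150, n = 5)
repressilator_params <- function(alpha = 0.75, beta = 300, n = 3) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta <= 0) stop("beta must be > 0")
  if (n < 1) stop("n must be >= 1")
  structure(list(alpha = alpha, beta = beta, n = n),
            class = "repressilator_params")
}

#' Parameters of the optorepressilator
#'
#' Extends [repressilator_params()] with the light-driven production rate of
#' the extra LacI copy: `beta_prime_on` applies under green light and
#' `beta_prime_off` under red light. Red light is modelled as fully silent
#' (`beta_prime_off = 0`) by default; promoter leakage is not modelled.
#'
#' @param alpha,beta,n Ring parameters, as in [repressilator_params()].
#'   Ignored when `base` is supplied.
#' @param beta_prime_on Light-induced production rate under green light (1/h).
#' @param beta_prime_off Production rate under red light (1/h), default 0.
#' @param base Optional `repressilator_params` supplying `alpha`, `beta`, `n`.
#' @return An object of class `opto_params` with fields `alpha`, `beta`, `n`,
#'   `beta_prime_on`, `beta_prime_off`.
#' @export
#' @examples
#' opto_params()                      # defaults: alpha 0.75, beta 300, n 3, beta' 80
#' opto_params(base = repressilator_params(n = 5), beta_prime_on = 40)
opto_params <- function(alpha = 0.75, beta = 300, n = 3,
                        beta_prime_on = 80, beta_prime_off = 0,
                        base = NULL) {
  if (!is.null(base)) {
    stopifnot(inherits(base, "repressilator_params"))
    alpha <- base$alpha; beta <- base$beta; n <- base$n
  }
  ring <- repressilator_params(alpha, beta, n)
  stopifnot(is.numeric(beta_prime_on), length(beta_prime_on) == 1L,
            is.finite(beta_prime_on),
            is.numeric(beta_prime_off), length(beta_prime_off) == 1L,
            is.finite(beta_prime_off))
  if (beta_prime_on < 0) stop("beta_prime_on must be >= 0")
  if (beta_prime_off < 0) stop("beta_prime_off must be >= 0")
  if (beta_prime_off > beta_prime_on)
    stop("beta_prime_off must not exceed beta_prime_on")
  structure(c(unclass(ring),
              list(beta_prime_on = beta_prime_on,
                   beta_prime_off = beta_prime_off)),
            class = "opto_params")
}

#' @export
print.repressilator_params <- function(x, ...) {
  cat("Repressilator parameters: alpha =", x$alpha, "1/h, beta =", x$beta,
      "1/h, n =", x$n, "\n")
  invisible(x)
}

#' @export
print.opto_params <- function(x, ...) {
  cat("Optorepressilator parameters: alpha =", x$alpha, "1/h, beta =", x$beta,
      "1/h, n =", x$n, "\n  beta' on =", x$beta_prime_on,
      "1/h, beta' off =", x$beta_prime_off, "1/h\n")
  invisible(x)
}

# coerce to opto_params (ring-only params get beta' = 0, i.e. permanent red)
as_opto_params <- function(params) {
  if (inherits(params, "opto_params")) return(params)
  if (inherits(params, "repressilator_params"))
    return(opto_params(base = params, beta_prime_on = 0, beta_prime_off = 0))
  stop("expected repressilator_params or opto_params")
}

#' Read and write parameter sets as flat JSON
#'
#' Parameter sets serialize to a flat key-value JSON file with keys `alpha`,
#' `beta`, `n`, `beta_prime_on`, `beta_prime_off`. Files missing the
#' `beta_prime_*` keys are read as plain repressilator parameters.
#'
#' @param params A `repressilator_params` or `opto_params` object.
#' @param path File path.
#' @return `read_params_json()` returns the parameter object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, c("repressilator_params", "opto_params")))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("alpha", "beta", "n") %in% names(vals)))
    stop("parameter file must contain keys alpha, beta, n")
  if ("beta_prime_on" %in% names(vals)) {
    opto_params(alpha = vals$alpha, beta = vals$beta, n = vals$n,
                beta_prime_on = vals$beta_prime_on,
                beta_prime_off = if (is.null(vals$beta_prime_off)) 0
                                 else vals$beta_prime_off)
  } else {
    repressilator_params(alpha = vals$alpha, beta = vals$beta, n = vals$n)
  }
}
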