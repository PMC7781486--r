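# The 11 rate/expression/dilution parameters of the simplified BLADE model.
#
# Naming: k1c/k2c and k1f/k2f are the first and second excision rates of Cre
# and Flp; k_1c, k_2c, k_1f, k_2f their reverse (re-insertion) counterparts;
# alpha the shared constitutive recombinase expression rate; beta_p protein
# degradation; delta_D dilution of intact platform DNA (acts on Z00 only);
# delta_X dilution of excised circles.

blade_param_names <- function() {
  c("k1c", "k2c", "k1f", "k2f", "k_1c", "k_2c", "k_1f", "k_2f",
    "alpha", "beta_p", "delta_D", "delta_X")
}

#' Simplified-model parameter set
#'
#' Returns the calibrated parameter set of the simplified BLADE excision
#' model as a named list, optionally overriding individual values. Defaults
#' are the genetic-algorithm optimum: forward excision rates
#' `k1c = k2c = 4.20e-5`, `k1f = k2f = 2.64e-5` (per molecule per second),
#' all reverse insertion rates `8.15e-5`, constitutive recombinase expression
#' `alpha = 0.629` (molecules per second), protein degradation
#' `beta_p = 1.69e-3`, DNA dilution `delta_D = 1.66e-4` and excised-circle
#' dilution `delta_X = 3.31e-3` (per second).
#'
#' @param ... Named overrides of individual parameters.
#' @return Named list of 12 strictly positive numerics (the 8 forward/reverse
#'   rates, `alpha`, `beta_p`, `delta_D`, `delta_X`).
#' @examples
#' blade_params()
#' blade_params(alpha = 0.1)
#' @export
blade_params <- function(...) {
  p <- list(
    k1c = 4.20e-5, k2c = 4.20e-5,
    k1f = 2.64e-5, k2f = 2.64e-5,
    k_1c = 8.15e-5, k_2c = 8.15e-5,
    k_1f = 8.15e-5, k_2f = 8.15e-5,
    alpha = 6.29e-1,
    beta_p = 1.69e-3,
    delta_D = 1.66e-4,
    delta_X = 3.31e-3
  )
  over <- list(...)
  if (length(over) > 0L) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) > 0L) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                               call. = FALSE)
    p <- modifyList(p, over)
  }
  validate_params(p)
}

validate_params <- function(p) {
  need <- blade_param_names()
  missing_p <- setdiff(need, names(p))
  if (length(missing_p) > 0L) {
    stop("parameter set lacks: ", paste(missing_p, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(p[need])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all model parameters must be strictly positive and finite", call. = FALSE)
  }
  p[need]
}
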