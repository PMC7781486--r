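# Deterministic mean-field model: mass-action ODEs of the simplified
# 10-species BLADE network. Serves as the oracle the stochastic engine is
# checked against at large copy number.

#' Right-hand side of the simplified-model ODE system
#'
#' Time derivatives of the ten species under mass-action kinetics. The
#' recombinase expression rate `alpha` is set to 0 for any recombinase absent
#' from the input condition. Platform DNA dilution (`delta_D`) acts on Z00
#' only, so the total DNA derivative is exactly `-delta_D * Z00` — converted
#' addresses are not diluted, a deliberate asymmetry of the simplified model.
#'
#' @param state Named numeric vector over [blade_species()].
#' @param params A [blade_params()] list.
#' @param cre_on,flp_on Input condition.
#' @return Named numeric vector of the ten derivatives.
#' @examples
#' s <- setNames(numeric(10), blade_species())
#' ode_rhs(s, blade_params(), cre_on = TRUE, flp_on = TRUE)
#' @export
ode_rhs <- function(state, params, cre_on = TRUE, flp_on = TRUE) {
  p <- validate_params(params)
  s <- as.list(state[blade_species()])
  aC <- if (cre_on) p$alpha else 0
  aF <- if (flp_on) p$alpha else 0
  with(c(s, p), {
    d <- c(
      C = aC - beta_p * C - k1c * Z00 * C + k_1c * Z10 * Z10X -
        k2c * Z01 * C + k_2c * Z11 * Z11Xc,
      F = aF - beta_p * F - k1f * Z00 * F + k_1f * Z01 * Z01X -
        k2f * Z10 * F + k_2f * Z11 * Z11Xf,
      Z00 = k_1c * Z10 * Z10X - k1c * Z00 * C + k_1f * Z01 * Z01X -
        k1f * Z00 * F - delta_D * Z00,
      Z10 = k1c * Z00 * C - k_1c * Z10 * Z10X - k2f * Z10 * F +
        k_2f * Z11 * Z11Xf,
      Z10X = k1c * Z00 * C - k_1c * Z10 * Z10X - delta_X * Z10X,
      Z01 = k1f * Z00 * F - k_1f * Z01 * Z01X - k2c * Z01 * C +
        k_2c * Z11 * Z11Xc,
      Z01X = k1f * Z00 * F - k_1f * Z01 * Z01X - delta_X * Z01X,
      Z11 = k2f * Z10 * F - k_2f * Z11 * Z11Xf + k2c * Z01 * C -
        k_2c * Z11 * Z11Xc,
      Z11Xc = k2c * Z01 * C - k_2c * Z11 * Z11Xc - delta_X * Z11Xc,
      Z11Xf = k2f * Z10 * F - k_2f * Z11 * Z11Xf - delta_X * Z11Xf
    )
    d
  })
}

#' Integrate the simplified model
#'
#' Stiff-capable integration (`deSolve::ode`, lsoda) of the mass-action
#' system from a given initial state. Tiny negative excursions from the
#' solver are clipped to 0 with a warning.
#'
#' @param initial Named numeric vector of initial concentrations; defaults to
#'   Z00 = 1000 and all else 0, matching the stochastic initial condition.
#' @param params A [blade_params()] list.
#' @param cre_on,flp_on Input condition.
#' @param horizon End time in seconds. Default 1.728e5 s (48 h), the
#'   experimental readout time.
#' @param times Optional explicit output times (overrides `horizon`).
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-8).
#' @return A tibble with `time` and one column per species, of class
#'   `blade_ode` (also a tibble).
#' @examples
#' sol <- blade_ode(params = blade_params(), horizon = 1000)
#' tail(sol, 1)
#' @export
blade_ode <- function(initial = NULL, params = blade_params(),
                      cre_on = TRUE, flp_on = TRUE,
                      horizon = 1.728e5, times = NULL,
                      rtol = 1e-8, atol = 1e-8) {
  sp <- blade_species()
  y0 <- setNames(numeric(length(sp)), sp)
  y0[["Z00"]] <- 1000
  if (!is.null(initial)) {
    if (is.null(names(initial))) {
      if (length(initial) != length(sp)) {
        stop("unnamed initial state must cover all ", length(sp), " species",
             call. = FALSE)
      }
      y0[] <- initial
    } else {
      bad <- setdiff(names(initial), sp)
      if (length(bad) > 0L) stop("unknown species: ", paste(bad, collapse = ", "),
                                 call. = FALSE)
      y0[names(initial)] <- initial
    }
  }
  if (is.null(times)) {
    if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
    times <- seq(0, horizon, length.out = 201)
  }
  deriv <- function(t, y, parms) list(ode_rhs(y, params, cre_on, flp_on))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed: ", paste(capture_diagnostics(sol), collapse = "; "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  spcols <- out[sp]
  if (any(spcols < 0)) {
    minval <- min(as.matrix(spcols))
    if (minval < -1e-6) {
      warning("negative concentrations clipped to 0 (min ", signif(minval, 3), ")")
    }
    out[sp] <- lapply(spcols, function(col) pmax(col, 0))
  }
  class(out) <- c("blade_ode", class(out))
  out
}

capture_diagnostics <- function(sol) {
  c(paste("istate =", attr(sol, "istate")[1]))
}

#' Address occupancy fractions along an ODE solution
#'
#' @param sol A `blade_ode` solution tibble.
#' @return The solution with added columns `f00`, `f10`, `f01`, `f11`, the
#'   four address concentrations normalised by their sum at each time.
#' @export
ode_occupancy <- function(sol) {
  tot <- sol$Z00 + sol$Z10 + sol$Z01 + sol$Z11
  dplyr::mutate(sol,
    f00 = .data$Z00 / tot, f10 = .data$Z10 / tot,
    f01 = .data$Z01 / tot, f11 = .data$Z11 / tot)
}
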