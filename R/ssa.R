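# Gillespie direct-method simulation of the BLADE network.

#' SSA run configuration
#'
#' Settings of a single stochastic simulation: the initial molecule counts
#' (all species 0 except 1000 copies of the platform DNA at Z00), the event
#' cap (10000 reactions) that is the primary stop criterion, and an optional
#' wall-clock-in-model-time guard `max_time` (disabled by default).
#'
#' @param initial_state Named integer vector over [blade_species()]; defaults
#'   to Z00 = 1000 and all other species 0.
#' @param max_reactions Maximum number of reaction events (default 10000).
#' @param max_time Optional cap on simulated time in seconds (default `Inf`).
#' @return A list of class `ssa_config`.
#' @export
ssa_config <- function(initial_state = NULL, max_reactions = 10000, max_time = Inf) {
  sp <- blade_species()
  init <- setNames(integer(length(sp)), sp)
  init[["Z00"]] <- 1000L
  if (!is.null(initial_state)) {
    bad <- setdiff(names(initial_state), sp)
    if (length(bad) > 0L) stop("unknown species: ", paste(bad, collapse = ", "),
                               call. = FALSE)
    init[names(initial_state)] <- as.integer(initial_state)
  }
  if (any(init < 0L)) stop("initial counts must be non-negative", call. = FALSE)
  if (max_reactions < 1) stop("max_reactions must be >= 1", call. = FALSE)
  structure(list(initial_state = init, max_reactions = as.integer(max_reactions),
                 max_time = max_time),
            class = "ssa_config")
}

#' Run one Gillespie simulation
#'
#' Simulates the network with the direct method: at each step an exponential
#' waiting time is drawn from the total propensity, a reaction is selected
#' with probability proportional to its propensity, and its stoichiometry is
#' applied. The run stops at the reaction cap, when the total propensity
#' reaches 0, or at `max_time`. Identical seed and configuration give an
#' identical trajectory.
#'
#' @param network A [blade_network()].
#' @param config An [ssa_config()].
#' @param seed Optional integer seed (applied via `set.seed`, caller RNG
#'   state restored afterwards).
#' @param record Keep the full event-by-event trajectory? Set `FALSE` for
#'   ensemble work where only the endpoint matters.
#' @return An object of class `blade_trajectory`: a list with `species`,
#'   `final_state`, `final_time`, `n_events`, `stopped` (one of
#'   `"max_reactions"`, `"exhausted"`, `"max_time"`), the last state with a
#'   non-empty DNA pool, and (when recorded) `times`, `reaction` indices and
#'   the `states` matrix after each event.
#' @examples
#' net <- blade_network(blade_params(), cre_on = TRUE, flp_on = TRUE)
#' tr <- gillespie_run(net, ssa_config(max_reactions = 200), seed = 1)
#' tr$n_events
#' @export
gillespie_run <- function(network, config = ssa_config(), seed = NULL, record = TRUE) {
  stopifnot(inherits(network, "blade_network"), inherits(config, "ssa_config"))
  kinds <- match(network$kinds, c("massaction", "linear_guard", "combinatorial")) - 1L
  # the double-monomer guard applies to Cre (species "C")
  guard_sp <- ifelse(kinds > 0L, match("C", network$species) - 1L, -1L)
  guard_min <- ifelse(kinds > 0L, 2L, 0L)
  res <- with_seed(seed, gillespie_cpp(
    network$reactants, network$products, network$rates, kinds,
    as.integer(guard_sp), as.integer(guard_min),
    config$initial_state, config$max_reactions,
    if (is.finite(config$max_time)) config$max_time else Inf,
    address_idx() - 1L, record
  ))
  res$species <- network$species
  names(res$final_state) <- network$species
  names(res$last_nonempty_state) <- network$species
  if (record && res$n_events > 0) colnames(res$states) <- network$species
  res$initial_state <- config$initial_state
  class(res) <- "blade_trajectory"
  res
}

#' @export
print.blade_trajectory <- function(x, ...) {
  cat("<blade_trajectory> ", x$n_events, " events, t = ",
      signif(x$final_time, 5), " s, stopped: ", x$stopped, "\n", sep = "")
  invisible(x)
}

#' Final address occupancy of a trajectory
#'
#' Fractions of the surviving platform DNA in each of the four addresses at
#' the end of a run. Errors when the final DNA pool is empty (all copies
#' diluted away); see [simulate_circuit()] for how ensemble simulation treats
#' that case.
#'
#' @param traj A `blade_trajectory`.
#' @param when `"final"` (strict, default) evaluates the final state;
#'   `"last_nonempty"` evaluates the last event at which the DNA pool was
#'   non-empty — the surviving-fraction limit when the pool later goes
#'   extinct through dilution.
#' @return Named numeric vector `c(f00, f10, f01, f11)` summing to 1.
#' @export
final_occupancy <- function(traj, when = c("final", "last_nonempty")) {
  when <- match.arg(when)
  state <- if (when == "final") traj$final_state else traj$last_nonempty_state
  counts <- state[names(address_idx())]
  tot <- sum(counts)
  if (!is.finite(tot) || tot <= 0) {
    stop("empty DNA population: all platform copies diluted away", call. = FALSE)
  }
  setNames(as.numeric(counts) / tot, c("f00", "f10", "f01", "f11"))
}

#' Tidy a trajectory into a long tibble
#'
#' @param x A `blade_trajectory` recorded with `record = TRUE`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `species`, `count` (the initial
#'   state at time 0 followed by the state after each event).
#' @export
tidy.blade_trajectory <- function(x, ...) {
  if (is.null(x$states)) stop("trajectory was not recorded; rerun with record = TRUE",
                              call. = FALSE)
  wide <- tibble::as_tibble(rbind(
    matrix(as.numeric(x$initial_state), nrow = 1,
           dimnames = list(NULL, x$species)),
    x$states
  ))
  wide$time <- c(0, x$times)
  tidyr::pivot_longer(wide, -"time", names_to = "species", values_to = "count")
}

#' Write a recorded trajectory to delimited text
#'
#' One row per event (plus the initial state): `time` followed by the ten
#' species counts.
#'
#' @param traj A recorded `blade_trajectory`.
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  wide <- tidyr::pivot_wider(tidy.blade_trajectory(traj),
                             names_from = "species", values_from = "count")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Plot a recorded trajectory
#'
#' @param object A recorded `blade_trajectory`.
#' @param ... Unused.
#' @return A ggplot of species counts against time.
#' @export
autoplot.blade_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy.blade_trajectory(object),
                  ggplot2::aes(x = .data$time, y = .data$count,
                               colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "molecules", colour = NULL)
}
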