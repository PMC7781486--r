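# Run configuration: one serialisable object tying together parameters, SSA
# settings, circuit selection and seeding, with a YAML round-trip.

#' Assemble a run configuration
#'
#' @param params A [blade_params()] list.
#' @param ssa An [ssa_config()].
#' @param ensemble_size Replicates per circuit.
#' @param circuits Circuit selection: `"non_trivial"` (default), `"all"`, or
#'   an integer vector of circuit ids.
#' @param seed Master seed.
#' @param out_dir Output directory for CLI runs.
#' @param log_level `"info"` or `"debug"`.
#' @return A list of class `blade_config`.
#' @export
blade_config <- function(params = blade_params(), ssa = ssa_config(),
                         ensemble_size = 100, circuits = "non_trivial",
                         seed = 1L, out_dir = ".", log_level = "info") {
  structure(list(params = params,
                 ssa = list(initial_state = as.list(ssa$initial_state),
                            max_reactions = ssa$max_reactions,
                            max_time = if (is.finite(ssa$max_time)) ssa$max_time else NULL),
                 ensemble_size = ensemble_size,
                 circuits = circuits,
                 seed = as.integer(seed),
                 out_dir = out_dir,
                 log_level = log_level),
            class = "blade_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips [blade_config()] objects through a nested key/value text file;
#' `read_blade_config(write_blade_config(cfg, f))` reproduces `cfg`.
#'
#' @param config A `blade_config`.
#' @param path YAML file path.
#' @return `write_blade_config()` returns `path` invisibly;
#'   `read_blade_config()` returns the `blade_config`.
#' @export
write_blade_config <- function(config, path) {
  stopifnot(inherits(config, "blade_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_blade_config
#' @export
read_blade_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ssa <- ssa_config(
    initial_state = unlist(raw$ssa$initial_state),
    max_reactions = raw$ssa$max_reactions,
    max_time = raw$ssa$max_time %||% Inf
  )
  blade_config(params = validate_params(raw$params), ssa = ssa,
               ensemble_size = raw$ensemble_size, circuits = raw$circuits,
               seed = raw$seed, out_dir = raw$out_dir,
               log_level = raw$log_level)
}

# Resolve the circuit selection of a config into a circuit tibble.
config_circuits <- function(config) {
  sel <- config$circuits
  if (identical(sel, "all")) return(blade_circuits(include_trivial = TRUE))
  if (identical(sel, "non_trivial")) return(blade_circuits())
  all_c <- blade_circuits(include_trivial = TRUE)
  missing_ids <- setdiff(sel, all_c$circuit_id)
  if (length(missing_ids) > 0L) {
    stop("unknown circuit id(s): ", paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  all_c[match(sel, all_c$circuit_id), ]
}
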