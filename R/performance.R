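# Circuit performance from ensembles of stochastic simulations.
#
# One ensemble replicate of a circuit runs the SSA once per input condition
# ((Cre, Flp) = 00, 10, 01, 11), reads off the final address occupancy
# fractions, and maps them to the 8-dimensional "% cells ON" vector: each of
# the 1000 initial DNA copies stands for one cell, and a cell is ON for a
# reporter when the gene at its current address expresses that reporter. The
# replicate's vector is scored with the adapted angular metric against the
# circuit's truth table; scores are computed per replicate and then averaged
# (not computed once on the mean vector), matching how the calibration
# objective aggregates ensembles.

input_conditions <- function() {
  list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
}

# Occupancy of one run with the surviving-fraction fallback: when the DNA
# pool went extinct (possible only through Z00 dilution, and certain for the
# no-input condition, whose sole active reaction is that dilution), the
# occupancy of the last non-empty pool is used and the run flagged.
run_occupancy <- function(traj) {
  extinct <- sum(traj$final_state[names(address_idx())]) <= 0
  occ <- final_occupancy(traj, when = if (extinct) "last_nonempty" else "final")
  list(occupancy = occ, extinct = extinct)
}

# Map address occupancies (one run per input) to the canonical 8-vector.
occupancy_to_vector <- function(occ_by_input, genes) {
  tab <- blade_genes()
  idx <- match(genes, tab$gene)
  gfp <- as.numeric(tab$expresses_gfp[idx])
  mch <- as.numeric(tab$expresses_mcherry[idx])
  out <- numeric(8)
  for (k in 1:4) {
    f <- occ_by_input[[k]]
    out[2 * k - 1] <- 100 * sum(f * gfp)
    out[2 * k] <- 100 * sum(f * mch)
  }
  out
}

#' Simulate an ensemble for one circuit
#'
#' Runs `ensemble_size` stochastic replicates of a circuit (each replicate
#' simulates the four input conditions), converts final address occupancies
#' to "% cells ON" vectors, and scores each replicate with the adapted
#' angular metric. Replicates whose DNA pool went extinct are retained at the
#' last non-empty state (the surviving-fraction limit) and counted in
#' `n_extinct_runs`.
#'
#' @param genes Circuit design: genes at (Z00, Z10, Z01, Z11). Must not be
#'   all-STOP.
#' @param params A [blade_params()] list.
#' @param config An [ssa_config()].
#' @param ensemble_size Number of replicates (default 100).
#' @param seed Master seed; per-(replicate, input) child seeds are derived
#'   deterministically from it.
#' @param circuit_id Optional identifier carried into the result.
#' @param double_cre Passed to [blade_network()].
#' @return An object of class `blade_ensemble`: per-replicate adapted-metric
#'   scores and output vectors, their ensemble mean and standard deviation,
#'   mean occupancies per input condition, and bookkeeping fields.
#' @examples
#' simulate_circuit(c("GFPmCherry", "GFP", "STOP", "GFP"),
#'                  ensemble_size = 2, seed = 1,
#'                  config = ssa_config(max_reactions = 500))
#' @export
simulate_circuit <- function(genes, params = blade_params(), config = ssa_config(),
                             ensemble_size = 100, seed = NULL, circuit_id = NA_integer_,
                             double_cre = "linear") {
  genes <- check_genes(genes)
  v_i <- ideal_vector(genes)
  n <- attr(v_i, "n_fluorescent")
  if (n == 0L) stop("trivial circuit: all-STOP designs cannot be simulated for scoring",
                    call. = FALSE)
  if (ensemble_size < 1) stop("ensemble_size must be >= 1", call. = FALSE)
  seed <- seed %||% sample.int(2^31 - 2, 1)

  nets <- lapply(input_conditions(), function(ic) {
    blade_network(params, cre_on = ic[1], flp_on = ic[2], double_cre = double_cre)
  })

  theta_bar <- numeric(ensemble_size)
  vectors <- matrix(NA_real_, ensemble_size, 8)
  occ_sum <- matrix(0, 4, 4, dimnames = list(
    c("input00", "input10", "input01", "input11"),
    c("f00", "f10", "f01", "f11")))
  n_extinct <- 0L

  for (r in seq_len(ensemble_size)) {
    occ_by_input <- vector("list", 4)
    for (k in 1:4) {
      traj <- gillespie_run(nets[[k]], config,
                            seed = derive_seed(seed, r, k), record = FALSE)
      ro <- run_occupancy(traj)
      if (ro$extinct) n_extinct <- n_extinct + 1L
      occ_by_input[[k]] <- ro$occupancy
      occ_sum[k, ] <- occ_sum[k, ] + ro$occupancy
    }
    v_e <- occupancy_to_vector(occ_by_input, genes)
    vectors[r, ] <- v_e
    theta_bar[r] <- adapted_metric(angular_metric(v_e, v_i), n)
  }

  structure(list(
    circuit_id = circuit_id,
    genes = genes,
    n_fluorescent = n,
    ensemble_size = ensemble_size,
    seed = seed,
    theta_bar = theta_bar,
    mean_theta_bar = mean(theta_bar),
    sd_theta_bar = if (ensemble_size > 1) sd(theta_bar) else 0,
    vectors = vectors,
    mean_vector = colMeans(vectors),
    mean_occupancy = occ_sum / ensemble_size,
    n_extinct_runs = n_extinct
  ), class = "blade_ensemble")
}

#' @export
print.blade_ensemble <- function(x, ...) {
  cat("<blade_ensemble> [", paste(x$genes, collapse = " "), "], ",
      x$ensemble_size, " runs: mean theta_bar = ", signif(x$mean_theta_bar, 4),
      " deg (sd ", signif(x$sd_theta_bar, 4), ")\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_circuit Per-replicate scores as a tibble.
#' @param x,object A `blade_ensemble`.
#' @param ... Unused.
#' @export
tidy.blade_ensemble <- function(x, ...) {
  tibble::tibble(
    circuit_id = x$circuit_id,
    run = seq_len(x$ensemble_size),
    theta_bar_deg = x$theta_bar
  )
}

#' @describeIn simulate_circuit One-row ensemble summary.
#' @export
glance.blade_ensemble <- function(x, ...) {
  tibble::tibble(
    circuit_id = x$circuit_id,
    mean_theta_bar = x$mean_theta_bar,
    sd_theta_bar = x$sd_theta_bar,
    ensemble_size = x$ensemble_size,
    n_extinct_runs = x$n_extinct_runs
  )
}

#' Score a cohort of circuits by ensemble simulation
#'
#' Simulates every circuit in `circuits`, summarises each by its
#' ensemble-mean adapted metric, and partitions the cohort into poor
#' performers (mean score above the cohort mean plus one standard deviation)
#' and the rest. Gene-composition percentages (over 4 addresses x circuits)
#' are reported for each partition.
#'
#' @param circuits Circuit tibble from [blade_circuits()] (all-STOP excluded).
#' @param params,config,ensemble_size,double_cre Passed to
#'   [simulate_circuit()].
#' @param seed Master seed; each circuit receives a derived child seed.
#' @param verbose Log progress every 50 circuits.
#' @return An object of class `blade_cohort`: `scores` tibble (one row per
#'   circuit with `mean_theta_bar`, `sd_theta_bar`, `is_poor`), cohort `mu`
#'   and `sigma` (degrees), and a `composition` tibble of gene percentages
#'   per partition.
#' @export
cohort_scores <- function(circuits, params = blade_params(), config = ssa_config(),
                          ensemble_size = 100, seed = NULL, double_cre = "linear",
                          verbose = FALSE) {
  if (any(circuits$n_fluorescent == 0L)) {
    stop("cohort contains the all-STOP circuit; exclude it (blade_circuits(include_trivial = FALSE))",
         call. = FALSE)
  }
  seed <- seed %||% sample.int(2^31 - 2, 1)
  rows <- purrr::map(seq_len(nrow(circuits)), function(i) {
    if (verbose && i %% 50 == 0) blade_log(sprintf("circuit %d / %d", i, nrow(circuits)))
    ens <- simulate_circuit(circuit_genes(circuits[i, ]), params, config,
                            ensemble_size, seed = derive_seed(seed, 1000L, i),
                            circuit_id = circuits$circuit_id[i],
                            double_cre = double_cre)
    glance.blade_ensemble(ens)
  })
  scores <- dplyr::bind_rows(rows)
  scores <- dplyr::left_join(
    scores,
    dplyr::select(circuits, "circuit_id", dplyr::starts_with("gene_"), "n_fluorescent"),
    by = "circuit_id"
  )
  mu <- mean(scores$mean_theta_bar)
  sigma <- sd(scores$mean_theta_bar)
  scores$is_poor <- scores$mean_theta_bar > mu + sigma

  structure(list(
    scores = scores,
    mu = mu,
    sigma = sigma,
    n_poor = sum(scores$is_poor),
    composition = cohort_composition(scores),
    ensemble_size = ensemble_size,
    seed = seed
  ), class = "blade_cohort")
}

# Gene-composition percentages (over 4 addresses x circuits) per partition.
cohort_composition <- function(scores) {
  long <- tidyr::pivot_longer(
    dplyr::select(scores, "circuit_id", "is_poor", dplyr::starts_with("gene_")),
    dplyr::starts_with("gene_"), names_to = "address", values_to = "gene")
  out <- dplyr::count(long, .data$is_poor, .data$gene)
  out <- dplyr::mutate(dplyr::group_by(out, .data$is_poor),
                       percent = 100 * .data$n / sum(.data$n))
  dplyr::ungroup(dplyr::mutate(out,
    partition = ifelse(.data$is_poor, "poor", "non_poor")))
}

#' @export
print.blade_cohort <- function(x, ...) {
  cat("<blade_cohort> ", nrow(x$scores), " circuits: mu = ", signif(x$mu, 4),
      " deg, sigma = ", signif(x$sigma, 4), " deg, ", x$n_poor,
      " poor performers (theta_bar > mu + sigma)\n", sep = "")
  invisible(x)
}

#' @describeIn cohort_scores Per-circuit scores as a tibble.
#' @param x,object A `blade_cohort`.
#' @param ... Unused.
#' @export
tidy.blade_cohort <- function(x, ...) x$scores

#' @describeIn cohort_scores One-row cohort summary.
#' @export
glance.blade_cohort <- function(x, ...) {
  comp <- x$composition
  stop_poor <- comp$percent[comp$partition == "poor" & comp$gene == "STOP"]
  stop_ok <- comp$percent[comp$partition == "non_poor" & comp$gene == "STOP"]
  tibble::tibble(
    n_circuits = nrow(x$scores),
    mu = x$mu,
    sigma = x$sigma,
    n_poor = x$n_poor,
    poor_stop_percent = if (length(stop_poor)) stop_poor else NA_real_,
    non_poor_stop_percent = if (length(stop_ok)) stop_ok else NA_real_,
    ensemble_size = x$ensemble_size
  )
}

#' Write cohort results to CSV
#'
#' @param cohort A `blade_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort$scores, path)
  invisible(path)
}

#' Recombinase-expression ratio scan
#'
#' Re-simulates circuits with the recombinase expression rate `alpha` scaled
#' by each factor in `scales`, emulating reduced reporter:recombinase
#' transfection ratios (1:1, 1:0.5, 1:0.1, 1:0.05 by default). Child seeds
#' depend only on (circuit, replicate, input), not on the scale, so the
#' scale-1 column reproduces an unscaled run exactly.
#'
#' @param circuits Circuit tibble (rows to scan).
#' @param params,config,ensemble_size,double_cre As in [simulate_circuit()].
#' @param scales Numeric vector of expression scale factors in (0, 1].
#' @param seed Master seed.
#' @return A tibble of class `blade_ratio_scan`: one row per
#'   (circuit, scale) with `mean_theta_bar` and `sd_theta_bar`.
#' @export
ratio_scan <- function(circuits, params = blade_params(),
                       scales = c(1, 0.5, 0.1, 0.05),
                       config = ssa_config(), ensemble_size = 100,
                       seed = NULL, double_cre = "linear") {
  if (any(scales <= 0 | scales > 1)) stop("scales must lie in (0, 1]", call. = FALSE)
  seed <- seed %||% sample.int(2^31 - 2, 1)
  out <- purrr::map_dfr(seq_len(nrow(circuits)), function(i) {
    purrr::map_dfr(scales, function(s) {
      p <- params
      p$alpha <- params$alpha * s
      ens <- simulate_circuit(circuit_genes(circuits[i, ]), p, config,
                              ensemble_size, seed = derive_seed(seed, 2000L, i),
                              circuit_id = circuits$circuit_id[i],
                              double_cre = double_cre)
      tibble::tibble(circuit_id = circuits$circuit_id[i],
                     scale = s,
                     mean_theta_bar = ens$mean_theta_bar,
                     sd_theta_bar = ens$sd_theta_bar)
    })
  })
  class(out) <- c("blade_ratio_scan", class(out))
  out
}
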