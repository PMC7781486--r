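# Circuit performance metrics.
#
# A circuit's observed behaviour is an 8-dimensional "% cells ON" vector (one
# (GFP, mCherry) pair per input condition). Performance is the angle between
# this vector and the circuit's ideal truth-table vector: 0 degrees is perfect
# agreement, 90 degrees the worst possible for non-negative vectors. Because
# real circuits find it much harder to reach 100% ON than to stay at 0% OFF,
# the adapted metric divides the angle by the number of outputs expected to
# fluoresce, putting circuits with many and few active outputs on a
# comparable scale.

check_vec8 <- function(v, what = "vector") {
  v <- as.numeric(v)
  if (length(v) != 8L) stop(what, " must have length 8, got ", length(v), call. = FALSE)
  if (anyNA(v)) stop(what, " contains NA", call. = FALSE)
  v
}

#' Angular metric between observed and ideal output vectors
#'
#' Computes `theta = arccos(v_e . v_i / (|v_e| |v_i|))` in degrees, the angle
#' between an observed 8-dimensional "% cells ON" vector and the ideal
#' truth-table vector. The cosine argument is clamped to `[-1, 1]` before
#' `acos` to guard against floating-point drift for near-parallel vectors.
#'
#' @param v_e Observed output vector (length 8, entries in percent).
#' @param v_i Ideal truth-table vector (length 8 of 0/100 entries), e.g. from
#'   [ideal_vector()].
#' @return The angle in degrees; in `[0, 90]` for non-negative vectors.
#' @examples
#' angular_metric(c(42, 53, 34, 46, 44, 59, 55, 69), rep(100, 8))
#' @export
angular_metric <- function(v_e, v_i) {
  v_e <- check_vec8(v_e, "v_e")
  v_i <- check_vec8(v_i, "v_i")
  ne <- sqrt(sum(v_e^2))
  ni <- sqrt(sum(v_i^2))
  if (ne == 0 || ni == 0) {
    stop("undefined angle: all-zero output vector (trivial all-STOP or dead circuit)",
         call. = FALSE)
  }
  cosang <- sum(v_e * v_i) / (ne * ni)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Adapted angular metric
#'
#' Divides the angular metric by `n`, the number of outputs expected to
#' fluoresce (entries equal to 100 in the ideal vector).
#'
#' @param theta Angular metric in degrees.
#' @param n Number of expected fluorescent outputs, an integer in `[1, 8]`.
#' @return `theta / n` in degrees.
#' @examples
#' adapted_metric(11.58, 8)
#' @export
adapted_metric <- function(theta, n) {
  if (any(n == 0)) {
    stop("division by zero: the all-STOP circuit has no expected fluorescent output",
         call. = FALSE)
  }
  theta / n
}

#' L1 errors between observed and ideal vectors
#'
#' @inheritParams angular_metric
#' @return A named list with `total` (sum of absolute entry-wise differences,
#'   in percentage points) and `average` (`total / 8`).
#' @examples
#' l1_errors(c(0, 0, 0, 2, 0, 0, 0, 89), c(0, 0, 0, 0, 0, 0, 0, 100))
#' @export
l1_errors <- function(v_e, v_i) {
  v_e <- check_vec8(v_e, "v_e")
  v_i <- check_vec8(v_i, "v_i")
  total <- sum(abs(v_e - v_i))
  list(total = total, average = total / 8)
}

#' Score one observed vector against a circuit design
#'
#' Composes [ideal_vector()], [angular_metric()], [adapted_metric()] and
#' [l1_errors()] into a one-row score record.
#'
#' @param v_e Observed output vector (length 8).
#' @param genes Circuit design: genes at (Z00, Z10, Z01, Z11).
#' @return A one-row tibble: `theta_deg`, `theta_bar_deg`, `n`,
#'   `total_error`, `average_error`.
#' @examples
#' score_circuit(c(67, 76, 60, 2, 6, 13, 77, 0), c("GFPmCherry", "GFP", "STOP", "GFP"))
#' @export
score_circuit <- function(v_e, genes) {
  v_i <- ideal_vector(genes)
  n <- attr(v_i, "n_fluorescent")
  if (n == 0L) {
    stop("trivial circuit: all-STOP designs cannot be scored", call. = FALSE)
  }
  theta <- angular_metric(v_e, v_i)
  err <- l1_errors(v_e, v_i)
  tibble::tibble(
    theta_deg = theta,
    theta_bar_deg = adapted_metric(theta, n),
    n = as.integer(n),
    total_error = err$total,
    average_error = err$average
  )
}

#' Score a table of observed vectors
#'
#' Data-frame-first scorer: joins observed vectors to their circuit designs
#' by `circuit_id` and returns one score record per circuit.
#'
#' @param observed Tibble with `circuit_id` and observed entries
#'   `obs_v1` .. `obs_v8` (percent, in the canonical output ordering).
#' @param circuits Circuit table from [blade_circuits()] (or a subset).
#' @return The `observed` tibble augmented with `theta_deg`, `theta_bar_deg`,
#'   `n`, `total_error`, `average_error`.
#' @export
score_circuits <- function(observed, circuits) {
  obs_cols <- paste0("obs_v", 1:8)
  missing_cols <- setdiff(c("circuit_id", obs_cols), names(observed))
  if (length(missing_cols) > 0L) {
    stop("observed table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(observed$circuit_id, circuits$circuit_id)
  if (length(unknown) > 0L) {
    stop("observed rows reference circuit_id(s) absent from the circuit table: ",
         paste(head(unknown, 5), collapse = ", "),
         " (rows ", paste(head(which(observed$circuit_id %in% unknown), 5), collapse = ", "),
         ")", call. = FALSE)
  }
  designs <- circuits[match(observed$circuit_id, circuits$circuit_id), ]
  scores <- purrr::map_dfr(seq_len(nrow(observed)), function(i) {
    score_circuit(
      unlist(observed[i, obs_cols], use.names = FALSE),
      circuit_genes(designs[i, ])
    )
  })
  dplyr::bind_cols(observed, scores)
}
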