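# The simplified 10-species, 17-reaction BLADE excision network.
#
# Species: the recombinases C (Cre) and F (Flp); the four platform addresses
# Z00, Z10, Z01, Z11; and the excised circles Z10X, Z01X, Z11Xc, Z11Xf that
# carry the recombinase-specific attachment sites removed at each excision.
#
# Reactions (17):
#   2 constitutive expression (0 -> C, 0 -> F; active only when the input
#     condition supplies that recombinase),
#   2 protein degradation (C -> 0, F -> 0),
#   4 forward excisions (Z00+C -> Z10+Z10X requiring C >= 2, Z00+F -> Z01+Z01X,
#     Z10+F -> Z11+Z11Xf, Z01+C -> Z11+Z11Xc),
#   4 reverse insertions, bimolecular in (address, matching circle)
#     (Z10+Z10X -> Z00+C, Z01+Z01X -> Z00+F, Z11+Z11Xf -> Z10+F,
#      Z11+Z11Xc -> Z01+C),
#   4 excised-circle dilutions (Z10X, Z01X, Z11Xc, Z11Xf -> 0),
#   1 DNA dilution on Z00 (Z00 -> 0).
#
# The first Cre excision collapses a two-step Cre-mediated transition, so
# twice the usual monomer count must be PRESENT for it to fire (C >= 2); one
# monomer is consumed, exactly as in the deterministic rate equations, whose
# Z00 equation removes k1c*Z00*C with a single -C term. By default the
# propensity stays linear in C (k1c*Z00*C, zero when C < 2); the pair-
# counting mass-action alternative k1c*Z00*C*(C-1)/2 is available via
# `double_cre = "combinatorial"`.

blade_species <- function() {
  c("C", "F", "Z00", "Z10", "Z10X", "Z01", "Z01X", "Z11", "Z11Xc", "Z11Xf")
}

# Column indices of the four platform addresses within blade_species().
address_idx <- function() c(Z00 = 3L, Z10 = 4L, Z01 = 6L, Z11 = 8L)

#' Build the simplified BLADE reaction network
#'
#' Assembles the 10-species, 17-reaction stochastic network for one input
#' condition. Expression reactions for Cre and/or Flp have rate 0 when the
#' corresponding recombinase is absent from the input, freezing the platform
#' in whatever states the remaining reactions allow.
#'
#' @param params Parameter set from [blade_params()].
#' @param cre_on,flp_on Logical: is the Cre / Flp recombinase supplied by the
#'   input condition?
#' @param double_cre Propensity form of the double-monomer first Cre excision
#'   (two Cre monomers must be present, one is consumed): `"linear"`
#'   (default) uses `k1c*Z00*C` with a `C >= 2` guard, preserving the
#'   deterministic mass-action rate; `"combinatorial"` uses the pair-counting
#'   form `k1c*Z00*C*(C-1)/2`.
#' @return An object of class `blade_network`: a list with the species names,
#'   reactant and product stoichiometry matrices (17 x 10), rate constants,
#'   per-reaction propensity kinds, human-readable reaction labels and the
#'   input condition.
#' @examples
#' net <- blade_network(blade_params(), cre_on = TRUE, flp_on = TRUE)
#' nrow(net$reactants)  # 17
#' @export
blade_network <- function(params = blade_params(), cre_on = TRUE, flp_on = TRUE,
                          double_cre = c("linear", "combinatorial")) {
  params <- validate_params(params)
  double_cre <- match.arg(double_cre)
  sp <- blade_species()
  ns <- length(sp)

  rx <- list()
  add <- function(label, rate, reactants = character(), products = character(),
                  kind = "massaction") {
    r <- setNames(integer(ns), sp)
    p <- setNames(integer(ns), sp)
    for (s in reactants) r[[s]] <- r[[s]] + 1L
    for (s in products) p[[s]] <- p[[s]] + 1L
    rx[[length(rx) + 1L]] <<- list(label = label, rate = rate, r = r, p = p, kind = kind)
  }

  p <- params
  cre_kind <- if (double_cre == "linear") "linear_guard" else "combinatorial"

  add("expression_C", if (cre_on) p$alpha else 0, character(), "C")
  add("expression_F", if (flp_on) p$alpha else 0, character(), "F")
  add("degradation_C", p$beta_p, "C", character())
  add("degradation_F", p$beta_p, "F", character())
  add("excision_Z00_Z10", p$k1c, c("Z00", "C"), c("Z10", "Z10X"), kind = cre_kind)
  add("excision_Z00_Z01", p$k1f, c("Z00", "F"), c("Z01", "Z01X"))
  add("excision_Z10_Z11", p$k2f, c("Z10", "F"), c("Z11", "Z11Xf"))
  add("excision_Z01_Z11", p$k2c, c("Z01", "C"), c("Z11", "Z11Xc"))
  add("insertion_Z10_Z00", p$k_1c, c("Z10", "Z10X"), c("Z00", "C"))
  add("insertion_Z01_Z00", p$k_1f, c("Z01", "Z01X"), c("Z00", "F"))
  add("insertion_Z11_Z10", p$k_2f, c("Z11", "Z11Xf"), c("Z10", "F"))
  add("insertion_Z11_Z01", p$k_2c, c("Z11", "Z11Xc"), c("Z01", "C"))
  add("dilution_Z10X", p$delta_X, "Z10X", character())
  add("dilution_Z01X", p$delta_X, "Z01X", character())
  add("dilution_Z11Xc", p$delta_X, "Z11Xc", character())
  add("dilution_Z11Xf", p$delta_X, "Z11Xf", character())
  add("dilution_Z00", p$delta_D, "Z00", character())

  structure(
    list(
      species = sp,
      reactants = do.call(rbind, lapply(rx, `[[`, "r")),
      products = do.call(rbind, lapply(rx, `[[`, "p")),
      rates = vapply(rx, `[[`, numeric(1), "rate"),
      kinds = vapply(rx, `[[`, character(1), "kind"),
      labels = vapply(rx, `[[`, character(1), "label"),
      input_condition = c(cre_on = cre_on, flp_on = flp_on),
      params = params
    ),
    class = "blade_network"
  )
}

#' @export
print.blade_network <- function(x, ...) {
  cat("<blade_network> ", length(x$species), " species, ", length(x$rates),
      " reactions; input (cre, flp) = (",
      as.integer(x$input_condition[["cre_on"]]), ", ",
      as.integer(x$input_condition[["flp_on"]]), ")\n", sep = "")
  invisible(x)
}

# Reaction indices whose firing removes platform DNA (the Z00 dilution).
dna_dilution_reaction <- function(network) which(network$labels == "dilution_Z00")
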