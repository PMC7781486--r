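# SBML Level 3 export of the simplified BLADE network, plus a reader used
# for round-trip checks. The document carries the 10 species, the 12 model
# parameters and the 17 reactions with mass-action kinetic laws written as
# MathML products of the rate constant and the reactant species.

#' Export the BLADE network as SBML Level 3
#'
#' Writes an SBML L3V2 core document with one compartment, the ten species
#' (with initial amounts from `initial_state`), the model parameters, and the
#' seventeen reactions, each carrying a mass-action kinetic law. Expression
#' reactions are exported with rate `alpha` regardless of input condition
#' (the document describes the full network; input conditions are a
#' simulation-time concern).
#'
#' @param params A [blade_params()] list.
#' @param path Output file path (`.xml`).
#' @param initial_state Optional named initial amounts (defaults to the
#'   standard Z00 = 1000 start).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' export_sbml(blade_params(), f)
#' @export
export_sbml <- function(params = blade_params(), path, initial_state = NULL) {
  params <- validate_params(params)
  net <- blade_network(params, cre_on = TRUE, flp_on = TRUE)
  init <- ssa_config(initial_state = initial_state)$initial_state

  # rate-constant parameter id per reaction
  rate_ids <- c("alpha", "alpha", "beta_p", "beta_p",
                "k1c", "k1f", "k2f", "k2c",
                "k_1c", "k_1f", "k_2f", "k_2c",
                "delta_X", "delta_X", "delta_X", "delta_X", "delta_D")

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2"
  )
  model <- xml2::xml_add_child(doc, "model", id = "blade_simplified",
                               name = "Simplified 2-input BLADE excision model")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", constant = "true",
                      spatialDimensions = "3", size = "1")

  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in net$species) {
    xml2::xml_add_child(sps, "species", id = s, compartment = "cell",
                        initialAmount = format(init[[s]]),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  }

  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (pn in blade_param_names()) {
    xml2::xml_add_child(pars, "parameter", id = pn,
                        value = format(params[[pn]], digits = 17),
                        constant = "true")
  }

  rxs <- xml2::xml_add_child(model, "listOfReactions")
  for (r in seq_along(net$labels)) {
    rx <- xml2::xml_add_child(rxs, "reaction", id = net$labels[r],
                              reversible = "false")
    rstoich <- net$reactants[r, ]
    pstoich <- net$products[r, ]
    if (any(rstoich > 0)) {
      lo <- xml2::xml_add_child(rx, "listOfReactants")
      for (j in which(rstoich > 0)) {
        xml2::xml_add_child(lo, "speciesReference", species = net$species[j],
                            stoichiometry = format(rstoich[j]), constant = "true")
      }
    }
    if (any(pstoich > 0)) {
      lo <- xml2::xml_add_child(rx, "listOfProducts")
      for (j in which(pstoich > 0)) {
        xml2::xml_add_child(lo, "speciesReference", species = net$species[j],
                            stoichiometry = format(pstoich[j]), constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    # rate_constant * reactant1 * reactant2 ... (species repeated per
    # stoichiometric unit; the double-Cre excision multiplies C once, its
    # propensity being linear in C)
    terms <- c(rate_ids[r], net$species[rstoich > 0])
    if (net$kinds[r] == "linear_guard") {
      terms <- c(rate_ids[r], unique(net$species[rstoich > 0]))
    }
    if (length(terms) == 1L) {
      xml2::xml_add_child(math, "ci", terms)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (tm in terms) xml2::xml_add_child(ap, "ci", tm)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an exported SBML network
#'
#' Parses an SBML L3 document written by [export_sbml()] back into its
#' components; used for round-trip verification.
#'
#' @param path SBML file path.
#' @return A list with `species` (tibble: id, initial_amount), `parameters`
#'   (tibble: id, value) and `reactions` (tibble: id, reactants, products,
#'   rate_parameter).
#' @export
read_sbml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")

  sp_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  species <- tibble::tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    initial_amount = as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  )

  par_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfParameters/sbml:parameter", ns)
  parameters <- tibble::tibble(
    id = xml2::xml_attr(par_nodes, "id"),
    value = as.numeric(xml2::xml_attr(par_nodes, "value"))
  )

  rx_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfReactions/sbml:reaction", ns)
  reactions <- purrr::map_dfr(rx_nodes, function(node) {
    side <- function(xp) {
      refs <- xml2::xml_find_all(node, xp, ns)
      paste(rep(xml2::xml_attr(refs, "species"),
                times = as.numeric(xml2::xml_attr(refs, "stoichiometry"))),
            collapse = "+")
    }
    cis <- xml2::xml_find_all(
      node, ".//sbml:kineticLaw//*[local-name() = 'ci']", ns)
    tibble::tibble(
      id = xml2::xml_attr(node, "id"),
      reactants = side(".//sbml:listOfReactants/sbml:speciesReference"),
      products = side(".//sbml:listOfProducts/sbml:speciesReference"),
      rate_parameter = trimws(xml2::xml_text(cis[1]))
    )
  })

  list(species = species, parameters = parameters, reactions = reactions)
}
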