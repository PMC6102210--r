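#' @title SBML input/output
#' @description
#' A purpose-built reader/writer for the SBML subset constraint-based and
#' kinetic models need here: Level 3 core (species, reactions,
#' stoichiometry, kinetic-law local parameters) plus the FBC flux-bound
#' attributes. Kinetic laws are recognised by their parameter signature
#' (Vmax/Km -> Michaelis-Menten, k -> mass action, rate -> constant);
#' reactions whose laws cannot be classified are reported, not silently
#' dropped.
#' @name sbml
NULL

SBML_NS <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

sbml_root <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "sbml") stop("not an SBML document: ", path)
  doc
}

#' Read a genome-scale metabolic model from SBML
#'
#' Bounds come from FBC `lowerFluxBound`/`upperFluxBound` parameter
#' references when present, otherwise from the `reversible` attribute with
#' the global default magnitude (a message reports how many defaulted).
#' Exchange reactions are those touching exactly one species (their other
#' side is the boundary) or flagged by an `EX_` id prefix. A reaction whose
#' id matches "biomass" (case-insensitively) is registered as the biomass
#' reaction.
#'
#' @param path SBML file
#' @param default_bound magnitude used when a bound is undeclared
#' @return a [metabolic_model()]
#' @export
read_gsmn_sbml <- function(path, default_bound = DEFAULT_BOUND) {
  doc <- sbml_root(path)
  model <- xml2::xml_find_first(doc, ".//s:model", SBML_NS)
  if (inherits(model, "xml_missing")) stop("SBML file has no <model>: ", path)

  params <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", SBML_NS)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", SBML_NS)
  sp_id <- xml2::xml_attr(species, "id")
  sp_comp <- xml2::xml_attr(species, "compartment")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]

  rxns <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", SBML_NS)
  if (!length(rxns)) stop("SBML model has no reactions: ", path)
  rx_id <- xml2::xml_attr(rxns, "id")
  n <- length(rx_id)
  S <- matrix(0, length(mets), n, dimnames = list(mets, rx_id))
  lb <- numeric(n); ub <- numeric(n)
  defaulted <- 0L
  for (k in seq_len(n)) {
    rx <- rxns[[k]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx, paste0("./s:", side, "/s:speciesReference"), SBML_NS)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (sp %in% mets) {
          sgn <- if (side == "listOfReactants") -1 else 1
          S[sp, k] <- S[sp, k] + sgn * st
        }
      }
    }
    lbp <- xml2::xml_attr(rx, "lowerFluxBound")
    ubp <- xml2::xml_attr(rx, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(pval) &&
        !is.na(ubp) && ubp %in% names(pval)) {
      lb[k] <- pval[[lbp]]; ub[k] <- pval[[ubp]]
    } else {
      rev <- xml2::xml_attr(rx, "reversible") %in% c("true", NA)
      lb[k] <- if (rev) -default_bound else 0
      ub[k] <- default_bound
      defaulted <- defaulted + 1L
    }
  }
  if (defaulted > 0L) {
    message(defaulted, " reaction(s) had no declared flux bounds; defaulted to +/-",
            default_bound, " mmol/g DW/h")
  }
  touches <- Matrix::colSums(S != 0)
  exchange <- rx_id[touches == 1L | startsWith(rx_id, "EX_")]
  bio <- grep("biomass", rx_id, ignore.case = TRUE, value = TRUE)
  biomass <- if (length(bio)) list(reaction = bio[[1]], demand = lb[match(bio[[1]], rx_id)]) else NULL
  message("read SBML model: ", length(mets), " metabolites, ", n, " reactions")
  metabolic_model(S, lb, ub, exchange = exchange, biomass = biomass,
                  compartments = setNames(sp_comp[!sp_boundary], mets))
}

#' Write a metabolic model to SBML (Level 3 + FBC)
#'
#' @param model a [metabolic_model()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gsmn_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS[["s"]], "xmlns:fbc" = SBML_NS[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")
  comps <- unique(c("c", unname(model$compartments)))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cmp, constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (met in model$metabolites) {
    cmp <- if (!is.null(model$compartments) && met %in% names(model$compartments))
      model$compartments[[met]] else "c"
    xml2::xml_add_child(ls, "species", id = met, compartment = cmp,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_along(model$reactions)) {
    rx <- model$reactions[k]
    lbid <- paste0("lb_", k); ubid <- paste0("ub_", k)
    xml2::xml_add_child(lp, "parameter", id = lbid, constant = "true",
                        value = format(model$lb[k], digits = 17))
    xml2::xml_add_child(lp, "parameter", id = ubid, constant = "true",
                        value = format(model$ub[k], digits = 17))
    rn <- xml2::xml_add_child(lr, "reaction", id = rx, fast = "false",
                              reversible = if (model$lb[k] < 0) "true" else "false",
                              "fbc:lowerFluxBound" = lbid,
                              "fbc:upperFluxBound" = ubid)
    col <- model$S[, k]
    nz <- which(col != 0)
    reac <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(reac)) {
      side <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in reac) {
        xml2::xml_add_child(side, "speciesReference",
                            species = model$metabolites[i], constant = "true",
                            stoichiometry = format(-col[i], digits = 17))
      }
    }
    if (length(prod)) {
      side <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in prod) {
        xml2::xml_add_child(side, "speciesReference",
                            species = model$metabolites[i], constant = "true",
                            stoichiometry = format(col[i], digits = 17))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a kinetic SBML model as a Petri net
#'
#' Species become continuous places (initial marking = initial
#' concentration) and reactions become kinetic transitions. A reaction's
#' rate law is classified from its kinetic-law local parameters: `Vmax` and
#' `Km` give Michaelis-Menten, `k` gives mass action, `rate` a constant
#' rate. Reactions with no kinetic law, or one that cannot be classified,
#' are collected in the import report rather than silently dropped.
#'
#' @param path SBML file
#' @return a [petri_net()] with an `import_report` attribute (character
#'   vector of skipped reaction ids with reasons)
#' @export
import_sbml_kinetic <- function(path) {
  doc <- sbml_root(path)
  model <- xml2::xml_find_first(doc, ".//s:model", SBML_NS)
  species <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", SBML_NS)
  places <- lapply(seq_along(species), function(i) {
    sp <- species[[i]]
    conc <- as.numeric(xml2::xml_attr(sp, "initialConcentration"))
    if (is.na(conc)) conc <- as.numeric(xml2::xml_attr(sp, "initialAmount"))
    if (is.na(conc)) conc <- 0
    pn_place(xml2::xml_attr(sp, "id"), kind = "species", marking = conc,
             units = "mM")
  })
  rxns <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", SBML_NS)
  report <- character(0)
  transitions <- list()
  for (rx in rxns) {
    rid <- xml2::xml_attr(rx, "id")
    kl <- xml2::xml_find_first(rx, "./s:kineticLaw", SBML_NS)
    if (inherits(kl, "xml_missing")) {
      report <- c(report, paste0(rid, ": no kinetic law")); next
    }
    lpars <- xml2::xml_find_all(kl, ".//s:localParameter | .//s:parameter", SBML_NS)
    pv <- setNames(as.numeric(xml2::xml_attr(lpars, "value")),
                   xml2::xml_attr(lpars, "id"))
    law <- if (all(c("Vmax", "Km") %in% names(pv))) {
      kinetic_law("michaelis_menten", Vmax = pv[["Vmax"]], Km = pv[["Km"]])
    } else if ("k" %in% names(pv)) {
      kinetic_law("mass_action", k = pv[["k"]])
    } else if ("rate" %in% names(pv)) {
      kinetic_law("constant", rate = pv[["rate"]])
    } else {
      report <- c(report, paste0(rid, ": unclassifiable rate law")); next
    }
    arcs <- NULL
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx, paste0("./s:", side, "/s:speciesReference"), SBML_NS)
      for (ref in refs) {
        st <- xml2::xml_attr(ref, "stoichiometry")
        arcs <- rbind(arcs, pn_arcs(xml2::xml_attr(ref, "species"),
                                    if (is.na(st)) 1 else as.numeric(st),
                                    if (side == "listOfReactants") "consume" else "produce"))
      }
    }
    if (is.null(arcs)) { report <- c(report, paste0(rid, ": no participants")); next }
    transitions <- c(transitions, list(
      pn_transition(rid, "kinetic", arcs, rate_law = law)))
  }
  net <- petri_net(places, transitions)
  attr(net, "import_report") <- report
  if (length(report)) {
    message("import report: ", length(report), " reaction(s) skipped (see ",
            "attr(net, 'import_report'))")
  }
  net
}
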