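#' Write a stoichiometric model as SBML Level 3 with FBC
#'
#' Emits SBML L3V1 with the Flux Balance Constraints (fbc v2) package:
#' species, flux-bound parameters, reactions with stoichiometric
#' speciesReferences, and an objective. Designated reactions (biomass,
#' uptake, levansucrase) are recorded as model annotations so they
#' round-trip.
#'
#' @param m a [stoich_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(m, path) {
  stopifnot(inherits(m, "stoich_model"))
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "true")
  ann <- xml2::xml_add_child(mod, "annotation")
  xml2::xml_add_child(ann, "designations",
                      biomass = m$biomass_id, uptake = m$uptake_id,
                      levansucrase = ifelse(is.na(m$levansucrase_id), "",
                                            m$levansucrase_id))
  cmp <- xml2::xml_add_child(mod, "listOfCompartments")
  xml2::xml_add_child(cmp, "compartment", id = "c", constant = "true")

  sp <- xml2::xml_add_child(mod, "listOfSpecies")
  for (met in m$mets) {
    xml2::xml_add_child(sp, "species", id = met, compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  par <- xml2::xml_add_child(mod, "listOfParameters")
  for (j in seq_along(m$rxns)) {
    xml2::xml_add_child(par, "parameter", id = paste0("lb_", j),
                        value = format(m$lb[j], digits = 17),
                        constant = "true")
    xml2::xml_add_child(par, "parameter", id = paste0("ub_", j),
                        value = format(m$ub[j], digits = 17),
                        constant = "true")
  }
  rx <- xml2::xml_add_child(mod, "listOfReactions")
  for (j in seq_along(m$rxns)) {
    r <- xml2::xml_add_child(
      rx, "reaction", id = m$rxns[j],
      reversible = tolower(as.character(m$lb[j] < 0)), fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", j),
      "fbc:upperFluxBound" = paste0("ub_", j))
    col <- m$S[, j]
    rea <- names(col)[col < 0]
    pro <- names(col)[col > 0]
    if (length(rea)) {
      lr <- xml2::xml_add_child(r, "listOfReactants")
      for (met in rea) {
        xml2::xml_add_child(lr, "speciesReference", species = met,
                            stoichiometry = format(-col[met], digits = 17),
                            constant = "true")
      }
    }
    if (length(pro)) {
      lp <- xml2::xml_add_child(r, "listOfProducts")
      for (met in pro) {
        xml2::xml_add_child(lp, "speciesReference", species = met,
                            stoichiometry = format(col[met], digits = 17),
                            constant = "true")
      }
    }
  }
  lo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (j in which(m$obj != 0)) {
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = m$rxns[j],
                        "fbc:coefficient" = format(m$obj[j], digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Load a stoichiometric model from SBML (Level 3 + FBC)
#'
#' Parses species, reactions (speciesReference stoichiometry), FBC flux
#' bounds and objective. The designated biomass/uptake/levansucrase
#' reaction ids are taken from `designations` if supplied, otherwise from
#' the model annotation written by [write_sbml()].
#'
#' @param path SBML file.
#' @param designations optional named list/vector with `biomass`, `uptake`
#'   and optionally `levansucrase` reaction ids.
#' @return A [stoich_model()].
#' @export
read_sbml <- function(path, designations = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("SBML parse failure: ",
                                                   conditionMessage(e))))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mets <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(mets) == 0 || length(rxn_nodes) == 0) {
    abort("SBML parse failure: no species or no reactions found")
  }
  rxns <- xml2::xml_attr(rxn_nodes, "id")
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))

  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- ub <- numeric(length(rxns))
  for (j in seq_along(rxn_nodes)) {
    node <- rxn_nodes[[j]]
    for (ref in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      S[xml2::xml_attr(ref, "species"), j] <-
        S[xml2::xml_attr(ref, "species"), j] -
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      S[xml2::xml_attr(ref, "species"), j] <-
        S[xml2::xml_attr(ref, "species"), j] +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    lbid <- xml2::xml_attr(node, "lowerFluxBound")
    ubid <- xml2::xml_attr(node, "upperFluxBound")
    lb[j] <- if (!is.na(lbid) && lbid %in% names(parval)) parval[[lbid]] else -1000
    ub[j] <- if (!is.na(ubid) && ubid %in% names(parval)) parval[[ubid]] else 1000
  }

  obj <- setNames(numeric(length(rxns)), rxns)
  fo <- xml2::xml_find_all(doc, ".//fbc:fluxObjective", ns)
  for (node in fo) {
    rid <- xml2::xml_attr(node, "reaction")
    if (rid %in% rxns) obj[rid] <- as.numeric(xml2::xml_attr(node, "coefficient"))
  }

  if (is.null(designations)) {
    des <- xml2::xml_find_first(doc, ".//s:annotation/s:designations", ns)
    if (inherits(des, "xml_missing")) {
      abort("no reaction designations found: supply `designations`")
    }
    designations <- list(biomass = xml2::xml_attr(des, "biomass"),
                         uptake = xml2::xml_attr(des, "uptake"),
                         levansucrase = xml2::xml_attr(des, "levansucrase"))
    if (identical(designations$levansucrase, "")) designations$levansucrase <- NA
  }
  lvs <- designations$levansucrase %||% NA
  if (!is.na(lvs) && !lvs %in% rxns) {
    abort(paste0("designated levansucrase reaction '", lvs,
                 "' missing from SBML; candidates: ",
                 paste(rxns, collapse = ", ")))
  }
  stoich_model(S, mets = mets, rxns = rxns, lb = lb, ub = ub, obj = obj,
               biomass_id = designations$biomass,
               uptake_id = designations$uptake,
               levansucrase_id = lvs)
}
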