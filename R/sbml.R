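# SBML Level 3 Version 1 export / import of the reaction network, for
# interchange with standard biochemical simulators.

.sbml_id <- function(name) {
  paste0("sp_", gsub("[^A-Za-z0-9]", "_", name))
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# MathML of a product k * x1 * x2 ... (ci references)
.mathml_product <- function(cis) {
  if (length(cis) == 1) {
    inner <- sprintf("<ci> %s </ci>", cis)
  } else {
    inner <- paste0("<apply><times/>",
                    paste(sprintf("<ci> %s </ci>", cis), collapse = ""),
                    "</apply>")
  }
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', inner, "</math>")
}

# MathML of the cAMP Hill production law
#   k2 * h / (1 + h),  h = (AC_on / EC50)^n,
#   AC_on = ACs / (ACs + ACi + AC)
.mathml_hill <- function(sp_acs, sp_aci, sp_ac) {
  acon <- sprintf(
    "<apply><divide/><ci> %s </ci><apply><plus/><ci> %s </ci><ci> %s </ci><ci> %s </ci></apply></apply>",
    sp_acs, sp_acs, sp_aci, sp_ac)
  h <- sprintf(
    "<apply><power/><apply><divide/>%s<ci> EC50_hill </ci></apply><ci> n_hill </ci></apply>",
    acon)
  expr <- sprintf(
    "<apply><divide/><apply><times/><ci> k2 </ci>%s</apply><apply><plus/><cn> 1 </cn>%s</apply></apply>",
    h, h)
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', expr, "</math>")
}

#' Export a network to SBML Level 3
#'
#' Writes species (with initial concentrations), global parameters (all
#' rate constants, including the resolved per-drug binding/degradation
#' rates) and reactions with mass-action kinetic laws; the cAMP
#' production reaction carries its Hill-law MathML.  The document
#' round-trips through [import_sbml()].
#'
#' @param network an `oic_network`.
#' @param path optional output file; when `NULL` the `xml_document` is
#'   returned without writing.
#' @return an `xml2::xml_document` (invisibly when `path` is given).
#' @export
#' @examples
#' doc <- export_sbml(build_network(pathways = "serotonin"))
export_sbml <- function(network, path = NULL) {
  sp <- network$species
  ids <- setNames(.sbml_id(sp$name), sp$name)
  species_xml <- paste(sprintf(
    '      <species id="%s" name="%s" compartment="cell" initialConcentration="%.17g" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    ids, .xml_escape(sp$name), sp$initial), collapse = "\n")

  # global parameters: rate table entries plus per-reaction resolved
  # constants for drug-level rates
  params <- network$rates
  for (rx in network$reactions) {
    if (!rx$rate_constant_name %in% names(params)) {
      params[[rx$rate_constant_name]] <- rx$k
    }
  }
  params_xml <- paste(sprintf(
    '      <parameter id="%s" value="%.17g" constant="true"/>',
    names(params), unlist(params)), collapse = "\n")

  rx_xml <- vapply(network$reactions, function(rx) {
    refs <- function(side) {
      if (!length(side)) return("")
      paste(sprintf(
        '          <speciesReference species="%s" stoichiometry="%d" constant="true"/>',
        ids[names(side)], as.integer(side)), collapse = "\n")
    }
    math <- if (rx$rate_law == "hill_production") {
      .mathml_hill(ids[["AC:aS_GTP"]],
                   if ("AC:aI_GTP" %in% names(ids)) ids[["AC:aI_GTP"]] else ids[["AC"]],
                   ids[["AC"]])
    } else {
      .mathml_product(c(rx$rate_constant_name, ids[names(rx$reactants)]))
    }
    paste0(
      sprintf('      <reaction id="%s" reversible="false">\n', rx$id),
      if (length(rx$reactants))
        paste0("        <listOfReactants>\n", refs(rx$reactants),
               "\n        </listOfReactants>\n") else "",
      if (length(rx$products))
        paste0("        <listOfProducts>\n", refs(rx$products),
               "\n        </listOfProducts>\n") else "",
      "        <kineticLaw>", math, "</kineticLaw>\n",
      "      </reaction>")
  }, character(1))

  doc_str <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">\n',
    '  <model id="enteric_signalling" name="serotonin-opioid enteric signalling">\n',
    '    <listOfCompartments>\n',
    '      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', species_xml, '\n    </listOfSpecies>\n',
    '    <listOfParameters>\n', params_xml, '\n    </listOfParameters>\n',
    '    <listOfReactions>\n', paste(rx_xml, collapse = "\n"),
    '\n    </listOfReactions>\n',
    '  </model>\n</sbml>\n')
  doc <- xml2::read_xml(doc_str)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Import an SBML document written by [export_sbml()]
#'
#' Reconstructs the species table, parameter values and reaction list
#' (reactants/products, rate constants and the Hill production law) into
#' an `oic_network` that simulates identically to the exported one.
#'
#' @param path SBML file path (or an `xml2::xml_document`).
#' @return an `oic_network`.
#' @export
import_sbml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  doc <- xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  sp_init <- as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))
  id2name <- setNames(sp_name, sp_id)

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_vals <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                       xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    side <- function(xp) {
      refs <- xml2::xml_find_all(node, xp)
      if (!length(refs)) return(setNames(numeric(0), character(0)))
      nm <- id2name[xml2::xml_attr(refs, "species")]
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      setNames(st, nm)
    }
    reactants <- side("./listOfReactants/speciesReference")
    products <- side("./listOfProducts/speciesReference")
    math <- xml2::xml_find_first(node, "./kineticLaw/math")
    cis <- trimws(xml2::xml_text(xml2::xml_find_all(math, ".//ci")))
    is_hill <- length(xml2::xml_find_all(math, ".//power")) > 0
    par_cis <- cis[cis %in% names(par_vals)]
    rate_name <- if (is_hill) "k2" else par_cis[1]
    list(id = id,
         block = substr(id, 1, 1),
         reactants = reactants, products = products,
         rate_constant_name = rate_name,
         rate_law = if (is_hill) "hill_production" else "mass_action",
         k = par_vals[[rate_name]])
  })

  species <- data.frame(name = unname(sp_name), initial = sp_init,
                        pathway_tag = "imported", stringsAsFactors = FALSE)
  tags <- .species_table()
  m <- match(species$name, tags$name)
  species$pathway_tag[!is.na(m)] <- tags$pathway_tag[m[!is.na(m)]]
  .network_from_parts(species, reactions, rates = as.list(par_vals))
}

# assemble an oic_network from explicit parts (used by import_sbml and by
# tests that need custom toy networks); each reaction must carry its
# resolved rate constant `k`
.network_from_parts <- function(species, reactions, rates = list(),
                                drug = NULL, pathways = "custom") {
  defaults <- list(EC50_hill = 135, n_hill = 2.44)
  for (nm in names(defaults)) {
    if (is.null(rates[[nm]])) rates[[nm]] <- defaults[[nm]]
  }
  net <- structure(list(
    species = species, reactions = reactions, rates = rates, drug = drug,
    pathways = pathways, release_ligand_on_unbind = FALSE,
    pulse_release = NULL
  ), class = "oic_network")
  net$stoich <- stoichiometric_matrix(net)
  net
}
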