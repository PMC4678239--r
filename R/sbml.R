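SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
KINFAULT_NS <- "https://kinfault.r-lib-ns.org/model"

mathml_factor <- function(x) {
  if (is.character(x)) sprintf("<ci> %s </ci>", x)
  else sprintf("<cn type=\"integer\"> %d </cn>", as.integer(x))
}

#' Export a kinetic model to SBML Level 3 Version 1
#'
#' Species carry the initial concentrations; the stimulus is written as a
#' constant boundary species; each reaction's mass-action kinetic law is
#' written explicitly as MathML (rate constant times reactant powers).
#' Catalytic species (kinetic reactants that are not consumed) are listed
#' as modifiers. Package-specific metadata (outputs, oscillatory flag,
#' default horizon) goes into a model annotation so the file round-trips.
#'
#' @param model a `kin_model`.
#' @param path output file path (.xml).
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "kin_model"))
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"1\">", SBML_NS),
    sprintf("  <model id=\"%s\">", esc(model$name)),
    "    <annotation>",
    sprintf("      <kinfault:info xmlns:kinfault=\"%s\">", KINFAULT_NS),
    sprintf("        <kinfault:outputs>%s</kinfault:outputs>",
            paste(model$output_names, collapse = " ")),
    sprintf("        <kinfault:oscillatory>%s</kinfault:oscillatory>",
            tolower(model$oscillatory)),
    sprintf("        <kinfault:horizonHours>%g</kinfault:horizonHours>",
            model$default_horizon_h),
    sprintf("        <kinfault:stimulusId>%s</kinfault:stimulusId>",
            model$stimulus_name),
    "      </kinfault:info>",
    "    </annotation>",
    "    <listOfCompartments>",
    "      <compartment id=\"cell\" size=\"1\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <listOfSpecies>"
  )
  for (i in seq_along(model$state_names)) {
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" compartment=\"cell\" ",
             "initialConcentration=\"%.17g\" constant=\"false\" ",
             "boundaryCondition=\"false\" hasOnlySubstanceUnits=\"false\"/>"),
      model$state_names[i], model$initial_state[i]))
  }
  lines <- c(lines, sprintf(
    paste0("      <species id=\"%s\" compartment=\"cell\" ",
           "initialConcentration=\"%.17g\" constant=\"true\" ",
           "boundaryCondition=\"true\" hasOnlySubstanceUnits=\"false\"/>"),
    model$stimulus_name, model$stimulus),
    "    </listOfSpecies>",
    "    <listOfParameters>")
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      "      <parameter id=\"k_%s\" value=\"%.17g\" constant=\"true\"/>",
      r$id, r$k))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (r in model$reactions) {
    consumed <- r$stoich[r$stoich < 0]
    produced <- r$stoich[r$stoich > 0]
    modifiers <- setdiff(names(r$reactants), names(consumed))
    if (r$stim > 0) modifiers <- c(modifiers, model$stimulus_name)
    lines <- c(lines, sprintf(
      "      <reaction id=\"%s\" reversible=\"false\">", r$id))
    if (length(consumed)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf(paste0("          <speciesReference species=\"%s\" ",
                                "stoichiometry=\"%g\" constant=\"true\"/>"),
                         names(consumed), -consumed),
                 "        </listOfReactants>")
    }
    if (length(produced)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf(paste0("          <speciesReference species=\"%s\" ",
                                "stoichiometry=\"%g\" constant=\"true\"/>"),
                         names(produced), produced),
                 "        </listOfProducts>")
    }
    if (length(modifiers)) {
      lines <- c(lines, "        <listOfModifiers>",
                 sprintf("          <modifierSpeciesReference species=\"%s\"/>",
                         modifiers),
                 "        </listOfModifiers>")
    }
    factors <- sprintf("<ci> k_%s </ci>", r$id)
    if (r$stim > 0) {
      f <- if (r$stim == 1) mathml_factor(model$stimulus_name)
      else sprintf("<apply><power/>%s%s</apply>",
                   mathml_factor(model$stimulus_name), mathml_factor(r$stim))
      factors <- c(factors, f)
    }
    for (sp in names(r$reactants)) {
      o <- r$reactants[[sp]]
      f <- if (o == 1) mathml_factor(sp)
      else sprintf("<apply><power/>%s%s</apply>",
                   mathml_factor(sp), mathml_factor(o))
      factors <- c(factors, f)
    }
    math <- if (length(factors) == 1) factors
    else sprintf("<apply><times/>%s</apply>", paste(factors, collapse = ""))
    lines <- c(lines,
               "        <kineticLaw>",
               sprintf("          <math xmlns=\"%s\">%s</math>",
                       MATHML_NS, math),
               "        </kineticLaw>",
               "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

local_name_all <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

# Parse a mass-action kinetic-law MathML node into k-parameter id, reactant
# orders, and stimulus order. Anything else is an unsupported construct.
parse_mass_action_math <- function(math, param_ids, species_ids, stim_id,
                                   rxn_id) {
  unsupported <- function(what)
    stop(sprintf("reaction %s: unsupported kinetic law (%s); only %s",
                 rxn_id, what,
                 "mass-action laws (rate constant times reactant powers) are supported"))
  kids <- xml2::xml_children(math)
  if (length(kids) != 1L) unsupported("empty or compound math")
  top <- kids[[1]]
  factors <- if (xml2::xml_name(top) == "apply") {
    ops <- xml2::xml_children(top)
    if (xml2::xml_name(ops[[1]]) == "times") ops[-1]
    else list(top)                       # single power factor
  } else list(top)
  k_id <- NULL
  orders <- c()
  stim_order <- 0
  for (f in factors) {
    nm <- xml2::xml_name(f)
    if (nm == "ci") {
      id <- trimws(xml2::xml_text(f))
      if (id %in% param_ids) {
        if (!is.null(k_id)) unsupported("multiple rate parameters")
        k_id <- id
      } else if (identical(id, stim_id)) {
        stim_order <- stim_order + 1
      } else if (id %in% species_ids) {
        orders[id] <- (if (id %in% names(orders)) orders[[id]] else 0) + 1
      } else unsupported(paste("unknown identifier", id))
    } else if (nm == "apply") {
      sub <- xml2::xml_children(f)
      if (xml2::xml_name(sub[[1]]) != "power" || length(sub) != 3L)
        unsupported("non-power sub-expression")
      base <- trimws(xml2::xml_text(sub[[2]]))
      expo <- suppressWarnings(as.numeric(xml2::xml_text(sub[[3]])))
      if (is.na(expo)) unsupported("non-numeric exponent")
      if (identical(base, stim_id)) stim_order <- stim_order + expo
      else if (base %in% species_ids)
        orders[base] <- (if (base %in% names(orders)) orders[[base]] else 0) + expo
      else unsupported(paste("power of unknown identifier", base))
    } else unsupported(paste("MathML element", nm))
  }
  if (is.null(k_id)) unsupported("no rate parameter")
  list(k_id = k_id, orders = orders, stim_order = stim_order)
}

#' Import a kinetic model from SBML
#'
#' Reads an SBML Level 3 document whose kinetic laws are mass-action (a
#' single rate parameter times powers of reactant species, optionally times
#' a constant boundary 'stimulus' species). Events, rules, constraints,
#' function definitions, initial assignments and non-mass-action laws are
#' rejected with an error naming the offending element. Files written by
#' [write_sbml()] round-trip, including the declared outputs.
#'
#' @param path SBML file path.
#' @param output_names optional character vector overriding the declared
#'   outputs (required if the file carries no kinfault annotation).
#' @return a `kin_model`.
#' @export
read_sbml <- function(path, output_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  for (bad in c("event", "algebraicRule", "assignmentRule", "rateRule",
                "constraint", "functionDefinition", "initialAssignment",
                "delay")) {
    hit <- local_name_all(doc, bad)
    if (length(hit))
      stop("unsupported SBML construct: <", bad, "> (", length(hit),
           " occurrence(s))")
  }
  model_node <- local_name_all(doc, "model")
  if (!length(model_node)) stop("not an SBML document: no <model> element")
  model_id <- xml2::xml_attr(model_node[[1]], "id")
  if (is.na(model_id)) model_id <- "sbml_model"

  sp_nodes <- local_name_all(doc, "species")
  if (!length(sp_nodes)) stop("SBML model declares no species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_init <- as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))
  sp_init[is.na(sp_init)] <- 0
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true" |
    xml2::xml_attr(sp_nodes, "constant") %in% "true"
  stim_id <- sp_id[boundary]
  if (length(stim_id) > 1L)
    stop("more than one constant/boundary species; cannot identify the stimulus")
  stimulus <- if (length(stim_id)) sp_init[boundary] else 0
  if (!length(stim_id)) stim_id <- "u"
  states <- sp_id[!boundary]
  init <- setNames(sp_init[!boundary], states)

  par_nodes <- local_name_all(doc, "parameter")
  par_ids <- xml2::xml_attr(par_nodes, "id")
  par_val <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")), par_ids)
  lp_nodes <- local_name_all(doc, "localParameter")
  if (length(lp_nodes)) {
    lp_ids <- xml2::xml_attr(lp_nodes, "id")
    par_val <- c(par_val, setNames(as.numeric(xml2::xml_attr(lp_nodes, "value")),
                                   lp_ids))
    par_ids <- c(par_ids, lp_ids)
  }

  rxn_nodes <- local_name_all(doc, "reaction")
  if (!length(rxn_nodes)) stop("SBML model declares no reactions")
  reactions <- lapply(rxn_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    get_refs <- function(listname) {
      lst <- local_name_all(rn, listname)
      if (!length(lst)) return(numeric(0))
      refs <- local_name_all(lst[[1]], "speciesReference")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      setNames(st, xml2::xml_attr(refs, "species"))
    }
    consumed <- get_refs("listOfReactants")
    produced <- get_refs("listOfProducts")
    stoich <- c()
    for (s in names(consumed))
      stoich[s] <- (if (s %in% names(stoich)) stoich[[s]] else 0) - consumed[[s]]
    for (s in names(produced))
      stoich[s] <- (if (s %in% names(stoich)) stoich[[s]] else 0) + produced[[s]]
    stoich <- stoich[stoich != 0]
    kl <- local_name_all(rn, "kineticLaw")
    if (!length(kl)) stop("reaction ", rid, " has no kinetic law")
    math <- local_name_all(kl[[1]], "math")
    if (!length(math)) stop("reaction ", rid, " has no MathML math element")
    pm <- parse_mass_action_math(math[[1]], par_ids, states, stim_id, rid)
    list(id = rid, k = unname(par_val[[pm$k_id]]),
         reactants = pm$orders, stoich = stoich, stim = pm$stim_order)
  })

  ann <- local_name_all(doc, "info")
  osc <- FALSE; horizon <- 10
  if (length(ann)) {
    outs_node <- local_name_all(ann[[1]], "outputs")
    if (is.null(output_names) && length(outs_node))
      output_names <- strsplit(trimws(xml2::xml_text(outs_node[[1]])),
                               "\\s+")[[1]]
    osc_node <- local_name_all(ann[[1]], "oscillatory")
    if (length(osc_node)) osc <- identical(trimws(xml2::xml_text(osc_node[[1]])), "true")
    h_node <- local_name_all(ann[[1]], "horizonHours")
    if (length(h_node)) horizon <- as.numeric(xml2::xml_text(h_node[[1]]))
  }
  if (is.null(output_names))
    stop("file declares no outputs; pass output_names explicitly")

  kinetic_model(model_id, init, reactions, stimulus = stimulus,
                stimulus_name = stim_id, output_names = output_names,
                oscillatory = osc, default_horizon_h = horizon)
}
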