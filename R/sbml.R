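.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

## R arithmetic expression -> MathML content markup.
.mathml <- function(e) {
  if (is.numeric(e)) {
    if (e == round(e) && abs(e) < 1e15)
      return(sprintf('<cn type="integer">%d</cn>', as.integer(e)))
    return(sprintf("<cn>%s</cn>", format(e, digits = 17)))
  }
  if (is.name(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.mathml(e[[2]]))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", NULL)
    if (is.null(tag))
      stop("cannot express operator in MathML: ", op)
    args <- vapply(as.list(e)[-1], .mathml, character(1))
    return(sprintf("<apply><%s/>%s</apply>", tag, paste(args, collapse = "")))
  }
  stop("cannot express in MathML: ", deparse(e))
}

.mathNode <- function(formula) {
  sprintf('<math xmlns="%s">%s</math>', .MATHML_NS,
          .mathml(str2lang(formula)))
}

.speciesRefs <- function(tag, lst) {
  if (!length(lst)) return("")
  inner <- paste(sprintf(
    '<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
    names(lst), format(unname(lst), digits = 17)), collapse = "")
  sprintf("<%s>%s</%s>", tag, inner, tag)
}

.modifierRefs <- function(sp) {
  if (!length(sp)) return("")
  sprintf("<listOfModifiers>%s</listOfModifiers>",
          paste(sprintf('<modifierSpeciesReference species="%s"/>', sp),
                collapse = ""))
}

.reactionXML <- function(id, reactants, products, modifiers, formula) {
  sprintf(paste0('<reaction id="%s" reversible="false">%s%s%s',
                 '<kineticLaw>%s</kineticLaw></reaction>'),
          id, .speciesRefs("listOfReactants", reactants),
          .speciesRefs("listOfProducts", products),
          .modifierRefs(modifiers), .mathNode(formula))
}

## Hill fraction as a formula string over parameter/species names.
.hillFormula <- function(reg, K, n) {
  sprintf("((%s / %s)^%s) / (1 + (%s / %s)^%s)", reg, K, n, reg, K, n)
}

#' Export a model as SBML Level 3
#'
#' Writes the model as an SBML Level 3 Version 2 document: one reaction per
#' tabulated rate law (kinetic laws transcribed to MathML, formula-only
#' species as modifiers), plus per gene one transcription reaction with the
#' Hill activator/repressor terms embedded in its kinetic law, and one mRNA
#' degradation reaction. Gene on/off state is deterministic and enters
#' through a constant active-copy parameter (\code{gActive_<gene>}, the
#' on/off equilibrium); species initial concentrations are in nM and
#' molecule-to-concentration conversion factors appear as parameters.
#' Identifiers are sanitized to the SBML grammar with a logged mapping.
#'
#' @param model a valid \linkS4class{MechModel} with at least one
#'   compartment.
#' @param path optional file path; when given the document is written there.
#' @return an \pkg{xml2} document (invisibly when \code{path} is given).
#' @seealso [importSBML()], [validateSBML()], [enlargeSBML()]
#' @export
exportSBML <- function(model, path = NULL) {
  stopifnot(is(model, "MechModel"))
  validObject(model)
  if (nrow(model@compartments) == 0)
    stop("cannot export a model with no compartments")
  sp <- model@species; gn <- model@genes; rl <- model@ratelaws
  tr <- model@tars
  sid <- .sanitizeId(sp$species)
  map <- attr(sid, "mapping")
  if (nrow(map))
    message(sprintf("sanitized %d identifier(s): %s", nrow(map),
                    paste(sprintf("%s->%s", map$original, map$sanitized),
                          collapse = ", ")))
  rename <- setNames(sid, sp$species)
  lookup <- function(x) ifelse(x %in% names(rename), rename[x], x)

  cmpXML <- paste(sprintf(
    '<compartment id="%s" size="%s" spatialDimensions="3" constant="true"/>',
    .sanitizeId(model@compartments$compartment),
    format(model@compartments$volume, digits = 17)), collapse = "")
  spXML <- paste(sprintf(
    paste0('<species id="%s" compartment="%s" initialConcentration="%s" ',
           'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
           'constant="false"/>'),
    sid, .sanitizeId(sp$compartment),
    format(sp$initial_nM, digits = 17)), collapse = "")

  params <- numeric(0)
  reactions <- character(0)
  for (j in seq_len(nrow(rl))) {
    p <- .parseParams(rl$parameters[j])
    params[names(p)] <- p
    re <- .parseSpeciesList(rl$reactants[j])
    pr <- .parseSpeciesList(rl$products[j])
    names(re) <- lookup(names(re)); names(pr) <- lookup(names(pr))
    syms <- all.vars(str2lang(rl$formula[j]))
    mods <- setdiff(lookup(intersect(syms, sp$species)),
                    c(names(re), names(pr)))
    f <- rl$formula[j]
    for (old in intersect(syms, names(rename)))
      f <- gsub(sprintf("\\b%s\\b", old), rename[old], f)
    reactions <- c(reactions,
                   .reactionXML(.sanitizeId(rl$ratelaw[j]), re, pr, mods, f))
  }
  volByComp <- setNames(model@compartments$volume,
                        model@compartments$compartment)
  for (i in seq_len(nrow(gn))) {
    g <- .sanitizeId(gn$gene[i])
    mSp <- lookup(gn$mRNA_species[i])
    comp <- sp$compartment[match(gn$mRNA_species[i], sp$species)]
    conv <- 1e9 / (.AVOGADRO * volByComp[[comp]])
    gAct <- gn$copy_number[i] * gn$kG_ac[i] /
      (gn$kG_ac[i] + gn$kG_in[i])
    params[paste0("gActive_", g)] <- gAct
    params[paste0("kTCbasal_", g)] <- gn$kTC_basal[i]
    params[paste0("conv_", g)] <- conv
    params[paste0("kTCd_", g)] <- gn$kTCd[i]
    tg <- tr[tr$target_gene == gn$gene[i], , drop = FALSE]
    actTerms <- character(0); repTerms <- character(0)
    mods <- character(0)
    for (k in seq_len(nrow(tg))) {
      reg <- lookup(tg$regulator[k])
      Kid <- .sanitizeId(sprintf("KA_%s_%s", reg, g))
      nid <- .sanitizeId(sprintf("nA_%s_%s", reg, g))
      params[Kid] <- tg$K_A[k]; params[nid] <- tg$n_A[k]
      h <- .hillFormula(reg, Kid, nid)
      if (tg$sign[k] == "activator") actTerms <- c(actTerms, h)
      else repTerms <- c(repTerms, sprintf("(1 - %s)", h))
      mods <- c(mods, reg)
    }
    mult <- paste(c(sprintf("(1 + %s)",
                            paste(actTerms, collapse = " + "))[length(actTerms) > 0],
                    repTerms), collapse = " * ")
    f <- sprintf("gActive_%s * kTCbasal_%s * conv_%s", g, g, g)
    if (nzchar(mult)) f <- paste(f, "*", mult)
    reactions <- c(reactions,
                   .reactionXML(paste0("vTC_", g), numeric(0),
                                setNames(1, mSp), unique(mods), f),
                   .reactionXML(paste0("vMD_", g),
                                setNames(1, mSp), numeric(0), character(0),
                                sprintf("kTCd_%s * %s", g, mSp)))
  }
  parXML <- paste(sprintf('<parameter id="%s" value="%s" constant="true"/>',
                          .sanitizeId(names(params)),
                          vapply(params, format, character(1), digits = 17)),
                  collapse = "")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="%s" level="3" version="2">',
    '<model id="expanded_model" substanceUnits="nanomole" timeUnits="second">',
    '<listOfCompartments>%s</listOfCompartments>',
    '<listOfSpecies>%s</listOfSpecies>',
    '<listOfParameters>%s</listOfParameters>',
    '<listOfReactions>%s</listOfReactions>',
    '</model></sbml>'),
    .SBML_NS, cmpXML, spXML, parXML, paste(reactions, collapse = ""))
  x <- xml2::read_xml(doc)
  if (!is.null(path)) {
    xml2::write_xml(x, path)
    return(invisible(x))
  }
  x
}

.sbmlFind <- function(doc, xpath) {
  xml2::xml_find_all(doc, xpath, ns = c(s = .SBML_NS))
}

#' Import summary of an SBML document
#'
#' Parses an SBML Level 3 document and returns its compartments, species
#' (with initial concentrations), global parameters and reaction summaries.
#' Used to verify that export round-trips preserve counts and values.
#'
#' @param x file path or \pkg{xml2} document.
#' @return list with data.frames \code{compartments}, \code{species},
#'   \code{parameters}, \code{reactions}.
#' @export
importSBML <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  att <- function(nodes, a) xml2::xml_attr(nodes, a)
  cmp <- .sbmlFind(doc, ".//s:listOfCompartments/s:compartment")
  spn <- .sbmlFind(doc, ".//s:listOfSpecies/s:species")
  par <- .sbmlFind(doc, ".//s:listOfParameters/s:parameter")
  rxn <- .sbmlFind(doc, ".//s:listOfReactions/s:reaction")
  list(
    compartments = data.frame(id = att(cmp, "id"),
                              size = .num(att(cmp, "size")),
                              stringsAsFactors = FALSE),
    species = data.frame(id = att(spn, "id"),
                         compartment = att(spn, "compartment"),
                         initialConcentration = .num(att(spn,
                                                         "initialConcentration")),
                         stringsAsFactors = FALSE),
    parameters = data.frame(id = att(par, "id"),
                            value = .num(att(par, "value")),
                            stringsAsFactors = FALSE),
    reactions = data.frame(
      id = att(rxn, "id"),
      nReactants = vapply(rxn, function(r) length(xml2::xml_find_all(
        r, "./s:listOfReactants/s:speciesReference", ns = c(s = .SBML_NS))),
        integer(1)),
      nProducts = vapply(rxn, function(r) length(xml2::xml_find_all(
        r, "./s:listOfProducts/s:speciesReference", ns = c(s = .SBML_NS))),
        integer(1)),
      stringsAsFactors = FALSE))
}

#' Structural consistency validation of an SBML document
#'
#' Checks the constraints a consistent reaction-network document must
#' satisfy: correct namespace and level, globally unique identifiers,
#' species referencing declared compartments, positive compartment sizes,
#' finite non-negative initial concentrations, species references and
#' modifiers resolving to declared species, and every kinetic-law symbol
#' resolving to a declared species, parameter or compartment.
#'
#' @param x file path or \pkg{xml2} document.
#' @return character vector of problems; empty when the document passes.
#' @export
validateSBML <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  errs <- character(0)
  root <- xml2::xml_name(xml2::xml_root(doc))
  if (root != "sbml") errs <- c(errs, "root element is not <sbml>")
  ns <- xml2::xml_ns(doc)
  if (!.SBML_NS %in% unlist(ns))
    return(c(errs, "document is not in the SBML Level 3 core namespace"))
  imp <- importSBML(doc)
  ids <- c(imp$compartments$id, imp$species$id, imp$parameters$id,
           imp$reactions$id)
  if (anyDuplicated(ids))
    errs <- c(errs, sprintf("duplicate identifiers: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (any(!is.finite(imp$compartments$size) | imp$compartments$size <= 0))
    errs <- c(errs, "compartment sizes must be positive")
  bad <- setdiff(imp$species$compartment, imp$compartments$id)
  if (length(bad))
    errs <- c(errs, sprintf("species reference undeclared compartments: %s",
                            paste(bad, collapse = ", ")))
  if (any(!is.finite(imp$species$initialConcentration) |
            imp$species$initialConcentration < 0))
    errs <- c(errs, "species initial concentrations must be finite and >= 0")
  rxns <- .sbmlFind(doc, ".//s:listOfReactions/s:reaction")
  known <- c(imp$species$id, imp$parameters$id, imp$compartments$id)
  for (r in rxns) {
    rid <- xml2::xml_attr(r, "id")
    refs <- xml2::xml_attr(xml2::xml_find_all(
      r, ".//s:speciesReference | .//s:modifierSpeciesReference",
      ns = c(s = .SBML_NS)), "species")
    bad <- setdiff(refs, imp$species$id)
    if (length(bad))
      errs <- c(errs, sprintf("reaction %s references undeclared species: %s",
                              rid, paste(bad, collapse = ", ")))
    cis <- xml2::xml_text(xml2::xml_find_all(
      r, ".//m:math//m:ci", ns = c(m = .MATHML_NS)))
    bad <- setdiff(trimws(cis), known)
    if (length(bad))
      errs <- c(errs, sprintf("reaction %s kinetic law has unresolved symbols: %s",
                              rid, paste(bad, collapse = ", ")))
  }
  errs
}

#' Enlarge an SBML document with species, reactions and parameters
#'
#' Generic SBML surgery: inserts user-defined lists of species, global
#' parameters and reactions into an existing document, so any SBML model can
#' be expanded with externally generated model elements. Identifier
#' collisions raise an error unless \code{merge = TRUE}, in which case the
#' colliding entries are skipped; a reaction referencing a species that is
#' neither present nor being added names the species in its error.
#'
#' @param x file path or \pkg{xml2} document (modified in place when a
#'   document is passed; a fresh document is returned when a path is given).
#' @param species data.frame with id, compartment, initialConcentration.
#' @param reactions list of lists with elements id, reactants, products
#'   (named numeric stoichiometry vectors or character vectors), optional
#'   modifiers, and formula (kinetic-law string).
#' @param parameters data.frame with id, value.
#' @param merge skip colliding identifiers instead of failing.
#' @return the enlarged \pkg{xml2} document.
#' @export
enlargeSBML <- function(x, species = NULL, reactions = NULL,
                        parameters = NULL, merge = FALSE) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  imp <- importSBML(doc)
  existing <- c(imp$compartments$id, imp$species$id, imp$parameters$id,
                imp$reactions$id)
  listNode <- function(tag) {
    node <- .sbmlFind(doc, sprintf(".//s:%s", tag))
    if (length(node)) return(node[[1]])
    parent <- .sbmlFind(doc, ".//s:model")[[1]]
    addInNamespace(parent, sprintf("<%s/>", tag))
    .sbmlFind(doc, sprintf(".//s:%s", tag))[[1]]
  }
  ## insert serialized XML so new nodes land in the SBML namespace
  addInNamespace <- function(parent, xmlString) {
    node <- xml2::read_xml(paste0('<dummy xmlns="', .SBML_NS, '">',
                                  xmlString, "</dummy>"))
    xml2::xml_add_child(parent, xml2::xml_child(node, 1))
  }
  asStoich <- function(v) {
    if (is.character(v)) setNames(rep(1, length(v)), v)
    else v
  }
  newSpeciesIds <- character(0)
  if (!is.null(species) && nrow(species)) {
    clash <- intersect(species$id, existing)
    if (length(clash) && !merge)
      stop("identifier collision (use merge = TRUE to skip): ",
           paste(clash, collapse = ", "))
    keep <- !(species$id %in% clash)
    ln <- listNode("listOfSpecies")
    for (i in which(keep)) {
      addInNamespace(ln, sprintf(
        paste0('<species id="%s" compartment="%s" initialConcentration="%s" ',
               'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
               'constant="false"/>'),
        species$id[i], species$compartment[i],
        format(species$initialConcentration[i], digits = 17)))
    }
    newSpeciesIds <- species$id[keep]
  }
  if (!is.null(parameters) && nrow(parameters)) {
    clash <- intersect(parameters$id, c(existing, newSpeciesIds))
    if (length(clash) && !merge)
      stop("identifier collision (use merge = TRUE to skip): ",
           paste(clash, collapse = ", "))
    ln <- listNode("listOfParameters")
    for (i in which(!(parameters$id %in% clash))) {
      addInNamespace(ln, sprintf('<parameter id="%s" value="%s" constant="true"/>',
                                 parameters$id[i],
                                 format(parameters$value[i], digits = 17)))
    }
  }
  if (!is.null(reactions) && length(reactions)) {
    knownSpecies <- c(imp$species$id, newSpeciesIds)
    ln <- listNode("listOfReactions")
    for (rx in reactions) {
      if (rx$id %in% existing) {
        if (merge) next
        stop("identifier collision (use merge = TRUE to skip): ", rx$id)
      }
      re <- asStoich(rx$reactants %||% numeric(0))
      pr <- asStoich(rx$products %||% numeric(0))
      mods <- rx$modifiers %||% character(0)
      bad <- setdiff(c(names(re), names(pr), mods), knownSpecies)
      if (length(bad))
        stop(sprintf("reaction %s references missing species: %s", rx$id,
                     paste(bad, collapse = ", ")))
      addInNamespace(ln, .reactionXML(rx$id, re, pr, mods, rx$formula))
    }
  }
  doc
}
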