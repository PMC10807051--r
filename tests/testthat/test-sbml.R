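test_that("SBML export round-trips counts and values and passes validation", {
  m <- toy3()$model
  path <- withr::local_tempfile(fileext = ".xml")
  suppressMessages(exportSBML(m, path))
  expect_length(validateSBML(path), 0)
  imp <- importSBML(path)
  expect_equal(nrow(imp$species), nrow(speciesTable(m)))
  # one reaction per rate law plus transcription + mRNA decay per gene
  expect_equal(nrow(imp$reactions),
               nrow(rateLaws(m)) + 2 * nrow(geneTable(m)))
  expect_equal(imp$species$initialConcentration,
               speciesTable(m)$initial_nM, tolerance = 1e-15)
  expect_equal(imp$compartments$size, compartments(m)$volume,
               tolerance = 1e-15)
  # every expansion half-maximal constant appears as a parameter, exactly
  tr <- tarTable(m)
  kaIds <- sprintf("KA_%s_%s", tr$regulator, tr$target_gene)
  idx <- match(kaIds, imp$parameters$id)
  expect_false(anyNA(idx))
  expect_equal(imp$parameters$value[idx], tr$K_A, tolerance = 1e-15)
})

test_that("exported Hill kinetic law halves its contribution at K_A", {
  # evaluate the transcription kinetic law of a regulated gene symbolically
  # from the SBML MathML, at regulator = K_A and regulator = 0
  m <- toy3()$model
  doc <- suppressMessages(exportSBML(m))
  tr <- tarTable(m)
  tr <- tr[tr$sign == "activator", ][1, ]
  rxn <- xml2::xml_find_first(
    doc, sprintf(".//s:reaction[@id='vTC_%s']", tr$target_gene),
    ns = c(s = "http://www.sbml.org/sbml/level3/version2/core"))
  expect_false(inherits(rxn, "xml_missing"))
  mathToExpr <- function(node) {
    name <- xml2::xml_name(node)
    kids <- xml2::xml_children(node)
    switch(name,
           math = mathToExpr(kids[[1]]),
           ci = as.name(trimws(xml2::xml_text(node))),
           cn = as.numeric(xml2::xml_text(node)),
           apply = {
             op <- xml2::xml_name(kids[[1]])
             fn <- switch(op, plus = "+", minus = "-", times = "*",
                          divide = "/", power = "^")
             args <- lapply(kids[-1], mathToExpr)
             as.call(c(as.name(fn), args))
           },
           stop("unexpected MathML node: ", name))
  }
  math <- xml2::xml_find_first(
    rxn, ".//m:math", ns = c(m = "http://www.w3.org/1998/Math/MathML"))
  expr <- mathToExpr(math)
  imp <- importSBML(doc)
  env <- as.environment(as.list(setNames(imp$parameters$value,
                                         imp$parameters$id)))
  parent.env(env) <- baseenv()
  for (sp in imp$species$id) assign(sp, 0, envir = env)
  base <- eval(expr, env)              # all regulators absent: basal flux
  assign(tr$regulator, tr$K_A, envir = env)
  atKA <- eval(expr, env)
  assign(tr$regulator, 1e12, envir = env)
  sat <- eval(expr, env)
  # activator at its half-max adds half its saturating contribution
  expect_equal(atKA - base, (sat - base) / 2, tolerance = 1e-9)
})

test_that("SBML enlargement adds exactly the requested elements", {
  m <- toy3()$base
  path <- withr::local_tempfile(fileext = ".xml")
  suppressMessages(exportSBML(m, path))
  before <- importSBML(path)
  doc <- enlargeSBML(path,
                     species = data.frame(id = c("X1", "X2"),
                                          compartment = "Cell",
                                          initialConcentration = c(1, 2)),
                     parameters = data.frame(id = "k_new", value = 0.5),
                     reactions = list(list(id = "v_new", reactants = "X1",
                                           products = "X2",
                                           formula = "k_new * X1")))
  after <- importSBML(doc)
  expect_equal(nrow(after$species), nrow(before$species) + 2)
  expect_equal(nrow(after$reactions), nrow(before$reactions) + 1)
  expect_equal(nrow(after$parameters), nrow(before$parameters) + 1)
  expect_length(validateSBML(doc), 0)

  # adding nothing changes nothing
  doc2 <- enlargeSBML(path)
  expect_equal(importSBML(doc2), before)

  # collisions error unless merged; missing species are named
  expect_error(enlargeSBML(path, species = data.frame(
    id = before$species$id[1], compartment = "Cell",
    initialConcentration = 1)), "collision")
  expect_error(enlargeSBML(path, reactions = list(list(
    id = "v_bad", reactants = "GHOST", products = character(0),
    formula = "1"))), "GHOST")
})

test_that("empty models cannot be exported and bad identifiers are sanitized", {
  expect_error(exportSBML(new("MechModel")), "no compartments")
  m <- toy3()$base
  m@species$species[1] <- "EGF-ligand"
  m@ratelaws$formula <- gsub("\\bEGF\\b", "`EGF-ligand`", m@ratelaws$formula)
  m@ratelaws$reactants <- gsub("^EGF$", "EGF-ligand", m@ratelaws$reactants)
  m@ratelaws$products <- gsub("^EGF$", "EGF-ligand", m@ratelaws$products)
  m@species$annotation[1] <- "renamed to exercise sanitization"
  # identifier with a dash must be mapped to an SBML-safe id with a message
  expect_message(doc <- exportSBML(m), "sanitized")
  imp <- importSBML(doc)
  expect_true("EGF_ligand" %in% imp$species$id)
  expect_length(validateSBML(doc), 0)
})
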