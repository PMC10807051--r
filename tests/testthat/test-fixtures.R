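test_that("toy base models are valid, reproducible and steady by construction", {
  spec <- toySpec(nBaseGenes = 3, seed = 21)
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  mA <- suppressMessages(makeToyBaseModel(spec, dirA))
  mB <- suppressMessages(makeToyBaseModel(spec, dirB))
  expect_true(validObject(mA))
  expect_equal(nrow(geneTable(mA)), 3)
  # same seed: byte-identical table files
  for (f in list.files(dirA)) {
    expect_identical(readLines(file.path(dirA, f)),
                     readLines(file.path(dirB, f)))
  }
  # fixture parses back through the reader without warnings
  expect_no_warning(m2 <- suppressMessages(readModelTables(dirA)))
  expect_equal(modelCounts(m2), modelCounts(mA))
  # consistency by construction: no-ligand simulation is steady at 1%
  tc <- simulateModel(mA, hours = 48, nOut = 13)
  expect_true(all(steadyStateCheck(tc, relTol = 0.01)))
})

test_that("toy networks have the requested shape and determinism", {
  spec <- toySpec(nNewGenes = 8, nEdges = 14, seed = 33)
  path <- withr::local_tempfile(fileext = ".tsv")
  net <- makeToyNetwork(spec, path)
  # mirrors the nine-gene / fourteen-connection case-study shape
  expect_length(nodes(net), 9)
  expect_equal(nrow(edges(net)), 14)
  expect_true("STAT1" %in% nodes(net))
  # file round trip reproduces the network
  net2 <- loadAssociationEdges(path)
  expect_equal(edges(net2), edges(net), tolerance = 1e-15)
  # determinism and seed sensitivity
  expect_equal(edges(makeToyNetwork(spec)), edges(net))
  expect_false(isTRUE(all.equal(
    edges(makeToyNetwork(toySpec(nNewGenes = 8, nEdges = 14, seed = 34))),
    edges(net))))
  # sign fractions at the extremes
  allAct <- makeToyNetwork(toySpec(nNewGenes = 5, nEdges = 8, seed = 1,
                                   fracNegative = 0))
  expect_true(all(edges(allAct)$coefficient > 0))
  allRep <- makeToyNetwork(toySpec(nNewGenes = 5, nEdges = 8, seed = 1,
                                   fracNegative = 1))
  expect_true(all(edges(allRep)$coefficient < 0))
  expect_error(toySpec(nNewGenes = 2, nEdges = 50), "nEdges")
})

test_that("synthetic omics stay in range, are reproducible and complete", {
  genes <- paste0("G", 1:40)
  om <- makeSyntheticOmics(genes, seed = 9, phosphoGenes = c("G1", "G2"))
  expect_true(all(om$mRNA_mpc >= 1 & om$mRNA_mpc <= 1000))
  expect_true(all(om$protein_nM >= 0.01 & om$protein_nM <= 1000))
  expect_true(all(om$mRNA_half_life_h >= 1 & om$mRNA_half_life_h <= 24))
  expect_true(all(om$protein_half_life_h >= 10 & om$protein_half_life_h <= 100))
  expect_true(all(om$copy_number == 2))
  expect_equal(sum(!is.na(om$phospho_nM)), 2)
  expect_identical(makeSyntheticOmics(genes, seed = 9,
                                      phosphoGenes = c("G1", "G2")), om)
  # feeding complete omics into expansion uses no defaults
  expect_equal(nrow(toy3()$report@defaultsUsed), 0)
})

test_that("ground-truth time courses sit on the model trajectory when noise-free", {
  fx <- toy3()
  conds <- stimulationConditions()
  gt <- makeGroundTruthTimeCourses(fx$model, conditions = conds,
                                   preEquilibrateHours = 0)
  expect_setequal(unique(gt$data$condition), names(conds))
  expect_equal(unique(gt$data$time_h), c(0, 1, 4, 8, 24, 48))
  # fold change at time zero is one by definition
  expect_equal(gt$data$value[gt$data$time_h == 0],
               rep(1, sum(gt$data$time_h == 0)))
  # noise-free data reproduce the simulated fold changes exactly
  sims <- GRNexpand:::.simulateConditions(fx$model, conds, hours = 48,
                                          preEquilibrateHours = 0, nOut = 49)
  expect_equal(timeCourseSSE(sims, gt$data), 0, tolerance = 1e-12)
  # noise changes values but not the shape; two seeds differ
  gtN1 <- makeGroundTruthTimeCourses(fx$model, conditions = conds,
                                     noiseCV = 0.05, seed = 1,
                                     preEquilibrateHours = 0)
  gtN2 <- makeGroundTruthTimeCourses(fx$model, conditions = conds,
                                     noiseCV = 0.05, seed = 2,
                                     preEquilibrateHours = 0)
  expect_equal(dim(gtN1$data), dim(gt$data))
  expect_false(isTRUE(all.equal(gtN1$data$value, gtN2$data$value)))
  expect_gt(timeCourseSSE(sims, gtN1$data), 0)
})
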