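# Shared fixtures, built once per test run. All inputs are generated in code
# from fixed seeds; nothing is downloaded or stored binary.

.fixtureCache <- new.env(parent = emptyenv())

.memo <- function(key, build) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, build(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# multiplicative spacing between neighboring values of the default
# 15-point / 3-decade grid
gridStepFactor <- 10^(3 / 14)

# Small expanded system: 3-gene base + 3 new genes, 4 edges (8 TARs).
toy3 <- function() .memo("toy3", function() {
  spec <- toySpec(nNewGenes = 3, nEdges = 4, seed = 7)
  base <- suppressMessages(makeToyBaseModel(spec))
  net <- makeToyNetwork(spec)
  omics <- makeSyntheticOmics(nodes(net), seed = 11)
  ex <- suppressMessages(expandModel(base, net, omics))
  list(spec = spec, base = base, net = net, omics = omics,
       model = ex$model, report = ex$report)
})

# Expansion mirroring the interferon / immune-checkpoint case study shape:
# base model containing STAT1, nine-gene / fourteen-edge candidate network.
paperShape <- function() .memo("paperShape", function() {
  base <- suppressMessages(makeToyBaseModel(toySpec(seed = 1)))
  path <- system.file("extdata", "irf1_pdl1_associations_synthetic.tsv",
                      package = "GRNexpand")
  net <- loadAssociationEdges(path)
  netF <- filterToSeeds(net, c("IRF1", "CD274", "PDCD1", "STAT1"))
  omics <- makeSyntheticOmics(nodes(netF), seed = 42)
  ex <- suppressMessages(expandModel(base, netF, omics))
  list(base = base, net = net, netFiltered = netF, omics = omics,
       model = ex$model, report = ex$report)
})

# Network object from an in-memory edge table (for parameterized cases).
netFromEdges <- function(g1, g2, coefficient) {
  new("AssociationNetwork",
      edges = data.frame(gene1 = g1, gene2 = g2, coefficient = coefficient,
                         stringsAsFactors = FALSE))
}

writeEdgeFile <- function(lines, header = TRUE) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(if (header) "gene1\tgene2\tcoefficient", lines), path)
  path
}
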