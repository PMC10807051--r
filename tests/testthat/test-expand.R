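test_that("gene entities are created with consistent rates and species", {
  base <- toy3()$base
  om <- makeSyntheticOmics(c("NEWG"), seed = 3)
  res <- makeGeneEntities(base, "NEWG", om)
  m <- res$model
  expect_setequal(res$speciesAdded, c("m_NEWG", "p_NEWG"))
  expect_length(res$ratelawsAdded, 2)
  expect_equal(nrow(res$defaultsUsed), 0)   # omics complete, no fallbacks
  g <- geneTable(m)[geneTable(m)$gene == "NEWG", ]
  omr <- om[om$gene == "NEWG", ]
  vol <- compartments(m)$volume[1]
  # designed fixed point: mRNA* = mRNA_count, protein* = protein_nM
  aEq <- g$copy_number * g$kG_ac / (g$kG_ac + g$kG_in)
  mStar <- aEq * g$kTC_basal / g$kTCd            # molecules per cell
  expect_equal(mStar, omr$mRNA_mpc, tolerance = 1e-12)
  p <- GRNexpand:::.parseParams(
    rateLaws(m)$parameters[rateLaws(m)$ratelaw == "vTL_NEWG"])
  pd <- GRNexpand:::.parseParams(
    rateLaws(m)$parameters[rateLaws(m)$ratelaw == "vPD_NEWG"])
  pStar <- p[["kTL_NEWG"]] * mpcToNM(mStar, vol) / pd[["kTLd_NEWG"]]
  expect_equal(pStar, omr$protein_nM, tolerance = 1e-12)

  # already-present gene is a no-op with a message
  expect_message(res2 <- makeGeneEntities(m, "NEWG", om), "already in model")
  expect_equal(modelCounts(res2$model), modelCounts(m))

  # phosphoprotein measurements add a third species
  om2 <- makeSyntheticOmics("PGENE", seed = 4, phosphoGenes = "PGENE")
  res3 <- makeGeneEntities(base, "PGENE", om2)
  expect_setequal(res3$speciesAdded, c("m_PGENE", "p_PGENE", "pp_PGENE"))

  # missing omics fields fall back to model means and are logged
  om3 <- om
  om3$protein_half_life_h <- NA
  res4 <- makeGeneEntities(base, "NEWG", om3)
  expect_equal(res4$defaultsUsed$field, "protein_half_life_h")
})

test_that("edges become two directed TARs each, with sign, K_A and n_A rules", {
  m <- toy3()$base
  om <- makeSyntheticOmics(c("GA", "GB"), seed = 5)
  for (g in c("GA", "GB")) m <- makeGeneEntities(m, g, om)$model
  net <- netFromEdges("GA", "GB", 0.4)
  res <- edgesToTARs(net, m)
  expect_equal(nrow(res$tars), 2)
  expect_setequal(paste(res$tars$regulator, res$tars$target_gene),
                  c("p_GA GB", "p_GB GA"))
  expect_true(all(res$tars$sign == "activator"))
  expect_true(all(res$tars$n_A == 4))
  sp <- speciesTable(m)
  expect_equal(res$tars$K_A,
               sp$initial_nM[match(res$tars$regulator, sp$species)] / 2)

  # negative edge yields mutual repression
  resNeg <- edgesToTARs(netFromEdges("GA", "GB", -0.4), m)
  expect_true(all(resNeg$tars$sign == "repressor"))

  # self-association: the two candidates are identical; one collapses,
  # a single autoregulation remains
  resSelf <- edgesToTARs(netFromEdges("GA", "GA", 0.2), m)
  expect_equal(nrow(resSelf$tars), 1)
  expect_equal(resSelf$dropped$reason, "duplicate")
  # drop policy removes autoregulation entirely
  resDrop <- edgesToTARs(netFromEdges("GA", "GA", 0.2), m,
                         selfRegulation = "drop")
  expect_equal(nrow(resDrop$tars), 0)
  expect_equal(nrow(resDrop$dropped), 2)

  expect_error(edgesToTARs(netFromEdges("GA", "GHOST", 1), m), "GHOST")
})

test_that("expansion counts are additive, provenanced and idempotent", {
  fx <- toy3()
  rep <- fx$report
  pre <- modelCounts(fx$base); post <- modelCounts(fx$model)
  expect_equal(rep@genesAdded, unname(post["genes"] - pre["genes"]))
  expect_equal(rep@speciesAdded, unname(post["species"] - pre["species"]))
  expect_equal(rep@ratelawsAdded, unname(post["ratelaws"] - pre["ratelaws"]))
  expect_equal(rep@tarsAdded, unname(post["tars"] - pre["tars"]))
  # count arithmetic from the network shape
  nNew <- length(setdiff(nodes(fx$net), geneTable(fx$base)$gene))
  expect_equal(rep@genesAdded, nNew)
  expect_equal(rep@speciesAdded, 2L * nNew)
  expect_equal(rep@ratelawsAdded, 2L * nNew)
  expect_equal(rep@tarsAdded,
               2L * nrow(edges(fx$net)) - nrow(rep@dropped))
  # every added entity has provenance
  expect_equal(nrow(rep@provenance),
               rep@genesAdded + rep@speciesAdded + rep@ratelawsAdded +
                 rep@tarsAdded)
  expect_equal(nrow(rep@defaultsUsed), 0)

  # second application adds nothing
  ex2 <- suppressMessages(expandModel(fx$model, fx$net, fx$omics))
  expect_equal(ex2$report@genesAdded, 0L)
  expect_equal(ex2$report@speciesAdded, 0L)
  expect_equal(ex2$report@tarsAdded, 0L)
  expect_equal(modelCounts(ex2$model), modelCounts(fx$model))

  # empty network: zero-delta report
  ex0 <- expandModel(fx$base, new("AssociationNetwork"))
  expect_equal(ex0$report@genesAdded, 0L)
  expect_equal(ex0$report@tarsAdded, 0L)
})

test_that("all created rate constants are finite and non-negative", {
  g <- geneTable(toy3()$model)
  expect_true(all(is.finite(g$kTC_basal) & g$kTC_basal >= 0))
  expect_true(all(is.finite(g$kTCd) & g$kTCd >= 0))
  tr <- tarTable(toy3()$model)
  expect_true(all(is.finite(tr$K_A) & tr$K_A > 0))
  for (p in rateLaws(toy3()$model)$parameters) {
    v <- GRNexpand:::.parseParams(p)
    expect_true(all(is.finite(v) & v >= 0))
  }
})

test_that("the calibration inventory pairs interactions with degradation rates", {
  fx <- toy3()
  inv <- calibrationInventory(fx$model)
  nTars <- sum(tarTable(fx$model)$origin == "expansion")
  nGenes <- sum(geneTable(fx$model)$origin == "expansion")
  expect_equal(sum(inv$type == "K_A"), nTars)
  expect_equal(sum(inv$type == "kTCd"), nGenes)
  expect_equal(sum(inv$type == "kTLd"), nGenes)
  expect_equal(nrow(inv), nTars + 2 * nGenes)
  expect_true(all(is.finite(inv$value) & inv$value > 0))
  # base model alone has no free parameters
  expect_equal(nrow(calibrationInventory(fx$base)), 0)
})
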