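test_that("transcription flux combines basal, activator and repressor terms", {
  m <- toy3()$model
  tr <- tarTable(m)
  g <- tr$target_gene[tr$sign == "activator" & tr$origin == "expansion"][1]
  gi <- geneTable(m)[geneTable(m)$gene == g, ]
  state <- setNames(speciesTable(m)$initial_nM, speciesTable(m)$species)
  tg <- tr[tr$target_gene == g, ]
  aEq <- gi$copy_number * gi$kG_ac / (gi$kG_ac + gi$kG_in)
  # no regulators present: purely basal
  state0 <- state; state0[tg$regulator] <- 0
  expect_equal(transcriptionFlux(g, m, state0), aEq * gi$kTC_basal,
               tolerance = 1e-12)
  # single activator exactly at K_A multiplies the basal flux by 1.5
  act <- tg[tg$sign == "activator", ][1, ]
  state1 <- state0; state1[act$regulator] <- act$K_A
  others <- setdiff(tg$regulator, act$regulator)
  state1[others] <- 0
  expect_equal(transcriptionFlux(g, m, state1),
               aEq * gi$kTC_basal * 1.5, tolerance = 1e-12)
  # saturating repressor silences transcription
  gRep <- tr$target_gene[tr$sign == "repressor"][1]
  if (!is.na(gRep)) {
    tgR <- tr[tr$target_gene == gRep, ]
    stateR <- state; stateR[tgR$regulator] <- 0
    rep1 <- tgR[tgR$sign == "repressor", ][1, ]
    stateR[rep1$regulator] <- 1e9
    expect_lt(transcriptionFlux(gRep, m, stateR),
              1e-6 * transcriptionFlux(gRep, m, setNames(
                rep(0, length(stateR)), names(stateR))))
  }
  expect_error(transcriptionFlux(g, m, state - 1e3), "non-negative")
  expect_error(transcriptionFlux("GHOST", m, state), "unknown gene")
})

test_that("the no-ligand fixed point matches the omics inputs analytically and numerically", {
  fx <- toy3()
  m <- fx$model
  tc <- simulateModel(m, hours = 48, nOut = 25)
  # closed-form fixed point vs integration, every species
  drift <- GRNexpand:::.relDrift(tc, colnames(tcValues(tc)))
  expect_lt(max(drift), 1e-6)
  # mRNA steady states equal the measured molecule counts
  g <- geneTable(m)
  vol <- compartments(m)$volume[1]
  mStarNM <- tcValues(tc)[nrow(tcValues(tc)), g$mRNA_species]
  expect_equal(unname(nMToMpc(mStarNM, vol)), g$mRNA_count,
               tolerance = 1e-6)
  omr <- omicsTable(m)
  pStar <- tcValues(tc)[nrow(tcValues(tc)), g$protein_species]
  expect_equal(unname(pStar), omr$protein_nM[match(g$gene, omr$gene)],
               tolerance = 1e-6)
})

test_that("ligand dosing produces a transient rise and decay of the active TF", {
  m <- toy3()$model
  tc <- simulateModel(m, hours = 48,
                      doses = rbind(doseSpec("EGF", 1.5625),
                                    doseSpec("IFNG", 1.1834)), nOut = 97)
  a <- tcValues(tc)[, "aSTAT1"]
  expect_gt(max(a), a[1])                    # rises above baseline
  expect_lt(a[length(a)], max(a))            # and decays from the peak
  # trajectories stay non-negative within solver tolerance
  expect_true(all(tcValues(tc) >= 0))
  # a late-onset dose is applied as a solver event
  tc2 <- simulateModel(m, hours = 10, nOut = 101,
                       doses = doseSpec("IFNG", 1.1834, onset = 5 * 3600))
  i <- tcValues(tc2)[, "IFNG"]
  expect_equal(max(i[tcTimes(tc2) < 5 * 3600]), 0)
  expect_gt(max(i[tcTimes(tc2) >= 5 * 3600]), 1)
  expect_error(simulateModel(m, hours = 1, doses = doseSpec("GHOST", 1)),
               "GHOST")
})

test_that("simulation is deterministic and consistent across output grids", {
  m <- toy3()$model
  doses <- doseSpec("IFNG", 1.1834)
  tcA <- simulateModel(m, hours = 24, doses = doses, nOut = 49)
  tcB <- simulateModel(m, hours = 24, doses = doses, nOut = 49)
  expect_identical(tcValues(tcA), tcValues(tcB))
  # doubling the output resolution leaves shared time points unchanged
  tcC <- simulateModel(m, hours = 24, doses = doses, nOut = 97)
  shared <- match(tcTimes(tcA), tcTimes(tcC))
  expect_false(anyNA(shared))
  rel <- abs(tcValues(tcC)[shared, ] - tcValues(tcA)) /
    pmax(abs(tcValues(tcA)), 1e-6)
  expect_lt(max(rel), 1e-5)
})

test_that("steady-state checks use inclusive relative drift", {
  flat <- new("TimeCourse", times = c(0, 3600),
              values = matrix(c(5, 5, 2, 2), 2, 2,
                              dimnames = list(NULL, c("A", "B"))),
              provenance = list())
  expect_true(all(steadyStateCheck(flat)))
  # exponential decay with short half-life fails
  tt <- seq(0, 48 * 3600, length.out = 25)
  dec <- new("TimeCourse", times = tt,
             values = matrix(exp(-tt / 3600), ncol = 1,
                             dimnames = list(NULL, "A")),
             provenance = list())
  expect_false(steadyStateCheck(dec, "A"))
  # boundary drift is inclusive
  bnd <- new("TimeCourse", times = c(0, 3600),
             values = matrix(c(1, 1.01), 2, 1,
                             dimnames = list(NULL, "A")),
             provenance = list())
  expect_true(steadyStateCheck(bnd, "A", relTol = 0.01))
  expect_error(steadyStateCheck(flat, "GHOST"), "GHOST")
})
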