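mkTC <- function(times_h, values) {
  new("TimeCourse", times = times_h * 3600, values = values,
      provenance = list())
}

test_that("the SSE objective is zero on itself, quadratic, and additive", {
  v <- matrix(c(2, 4, 6), ncol = 1, dimnames = list(NULL, "m_X"))
  tc <- mkTC(c(0, 1, 2), v)
  dataExact <- data.frame(condition = "EGF", species = "m_X",
                          time_h = c(0, 1, 2), value = c(1, 2, 3))
  expect_equal(timeCourseSSE(list(EGF = tc), dataExact), 0)
  # one observable, one time point, difference 2 -> 4
  d1 <- data.frame(condition = "EGF", species = "m_X", time_h = 1, value = 4)
  expect_equal(timeCourseSSE(list(EGF = tc), d1), 4)
  # additivity over conditions
  d2 <- rbind(dataExact,
              data.frame(condition = "B", species = "m_X", time_h = 1,
                         value = 5))
  sims <- list(EGF = tc, B = tc)
  expect_equal(timeCourseSSE(sims, d2),
               timeCourseSSE(list(EGF = tc), dataExact) +
                 timeCourseSSE(list(B = tc),
                               d2[d2$condition == "B", ]))
  # interpolation between simulated points
  dH <- data.frame(condition = "EGF", species = "m_X", time_h = 0.5,
                   value = 1.5)
  expect_equal(timeCourseSSE(list(EGF = tc), dH), 0)
  # observable mapping and error paths
  dObs <- data.frame(condition = "EGF", observable = "X", time_h = 1,
                     value = 2)
  expect_equal(timeCourseSSE(list(EGF = tc), dObs, mapping = c(X = "m_X")), 0)
  expect_error(timeCourseSSE(list(EGF = tc), dObs), "mapping")
  dOut <- data.frame(condition = "EGF", species = "m_X", time_h = 99,
                     value = 1)
  expect_error(timeCourseSSE(list(EGF = tc), dOut), "outside")
})

test_that("consistently initialized genes are skipped by the basal-rate fit", {
  fb <- suppressMessages(fitBasalRates(toy3()$model))
  tb <- fitTable(fb$fits)
  expect_equal(nrow(tb), 3)
  expect_true(all(tb$skipped))
  expect_equal(geneTable(fb$model)$kTC_basal, geneTable(toy3()$model)$kTC_basal)
})

test_that("a perturbed basal rate is recovered within one grid step", {
  fx <- toy3()
  m <- fx$model
  gi <- which(geneTable(m)$origin == "expansion")[2]
  g <- geneTable(m)$gene[gi]
  true <- geneTable(m)$kTC_basal[gi]
  m@genes$kTC_basal[gi] <- true * 10
  fb <- suppressWarnings(fitBasalRates(m))
  tb <- fitTable(fb$fits)
  chosen <- tb$chosen[tb$parameter == sprintf("kTC_basal[%s]", g)]
  expect_lte(abs(log10(chosen / true)), log10(gridStepFactor) + 1e-9)
  # the fitted gene's drift objective decreased from its unfitted value
  row <- tb[tb$parameter == sprintf("kTC_basal[%s]", g), ]
  expect_false(row$skipped)
  expect_lt(row$objective, row$objectiveAtDefault)
})

test_that("fitting order is irrelevant for dynamically uncoupled genes", {
  base <- toy3()$base
  om <- makeSyntheticOmics(c("UA", "UB"), seed = 13)
  m <- base
  for (g in c("UA", "UB"))
    m <- makeGeneEntities(m, g, om)$model
  m@genes$origin[m@genes$gene %in% c("UA", "UB")] <- "expansion"
  # no TARs between them: block-diagonal dynamics
  i <- match(c("UA", "UB"), m@genes$gene)
  m@genes$kTC_basal[i] <- m@genes$kTC_basal[i] * c(10, 0.1)
  fwd <- suppressWarnings(fitBasalRates(m, order = c("UA", "UB")))
  rev <- suppressWarnings(fitBasalRates(m, order = c("UB", "UA")))
  expect_equal(geneTable(fwd$model)$kTC_basal,
               geneTable(rev$model)$kTC_basal, tolerance = 1e-12)
})

test_that("flat SSE profiles keep the default value by tie-breaking", {
  # a TAR whose regulator never moves: identical data under both conditions
  fx <- toy3()
  m <- fx$model
  tars <- tarTable(m)
  id <- paste0(tars$regulator, "->", tars$target_gene)
  # constant fold-change data for an unrelated base species
  d <- data.frame(condition = rep(c("EGF", "EGF+IFNG"), each = 2),
                  species = "p_BGENE2", time_h = c(0, 10, 0, 10), value = 1)
  conds <- list("EGF" = NULL, "EGF+IFNG" = NULL)  # no dosing at all
  pick <- which(tars$origin == "expansion")[1]
  fit <- fitKA(m, d, conds, order = id[pick], preEquilibrateHours = 0,
               nOut = 11)
  tb <- fitTable(fit$fits)
  expect_equal(tb$chosen, tb$default)   # insensitive parameter stays put
})
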