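test_that("degradation rates are ln(2) over the half-life", {
  # unit half-life: ln2 per hour, 1.92541e-4 per second
  expect_equal(mrnaDegradationRate(1) * 3600, log(2), tolerance = 1e-12)
  expect_equal(mrnaDegradationRate(1), 1.92541e-4, tolerance = 1e-5)
  expect_equal(mrnaDegradationRate(9) * 3600, 0.0770164, tolerance = 1e-5)
  expect_equal(proteinDegradationRate(46) * 3600, 0.0150684, tolerance = 1e-5)
  expect_equal(proteinDegradationRate(log(2)) * 3600, 1.0, tolerance = 1e-12)
  # doubling the half-life halves the rate
  withr::with_seed(2, {
    hl <- exp(runif(200, log(0.1), log(100)))
    expect_equal(mrnaDegradationRate(2 * hl), mrnaDegradationRate(hl) / 2,
                 tolerance = 1e-12)
  })
  expect_error(mrnaDegradationRate(0), "positive")
  expect_error(proteinDegradationRate(-1), "positive")
})

test_that("basal transcription rate hits the printed worked examples", {
  # symmetric on/off cancels: (0.1*10)*(2k)/(k*2) = 1
  expect_equal(basalTranscriptionRate(0.1, 10, 0.3, 0.3, 2), 1.0,
               tolerance = 1e-12)
  # always-on gene limit
  expect_equal(basalTranscriptionRate(0.1, 10, 0, 0.3, 2), 0.1 * 10 / 2,
               tolerance = 1e-12)
  expect_equal(basalTranscriptionRate(0.05, 17, 0.02, 0.01, 2), 1.275,
               tolerance = 1e-12)
  expect_error(basalTranscriptionRate(0.1, 10, 0.1, 0, 2), "kG_ac")
  expect_error(basalTranscriptionRate(0.1, 10, 0.1, 0.1, 0), "copy number")
})

test_that("translation rate fixes the protein steady state", {
  expect_equal(translationRate(100, 0.1, 10), 1.0, tolerance = 1e-12)
  expect_equal(translationRate(0, 0.1, 10), 0)
  expect_equal(translationRate(0, 0.1, 0), 0)  # no protein, no translation
  expect_equal(translationRate(3.4, 0.0151, 0.002), 25.67, tolerance = 1e-4)
  expect_error(translationRate(5, 0.1, 0), "mRNA")
})

test_that("mpc/nM conversions are exact inverses through the volume", {
  # 602214 molecules in a 1 pL cell is 1 micromolar, i.e. 1000 nM
  expect_equal(mpcToNM(602214, 1e-12), 1000, tolerance = 1e-6)
  expect_equal(mpcToNM(602.214076, 1e-12), 1.0, tolerance = 1e-6)
  expect_equal(mpcToNM(6.02214076e23 * 1e-12 * 1e-9, 1e-12), 1.0,
               tolerance = 1e-12)
  withr::with_seed(3, {
    n <- exp(runif(500, log(1e-3), log(1e9)))
    v <- exp(runif(500, log(1e-15), log(1e-9)))
    expect_equal(nMToMpc(mpcToNM(n, v), v), n, tolerance = 1e-12)
  })
  expect_error(mpcToNM(1, 0), "volume")
})

test_that("Hill fraction has the canonical landmarks and monotonicity", {
  expect_equal(hillActivation(1, 1, 4), 0.5, tolerance = 1e-12)
  expect_equal(hillActivation(5, 5, 1.7), 0.5, tolerance = 1e-12)
  expect_equal(hillActivation(0, 3, 4), 0)
  expect_equal(hillActivation(2, 1, 4), 16 / 17, tolerance = 1e-12)
  withr::with_seed(4, {
    for (i in 1:20) {
      K <- exp(runif(1, log(0.01), log(100)))
      n <- runif(1, 1, 6)
      x <- sort(exp(runif(50, log(1e-3), log(1e3))))
      h <- hillActivation(x, K, n)
      expect_true(all(diff(h) >= 0) && all(h >= 0 & h <= 1))
      # strictly increasing away from numerical saturation
      xs <- seq(K / 10, 10 * K, length.out = 25)
      expect_true(all(diff(hillActivation(xs, K, n)) > 0))
    }
  })
  expect_error(hillActivation(1, 0, 4), "positive")
  expect_error(hillActivation(1, 1, 0.5), "Hill coefficient")
})

test_that("the log grid spans three decades symmetrically around the default", {
  g <- logGrid(1.0)
  expect_length(g, 15)
  expect_equal(min(g), 0.0316228, tolerance = 1e-6)
  expect_equal(max(g), 31.6228, tolerance = 1e-6)
  expect_true(all(diff(g) > 0))
  # symmetric in log space: values[i] * values[n+1-i] = default^2
  withr::with_seed(5, {
    for (d in exp(runif(10, log(1e-6), log(1e3)))) {
      g <- logGrid(d, decades = 3, points = 15)
      expect_equal(g * rev(g), rep(d^2, 15), tolerance = 1e-10)
      expect_equal(g[8], d, tolerance = 1e-12)  # incumbent on the grid
    }
  })
  expect_equal(logGrid(2, points = 2), 2 * 10^c(-1.5, 1.5), tolerance = 1e-12)
  expect_equal(logGrid(1, span = "one_sided_down")[15], 1, tolerance = 1e-12)
  expect_error(logGrid(0), "positive")
  expect_error(logGrid(1, points = 1), "2 points")
})

test_that("default half-maximal constants halve the regulator concentration", {
  expect_equal(initialKA(10), 5)
  expect_equal(initialKA(c(1, 8)), c(0.5, 4))
  # linear scaling
  expect_equal(initialKA(7 * 3), 3 * initialKA(7))
  # zero regulator takes the positive fallback path
  expect_message(ka <- initialKA(0, fallback = 4), "fallback")
  expect_equal(ka, 2)
  expect_gt(ka, 0)
  expect_error(initialKA(-1), ">= 0")
})
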