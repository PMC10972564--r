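test_that("centroid mass is decharged, weighted, and scale-invariant", {
  z <- 2L
  one <- SpectrumEnvelope((1000 + z * 1.007276467) / z, 1, charge = z)
  expect_equal(centroidMass(one), 1000)
  two <- SpectrumEnvelope((c(1000, 1001) + z * 1.007276467) / z, c(1, 1),
                          charge = z)
  expect_equal(centroidMass(two), 1000.5)
  scaled <- SpectrumEnvelope(two@mz, two@intensity * 37, charge = z)
  expect_equal(centroidMass(scaled), centroidMass(two))
  expect_error(SpectrumEnvelope(1:2, c(-1, 2)), "non-negative")
})

test_that("centroid of a simulated binomial envelope matches the analytic mean", {
  pep <- Peptide(191L, 198L, "YRAPEIML")         # 6 exchangeable sites
  und <- centroidMass(simulateIsotopeEnvelope(pep, 0, charge = 2L))
  deut <- centroidMass(simulateIsotopeEnvelope(pep, 0.3, charge = 2L))
  expect_equal(deut - und, 6 * 0.3 * 1.00627675, tolerance = 1e-6)
})

test_that("deuterium uptake is a signed difference, flagged when negative", {
  expect_equal(deuteriumUptake(1000, 1000), 0)
  expect_equal(deuteriumUptake(1002.5, 1000), 2.5)
  expect_warning(d <- deuteriumUptake(999.8, 1000), "negative")
  expect_equal(d, -0.2)
})

test_that("in-exchange correction is a pure shift that preserves raw values", {
  raw <- UptakeCurve(times = c(30, 60, 180), rawUptake = c(1, 2, 3))
  same <- inExchangeCorrect(raw, 0)
  expect_equal(correctedUptake(same), c(1, 2, 3))
  cor <- inExchangeCorrect(raw, 0.3)
  expect_equal(correctedUptake(cor), c(0.7, 1.7, 2.7))
  expect_equal(cor@rawUptake, c(1, 2, 3))
  low <- UptakeCurve(times = c(30, 60), rawUptake = c(0.1, 0.5))
  expect_warning(neg <- inExchangeCorrect(low, 0.3), "negative")
  expect_equal(correctedUptake(neg)[1], -0.2)
  expect_error(inExchangeCorrect(raw, -1), ">= 0")
})

test_that("time-course assembly averages replicates per time point", {
  df <- data.frame(time_s = c(30, 30, 60), uptake_Da = c(1, 2, 3))
  tc <- buildTimeCourse(df)
  expect_equal(labelingTimes(tc), c(30, 60))
  expect_equal(tc@rawUptake, c(1.5, 3))
  expect_equal(tc@sd, c(stats::sd(c(1, 2)), 0))
  dup <- buildTimeCourse(data.frame(time_s = c(30, 30),
                                    uptake_Da = c(2, 2)))
  expect_equal(dup@rawUptake, 2)
  expect_equal(dup@sd, 0)
  expect_error(buildTimeCourse(data.frame(time_s = numeric(0),
                                          uptake_Da = numeric(0))),
               "no replicate")
})

test_that("uptake tables round-trip through CSV at printed precision", {
  tab <- simulatePanel(defaultInhibitorPanel()[c("#1", "VTX11e")],
                       peptides = defaultPeptides()["dfg"],
                       noiseSd = 0.03, seed = 7L)
  path <- tempfile(fileext = ".csv")
  writeUptakeTable(tab, path)
  back <- readUptakeTable(path)
  expect_identical(dim(back), dim(tab))
  expect_equal(back$uptake_Da, tab$uptake_Da, tolerance = 1e-12)
  expect_identical(back$condition, tab$condition)
  expect_identical(back$is_control, tab$is_control)
  expect_error(readUptakeTable(tempfile()), "no such file")
})
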