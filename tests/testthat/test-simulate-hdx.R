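test_that("corrected uptake is zero at t = 0 and with infinite protection", {
  pep <- defaultPeptides()$dfg
  res <- residueExchangeSpecs(pep)
  cur <- simulatePeptideUptake(pep, res, ConformerModel(0.8),
                               times = c(0, 30, 60))
  expect_equal(correctedUptake(cur)[1], 0)
  frozen <- residueExchangeSpecs(pep, pfR = Inf, pfL = Inf)
  cur0 <- simulatePeptideUptake(pep, frozen, ConformerModel(0.8))
  expect_equal(correctedUptake(cur0), rep(0, 9))
})

test_that("a single amide follows the closed-form exponential", {
  pep <- singleAmidePeptide()
  res <- manualResidues(1:2, c(NA, 0.01))
  cur <- simulatePeptideUptake(pep, res, ConformerModel(1), times = 100,
                               labelingFraction = 1,
                               backExchangeFactor = 1)
  expect_equal(correctedUptake(cur), 1 - exp(-1), tolerance = 1e-9)
})

test_that("uptake curves are monotone and bounded for random parameter draws", {
  set.seed(11)
  pep <- defaultPeptides()$p1
  for (i in 1:20) {
    res <- residueExchangeSpecs(pep, pfR = runif(1, 1, 500),
                                pfL = runif(1, 1, 500))
    lf <- runif(1, 0.5, 1)
    bx <- runif(1, 0.5, 1)
    cur <- simulatePeptideUptake(pep, res, ConformerModel(runif(1)),
                                 labelingFraction = lf,
                                 backExchangeFactor = bx)
    u <- correctedUptake(cur)
    expect_true(all(diff(u) >= -1e-12))
    expect_true(all(u <= lf * bx * nExchangeable(pep) + 1e-12))
  }
})

test_that("population mixing equals the convex combination only when PR = PL", {
  pep <- defaultPeptides()$dfg
  alpha <- 0.6
  ## equal per-state protection: all three ensembles coincide
  eq <- residueExchangeSpecs(pep, pfR = 40, pfL = 40)
  mixEq <- correctedUptake(simulatePeptideUptake(pep, eq,
                                                 ConformerModel(alpha)))
  pureR <- correctedUptake(simulatePeptideUptake(pep, eq,
                                                 ConformerModel(1)))
  pureL <- correctedUptake(simulatePeptideUptake(pep, eq,
                                                 ConformerModel(0)))
  expect_equal(mixEq, alpha * pureR + (1 - alpha) * pureL,
               tolerance = 1e-12)
  ## unequal protection: mixture lies between the pure curves and above
  ## the convex combination (concavity of 1 - exp(-kt) in k)
  ne <- residueExchangeSpecs(pep, pfR = 150, pfL = 30)
  mix <- correctedUptake(simulatePeptideUptake(pep, ne,
                                               ConformerModel(alpha)))
  r <- correctedUptake(simulatePeptideUptake(pep, ne, ConformerModel(1)))
  l <- correctedUptake(simulatePeptideUptake(pep, ne, ConformerModel(0)))
  expect_true(all(mix >= pmin(r, l) - 1e-12 & mix <= pmax(r, l) + 1e-12))
  expect_true(all(mix >= alpha * r + (1 - alpha) * l - 1e-12))
  expect_gt(max(mix - (alpha * r + (1 - alpha) * l)), 1e-6)
})

test_that("invalid simulation inputs are rejected", {
  pep <- defaultPeptides()$dfg
  res <- residueExchangeSpecs(pep)
  expect_error(simulatePeptideUptake(pep, res, ConformerModel(0.8),
                                     times = c(60, 30)), "sorted")
  expect_error(simulatePeptideUptake(pep, res, ConformerModel(0.8),
                                     labelingFraction = 0),
               "labelingFraction")
})

test_that("panel generation is seed-reproducible and seed-free when noiseless", {
  small <- defaultInhibitorPanel()[c("#1", "#4", "VTX11e")]
  peps <- defaultPeptides()["dfg"]
  a <- simulatePanel(small, peps, noiseSd = 0.05, seed = 3L)
  b <- simulatePanel(small, peps, noiseSd = 0.05, seed = 3L)
  expect_identical(a, b)
  c2 <- simulatePanel(small, peps, noiseSd = 0.05, seed = 4L)
  expect_false(identical(a$uptake_Da, c2$uptake_Da))
  n1 <- simulatePanel(small, peps, noiseSd = 0, seed = 1L)
  n2 <- simulatePanel(small, peps, noiseSd = 0, seed = 99L)
  expect_identical(n1, n2)
  ## noiseless curves are non-decreasing within every condition
  meas <- n1[!n1$is_control, ]
  for (cond in unique(meas$condition)) {
    u <- meas$uptake_Da[meas$condition == cond & meas$replicate == 1 &
                          meas$protein_state == "2P"]
    expect_true(all(diff(u) >= -1e-12))
  }
})

test_that("0P datasets keep the pure-L ensemble for every inhibitor", {
  small <- defaultInhibitorPanel()[c("VTX11e", "#1")]
  tab <- simulatePanel(small, defaultPeptides()["dfg"], noiseSd = 0)
  apo <- uptakeCurveFromTable(tab, "0P", "apo", 161)
  vtx <- uptakeCurveFromTable(tab, "0P", "VTX11e", 161)
  expect_equal(correctedUptake(vtx), correctedUptake(apo),
               tolerance = 1e-12)
})

test_that("duplicate inhibitor ids are rejected", {
  dup <- defaultInhibitorPanel()[c("#1", "#1")]
  expect_error(simulatePanel(dup, defaultPeptides()["dfg"]), "duplicate")
})

test_that("RNG state of the caller is left untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulatePanel(defaultInhibitorPanel()["#1"],
                          defaultPeptides()["dfg"], noiseSd = 0.1,
                          seed = 5L))
  expect_identical(.Random.seed, before)
})
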