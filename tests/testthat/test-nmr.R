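test_that("volume ratios give exact populations at zero noise", {
  for (p in c(0, 0.5, 0.8, 1)) {
    tab <- simulateHmqcPeakPairs(defaultMethylProbes()[1:3],
                                 ConformerModel(p))
    est <- estimatePopulations(peakPairs(tab))
    expect_equal(est$p_R, rep(p, 3))
  }
})

test_that("pR = 1 silences the L peak; pR = 0.8 gives a 4:1 volume ratio", {
  tab1 <- simulateHmqcPeakPairs(defaultMethylProbes()["I72"],
                                ConformerModel(1))
  expect_equal(tab1$volume[tab1$state == "L"], 0)
  tab <- simulateHmqcPeakPairs(defaultMethylProbes()["I72"],
                               ConformerModel(0.8))
  expect_equal(tab$volume[tab$state == "R"] / tab$volume[tab$state == "L"],
               4)
})

test_that("population recovery: MAE below 0.02 at 2 percent volume noise", {
  for (p in c(0, 0.5, 0.8, 1)) {
    err <- vapply(1:50, function(s) {
      tab <- simulateHmqcPeakPairs(defaultMethylProbes()["L220"],
                                   ConformerModel(p), noiseSd = 0.02,
                                   seed = s)
      abs(estimatePopulations(peakPairs(tab))$p_R - p)
    }, numeric(1))
    expect_lt(mean(err), 0.02)
  }
})

test_that("broadened pairs yield no estimate and double zeros are an error", {
  inh <- defaultInhibitorPanel()$`#5`
  tab <- simulateHmqcPeakPairs(defaultMethylProbes()["I82"],
                               ConformerModel(0.8), inhibitor = inh)
  pr <- peakPairs(tab)
  expect_true(pr$broadened)
  expect_true(is.na(estimatePopulations(pr)$p_R))
  bad <- data.frame(probe_id = "x", volume_R = 0, volume_L = 0,
                    broadened = FALSE)
  expect_error(estimatePopulations(bad), "both peak volumes zero")
})

test_that("uncertainty propagation follows the delta method", {
  pr <- data.frame(probe_id = "x", volume_R = 0.8, volume_L = 0.2,
                   broadened = FALSE)
  est <- estimatePopulations(pr, volumeNoiseSd = 0.02)
  expect_equal(est$uncertainty, 0.02 * sqrt(0.8^2 + 0.2^2) / 1^2)
})

test_that("combined CSP follows the weighted quadrature formula", {
  expect_equal(chemicalShiftPerturbation(c(1, 20), c(1, 20)), 0)
  expect_equal(chemicalShiftPerturbation(c(1, 20), c(1.1, 20)), 0.1)
  expect_equal(chemicalShiftPerturbation(c(1, 20), c(1.1, 20.4), 0.25),
               sqrt(0.01 + 0.01), tolerance = 1e-12)
  ## symmetric distance
  a <- c(0.73, 13.2); b <- c(0.81, 14.0)
  expect_equal(chemicalShiftPerturbation(a, b),
               chemicalShiftPerturbation(b, a))
  expect_error(chemicalShiftPerturbation(a, b, carbonWeight = 0),
               "positive")
})

test_that("probe categorisation recovers the generator's ground truth", {
  panel <- defaultInhibitorPanel()
  probes <- defaultMethylProbes()
  model <- ConformerModel(0.8)
  apo <- simulateHmqcPeakPairs(probes, model)
  bound <- lapply(panel, function(inh)
    simulateHmqcPeakPairs(probes, model, inh))
  csp <- cspMatrix(apo, bound)
  cats <- categorizeProbes(csp, panelClasses(panel),
                           vapply(panel, function(x) x@leftSideGroup,
                                  character(1)))
  expect_equal(unname(cats[c("I196", "I345")]),
               rep("R_STATE_REPORTER", 2))
  expect_equal(unname(cats[c("L26", "L105", "L155", "L161")]),
               rep("LEFT_SIDE_REPORTER", 4))
  expect_equal(unname(cats[c("I82", "L154")]),
               rep("CONTACT_BROADENED", 2))
  ## slow-exchange reporters do not move and stay unclassified
  expect_equal(unname(cats["I72"]), "UNCLASSIFIED")
})

test_that("flat probes are never classified as reporters", {
  csp <- matrix(0.05, nrow = 1, ncol = 6,
                dimnames = list("X1", paste0("i", 1:6)))
  labels <- setNames(rep(c("R_SELECTIVE", "EXCHANGE"), 3), paste0("i", 1:6))
  expect_equal(unname(categorizeProbes(csp, labels)), "UNCLASSIFIED")
})

test_that("slow-exchange condition is enforced at probe construction", {
  expect_error(MethylProbe("bad", c(0.8, 13.0), c(0.8, 13.0),
                           "EXCHANGE_REPORTER"), "distinct")
  expect_error(MethylProbe("slowish", c(0.80, 13.00), c(0.79, 13.05),
                           "EXCHANGE_REPORTER"), "slow-exchange")
})
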