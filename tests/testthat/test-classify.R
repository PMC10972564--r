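mkRecords <- function(daucByInh, segments = c("S1", "S2")) {
  do.call(rbind, lapply(segments, function(sg)
    data.frame(inhibitor_id = names(daucByInh), segment_id = sg,
               dauc = unname(daucByInh), rank = NA_real_,
               stringsAsFactors = FALSE)))
}

test_that("threshold rule assigns the extreme and middle labels", {
  rec <- mkRecords(c(ref_hi = 10, ref_lo = 0, top = 10, mid = 5, low = 0))
  cls <- classifyPanel(rec, referenceIds = c("ref_hi", "ref_lo"))
  lab <- setNames(cls$label, cls$inhibitor_id)
  expect_equal(unname(lab["top"]), "R_SELECTIVE")
  expect_equal(unname(lab["mid"]), "INTERMEDIATE")
  expect_equal(unname(lab["low"]), "EXCHANGE")
  expect_true(all(cls$combined_score >= 0 & cls$combined_score <= 1))
})

test_that("classification is invariant to affine rescaling of dAUC", {
  rec <- mkRecords(c(a = 8, b = 3, c = 0, d = 6))
  base <- classifyPanel(rec, referenceIds = character(0))
  rec2 <- rec
  rec2$dauc <- 3.7 * rec2$dauc + 11
  shifted <- classifyPanel(rec2, referenceIds = character(0))
  expect_equal(shifted$combined_score, base$combined_score,
               tolerance = 1e-12)
  expect_identical(shifted$label, base$label)
})

test_that("degenerate normalisation yields 0.5 scores with a warning", {
  rec <- mkRecords(c(a = 2, b = 2, c = 2), segments = "S1")
  expect_warning(cls <- classifyPanel(rec, segments = "S1",
                                      referenceIds = character(0)),
                 "degenerate")
  expect_true(all(cls$combined_score == 0.5))
  expect_true(all(cls$label == "INTERMEDIATE"))
})

test_that("compounds at zero dAUC classify as exchange-retaining", {
  rec <- mkRecords(c(VTX11e = 9, GDC0994 = 0, u = 0, v = 0))
  cls <- classifyPanel(rec)
  expect_true(all(cls$label[cls$inhibitor_id %in% c("u", "v")] ==
                    "EXCHANGE"))
})

test_that("missing segments or inhibitors are reported", {
  rec <- mkRecords(c(a = 1, b = 2))
  expect_error(classifyPanel(rec, segments = "S9"), "no records")
  uneven <- rbind(rec, data.frame(inhibitor_id = "c", segment_id = "S1",
                                  dauc = 3, rank = NA_real_))
  expect_error(classifyPanel(uneven), "missing inhibitors")
})

test_that("ground-truth classes are recovered on noisy panels", {
  ## noise at the generator's realistic upper bound (0.1 Da per
  ## measurement); recovery is checked compound-wise across panels
  panel <- defaultInhibitorPanel()
  truth <- panelClasses(panel)
  segs <- list(DFG_161_168 = c(161L, 168L), P1_191_198 = c(191L, 198L))
  peps <- defaultPeptides()[c("dfg", "p1")]
  nPanels <- 200
  hits <- 0L
  total <- 0L
  for (s in seq_len(nPanels)) {
    tab <- simulatePanel(panel, peps, noiseSd = 0.1, seed = 1000L + s)
    cls <- classifyPanel(daucTable(tab, segs))
    got <- setNames(cls$label, cls$inhibitor_id)
    ids <- names(truth)[!vapply(panel, function(x) x@isReference,
                                logical(1))]
    hits <- hits + sum(got[ids] == truth[ids])
    total <- total + length(ids)
  }
  expect_gte(hits / total, 0.95)
})
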