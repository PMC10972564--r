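## The default inhibitor panel and the full-panel HDX dataset generator.

#' Default inhibitor panel
#'
#' Ground-truth panel of 19 surveyed compounds plus the two normalisation
#' references.  The 17 panel compounds ("#1".."#17") follow the published
#' cluster memberships: thirteen R-state selective (#2, #3, #5-#12, #14,
#' #16, #17), three exchange-retaining (#4, #13, #15) and one
#' intermediate (#1).  BVD523 is R-state selective and ATG017
#' exchange-retaining.  VTX11e (R-selective) and GDC0994
#' (exchange-retaining) are included as references anchoring the min-max
#' normalisation of the classifier.  Left-side chemistry is assigned
#' where known (tetrahydropyran: #4, #6, #8, #15; pyrazole: #1, #5, #16,
#' GDC0994); the amidopyrrole central scaffold marks VTX11e and BVD523.
#'
#' @return Named list of \code{\linkS4class{InhibitorSpec}} objects.
#' @export
defaultInhibitorPanel <- function() {
  rsel <- c(2, 3, 5:12, 14, 16, 17)
  exch <- c(4, 13, 15)
  thp  <- c(4, 6, 8, 15)
  pyz  <- c(1, 5, 16)
  panel <- lapply(1:17, function(i) {
    cls <- if (i %in% rsel) "R_SELECTIVE"
           else if (i %in% exch) "EXCHANGE" else "INTERMEDIATE"
    left <- if (i %in% thp) "TETRAHYDROPYRAN"
            else if (i %in% pyz) "PYRAZOLE" else "OTHER"
    scaf <- if (i %in% c(8, 16)) "TRIAZOLOPYRAZINE" else "PYRIDONE"
    InhibitorSpec(paste0("#", i), cls, leftSideGroup = left,
                  scaffold = scaf)
  })
  names(panel) <- paste0("#", 1:17)
  c(panel,
    list(
      BVD523  = InhibitorSpec("BVD523", "R_SELECTIVE",
                              scaffold = "AMIDOPYRROLE"),
      ATG017  = InhibitorSpec("ATG017", "EXCHANGE"),
      VTX11e  = InhibitorSpec("VTX11e", "R_SELECTIVE",
                              scaffold = "AMIDOPYRROLE", isReference = TRUE),
      GDC0994 = InhibitorSpec("GDC0994", "EXCHANGE",
                              leftSideGroup = "PYRAZOLE",
                              scaffold = "PYRIDONE", isReference = TRUE)))
}

#' Ground-truth class labels of an inhibitor panel
#'
#' @param panel list of \code{\linkS4class{InhibitorSpec}} objects.
#' @return Named character vector of conformational classes.
#' @export
panelClasses <- function(panel = defaultInhibitorPanel()) {
  vapply(panel, function(x) x@confClass, character(1))
}

#' Simulate a full HDX-MS inhibitor-panel dataset
#'
#' Generates raw uptake tables for both enzyme forms (0P and 2P), the
#' apoenzyme and every panel compound, all peptides, the 9-point labeling
#' grid and an in-exchange control row per condition.  Binding is assumed
#' saturating (1:1.2 enzyme:inhibitor), so bound curves use the
#' inhibitor's class populations outright; in the 0P form every compound
#' retains the pure-L apoenzyme ensemble.  With \code{noiseSd = 0} the
#' output is deterministic and seed-independent; with noise the same
#' seed reproduces the dataset bit-identically.
#'
#' @param panel named list of \code{\linkS4class{InhibitorSpec}}; ids
#'   must be unique.
#' @param peptides list of \code{\linkS4class{Peptide}} objects.
#' @param model2P,model0P apo ensembles of the two enzyme forms.
#' @param times labeling time grid (s).
#' @param nReplicates replicate measurements per time point.
#' @param noiseSd additive Gaussian noise on uptake (Da).
#' @param seed integer seed (used only when \code{noiseSd > 0}).
#' @param pD,temperatureC labeling conditions.
#' @param labelingFraction,backExchangeFactor forward-model scaling, see
#'   \code{\link{simulatePeptideUptake}}.
#' @return data.frame with columns protein_state, condition,
#'   peptide_start, peptide_end, sequence, time_s, uptake_Da, replicate,
#'   is_control.  Control rows carry \code{time_s = 0} and
#'   \code{is_control = TRUE}.
#' @export
simulatePanel <- function(panel = defaultInhibitorPanel(),
                          peptides = defaultPeptides(),
                          model2P = ConformerModel(0.8),
                          model0P = ConformerModel(0),
                          times = defaultTimeGrid(),
                          nReplicates = 2L, noiseSd = 0, seed = 1L,
                          pD = 7.2, temperatureC = 25,
                          labelingFraction = 0.9,
                          backExchangeFactor = 0.75) {
  ids <- vapply(panel, function(x) x@inhibitorId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate inhibitor_id in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  residues <- lapply(peptides, residueExchangeSpecs, pD = pD,
                     temperatureC = temperatureC)
  conditions <- c(list(apo = NULL), panel)
  names(conditions)[1] <- "apo"
  blocks <- list()
  for (state in c("0P", "2P")) {
    model <- if (state == "2P") model2P else model0P
    for (ci in seq_along(conditions)) {
      cond <- conditions[[ci]]
      condId <- if (is.null(cond)) "apo" else cond@inhibitorId
      for (pi in seq_along(peptides)) {
        pep <- peptides[[pi]]
        curve <- simulatePeptideUptake(
          pep, residues[[pi]], model, inhibitor = cond, times = times,
          labelingFraction = labelingFraction,
          backExchangeFactor = backExchangeFactor, proteinState = state)
        blocks[[length(blocks) + 1L]] <- data.frame(
          protein_state = state, condition = condId,
          peptide_start = pep@start, peptide_end = pep@end,
          sequence = pep@sequence,
          time_s = c(rep(times, nReplicates), 0),
          uptake_Da = c(rep(curve@rawUptake, nReplicates),
                        curve@inExchange),
          replicate = c(rep(seq_len(nReplicates), each = length(times)), 1L),
          is_control = c(rep(FALSE, length(times) * nReplicates), TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  if (noiseSd > 0)
    out$uptake_Da <- withSeed(seed,
      out$uptake_Da + stats::rnorm(nrow(out), 0, noiseSd))
  out
}
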