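## Default peptide set and per-residue exchange specifications used by
## the forward model.

#' Default peptide set of the synthetic HDX panel
#'
#' Five reporter peptides on rat ERK2 numbering.  The three C-lobe
#' peptides carry the sequences of the segments used for the
#' conformation-selection readout: the DFG motif (161-168, LKICDFGL), the
#' P+1 segment (191-198, YRAPEIML) and helix alphaF (203-210, YTKSIDIW).
#' The Gly-loop and hinge peptides represent the direct-contact regions
#' protected by all nucleotide-pocket binders; their sequences are
#' generator defaults chosen to be composition-plausible, not measured
#' digests.
#'
#' @return Named list of \code{\linkS4class{Peptide}} objects.
#' @export
defaultPeptides <- function() {
  list(
    glyLoop = Peptide(29L, 36L, "IGEGAYGM", region = "GLY_LOOP"),
    hinge   = Peptide(103L, 110L, "QDLMETDL", region = "HINGE"),
    dfg     = Peptide(161L, 168L, "LKICDFGL", region = "DFG"),
    p1      = Peptide(191L, 198L, "YRAPEIML", region = "P1"),
    alphaF  = Peptide(203L, 210L, "YTKSIDIW", region = "ALPHA_F"))
}

#' Default labeling time grid
#'
#' Nine labeling times from 0.5 to 180 minutes, returned in seconds.
#'
#' @return Numeric vector of 9 times (s).
#' @export
defaultTimeGrid <- function() {
  c(0.5, 1, 3, 8, 16, 30, 60, 90, 180) * 60
}

#' Per-residue exchange specifications for a peptide
#'
#' Expands a peptide into the per-residue table consumed by
#' \code{\link{simulatePeptideUptake}}: intrinsic rate, R-state and
#' L-state protection factors, and region tag.  By default residues in
#' allosterically coupled regions (DFG, beta9, P+1, helix alphaF) are
#' strongly protected in the R state (protection factor 150) and weakly
#' in the mobile L state (30), encoding the model in which the R
#' conformer rigidifies the activation-loop surroundings; direct-contact
#' regions get a state-independent baseline of 20.
#'
#' @param peptide a \code{\linkS4class{Peptide}}.
#' @param pD,temperatureC labeling conditions passed to
#'   \code{\link{intrinsicRates}}.
#' @param pfR,pfL protection factors for allosteric-region residues in
#'   the R and L states.
#' @param pfContact state-independent protection factor for
#'   contact-region (and untagged) residues.
#' @return data.frame with columns resno, aa, kInt, pfR, pfL, region,
#'   isProline, exchangeable.
#' @export
residueExchangeSpecs <- function(peptide, pD = 7.2, temperatureC = 25,
                                 pfR = 150, pfL = 30, pfContact = 20) {
  stopifnot(is(peptide, "Peptide"))
  aa <- strsplit(peptide@sequence, "")[[1]]
  k <- intrinsicRates(peptide@sequence, pD = pD, temperatureC = temperatureC)
  allo <- peptide@region %in% ALLOSTERIC_REGIONS
  data.frame(
    resno = seq(peptide@start, peptide@end),
    aa = aa,
    kInt = unname(k),
    pfR = if (allo) pfR else pfContact,
    pfL = if (allo) pfL else pfContact,
    region = peptide@region,
    isProline = aa == "P",
    exchangeable = !is.na(k),
    stringsAsFactors = FALSE)
}
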