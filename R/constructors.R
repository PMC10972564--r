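## User-facing constructors, accessors and show() methods.

#' Create a two-state conformer model
#'
#' @param pR R-state population in [0, 1].
#' @param kEx global exchange rate constant, 1/s.  The default of 300/s is
#'   far faster than any observable amide-exchange rate on the labeling
#'   time grid, which justifies the fast-ensemble population averaging
#'   used by the uptake simulator.
#' @param temperatureC temperature in degrees Celsius.
#' @return A \code{\linkS4class{ConformerModel}}.
#' @examples
#' apo2P <- ConformerModel(pR = 0.8)            # 2P apoenzyme, 25 C
#' apo0P <- ConformerModel(pR = 0, temperatureC = 25)
#' @export
ConformerModel <- function(pR, kEx = 300, temperatureC = 25) {
  new("ConformerModel", pR = as.numeric(pR), pL = 1 - as.numeric(pR),
      kEx = as.numeric(kEx), temperatureC = as.numeric(temperatureC))
}

#' @describeIn ConformerModel R-state population accessor.
#' @param object a \code{ConformerModel}.
#' @export
pR <- function(object) object@pR

#' @describeIn ConformerModel L-state population accessor.
#' @export
pL <- function(object) object@pL

#' @describeIn ConformerModel exchange-rate accessor.
#' @export
kEx <- function(object) object@kEx

setMethod("show", "ConformerModel", function(object) {
  cat(sprintf(
    "ConformerModel: R:L = %.0f:%.0f, kEx = %g /s, %g degC\n",
    100 * object@pR, 100 * object@pL, object@kEx, object@temperatureC))
})

#' Create an inhibitor specification
#'
#' The conformational class fixes the bound R-state population and the
#' default protection multipliers: R-state-selective compounds trap the R
#' state (boundPR = 1) and protect the allosterically coupled regions
#' (DFG, beta9, P+1, helix alphaF) 20-fold in the 2P enzyme;
#' exchange-retaining compounds leave the populations at the apoenzyme
#' value and protect only their direct-contact regions; intermediate
#' compounds partially shift the equilibrium (default boundPR = 0.9) with
#' a weaker (5-fold) allosteric effect.  All compounds protect contact
#' regions 20-fold, reflecting steric occlusion of the nucleotide pocket.
#'
#' @param inhibitorId compound identifier.
#' @param confClass \code{"R_SELECTIVE"}, \code{"EXCHANGE"} or
#'   \code{"INTERMEDIATE"}.
#' @param boundPR bound R population; defaults by class (1 for
#'   R-selective, NA = apo value for exchange-retaining, 0.9 for
#'   intermediate).
#' @param leftSideGroup,scaffold chemistry descriptors used by the NMR
#'   peak simulator.
#' @param contactMultiplier,allostericMultiplier protection-factor
#'   multipliers; defaults by class as described above.
#' @param isReference whether the compound anchors the min-max
#'   normalisation of the classifier.
#' @return An \code{\linkS4class{InhibitorSpec}}.
#' @export
InhibitorSpec <- function(inhibitorId, confClass,
                          boundPR = switch(confClass,
                            R_SELECTIVE = 1, EXCHANGE = NA_real_,
                            INTERMEDIATE = 0.9),
                          leftSideGroup = "OTHER", scaffold = "OTHER",
                          contactMultiplier = 20,
                          allostericMultiplier = switch(confClass,
                            R_SELECTIVE = 20, EXCHANGE = 1,
                            INTERMEDIATE = 5),
                          isReference = FALSE) {
  confClass <- match.arg(confClass, CONF_CLASSES)
  new("InhibitorSpec", inhibitorId = inhibitorId, confClass = confClass,
      boundPR = as.numeric(boundPR),
      leftSideGroup = match.arg(leftSideGroup, LEFT_SIDE_GROUPS),
      scaffold = match.arg(scaffold, SCAFFOLDS),
      contactMultiplier = contactMultiplier,
      allostericMultiplier = allostericMultiplier,
      isReference = isReference)
}

#' @describeIn InhibitorSpec identifier accessor.
#' @param object an \code{InhibitorSpec}.
#' @export
inhibitorId <- function(object) object@inhibitorId

#' @describeIn InhibitorSpec conformational-class accessor.
#' @export
confClass <- function(object) object@confClass

setMethod("show", "InhibitorSpec", function(object) {
  cat(sprintf("InhibitorSpec %s: %s (boundPR = %s, left side %s, %s%s)\n",
              object@inhibitorId, object@confClass,
              ifelse(is.na(object@boundPR), "apo", object@boundPR),
              object@leftSideGroup, object@scaffold,
              if (object@isReference) ", reference" else ""))
})

#' Create a peptide definition
#'
#' The exchange-competent amide count follows the standard bottom-up HDX
#' convention: the N-terminal residue (which back-exchanges during
#' quench/LC handling) and all prolines (no amide hydrogen) are excluded.
#'
#' @param start,end 1-based inclusive residue numbers on the protein.
#' @param sequence one-letter amino-acid sequence.
#' @param region optional structural-region tag (see
#'   \code{\link{defaultPeptides}}).
#' @return A \code{\linkS4class{Peptide}}.
#' @examples
#' Peptide(161, 168, "LKICDFGL", region = "DFG")  # 7 exchangeable amides
#' @export
Peptide <- function(start, end, sequence, region = "") {
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% AA_ONE_LETTER))
    stop("unknown residue code(s): ",
         paste(unique(aa[!aa %in% AA_ONE_LETTER]), collapse = ", "))
  nex <- nchar(sequence) - 1L - sum(aa[-1L] == "P")
  new("Peptide", start = as.integer(start), end = as.integer(end),
      sequence = sequence, nExchangeable = as.integer(nex), region = region)
}

#' @describeIn Peptide exchangeable-amide count accessor.
#' @param object a \code{Peptide}.
#' @export
nExchangeable <- function(object) object@nExchangeable

setMethod("show", "Peptide", function(object) {
  cat(sprintf("Peptide %d-%d %s (%d exchangeable amides%s)\n",
              object@start, object@end, object@sequence,
              object@nExchangeable,
              if (nzchar(object@region)) paste0(", ", object@region) else ""))
})

## Angular-frequency gap between two (1H, 13C) ppm positions, rad/s.
## Field default 900 MHz 1H; the 13C dimension is scaled by the
## gyromagnetic ratio (gammaC/gammaH = 0.25145).
deltaOmega <- function(shiftA, shiftB, fieldMHz = 900) {
  dH <- (shiftA[1] - shiftB[1]) * fieldMHz
  dC <- (shiftA[2] - shiftB[2]) * fieldMHz * 0.25145
  2 * pi * sqrt(dH^2 + dC^2)
}

#' Create a methyl-probe specification
#'
#' For exchange reporters the R and L peak positions must differ by an
#' angular-frequency gap more than tenfold larger than the default
#' exchange rate (300/s), i.e. the pair must be in slow exchange so that
#' both conformers give resolved peaks.  Probes of other categories carry
#' a single peak; pass only \code{shiftR} (it is reused for both states).
#'
#' @param probeId residue label, e.g. \code{"I72"}.
#' @param shiftR,shiftL numeric (1H ppm, 13C ppm) positions of the R- and
#'   L-state peaks.
#' @param category one of \code{PROBE_CATEGORIES}.
#' @return A \code{\linkS4class{MethylProbe}}.
#' @export
MethylProbe <- function(probeId, shiftR, shiftL = shiftR,
                        category = "EXCHANGE_REPORTER") {
  new("MethylProbe", probeId = probeId, shiftR = as.numeric(shiftR),
      shiftL = as.numeric(shiftL),
      category = match.arg(category, PROBE_CATEGORIES))
}

setMethod("show", "MethylProbe", function(object) {
  cat(sprintf("MethylProbe %s [%s] R=(%.2f, %.1f) L=(%.2f, %.1f) ppm\n",
              object@probeId, object@category,
              object@shiftR[1], object@shiftR[2],
              object@shiftL[1], object@shiftL[2]))
})

#' Create a spectrum envelope
#'
#' @param mz m/z values.
#' @param intensity intensities, same length as \code{mz}.
#' @param charge positive integer charge state.
#' @return A \code{\linkS4class{SpectrumEnvelope}}.
#' @export
SpectrumEnvelope <- function(mz, intensity, charge = 1L) {
  new("SpectrumEnvelope", mz = as.numeric(mz),
      intensity = as.numeric(intensity), charge = as.integer(charge))
}

setMethod("show", "SpectrumEnvelope", function(object) {
  cat(sprintf("SpectrumEnvelope: %d peaks, charge %d+, m/z %.4f-%.4f\n",
              length(object@mz), object@charge,
              min(object@mz), max(object@mz)))
})

#' Create an uptake curve
#'
#' @param times labeling times (s), strictly increasing.
#' @param rawUptake raw deuterium uptake (Da) per time point.
#' @param inExchange in-exchange control uptake (Da); subtracted from all
#'   time points to give the corrected curve.
#' @param peptide optional \code{Peptide} the curve belongs to.
#' @param sd optional per-time replicate standard deviations.
#' @return An \code{\linkS4class{UptakeCurve}}.
#' @export
UptakeCurve <- function(times, rawUptake, inExchange = 0, peptide = NULL,
                        sd = numeric(0)) {
  new("UptakeCurve", peptide = peptide, times = as.numeric(times),
      rawUptake = as.numeric(rawUptake),
      inExchange = as.numeric(inExchange),
      correctedUptake = as.numeric(rawUptake) - as.numeric(inExchange),
      sd = as.numeric(sd))
}

#' @describeIn UptakeCurve corrected-uptake accessor.
#' @param object an \code{UptakeCurve}.
#' @export
correctedUptake <- function(object) object@correctedUptake

#' @describeIn UptakeCurve labeling-time accessor.
#' @export
labelingTimes <- function(object) object@times

setMethod("show", "UptakeCurve", function(object) {
  cat(sprintf(
    "UptakeCurve: %d time points (%g-%g s), in-exchange %.3f Da\n",
    length(object@times), min(object@times), max(object@times),
    object@inExchange))
  if (!is.null(object@peptide)) show(object@peptide)
})

#' Create an atom selection for superposition
#'
#' @param residueRanges two-column matrix (or vector of length 2) of
#'   inclusive residue ranges, e.g.
#'   \code{rbind(c(109, 141), c(205, 245), c(272, 310))} for a C-terminal
#'   domain fit.
#' @param chainId chain to select (\code{NA} = first chain in the model).
#' @param atomNames atom names (default \code{"CA"}).
#' @param numberingOffset integer added to the mobile structure's residue
#'   numbers before matching, to reconcile author numbering between
#'   deposited entries.
#' @return A \code{\linkS4class{SelectionSpec}}.
#' @export
SelectionSpec <- function(residueRanges, chainId = NA_character_,
                          atomNames = "CA", numberingOffset = 0L) {
  if (is.null(dim(residueRanges)))
    residueRanges <- matrix(residueRanges, ncol = 2, byrow = TRUE)
  storage.mode(residueRanges) <- "integer"
  new("SelectionSpec", chainId = as.character(chainId),
      residueRanges = residueRanges, atomNames = atomNames,
      numberingOffset = as.integer(numberingOffset))
}

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: %d atoms, RMSD %.3f A\n",
              object@nAtoms, object@rmsd))
})

#' @describeIn kabschSuperpose RMSD accessor for a fit result.
#' @export
fitRmsd <- function(object) object@rmsd
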