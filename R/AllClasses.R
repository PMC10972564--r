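## Central S4 classes for the two-state (R/L) conformation-selection analysis.

#' @import methods
NULL

## enumerations used by validity checks and constructors
CONF_CLASSES   <- c("R_SELECTIVE", "EXCHANGE", "INTERMEDIATE")
LEFT_SIDE_GROUPS <- c("PYRAZOLE", "TETRAHYDROPYRAN", "OTHER")
SCAFFOLDS      <- c("AMIDOPYRROLE", "PYRIDONE", "TRIAZOLOPYRAZINE", "OTHER")
PROBE_CATEGORIES <- c("EXCHANGE_REPORTER", "R_STATE_REPORTER",
                      "LEFT_SIDE_REPORTER", "CONTACT_BROADENED",
                      "CONTACT_BROADENED_EXCEPT_AMIDOPYRROLE")
CONTACT_REGIONS    <- c("GLY_LOOP", "HINGE", "ALPHA_C", "ALPHA_E",
                        "ALPHA_L16", "B7_B8")
ALLOSTERIC_REGIONS <- c("DFG", "B9", "P1", "ALPHA_F")

#' ConformerModel: a two-state conformational ensemble
#'
#' Describes a kinase ensemble exchanging between an R (catalytically
#' productive) and an L state, with populations \code{pR} and \code{pL}
#' and a global exchange rate \code{kEx}.  The dual-phosphorylated (2P)
#' apoenzyme at 25 degrees C has pR = 0.8, at 5 degrees C pR = 0.5; the
#' unphosphorylated (0P) enzyme has pR = 0 at both temperatures.
#'
#' @slot pR numeric, R-state population in [0, 1].
#' @slot pL numeric, L-state population; pR + pL = 1.
#' @slot kEx numeric, exchange rate constant in 1/s (default 300).
#' @slot temperatureC numeric, temperature in degrees Celsius.
#' @exportClass ConformerModel
setClass("ConformerModel",
  representation(pR = "numeric", pL = "numeric", kEx = "numeric",
                 temperatureC = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pR) != 1L || object@pR < 0 || object@pR > 1)
      msg <- c(msg, "pR must be a single value in [0, 1]")
    if (abs(object@pR + object@pL - 1) > 1e-8)
      msg <- c(msg, "pR + pL must equal 1")
    if (object@kEx <= 0)
      msg <- c(msg, "kEx must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' InhibitorSpec: conformational-class specification of one inhibitor
#'
#' Ground-truth description of an ATP-competitive inhibitor used by the
#' synthetic-data generator: its conformational class (R-state selective,
#' exchange-retaining, or intermediate), the R-state population it enforces
#' when bound to the 2P enzyme, its left-side chemistry and central
#' scaffold, and the steric/allosteric protection it confers.
#'
#' @slot inhibitorId character identifier.
#' @slot confClass one of \code{"R_SELECTIVE"}, \code{"EXCHANGE"},
#'   \code{"INTERMEDIATE"}.
#' @slot boundPR numeric, bound-state R population; \code{NA} for
#'   exchange-retaining compounds (they keep the apoenzyme value).
#' @slot leftSideGroup one of \code{"PYRAZOLE"}, \code{"TETRAHYDROPYRAN"},
#'   \code{"OTHER"}.
#' @slot scaffold central-scaffold chemistry; the amidopyrrole scaffold is
#'   the one exempt from broadening of the second-shell contact probes.
#' @slot contactMultiplier protection-factor multiplier (>= 1) applied to
#'   residues in direct-contact regions (Gly loop, hinge, helices
#'   alphaC/alphaE/alphaL16, strands beta7-beta8) in both enzyme forms.
#' @slot allostericMultiplier protection-factor multiplier (>= 1) applied
#'   to allosterically coupled regions (DFG, beta9, P+1, helix alphaF) in
#'   the 2P form only.
#' @slot isReference logical; TRUE for the normalisation reference
#'   compounds (R-selective maximum and exchange-retaining minimum).
#' @exportClass InhibitorSpec
setClass("InhibitorSpec",
  representation(inhibitorId = "character", confClass = "character",
                 boundPR = "numeric", leftSideGroup = "character",
                 scaffold = "character", contactMultiplier = "numeric",
                 allostericMultiplier = "numeric", isReference = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@confClass %in% CONF_CLASSES)
      msg <- c(msg, paste("confClass must be one of:",
                          paste(CONF_CLASSES, collapse = ", ")))
    if (!object@leftSideGroup %in% LEFT_SIDE_GROUPS)
      msg <- c(msg, "invalid leftSideGroup")
    if (!object@scaffold %in% SCAFFOLDS)
      msg <- c(msg, "invalid scaffold")
    if (object@contactMultiplier < 1 || object@allostericMultiplier < 1)
      msg <- c(msg, "protection multipliers must be >= 1")
    if (identical(object@confClass, "R_SELECTIVE") &&
        !isTRUE(all.equal(object@boundPR, 1)))
      msg <- c(msg, "R_SELECTIVE inhibitors must have boundPR = 1")
    if (identical(object@confClass, "EXCHANGE") && !is.na(object@boundPR))
      msg <- c(msg, "EXCHANGE inhibitors must have boundPR = NA (apo value)")
    if (identical(object@confClass, "INTERMEDIATE") &&
        (is.na(object@boundPR) || object@boundPR <= 0 || object@boundPR >= 1))
      msg <- c(msg, "INTERMEDIATE inhibitors need boundPR strictly in (0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' Peptide: a proteolytic peptide on the protein's numbering
#'
#' @slot start,end integer residue numbers (1-based, inclusive).
#' @slot sequence one-letter amino-acid string; its length must equal
#'   end - start + 1.
#' @slot nExchangeable number of exchange-competent backbone amides:
#'   peptide length minus the first residue and any prolines beyond it.
#' @slot region structural-region tag used by the generator's protection
#'   model (e.g. \code{"DFG"}, \code{"P1"}); may be empty.
#' @exportClass Peptide
setClass("Peptide",
  representation(start = "integer", end = "integer", sequence = "character",
                 nExchangeable = "integer", region = "character"),
  validity = function(object) {
    msg <- NULL
    n <- nchar(object@sequence)
    if (n != object@end - object@start + 1L)
      msg <- c(msg, "sequence length must equal end - start + 1")
    aa <- strsplit(object@sequence, "")[[1]]
    expect <- n - 1L - sum(aa[-1L] == "P")
    if (object@nExchangeable != expect)
      msg <- c(msg, sprintf(
        "nExchangeable must be %d (length - 1 - interior prolines)", expect))
    if (is.null(msg)) TRUE else msg
  })

#' MethylProbe: a methyl group reporting on the R/L ensemble
#'
#' A [13C,1H]-methyl probe with R-state and L-state peak positions.  For
#' probes in slow exchange the two states give separate peaks whose
#' volumes are proportional to the state populations; the slow-exchange
#' condition (chemical-shift gap in angular frequency much greater than
#' the exchange rate) is enforced at construction.
#'
#' @slot probeId residue label, e.g. \code{"I72"}.
#' @slot shiftR,shiftL numeric length-2 (1H ppm, 13C ppm) peak positions.
#' @slot category probe category; see \code{PROBE_CATEGORIES}.
#' @exportClass MethylProbe
setClass("MethylProbe",
  representation(probeId = "character", shiftR = "numeric",
                 shiftL = "numeric", category = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shiftR) != 2L || length(object@shiftL) != 2L)
      msg <- c(msg, "shiftR and shiftL must be (1H ppm, 13C ppm) pairs")
    if (!object@category %in% PROBE_CATEGORIES)
      msg <- c(msg, "invalid probe category")
    if (identical(object@category, "EXCHANGE_REPORTER")) {
      if (isTRUE(all.equal(object@shiftR, object@shiftL)))
        msg <- c(msg, "exchange reporters must have distinct R and L shifts")
      else {
        ratio <- deltaOmega(object@shiftR, object@shiftL) / 300
        if (ratio <= 10)
          msg <- c(msg, sprintf(
            "slow-exchange condition violated: delta-omega/kEx = %.2f <= 10",
            ratio))
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' SpectrumEnvelope: an isotope envelope of one peptide charge state
#'
#' @slot mz numeric m/z positions.
#' @slot intensity non-negative intensities (same length as mz).
#' @slot charge positive integer charge state.
#' @exportClass SpectrumEnvelope
setClass("SpectrumEnvelope",
  representation(mz = "numeric", intensity = "numeric", charge = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@mz) != length(object@intensity))
      msg <- c(msg, "mz and intensity must have equal length")
    if (any(object@intensity < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (!any(object@intensity > 0))
      msg <- c(msg, "at least one intensity must be positive")
    if (object@charge < 1L)
      msg <- c(msg, "charge must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' UptakeCurve: a per-peptide deuterium-uptake time course
#'
#' Holds the raw (as-measured) uptake values, the in-exchange control, and
#' the corrected values (raw minus control).  Negative corrected values
#' are retained, never clamped.
#'
#' @slot peptide a \code{Peptide}, or NULL when assembled from a bare table.
#' @slot times labeling times in seconds, strictly increasing.
#' @slot rawUptake raw uptake in Da, one per time point.
#' @slot inExchange in-exchange control uptake (Da), a single value.
#' @slot correctedUptake rawUptake - inExchange.
#' @slot sd per-time replicate standard deviation (may be empty).
#' @exportClass UptakeCurve
setClass("UptakeCurve",
  representation(peptide = "ANY", times = "numeric", rawUptake = "numeric",
                 inExchange = "numeric", correctedUptake = "numeric",
                 sd = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(object@rawUptake) != length(object@times) ||
        length(object@correctedUptake) != length(object@times))
      msg <- c(msg, "uptake vectors must match the time grid")
    if (length(object@inExchange) != 1L || !is.finite(object@inExchange))
      msg <- c(msg, "inExchange must be a single finite value")
    if (max(abs(object@correctedUptake -
                (object@rawUptake - object@inExchange))) > 1e-8)
      msg <- c(msg, "correctedUptake must equal rawUptake - inExchange")
    if (!is.null(object@peptide) && !is(object@peptide, "Peptide"))
      msg <- c(msg, "peptide must be a Peptide or NULL")
    if (is.null(msg)) TRUE else msg
  })

#' StructureModel: atomic coordinates with author residue numbering
#'
#' @slot atoms data.frame with columns chain, resno, resid, elety, element,
#'   o (occupancy), alt, x, y, z.
#' @exportClass StructureModel
setClass("StructureModel",
  representation(atoms = "data.frame"),
  validity = function(object) {
    need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
    msg <- NULL
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, paste("atoms must have columns:",
                          paste(need, collapse = ", ")))
    else {
      if (nrow(object@atoms) == 0L)
        msg <- c(msg, "empty model")
      if (any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
        msg <- c(msg, "coordinates must be finite")
      key <- with(object@atoms, paste(chain, resno, elety))
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (chain, residue, atom) after altloc filtering")
    }
    if (is.null(msg)) TRUE else msg
  })

#' SelectionSpec: an atom selection for superposition
#'
#' @slot chainId chain identifier (\code{NA} selects the first chain).
#' @slot residueRanges two-column integer matrix of inclusive
#'   (start, end) residue ranges; ranges must not overlap.
#' @slot atomNames atom names to select (default C-alpha only).
#' @slot numberingOffset integer added to the mobile structure's residue
#'   numbers to reconcile author numbering between entries.
#' @exportClass SelectionSpec
setClass("SelectionSpec",
  representation(chainId = "character", residueRanges = "matrix",
                 atomNames = "character", numberingOffset = "integer"),
  validity = function(object) {
    msg <- NULL
    rr <- object@residueRanges
    if (ncol(rr) != 2L || any(rr[, 2] < rr[, 1]))
      msg <- c(msg, "residueRanges must be a 2-column matrix with end >= start")
    if (nrow(rr) > 1L) {
      o <- order(rr[, 1])
      if (any(rr[o, 1][-1] <= rr[o, 2][-nrow(rr)]))
        msg <- c(msg, "residue ranges must not overlap")
    }
    if (is.null(msg)) TRUE else msg
  })

#' SuperpositionResult: an optimal rigid-body alignment
#'
#' @slot rotation 3x3 proper rotation matrix (applied as \code{x \%*\% R}).
#' @slot translation length-3 translation applied after rotation.
#' @slot rmsd least-squares RMSD over the fitted selection, in Angstrom.
#' @slot nAtoms number of atom pairs used in the fit.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer"),
  validity = function(object) {
    msg <- NULL
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)))
      msg <- c(msg, "rotation must be 3x3")
    else {
      if (max(abs(t(R) %*% R - diag(3))) > 1e-6)
        msg <- c(msg, "rotation must be orthonormal")
      if (abs(det(R) - 1) > 1e-6)
        msg <- c(msg, "rotation must be proper (det = +1)")
    }
    if (object@rmsd < 0)
      msg <- c(msg, "rmsd must be non-negative")
    if (is.null(msg)) TRUE else msg
  })
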