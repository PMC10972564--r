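## Population estimation from slow-exchange peak pairs, chemical-shift
## perturbations, and probe categorisation.

#' Reshape a peak table into R/L peak pairs
#'
#' Pairs the R- and L-state rows of each probe and flags pairs whose
#' total volume falls below the detection threshold (broadened).
#' Single-peak probes yield a pair with zero L volume.
#'
#' @param peakTable data.frame from \code{\link{simulateHmqcPeakPairs}}
#'   or \code{\link{readPeakTable}}.
#' @param apoVolumes optional named vector of per-probe apo total
#'   volumes used as the broadening reference (default: unit volume).
#' @param detectionFraction volumes below this fraction of the reference
#'   are treated as undetectable (default 5 percent).
#' @return data.frame with columns probe_id, h_ppm_R, c_ppm_R,
#'   volume_R, h_ppm_L, c_ppm_L, volume_L, broadened.
#' @export
peakPairs <- function(peakTable, apoVolumes = NULL,
                      detectionFraction = 0.05) {
  rows <- lapply(unique(peakTable$probe_id), function(id) {
    sub <- peakTable[peakTable$probe_id == id, , drop = FALSE]
    r <- sub[sub$state == "R", , drop = FALSE]
    l <- sub[sub$state == "L", , drop = FALSE]
    ref <- if (!is.null(apoVolumes) && id %in% names(apoVolumes))
      apoVolumes[[id]] else 1
    vR <- if (nrow(r)) sum(r$volume) else 0
    vL <- if (nrow(l)) sum(l$volume) else 0
    lim <- detectionFraction * ref
    data.frame(
      probe_id = id,
      h_ppm_R = if (nrow(r)) r$h_ppm[1] else NA_real_,
      c_ppm_R = if (nrow(r)) r$c_ppm[1] else NA_real_,
      volume_R = if (vR >= lim) vR else 0,
      h_ppm_L = if (nrow(l)) l$h_ppm[1] else NA_real_,
      c_ppm_L = if (nrow(l)) l$c_ppm[1] else NA_real_,
      volume_L = if (vL >= lim) vL else 0,
      broadened = vR < lim && vL < lim,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Estimate R:L populations from slow-exchange peak pairs
#'
#' Under slow exchange each conformer gives a resolved peak whose volume
#' is proportional to its population, so \eqn{\hat p_R =
#' V_R / (V_R + V_L)}.  Broadened pairs yield no estimate (NA, with the
#' reason recorded); a pair with both volumes zero but not flagged
#' broadened is an error.  When the volume noise level is supplied the
#' estimator's uncertainty is propagated by the delta method.
#'
#' @param pairs data.frame from \code{\link{peakPairs}}, or a peak table
#'   (then converted with default settings).
#' @param volumeNoiseSd optional volume noise standard deviation used
#'   for uncertainty propagation.
#' @return data.frame with columns probe_id, p_R, uncertainty.
#' @examples
#' tab <- simulateHmqcPeakPairs(defaultMethylProbes()[1:3],
#'                              ConformerModel(0.8))
#' estimatePopulations(peakPairs(tab))
#' @export
estimatePopulations <- function(pairs, volumeNoiseSd = NA_real_) {
  if (!"volume_R" %in% names(pairs)) pairs <- peakPairs(pairs)
  est <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    if (isTRUE(p$broadened))
      return(data.frame(probe_id = p$probe_id, p_R = NA_real_,
                        uncertainty = NA_real_,
                        stringsAsFactors = FALSE))
    tot <- p$volume_R + p$volume_L
    if (tot <= 0)
      stop("both peak volumes zero for probe ", p$probe_id,
           " (not flagged broadened)")
    pr <- p$volume_R / tot
    unc <- if (is.na(volumeNoiseSd)) 0 else
      volumeNoiseSd * sqrt(p$volume_R^2 + p$volume_L^2) / tot^2
    data.frame(probe_id = p$probe_id, p_R = pr, uncertainty = unc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(est, list(make.row.names = FALSE)))
}

#' Combined 1H/13C chemical-shift perturbation
#'
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 +
#'   (w_C \, \Delta\delta_C)^2}}
#' with the conventional methyl carbon weight \eqn{w_C = 0.25}.  The
#' measure is a symmetric distance: swapping apo and bound leaves it
#' unchanged, and it is zero iff both dimensions coincide.
#'
#' @param apo,bound numeric (1H ppm, 13C ppm) peak positions.
#' @param carbonWeight carbon scaling weight in (0, 1].
#' @return Non-negative combined shift perturbation in ppm.
#' @export
chemicalShiftPerturbation <- function(apo, bound, carbonWeight = 0.25) {
  if (carbonWeight <= 0) stop("carbonWeight must be positive")
  sqrt((apo[1] - bound[1])^2 + (carbonWeight * (apo[2] - bound[2]))^2)
}

#' Chemical-shift-perturbation matrix across an inhibitor panel
#'
#' Computes the combined shift perturbation of every probe under every
#' inhibitor, relative to the apo peak table.  Broadened probes (volume
#' below the detection fraction of their apo volume) are recorded as
#' \code{NA}.  For slow-exchange reporters the dominant-state (R) peak
#' is used.
#'
#' @param apoTable apo peak table.
#' @param boundTables named list of bound peak tables (names = inhibitor
#'   ids).
#' @param carbonWeight passed to
#'   \code{\link{chemicalShiftPerturbation}}.
#' @param detectionFraction broadening threshold relative to the apo
#'   volume.
#' @return Numeric matrix, probes x inhibitors, with NA marking
#'   broadened entries.
#' @export
cspMatrix <- function(apoTable, boundTables, carbonWeight = 0.25,
                      detectionFraction = 0.05) {
  apoPairs <- peakPairs(apoTable)
  apoVol <- stats::setNames(apoPairs$volume_R + apoPairs$volume_L,
                            apoPairs$probe_id)
  probes <- apoPairs$probe_id
  out <- matrix(NA_real_, length(probes), length(boundTables),
                dimnames = list(probes, names(boundTables)))
  for (inh in names(boundTables)) {
    bp <- peakPairs(boundTables[[inh]], apoVolumes = apoVol,
                    detectionFraction = detectionFraction)
    for (id in probes) {
      b <- bp[bp$probe_id == id, ]
      a <- apoPairs[apoPairs$probe_id == id, ]
      if (!nrow(b) || isTRUE(b$broadened)) next
      out[id, inh] <- chemicalShiftPerturbation(
        c(a$h_ppm_R, a$c_ppm_R), c(b$h_ppm_R, b$c_ppm_R),
        carbonWeight = carbonWeight)
    }
  }
  out
}

## point-biserial correlation between a numeric vector and a logical
## indicator; NA when either side is constant
.pointBiserial <- function(x, ind) {
  if (length(unique(ind)) < 2L || stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, as.numeric(ind))
}

#' Categorise methyl probes from their perturbation patterns
#'
#' Applies the fixed rules: a probe broadened under every inhibitor is a
#' contact probe (\code{CONTACT_BROADENED}); otherwise, a probe whose
#' shift perturbations correlate with the R-state-selective indicator
#' (point-biserial correlation at least \code{threshold}, with a minimum
#' perturbation dynamic range to exclude flat probes) is an
#' \code{R_STATE_REPORTER}; analogously for the left-side
#' (tetrahydropyran) indicator and \code{LEFT_SIDE_REPORTER}; anything
#' else is \code{UNCLASSIFIED}.  Broadened entries are dropped pairwise
#' before computing correlations.
#'
#' @param csp probes x inhibitors matrix from \code{\link{cspMatrix}}
#'   (NA = broadened).
#' @param classLabels named character vector of conformational classes
#'   per inhibitor (\code{"R_SELECTIVE"} etc.); at least two inhibitors
#'   per indicator level are required.
#' @param leftSideLabels named character vector of left-side groups per
#'   inhibitor.
#' @param threshold point-biserial correlation threshold (default 0.8).
#' @param minRange minimum perturbation dynamic range in ppm (default
#'   0.02).
#' @return Named character vector of categories per probe.
#' @export
categorizeProbes <- function(csp, classLabels, leftSideLabels = NULL,
                             threshold = 0.8, minRange = 0.02) {
  stopifnot(!is.null(rownames(csp)), !is.null(colnames(csp)))
  if (!all(colnames(csp) %in% names(classLabels)))
    stop("classLabels missing for: ",
         paste(setdiff(colnames(csp), names(classLabels)), collapse = ", "))
  out <- stats::setNames(rep("UNCLASSIFIED", nrow(csp)), rownames(csp))
  for (id in rownames(csp)) {
    x <- csp[id, ]
    if (all(is.na(x))) { out[id] <- "CONTACT_BROADENED"; next }
    ok <- !is.na(x)
    if (diff(range(x[ok])) < minRange) next
    rsel <- classLabels[colnames(csp)[ok]] == "R_SELECTIVE"
    rR <- .pointBiserial(x[ok], rsel)
    rL <- NA_real_
    if (!is.null(leftSideLabels)) {
      thp <- leftSideLabels[colnames(csp)[ok]] == "TETRAHYDROPYRAN"
      rL <- .pointBiserial(x[ok], thp)
    }
    cand <- c(R_STATE_REPORTER = rR, LEFT_SIDE_REPORTER = rL)
    cand <- cand[!is.na(cand) & cand >= threshold]
    if (length(cand)) out[id] <- names(cand)[which.max(cand)]
  }
  out
}
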