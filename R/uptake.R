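## Deuterium-uptake computation from isotope envelopes and assembly of
## corrected time courses.

#' Intensity-weighted centroid mass of an isotope envelope
#'
#' Returns the intensity-weighted mean mass on the neutral scale: each
#' m/z is decharged (\code{mz * z - z * 1.007276}) before averaging, so
#' the result is charge-independent and invariant to uniform intensity
#' scaling.
#'
#' @param envelope a \code{\linkS4class{SpectrumEnvelope}}.
#' @return Neutral centroid mass in Da.
#' @examples
#' centroidMass(SpectrumEnvelope(c(501.0, 501.5), c(1, 1), charge = 2L))
#' @export
centroidMass <- function(envelope) {
  stopifnot(is(envelope, "SpectrumEnvelope"))
  z <- envelope@charge
  neutral <- envelope@mz * z - z * PROTON_MASS
  sum(neutral * envelope@intensity) / sum(envelope@intensity)
}

#' Deuterium uptake from a pair of centroid masses
#'
#' The deuterated centroid referenced to the undeuterated (unlabeled)
#' centroid of the same peptide.  Negative differences (possible with
#' noisy centroids) are preserved and flagged with a warning, never
#' clamped, because clamping would bias the downstream dAUC statistic.
#'
#' @param deuteratedCentroid,undeuteratedCentroid neutral centroid
#'   masses in Da.
#' @return Signed uptake in Da.
#' @export
deuteriumUptake <- function(deuteratedCentroid, undeuteratedCentroid) {
  stopifnot(is.finite(deuteratedCentroid), is.finite(undeuteratedCentroid))
  d <- deuteratedCentroid - undeuteratedCentroid
  if (d < 0)
    warning(sprintf("negative deuterium uptake (%.4g Da) retained", d))
  d
}

#' Apply the in-exchange correction to a raw uptake curve
#'
#' Subtracts the in-exchange control (deuterium acquired during quench
#' handling, measured by quenching before labeling) from every time
#' point.  Raw values are retained alongside the corrected ones;
#' negative corrected values are flagged, not clamped.
#'
#' @param raw an \code{\linkS4class{UptakeCurve}} holding raw values
#'   (its existing correction, if any, is ignored).
#' @param controlUptake non-negative control uptake in Da.
#' @return An \code{\linkS4class{UptakeCurve}} with
#'   \code{correctedUptake = rawUptake - controlUptake}.
#' @export
inExchangeCorrect <- function(raw, controlUptake) {
  stopifnot(is(raw, "UptakeCurve"))
  if (controlUptake < 0) stop("controlUptake must be >= 0")
  out <- UptakeCurve(times = raw@times, rawUptake = raw@rawUptake,
                     inExchange = controlUptake, peptide = raw@peptide,
                     sd = raw@sd)
  if (any(out@correctedUptake < 0))
    warning("negative corrected uptake value(s) retained")
  out
}

#' Assemble a replicate-averaged uptake time course
#'
#' Averages replicate (time, uptake) measurements onto a sorted time
#' grid, recording the per-time standard deviation.
#'
#' @param replicates data.frame with columns \code{time_s} and
#'   \code{uptake_Da} (one row per replicate measurement).
#' @param peptide optional \code{\linkS4class{Peptide}}.
#' @param inExchange in-exchange value carried into the curve (default
#'   0, i.e. values are taken as already corrected or uncorrected).
#' @return An \code{\linkS4class{UptakeCurve}} of per-time means.
#' @export
buildTimeCourse <- function(replicates, peptide = NULL, inExchange = 0) {
  if (!nrow(replicates)) stop("no replicate measurements supplied")
  stopifnot(all(c("time_s", "uptake_Da") %in% names(replicates)))
  tm <- sort(unique(replicates$time_s))
  mu <- vapply(tm, function(t)
    mean(replicates$uptake_Da[replicates$time_s == t]), numeric(1))
  sdv <- vapply(tm, function(t) {
    x <- replicates$uptake_Da[replicates$time_s == t]
    if (length(x) > 1L) stats::sd(x) else 0
  }, numeric(1))
  UptakeCurve(times = tm, rawUptake = mu + inExchange,
              inExchange = inExchange, peptide = peptide, sd = sdv)
}

#' Build a corrected, averaged uptake curve from a panel table
#'
#' Extracts one (enzyme form, condition, peptide) time course from the
#' long-format uptake table produced by \code{\link{simulatePanel}} (or
#' read back from CSV), subtracts the condition's in-exchange control
#' from every replicate value, and averages replicates per time point.
#'
#' @param uptakeTable long-format uptake data.frame.
#' @param proteinState \code{"0P"} or \code{"2P"}.
#' @param condition \code{"apo"} or an inhibitor id.
#' @param peptideStart start residue number of the peptide to extract.
#' @return An \code{\linkS4class{UptakeCurve}} of corrected means.
#' @export
uptakeCurveFromTable <- function(uptakeTable, proteinState, condition,
                                 peptideStart) {
  sel <- uptakeTable$protein_state == proteinState &
    uptakeTable$condition == condition &
    uptakeTable$peptide_start == peptideStart
  sub <- uptakeTable[sel, , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("no rows for %s/%s/peptide %s", proteinState, condition,
                 peptideStart))
  ctrl <- sub$uptake_Da[sub$is_control]
  control <- if (length(ctrl)) mean(ctrl) else 0
  meas <- sub[!sub$is_control, , drop = FALSE]
  ## correct each replicate, then average (the two operations commute
  ## for a constant control)
  meas$uptake_Da <- meas$uptake_Da - control
  curve <- buildTimeCourse(meas[, c("time_s", "uptake_Da")])
  UptakeCurve(times = curve@times,
              rawUptake = curve@rawUptake - curve@inExchange + control,
              inExchange = control, sd = curve@sd)
}

#' Write / read the long-format uptake table CSV
#'
#' The dialect has columns protein_state, condition, peptide_start,
#' peptide_end, sequence, time_s, uptake_Da, replicate, is_control;
#' in-exchange control rows use \code{time_s = 0} with
#' \code{is_control = TRUE}.  Values round-trip at full printed
#' precision.
#'
#' @param uptakeTable data.frame in the dialect above.
#' @param path file path.
#' @return \code{readUptakeTable} returns the data.frame;
#'   \code{writeUptakeTable} returns \code{path} invisibly.
#' @export
writeUptakeTable <- function(uptakeTable, path) {
  utils::write.csv(uptakeTable, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeUptakeTable
#' @export
readUptakeTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a methyl peak-table CSV
#'
#' Columns: probe_id, state, h_ppm, c_ppm, volume.
#'
#' @param peakTable data.frame as produced by
#'   \code{\link{simulateHmqcPeakPairs}}.
#' @param path file path.
#' @export
writePeakTable <- function(peakTable, path) {
  utils::write.csv(peakTable, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePeakTable
#' @export
readPeakTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read an isotope-envelope CSV (mz, intensity; single charge)
#'
#' @param path CSV with columns mz, intensity and a charge column (or a
#'   single charge value repeated).
#' @return A \code{\linkS4class{SpectrumEnvelope}}.
#' @export
readEnvelopeCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mz", "intensity", "charge") %in% names(df)))
  z <- unique(df$charge)
  if (length(z) != 1L) stop("envelope file must carry a single charge state")
  SpectrumEnvelope(df$mz, df$intensity, as.integer(z))
}
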