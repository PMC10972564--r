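## The dAUC difference statistic, per-segment ranking, and panel
## classification.

#' Difference-AUC (dAUC) between apo and inhibitor-bound uptake curves
#'
#' The conformation-selection statistic: the sum over the labeling time
#' points of the corrected-uptake difference,
#' \deqn{dAUC = \sum_t (HDX_{apo} - HDX_{inhibitor})_t.}
#' Positive values mean the inhibitor protects the segment (lower uptake
#' than apoenzyme).  The statistic is antisymmetric in its arguments,
#' linear in each curve, and invariant to adding a common constant to
#' both curves.
#'
#' @param apo,inhibitor \code{\linkS4class{UptakeCurve}} objects on
#'   identical time grids (and the same peptide, when both carry one).
#' @return dAUC in Da summed over time points.
#' @export
computeDauc <- function(apo, inhibitor) {
  stopifnot(is(apo, "UptakeCurve"), is(inhibitor, "UptakeCurve"))
  if (length(apo@times) != length(inhibitor@times) ||
      any(apo@times != inhibitor@times))
    stop("time grids differ between curves")
  if (!is.null(apo@peptide) && !is.null(inhibitor@peptide) &&
      !identical(apo@peptide@sequence, inhibitor@peptide@sequence))
    stop("curves belong to different peptides")
  sum(apo@correctedUptake - inhibitor@correctedUptake)
}

#' Per-segment dAUC table for an inhibitor panel
#'
#' Builds corrected, replicate-averaged curves from a long-format uptake
#' table and computes dAUC against the apoenzyme for every (inhibitor,
#' segment) pair.
#'
#' @param uptakeTable long-format table from \code{\link{simulatePanel}}
#'   or \code{\link{readUptakeTable}}.
#' @param segments named list of start residue numbers, or of
#'   \code{c(start, end)} pairs, identifying the reporter peptides (e.g.
#'   \code{list(DFG_161_168 = c(161, 168), P1_191_198 = c(191, 198))}).
#' @param proteinState enzyme form to analyse (default \code{"2P"}, the
#'   form in which allosteric protection reports conformation
#'   selection).
#' @return data.frame with columns inhibitor_id, segment_id, dauc, rank
#'   (rank unset; see \code{\link{rankInhibitors}}).
#' @export
daucTable <- function(uptakeTable, segments, proteinState = "2P") {
  stopifnot(length(segments) >= 1, !is.null(names(segments)))
  sub <- uptakeTable[uptakeTable$protein_state == proteinState, ,
                     drop = FALSE]
  inhibitors <- setdiff(unique(sub$condition), "apo")
  rows <- list()
  for (sg in names(segments)) {
    start <- segments[[sg]][1]
    if (!any(sub$peptide_start == start))
      stop("segment not present in uptake table: ", sg)
    apo <- uptakeCurveFromTable(sub, proteinState, "apo", start)
    for (inh in inhibitors) {
      cur <- uptakeCurveFromTable(sub, proteinState, inh, start)
      rows[[length(rows) + 1L]] <- data.frame(
        inhibitor_id = inh, segment_id = sg,
        dauc = computeDauc(apo, cur), rank = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Rank inhibitors by dAUC within a segment
#'
#' Descending dAUC maps to ascending rank (rank 1 = strongest
#' protection); ties receive the average rank.
#'
#' @param records dAUC data.frame from \code{\link{daucTable}}.
#' @param segmentId segment to rank; must be present.
#' @return The records with the \code{rank} column filled for that
#'   segment.
#' @export
rankInhibitors <- function(records, segmentId) {
  sel <- records$segment_id == segmentId
  if (!any(sel)) stop("no records for segment: ", segmentId)
  records$rank[sel] <- rank(-records$dauc[sel], ties.method = "average")
  records
}

#' Classify a panel as R-selective / exchange-retaining / intermediate
#'
#' Per segment, dAUC values are min-max normalised to [0, 1] across the
#' panel (the reference compounds anchor the extremes on the default
#' generator); the combined score is the mean of the per-segment
#' normalised scores, and a fixed threshold rule replaces visual
#' clustering: R-selective when the combined score is at least
#' \code{tHigh}, exchange-retaining when at most \code{tLow}, otherwise
#' intermediate.  The rule is invariant to affine rescaling of all dAUC
#' values.  If a segment's dAUC values are all equal, its normalised
#' scores degenerate to 0.5 and a warning is emitted.
#'
#' @param records dAUC data.frame from \code{\link{daucTable}}.
#' @param segments character vector of (typically two) segment ids to
#'   combine.
#' @param tLow,tHigh classification thresholds on the combined score.
#' @param referenceIds ids of the normalisation reference compounds;
#'   they are classified too but are conventionally excluded from panel
#'   counts.
#' @return data.frame with one row per inhibitor: per-segment normalised
#'   scores (\code{score_<segment>}), \code{combined_score},
#'   \code{label}, and \code{is_reference}.
#' @export
classifyPanel <- function(records,
                          segments = unique(records$segment_id),
                          tLow = 0.4, tHigh = 0.6,
                          referenceIds = c("VTX11e", "GDC0994")) {
  stopifnot(length(segments) >= 1, tLow <= tHigh)
  ids <- unique(records$inhibitor_id)
  scores <- matrix(NA_real_, length(ids), length(segments),
                   dimnames = list(ids, segments))
  for (sg in segments) {
    sub <- records[records$segment_id == sg, , drop = FALSE]
    if (!nrow(sub)) stop("no records for segment: ", sg)
    if (!all(ids %in% sub$inhibitor_id))
      stop("segment ", sg, " missing inhibitors: ",
           paste(setdiff(ids, sub$inhibitor_id), collapse = ", "))
    rng <- range(sub$dauc)
    if (diff(rng) == 0) {
      warning("degenerate normalisation for segment ", sg,
              " (all dAUC equal); scores set to 0.5")
      scores[sub$inhibitor_id, sg] <- 0.5
    } else {
      scores[sub$inhibitor_id, sg] <- (sub$dauc - rng[1]) / diff(rng)
    }
  }
  combined <- rowMeans(scores)
  label <- ifelse(combined >= tHigh, "R_SELECTIVE",
                  ifelse(combined <= tLow, "EXCHANGE", "INTERMEDIATE"))
  out <- data.frame(inhibitor_id = ids, scores,
                    combined_score = combined, label = label,
                    is_reference = ids %in% referenceIds,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[seq_along(segments) + 1L] <- paste0("score_", segments)
  out
}
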