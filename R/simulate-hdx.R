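## Forward model for peptide-level deuterium uptake under two-state
## conformational exchange.

## Effective R-state population of a (model, inhibitor, enzyme form)
## combination.  In the 0P form all inhibitors retain the pure-L
## apoenzyme ensemble; in the 2P form the inhibitor's conformational
## class decides whether the equilibrium is trapped (R-selective),
## untouched (exchange-retaining), or partially shifted (intermediate).
effectivePR <- function(model, inhibitor = NULL, proteinState = "2P") {
  if (is.null(inhibitor) || identical(proteinState, "0P"))
    return(model@pR)
  switch(inhibitor@confClass,
         R_SELECTIVE = 1,
         EXCHANGE = model@pR,
         INTERMEDIATE = inhibitor@boundPR)
}

## Per-residue observed rates under the fast-ensemble limit.  Because the
## conformational exchange rate (default 300/s) vastly exceeds every
## observable amide rate on the labeling grid (slowest point 30 s), each
## amide exchanges at the population-weighted mean of its state rates:
##   k_obs = pR * kInt / PF_R + pL * kInt / PF_L.
observedRates <- function(residues, model, inhibitor = NULL,
                          proteinState = "2P") {
  pr <- effectivePR(model, inhibitor, proteinState)
  pfR <- residues$pfR
  pfL <- residues$pfL
  if (!is.null(inhibitor)) {
    contact <- residues$region %in% CONTACT_REGIONS |
      !nzchar(residues$region)
    allo <- residues$region %in% ALLOSTERIC_REGIONS
    mult <- rep(1, nrow(residues))
    mult[contact] <- inhibitor@contactMultiplier
    if (identical(proteinState, "2P"))
      mult[allo] <- inhibitor@allostericMultiplier
    pfR <- pfR * mult
    pfL <- pfL * mult
  }
  ifelse(residues$exchangeable,
         pr * residues$kInt / pfR + (1 - pr) * residues$kInt / pfL,
         NA_real_)
}

#' Simulate a peptide deuterium-uptake time course
#'
#' Forward model: every exchange-competent amide exchanges as a single
#' exponential at its population-weighted observed rate (fast-ensemble
#' limit of the two-state model), and peptide-level uptake is the scaled
#' sum
#' \deqn{u(t) = f_{lab} \, f_{bx} \sum_i (1 - e^{-k_{obs,i} t}),}
#' where \eqn{f_{lab}} is the labeling D2O fraction and \eqn{f_{bx}} the
#' constant back-exchange survival factor.  An in-exchange offset
#' (deuterium picked up during quench handling, modeled as a fixed
#' window at strongly reduced rates) is added to every raw value and
#' recorded in the returned curve so that correction reproduces the
#' offset-free course.
#'
#' @param peptide a \code{\linkS4class{Peptide}}.
#' @param residues per-residue table from
#'   \code{\link{residueExchangeSpecs}}.
#' @param model a \code{\linkS4class{ConformerModel}} (apo ensemble).
#' @param inhibitor optional \code{\linkS4class{InhibitorSpec}}; NULL
#'   simulates the apoenzyme.
#' @param times labeling times in seconds, sorted ascending.
#' @param labelingFraction D2O fraction during labeling, in (0, 1];
#'   default 0.9 (54 uL D2O added to 6 uL protein).
#' @param backExchangeFactor fraction of incorporated deuterium surviving
#'   quench and LC handling; default 0.75, constant across peptides.
#' @param proteinState \code{"2P"} or \code{"0P"}; in the 0P form
#'   inhibitors retain the pure-L ensemble and allosteric protection does
#'   not apply.
#' @param inExchangeWindow duration (s) of the quench-handling window
#'   generating the in-exchange control.
#' @param inExchangeRateFactor factor by which rates are reduced during
#'   that window (default 100).
#' @return An \code{\linkS4class{UptakeCurve}} whose raw values include
#'   the in-exchange offset and whose \code{inExchange} slot holds it.
#' @examples
#' pep <- defaultPeptides()$dfg
#' res <- residueExchangeSpecs(pep)
#' simulatePeptideUptake(pep, res, ConformerModel(0.8))
#' @export
simulatePeptideUptake <- function(peptide, residues, model,
                                  inhibitor = NULL,
                                  times = defaultTimeGrid(),
                                  labelingFraction = 0.9,
                                  backExchangeFactor = 0.75,
                                  proteinState = c("2P", "0P"),
                                  inExchangeWindow = 30,
                                  inExchangeRateFactor = 100) {
  proteinState <- match.arg(proteinState)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be sorted strictly ascending")
  if (labelingFraction <= 0 || labelingFraction > 1)
    stop("labelingFraction must be in (0, 1]")
  k <- observedRates(residues, model, inhibitor, proteinState)
  k <- k[!is.na(k)]
  scale <- labelingFraction * backExchangeFactor
  uptake <- vapply(times, function(t) scale * sum(1 - exp(-k * t)),
                   numeric(1))
  inex <- scale * sum(1 - exp(-k * inExchangeWindow / inExchangeRateFactor))
  UptakeCurve(times = times, rawUptake = uptake + inex, inExchange = inex,
              peptide = peptide)
}
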