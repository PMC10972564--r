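## Default methyl-probe set and the peak-response model of the NMR
## simulator.

#' Default methyl-probe set
#'
#' Thirteen [13C,1H]-methyl probes mirroring the reporter groups of the
#' ERK2 system: three slow-exchange reporters whose R/L peak pairs read
#' out the conformational populations (I72, L220, L242); two R-state
#' reporters in the P+1 segment and helix alphaL16 whose chemical-shift
#' perturbations track R-state selection (I196, I345); four left-side
#' reporters near the hinge/front pocket that distinguish
#' tetrahydropyran from pyrazole left-side substituents (L26, L105,
#' L155, L161); two first-shell contact probes broadened by every bound
#' inhibitor (I82, L154); and three second-shell probes broadened by all
#' inhibitors except the amidopyrrole-scaffold compounds (V12, V37,
#' I101).  Peak positions are generator defaults on a plausible
#' methyl-region grid, not measured shifts.
#'
#' @return Named list of \code{\linkS4class{MethylProbe}} objects.
#' @export
defaultMethylProbes <- function() {
  list(
    I72  = MethylProbe("I72",  c(0.78, 12.9), c(0.43, 10.9),
                       "EXCHANGE_REPORTER"),
    L220 = MethylProbe("L220", c(0.85, 24.6), c(0.55, 22.4),
                       "EXCHANGE_REPORTER"),
    L242 = MethylProbe("L242", c(0.95, 25.3), c(0.50, 23.4),
                       "EXCHANGE_REPORTER"),
    I196 = MethylProbe("I196", c(0.62, 13.4), category = "R_STATE_REPORTER"),
    I345 = MethylProbe("I345", c(0.70, 14.1), category = "R_STATE_REPORTER"),
    L26  = MethylProbe("L26",  c(0.88, 23.8), category = "LEFT_SIDE_REPORTER"),
    L105 = MethylProbe("L105", c(0.80, 25.1), category = "LEFT_SIDE_REPORTER"),
    L155 = MethylProbe("L155", c(0.74, 22.9), category = "LEFT_SIDE_REPORTER"),
    L161 = MethylProbe("L161", c(0.92, 24.2), category = "LEFT_SIDE_REPORTER"),
    I82  = MethylProbe("I82",  c(0.66, 13.0), category = "CONTACT_BROADENED"),
    L154 = MethylProbe("L154", c(0.81, 23.4), category = "CONTACT_BROADENED"),
    V12  = MethylProbe("V12",  c(0.90, 21.5),
                       category = "CONTACT_BROADENED_EXCEPT_AMIDOPYRROLE"),
    V37  = MethylProbe("V37",  c(0.84, 20.9),
                       category = "CONTACT_BROADENED_EXCEPT_AMIDOPYRROLE"),
    I101 = MethylProbe("I101", c(0.73, 13.7),
                       category = "CONTACT_BROADENED_EXCEPT_AMIDOPYRROLE"))
}

## peak-displacement model (ppm): R-state reporters move in proportion to
## the population shift the inhibitor induces; left-side reporters move
## by a fixed vector set by the left-side substituent chemistry.
.R_STATE_RESPONSE <- c(h = 0.15, c = 0.60)        # ppm per unit delta-pR
.LEFT_SIDE_DISPLACEMENT <- list(
  PYRAZOLE        = c(h = 0.015, c = 0.05),
  TETRAHYDROPYRAN = c(h = 0.060, c = 0.25),
  OTHER           = c(h = 0.010, c = 0.03))

## TRUE when the probe's peak is broadened beyond detection under the
## given inhibitor
isBroadened <- function(probe, inhibitor) {
  if (is.null(inhibitor)) return(FALSE)
  switch(probe@category,
         CONTACT_BROADENED = TRUE,
         CONTACT_BROADENED_EXCEPT_AMIDOPYRROLE =
           !identical(inhibitor@scaffold, "AMIDOPYRROLE"),
         FALSE)
}

## bound-state peak position of a single-peak probe
boundPosition <- function(probe, model, inhibitor) {
  pos <- probe@shiftR
  if (is.null(inhibitor)) return(pos)
  if (identical(probe@category, "R_STATE_REPORTER")) {
    dpr <- effectivePR(model, inhibitor) - model@pR
    pos <- pos + unname(.R_STATE_RESPONSE) * dpr
  } else if (identical(probe@category, "LEFT_SIDE_REPORTER")) {
    pos <- pos + unname(.LEFT_SIDE_DISPLACEMENT[[inhibitor@leftSideGroup]])
  }
  pos
}
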