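## Intrinsic (unstructured-chain) amide exchange rates.
##
## Standard acid/base/water-catalysed form:
##   k_int = kA * 10^(-pD) * fA  +  kB * 10^(pD - pKD) * fB  +  kW
## with sequence dependence entering through log10 factors contributed by
## the residue's own side chain and that of the preceding residue.  Above
## pD ~ 5 the base-catalysed term dominates, so k_int scales linearly with
## deuteroxide concentration (tenfold per pD unit).  The neighbour-factor
## values are the generator's own parameterisation (see the methods
## vignette): they reproduce the qualitative spread of sequence effects
## rather than any published table verbatim.

AA_ONE_LETTER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## log10 modifiers of the base-catalysed rate: contribution of the
## residue's own side chain ("self") and of the preceding residue
## ("prev").  Alanine is the reference (0).
.BASE_FACTOR_SELF <- c(
  A =  0.00, C =  0.46, D =  0.10, E = -0.11, F = -0.24, G =  0.27,
  H =  0.14, I = -0.59, K = -0.04, L = -0.27, M = -0.11, N =  0.32,
  P =  0.00, Q =  0.06, R =  0.03, S =  0.37, T = -0.07, V = -0.52,
  W = -0.11, Y = -0.28)
.BASE_FACTOR_PREV <- c(
  A =  0.00, C =  0.62, D = -0.18, E = -0.15, F =  0.06, G =  0.17,
  H =  0.30, I = -0.23, K =  0.12, L = -0.21, M =  0.18, N =  0.60,
  P = -0.24, Q =  0.20, R =  0.23, S =  0.55, T = -0.06, V = -0.21,
  W =  0.12, Y =  0.05)

## reference rate constants at 25 C (s^-1, s^-1 M^-1 as appropriate) and
## activation energies (kcal/mol) for Arrhenius temperature scaling
.KB_LOG10 <- 8.50    # base catalysis, s^-1 M^-1
.KA_LOG10 <- 0.55    # acid catalysis, s^-1 M^-1
.KW_LOG10 <- -4.0    # water catalysis, s^-1
.PKD <- 15.05        # ion product of D2O at 25 C
.EA <- c(base = 17, acid = 14, water = 19)

.arrhenius <- function(temperatureC, EaKcal) {
  R <- 1.987204e-3                       # kcal / (mol K)
  exp(-EaKcal / R * (1 / (temperatureC + 273.15) - 1 / 298.15))
}

#' Intrinsic amide exchange rates along a sequence
#'
#' Computes per-residue intrinsic (unstructured) amide hydrogen-exchange
#' rates for a peptide or protein sequence at the given pD and
#' temperature, using the standard acid/base/water-catalysed form with
#' nearest-neighbour side-chain modifiers on the dominant base-catalysed
#' term.  The first residue and all prolines carry no observable amide
#' and return \code{NA}.
#'
#' @param sequence one-letter amino-acid string.
#' @param pD glass-electrode-corrected pD of the labeling buffer.
#' @param temperatureC labeling temperature in degrees Celsius.
#' @return Named numeric vector of rates (1/s), one element per residue;
#'   \code{NA} at position 1 and at prolines.
#' @examples
#' intrinsicRates("LKICDFGL", pD = 7.2, temperatureC = 25)
#' @export
intrinsicRates <- function(sequence, pD = 7.2, temperatureC = 25) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), AA_ONE_LETTER)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  n <- length(aa)
  kb <- 10^(.KB_LOG10 + pD - .PKD) * .arrhenius(temperatureC, .EA["base"])
  ka <- 10^(.KA_LOG10 - pD) * .arrhenius(temperatureC, .EA["acid"])
  kw <- 10^.KW_LOG10 * .arrhenius(temperatureC, .EA["water"])
  rates <- rep(NA_real_, n)
  for (i in seq_len(n)[-1L]) {
    if (aa[i] == "P") next
    fB <- 10^(.BASE_FACTOR_SELF[aa[i]] + .BASE_FACTOR_PREV[aa[i - 1L]])
    rates[i] <- unname(kb * fB + ka + kw)
  }
  names(rates) <- paste0(aa, seq_len(n))
  rates
}
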