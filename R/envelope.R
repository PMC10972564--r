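## Isotope-envelope simulation: natural-abundance fine structure
## convolved with a binomial deuteration distribution.

## monoisotopic element masses
.MONO <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)
PROTON_MASS <- 1.007276467
DEUTERIUM_INCREMENT <- 1.00627675  # mass(2H) - mass(1H), Da

## residue elemental compositions (C, H, N, O, S), peptide-bond form
.AA_COMP <- rbind(
  A = c(3, 5, 1, 1, 0),  C = c(3, 5, 1, 1, 1),  D = c(4, 5, 1, 3, 0),
  E = c(5, 7, 1, 3, 0),  F = c(9, 9, 1, 1, 0),  G = c(2, 3, 1, 1, 0),
  H = c(6, 7, 3, 1, 0),  I = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
  L = c(6, 11, 1, 1, 0), M = c(5, 9, 1, 1, 1),  N = c(4, 6, 2, 2, 0),
  P = c(5, 7, 1, 1, 0),  Q = c(5, 8, 2, 2, 0),  R = c(6, 12, 4, 1, 0),
  S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  V = c(5, 9, 1, 1, 0),
  W = c(11, 10, 2, 1, 0), Y = c(9, 9, 1, 2, 0))
colnames(.AA_COMP) <- c("C", "H", "N", "O", "S")

## heavy-isotope abundances by nominal mass increment (+1, +2)
.ISO_PLUS1 <- c(C = 0.0107, H = 0.000115, N = 0.00364, O = 0.00038,
                S = 0.0076)
.ISO_PLUS2 <- c(C = 0, H = 0, N = 0, O = 0.00205, S = 0.0429)

## elemental composition (named vector) of a peptide, free termini (+H2O)
peptideComposition <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), rownames(.AA_COMP))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  comp <- colSums(.AA_COMP[aa, , drop = FALSE])
  comp["H"] <- comp["H"] + 2
  comp["O"] <- comp["O"] + 1
  comp
}

## monoisotopic neutral mass of a peptide
peptideMonoMass <- function(sequence) {
  comp <- peptideComposition(sequence)
  sum(comp * .MONO[names(comp)])
}

## plain polynomial (distribution) convolution
.polyMul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (j in seq_along(b))
    out[seq_along(a) + j - 1L] <- out[seq_along(a) + j - 1L] + a * b[j]
  out
}

## distribution of nominal-mass increments for n atoms of one element
.elementDist <- function(n, p1, p2) {
  d <- 1
  step <- c(1 - p1 - p2, p1, p2)
  for (i in seq_len(n)) d <- .polyMul(d, step)
  d
}

## natural-abundance isotopologue distribution over integer increments
naturalAbundanceDist <- function(comp, tol = 1e-10) {
  d <- 1
  for (el in names(comp)) {
    if (comp[[el]] == 0) next
    d <- .polyMul(d, .elementDist(comp[[el]], .ISO_PLUS1[[el]],
                                  .ISO_PLUS2[[el]]))
  }
  keep <- max(which(d > tol))
  d[seq_len(keep)] / sum(d[seq_len(keep)])
}

#' Simulate the isotope envelope of a (partly deuterated) peptide
#'
#' Builds the natural-abundance isotope distribution from the peptide's
#' elemental composition and convolves it with a binomial distribution of
#' deuterium over the exchange-competent amides, each deuterated
#' independently with probability \code{deuterationProbability}.  Peaks
#' are laid on a uniform grid spaced by the 2H-1H mass difference
#' (1.00628 Da divided by the charge), the increment relevant to
#' deuteration, so that the envelope centroid shifts by exactly
#' \code{nExchangeable * p * 1.00628} Da relative to the undeuterated
#' envelope.
#'
#' @param peptide a \code{\linkS4class{Peptide}}.
#' @param deuterationProbability per-site deuteration probability in
#'   [0, 1].
#' @param charge positive integer charge state (protonation).
#' @return A \code{\linkS4class{SpectrumEnvelope}} with intensities
#'   normalised to sum 1.
#' @examples
#' env <- simulateIsotopeEnvelope(defaultPeptides()$dfg, 0.3, charge = 2L)
#' centroidMass(env)
#' @export
simulateIsotopeEnvelope <- function(peptide, deuterationProbability,
                                    charge = 1L) {
  stopifnot(is(peptide, "Peptide"))
  if (deuterationProbability < 0 || deuterationProbability > 1)
    stop("deuterationProbability must be in [0, 1]")
  if (charge < 1L) stop("charge must be >= 1")
  nat <- naturalAbundanceDist(peptideComposition(peptide@sequence))
  n <- peptide@nExchangeable
  deut <- stats::dbinom(0:n, n, deuterationProbability)
  full <- numeric(length(nat) + n)
  for (j in 0:n)
    full[seq_along(nat) + j] <- full[seq_along(nat) + j] + nat * deut[j + 1L]
  full <- full / sum(full)
  m0 <- peptideMonoMass(peptide@sequence)
  masses <- m0 + (seq_along(full) - 1L) * DEUTERIUM_INCREMENT
  SpectrumEnvelope(mz = (masses + charge * PROTON_MASS) / charge,
                   intensity = full, charge = as.integer(charge))
}
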