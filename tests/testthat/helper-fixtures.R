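## Shared fixtures and independent oracles, all built in code.

## a peptide with a single exchangeable amide
singleAmidePeptide <- function() Peptide(1L, 2L, "AG")

## residue table with fully specified kinetics (bypasses the rate model)
manualResidues <- function(resno, kInt, pfR = 1, pfL = 1, region = "") {
  n <- length(resno)
  data.frame(resno = resno, aa = rep("A", n), kInt = kInt,
             pfR = rep_len(pfR, n), pfL = rep_len(pfL, n),
             region = rep_len(region, n), isProline = FALSE,
             exchangeable = !is.na(kInt), stringsAsFactors = FALSE)
}

## Exhaustive-enumeration oracle for the envelope centroid shift: sum
## over all 2^n deuteration states of P(state) * (#deuterons * increment).
enumCentroidShift <- function(n, p, increment = 1.00627675) {
  states <- expand.grid(rep(list(0:1), n))
  k <- rowSums(states)
  prob <- p^k * (1 - p)^(n - k)
  sum(prob * k * increment)
}

## Brute-force rigid-fit oracle: minimise RMSD between centred clouds
## over ZYZ Euler angles (translation is optimal at centroid overlap).
bruteForceFitRmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rot <- function(a) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
    Rz(a[1]) %*% Ry(a[2]) %*% Rz(a[3])
  }
  obj <- function(a) sqrt(mean(rowSums((Xc %*% rot(a) - Yc)^2)))
  best <- Inf
  set.seed(42)
  for (i in 1:30) {
    fit <- stats::optim(stats::runif(3, -pi, pi), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

## rotation matrix about z by theta (row-vector convention x %*% R)
rotZ <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

## helix-like test structure: nRes residues with CA (+ optional CB/N/C)
## atoms on a spiral, as an atom data.frame
spiralAtoms <- function(nRes, atoms = "CA", chain = "A") {
  rows <- list()
  for (i in seq_len(nRes)) {
    base <- c(cos(i / 2) * 5, sin(i / 2) * 5, i * 1.5)
    for (j in seq_along(atoms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = i, resid = "ALA", elety = atoms[j],
        element = substr(atoms[j], 1, 1), o = 1, alt = "",
        x = base[1] + j * 0.9, y = base[2] - j * 0.4,
        z = base[3] + j * 0.6, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## apply a rigid transform to a StructureModel (for invariance tests)
rigidTransform <- function(model, R = diag(3), t = c(0, 0, 0)) {
  a <- model@atoms
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% R, 2, t, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  structureFromAtoms(a)
}

## minimal PDB writer for fixture files
writeMiniPdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    nm <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety) else a$elety
    sprintf("ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, nm, ifelse(nzchar(a$alt), a$alt, " "), a$resid,
            a$chain, a$resno, a$x, a$y, a$z, a$o, 0, a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

## ids of the 17 panel compounds
panelCompoundIds <- function() paste0("#", 1:17)
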