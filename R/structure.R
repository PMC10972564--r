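## Structural geometry: coordinate reading, Kabsch superposition,
## per-residue RMSD, and halogen-to-ring-centroid distances.

#' Read a structure from PDB or mmCIF
#'
#' Parses the file with bio3d, drops hydrogens, and keeps the
#' highest-occupancy alternate location per (chain, residue, atom name).
#' Waters are retained (they are never part of the measurements here but
#' provide context); author residue numbering is preserved.
#'
#' @param path path to a coordinate file.
#' @param format \code{"PDB"}, \code{"mmCIF"}, or \code{"auto"} (by
#'   file extension).
#' @return A \code{\linkS4class{StructureModel}}.
#' @export
readStructure <- function(path, format = c("auto", "PDB", "mmCIF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmCIF" else "PDB"
  pdb <- if (format == "mmCIF") bio3d::read.cif(path, rm.alt = FALSE) else
    bio3d::read.pdb(path, rm.alt = FALSE)
  atoms <- pdb$atom
  if (is.null(atoms) || !nrow(atoms)) stop("empty model in ", path)
  structureFromAtoms(data.frame(
    chain = atoms$chain, resno = atoms$resno, resid = atoms$resid,
    elety = atoms$elety, element = atoms$elesy,
    o = ifelse(is.na(atoms$o), 1, atoms$o),
    alt = ifelse(is.na(atoms$alt), "", atoms$alt),
    x = atoms$x, y = atoms$y, z = atoms$z, stringsAsFactors = FALSE))
}

#' Build a structure model from an atom table
#'
#' Applies the same hydrogen and alternate-location filtering as
#' \code{\link{readStructure}}.  Useful for constructing fixtures in
#' code.
#'
#' @param atoms data.frame with columns chain, resno, resid, elety, x,
#'   y, z and optionally element, o (occupancy), alt.
#' @return A \code{\linkS4class{StructureModel}}.
#' @export
structureFromAtoms <- function(atoms) {
  if (is.null(atoms$element))
    atoms$element <- sub("^[0-9]*", "", substr(trimws(atoms$elety), 1, 1))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  ## keep the highest-occupancy altloc per (chain, residue, atom)
  key <- with(atoms, paste(chain, resno, elety))
  atoms <- atoms[order(key, -atoms$o), , drop = FALSE]
  atoms <- atoms[!duplicated(with(atoms, paste(chain, resno, elety))), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms)
}

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel: %d atoms, chains %s, residues %d-%d\n",
              nrow(a), paste(unique(a$chain), collapse = ","),
              min(a$resno, na.rm = TRUE), max(a$resno, na.rm = TRUE)))
})

## coordinate matrix of selected atoms, ordered by (resno, atom name);
## errors list every missing (residue, atom)
.selectCoords <- function(model, selection) {
  a <- model@atoms
  chain <- selection@chainId
  if (is.na(chain)) chain <- a$chain[1]
  rr <- selection@residueRanges
  resnos <- unlist(lapply(seq_len(nrow(rr)), function(i) rr[i, 1]:rr[i, 2]))
  want <- expand.grid(resno = resnos, elety = selection@atomNames,
                      stringsAsFactors = FALSE)
  sub <- a[a$chain == chain, , drop = FALSE]
  sub$resno <- sub$resno + selection@numberingOffset
  idx <- match(paste(want$resno, want$elety),
               paste(sub$resno, sub$elety))
  if (anyNA(idx)) {
    miss <- want[is.na(idx), , drop = FALSE]
    stop("selection atoms missing from structure: ",
         paste(paste0(miss$elety, " ", miss$resno), collapse = ", "))
  }
  as.matrix(sub[idx, c("x", "y", "z")])
}

#' Least-squares rigid superposition of two structures
#'
#' Kabsch algorithm: selected paired atoms are mean-centred, the optimal
#' proper rotation is obtained from the SVD of their cross-covariance
#' (with sign correction to exclude reflections), and the minimal RMSD
#' over the selection is reported.  The numbering offset in the
#' selection is applied to the mobile structure.
#'
#' @param reference,mobile \code{\linkS4class{StructureModel}} objects.
#' @param selection a \code{\linkS4class{SelectionSpec}}; every selected
#'   atom must be present in both models (missing ones are listed in the
#'   error), and at least 3 atoms are required.
#' @return A \code{\linkS4class{SuperpositionResult}}; apply it with
#'   \code{\link{applySuperposition}}.
#' @export
kabschSuperpose <- function(reference, mobile, selection) {
  Y <- .selectCoords(reference,
                     SelectionSpec(selection@residueRanges,
                                   selection@chainId,
                                   selection@atomNames, 0L))
  X <- .selectCoords(mobile, selection)
  if (nrow(X) < 3L) stop("at least 3 atoms are required for superposition")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))          # maximise tr(R' X'Y)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cy - cx %*% R), rmsd = rmsd,
      nAtoms = nrow(X))
}

#' Apply a superposition to a structure
#'
#' @param model a \code{\linkS4class{StructureModel}} (the mobile
#'   structure the fit was computed for).
#' @param fit a \code{\linkS4class{SuperpositionResult}}.
#' @return The transformed \code{StructureModel}.
#' @export
applySuperposition <- function(model, fit) {
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% fit@rotation
  xyz <- sweep(xyz, 2, fit@translation, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("StructureModel", atoms = a)
}

#' Per-residue RMSD between two (already superposed) structures
#'
#' Computes the RMSD over the matched atoms of one residue after a
#' single global superposition; no per-residue refit is performed.  Atom
#' names are matched by intersection and the number used is reported as
#' an attribute.
#'
#' @param reference superposition target.
#' @param mobileSuperposed mobile structure after
#'   \code{\link{applySuperposition}}.
#' @param residueNumber author residue number (reference numbering; the
#'   offset is applied to the mobile structure).
#' @param atomSubset \code{"ALL_HEAVY"}, \code{"SIDECHAIN_HEAVY"} or
#'   \code{"CA"}.
#' @param chain chain id (default: first chain of each model).
#' @param numberingOffset offset added to the mobile structure's residue
#'   numbers.
#' @return RMSD in Angstrom with attribute \code{nAtoms}.
#' @export
residueRmsd <- function(reference, mobileSuperposed, residueNumber,
                        atomSubset = c("ALL_HEAVY", "SIDECHAIN_HEAVY", "CA"),
                        chain = NA_character_, numberingOffset = 0L) {
  atomSubset <- match.arg(atomSubset)
  backbone <- c("N", "CA", "C", "O", "OXT")
  pick <- function(model, resno, off) {
    a <- model@atoms
    ch <- if (is.na(chain)) a$chain[1] else chain
    sub <- a[a$chain == ch & a$resno + off == resno, , drop = FALSE]
    sub <- switch(atomSubset,
      ALL_HEAVY = sub,
      SIDECHAIN_HEAVY = sub[!sub$elety %in% backbone, , drop = FALSE],
      CA = sub[sub$elety == "CA", , drop = FALSE])
    sub
  }
  rsub <- pick(reference, residueNumber, 0L)
  msub <- pick(mobileSuperposed, residueNumber, numberingOffset)
  common <- intersect(rsub$elety, msub$elety)
  if (!length(common))
    stop("no common atoms for residue ", residueNumber)
  rxyz <- as.matrix(rsub[match(common, rsub$elety), c("x", "y", "z")])
  mxyz <- as.matrix(msub[match(common, msub$elety), c("x", "y", "z")])
  out <- sqrt(mean(rowSums((rxyz - mxyz)^2)))
  attr(out, "nAtoms") <- length(common)
  out
}

#' Halogen-to-aromatic-ring-centroid distance
#'
#' Measures a halogen-pi contact as the Euclidean distance from a ligand
#' halogen atom to the unweighted centroid of the six-membered tyrosine
#' ring (CG, CD1, CD2, CE1, CE2, CZ); the standard convention for the
#' 3.3-3.5 Angstrom contacts between right-side chlorobenzyl groups and
#' the Gly-loop tyrosine.
#'
#' @param structure a \code{\linkS4class{StructureModel}}.
#' @param halogen list with elements \code{chain}, \code{resno},
#'   \code{atomName} identifying the halogen atom.
#' @param tyrosineResidue residue number of the tyrosine.
#' @param tyrosineChain chain of the tyrosine (default: first chain).
#' @return Distance in Angstrom.
#' @export
clPiDistance <- function(structure, halogen, tyrosineResidue,
                         tyrosineChain = NA_character_) {
  a <- structure@atoms
  hal <- a[a$chain == halogen$chain & a$resno == halogen$resno &
             a$elety == halogen$atomName, , drop = FALSE]
  if (nrow(hal) != 1L)
    stop("halogen atom not found: ", halogen$atomName, " in residue ",
         halogen$resno)
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ch <- if (is.na(tyrosineChain)) a$chain[1] else tyrosineChain
  tyr <- a[a$chain == ch & a$resno == tyrosineResidue &
             a$elety %in% ring, , drop = FALSE]
  if (nrow(tyr) != 6L)
    stop("tyrosine ", tyrosineResidue, " is missing ring atoms: ",
         paste(setdiff(ring, tyr$elety), collapse = ", "))
  centroid <- colMeans(as.matrix(tyr[, c("x", "y", "z")]))
  sqrt(sum((as.numeric(hal[, c("x", "y", "z")]) - centroid)^2))
}
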