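cdomain <- function() SelectionSpec(c(5L, 20L))

test_that("PDB fixtures read back with altloc and hydrogen filtering", {
  atoms <- spiralAtoms(3)
  path <- writeMiniPdb(atoms, tempfile(fileext = ".pdb"))
  mod <- readStructure(path)
  expect_equal(nrow(mod@atoms), 3)
  ## altloc pair: keep the higher occupancy B conformer
  alt <- rbind(
    transform(atoms[1, ], alt = "A", o = 0.4),
    transform(atoms[1, ], alt = "B", o = 0.6, x = atoms$x[1] + 2),
    atoms[2:3, ])
  path2 <- writeMiniPdb(alt, tempfile(fileext = ".pdb"))
  mod2 <- readStructure(path2)
  expect_equal(nrow(mod2@atoms), 3)
  expect_equal(mod2@atoms$x[mod2@atoms$resno == 1], atoms$x[1] + 2,
               tolerance = 1e-3)          # PDB coordinates print 3 decimals
  expect_error(readStructure(tempfile()), "no such file")
})

test_that("hydrogens are dropped when building a model", {
  atoms <- rbind(spiralAtoms(2),
                 data.frame(chain = "A", resno = 1, resid = "ALA",
                            elety = "H", element = "H", o = 1, alt = "",
                            x = 0, y = 0, z = 0))
  mod <- structureFromAtoms(atoms)
  expect_equal(nrow(mod@atoms), 2)
})

test_that("superposing a structure onto itself gives zero RMSD", {
  mod <- structureFromAtoms(spiralAtoms(25))
  fit <- kabschSuperpose(mod, mod, cdomain())
  expect_equal(fitRmsd(fit), 0, tolerance = 1e-9)
  expect_equal(fit@rotation, diag(3), tolerance = 1e-9)
})

test_that("a known rigid transform is recovered to below 1e-9 RMSD", {
  ref <- structureFromAtoms(spiralAtoms(25))
  mob <- rigidTransform(ref, rotZ(pi / 6), c(3, -2, 7))
  fit <- kabschSuperpose(ref, mob, cdomain())
  expect_lt(fitRmsd(fit), 1e-9)
  expect_equal(fit@rotation, t(rotZ(pi / 6)), tolerance = 1e-9)
  back <- applySuperposition(mob, fit)
  expect_equal(back@atoms$x, ref@atoms$x, tolerance = 1e-9)
})

test_that("fit RMSD matches the brute-force rotation-search oracle", {
  set.seed(31)
  base <- spiralAtoms(4)
  ref <- structureFromAtoms(base)
  moved <- base
  moved$x[2] <- moved$x[2] + 1.7      # one displaced point
  mob <- structureFromAtoms(moved)
  sel <- SelectionSpec(c(1L, 4L))
  fit <- kabschSuperpose(ref, mob, sel)
  X <- as.matrix(mob@atoms[, c("x", "y", "z")])
  Y <- as.matrix(ref@atoms[, c("x", "y", "z")])
  expect_equal(fitRmsd(fit), bruteForceFitRmsd(X, Y), tolerance = 1e-6)
  ## cross-check against bio3d's least-squares fit
  b3d <- bio3d::rmsd(as.vector(t(Y)), as.vector(t(X)), fit = TRUE)
  expect_equal(fitRmsd(fit), b3d, tolerance = 1e-3)
})

test_that("mirror-image inputs still produce a proper rotation", {
  ref <- structureFromAtoms(spiralAtoms(10))
  refl <- ref@atoms
  refl$z <- -refl$z
  mob <- structureFromAtoms(refl)
  fit <- kabschSuperpose(ref, mob, SelectionSpec(c(1L, 10L)))
  expect_equal(det(fit@rotation), 1, tolerance = 1e-9)
  expect_gt(fitRmsd(fit), 0.1)
})

test_that("superposition RMSD is invariant to rigid pre-transforms", {
  ref <- structureFromAtoms(spiralAtoms(25))
  moved <- ref@atoms
  moved$x <- moved$x + stats::rnorm(nrow(moved), sd = 0.3)
  mob <- structureFromAtoms(moved)
  fit0 <- kabschSuperpose(ref, mob, cdomain())
  mob2 <- rigidTransform(mob, rotZ(1.1), c(-5, 4, 12))
  ref2 <- rigidTransform(ref, rotZ(-0.7), c(8, 1, -3))
  expect_equal(fitRmsd(kabschSuperpose(ref2, mob2, cdomain())),
               fitRmsd(fit0), tolerance = 1e-9)
})

test_that("selection errors name the missing residues", {
  ref <- structureFromAtoms(spiralAtoms(10))
  short <- structureFromAtoms(spiralAtoms(8))
  expect_error(kabschSuperpose(ref, short, SelectionSpec(c(1L, 10L))),
               "CA 9")
})

test_that("per-residue RMSD equals closed-form values on fixtures", {
  ref <- structureFromAtoms(spiralAtoms(10, atoms = c("N", "CA", "C")))
  expect_equal(residueRmsd(ref, ref, 5), 0, ignore_attr = TRUE)
  moved <- ref@atoms
  sel <- moved$resno == 5 & moved$elety == "CA"
  moved$x[sel] <- moved$x[sel] + 3
  mob <- structureFromAtoms(moved)
  expect_equal(residueRmsd(ref, mob, 5, atomSubset = "CA"), 3,
               ignore_attr = TRUE)
  ## all-heavy RMSD mixes the displaced CA with two unmoved atoms
  expect_equal(residueRmsd(ref, mob, 5), sqrt(9 / 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(residueRmsd(ref, mob, 99), "no common atoms")
})

test_that("aggregated CA residue RMSDs reproduce the fit RMSD", {
  ref <- structureFromAtoms(spiralAtoms(25))
  moved <- ref@atoms
  set.seed(7)
  moved$x <- moved$x + rnorm(nrow(moved), sd = 0.4)
  moved$y <- moved$y + rnorm(nrow(moved), sd = 0.4)
  mob <- structureFromAtoms(moved)
  fit <- kabschSuperpose(ref, mob, cdomain())
  sup <- applySuperposition(mob, fit)
  perRes <- vapply(5:20, function(r)
    residueRmsd(ref, sup, r, atomSubset = "CA")^2, numeric(1))
  expect_equal(sqrt(mean(perRes)), fitRmsd(fit), tolerance = 1e-9)
})

test_that("halogen-pi distance matches constructed geometry and is rigid", {
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  tyr <- data.frame(chain = "A", resno = 34, resid = "TYR", elety = ring,
                    element = "C", o = 1, alt = "",
                    x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0,
                    stringsAsFactors = FALSE)
  lig <- data.frame(chain = "B", resno = 401, resid = "LIG",
                    elety = "CL1", element = "CL", o = 1, alt = "",
                    x = 0, y = 0, z = 3.5, stringsAsFactors = FALSE)
  mod <- structureFromAtoms(rbind(tyr, lig))
  hal <- list(chain = "B", resno = 401, atomName = "CL1")
  expect_equal(clPiDistance(mod, hal, 34), 3.5, tolerance = 1e-12)
  moved <- rigidTransform(mod, rotZ(0.8), c(10, -4, 2))
  expect_equal(clPiDistance(moved, hal, 34), 3.5, tolerance = 1e-9)
  expect_error(clPiDistance(mod, list(chain = "B", resno = 401,
                                      atomName = "CL9"), 34),
               "halogen atom not found")
  broken <- structureFromAtoms(rbind(tyr[-2, ], lig))
  expect_error(clPiDistance(broken, hal, 34), "missing ring atoms")
})
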