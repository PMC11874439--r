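test_that("toy receptor PDB round-trips through the reader", {
  cx <- toyCx(1)
  pdb <- tempfile(fileext = ".pdb")
  writeToyReceptorPDB(cx, pdb)
  rec <- readReceptor(pdb)
  expect_equal(natoms(rec), natoms(cx$receptor))
  expect_equal(coords(rec), coords(cx$receptor), tolerance = 1e-3)
  expect_true(all(c("chain", "resno", "atomName") %in% colnames(rec@atoms)))
  expect_equal(rec@atoms$atomName[rec@atoms$resname == "CYS"],
               c("N", "CA", "C", "O", "CB", "SG"))
})

test_that("altLoc records collapse to the highest-occupancy copy and waters drop", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.450   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  rec <- readReceptor(f)
  expect_equal(natoms(rec), 3L)          # one CA survives, water excluded
  ca <- rec@atoms[rec@atoms$atomName == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.5)                # the occupancy-0.60 copy
})

test_that("a PDB without atoms is an empty-input error", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(readReceptor(f), "empty|parse")
})

test_that("SDF write -> read round-trip preserves structure to format precision", {
  lig <- ligandTemplate("thiolLig")
  f <- tempfile(fileext = ".sdf")
  writeMolecule(lig, f)
  back <- readLigands(f)
  expect_length(back, 1)
  m <- back[[1]]
  expect_equal(m@atoms$element, lig@atoms$element)
  expect_equal(coords(m), coords(lig), tolerance = 1e-4)
  bkey <- function(b) sort(paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]), b[, 3]))
  expect_equal(bkey(bonds(m)), bkey(bonds(lig)))
})

test_that("a corrupt SDF record among valid ones is skipped with a warning", {
  lig <- ligandTemplate("thiolLig")   # non-planar, no 2D warning
  f1 <- tempfile(); f2 <- tempfile(); f <- tempfile(fileext = ".sdf")
  writeMolecule(lig, f1, title = "ok1")
  writeMolecule(lig, f2, title = "ok2")
  corrupt <- c("broken", "  MiniDock          3D", "",
               " 12  0  0  0  0  0  0  0  0  0999 V2000",  # claims 12 atoms, has none
               "M  END", "$$$$")
  writeLines(c(readLines(f1), corrupt, readLines(f2)), f)
  expect_warning(res <- readLigands(f), "skipped")
  expect_length(res, 2)
})

test_that("2D-looking SDF coordinates warn but still parse", {
  lig <- ligandTemplate("butane")   # template is planar in z
  f <- tempfile(fileext = ".sdf")
  writeMolecule(lig, f)
  expect_warning(res <- readLigands(f), "2D")
  expect_length(res, 1)
})

test_that("atom typing follows the donor/acceptor and hydrophobic rules", {
  expect_equal(atomTypes(ligandTemplate("methane"))[1], "HydrophobicC")
  # hydroxyl oxygen: O with one H and one C
  thl <- ligandTemplate("thiolLig")
  expect_equal(atomTypes(thl)[5], "DonorAcceptorO")
  # amide-like nitrogen with one H and two heavy neighbors -> donor only
  amide <- assignAtomTypes(newTypedMolecule(
    c("C", "N", "C", "H"),
    rbind(c(-1.4, 0, 0), c(0, 0, 0), c(1.4, 0.2, 0), c(-0.3, 1.0, 0)),
    rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(2L, 4L, 1L))))
  expect_equal(atomTypes(amide)[2], "DonorN")
  # carbon bonded to nitrogen is not hydrophobic
  expect_equal(atomTypes(amide)[1], "NonHydrophobicC")
})

test_that("typing is idempotent and unknown elements warn", {
  lig <- ligandTemplate("thiolLig")
  expect_identical(assignAtomTypes(lig)@atoms, lig@atoms)
  odd <- newTypedMolecule(c("C", "Xx"), rbind(c(0, 0, 0), c(2, 0, 0)),
                          rbind(c(1L, 2L, 1L)))
  expect_warning(t2 <- assignAtomTypes(odd), "unknown element")
  expect_equal(atomTypes(t2)[2], "Metal")
})

test_that("torsion trees follow the rotatable-bond rule", {
  expect_equal(nrot(buildTorsionTree(ligandTemplate("butane"))), 1L)
  expect_equal(nrot(buildTorsionTree(ligandTemplate("benzene"))), 0L)
  expect_equal(nrot(buildTorsionTree(ligandTemplate("biphenyl"))), 1L)
  tt <- buildTorsionTree(ligandTemplate("butane"))
  expect_setequal(c(tt@torsions[[1]]$a, tt@torsions[[1]]$b), c(2L, 3L))
})

test_that("rotating a torsion moves exactly its moving set", {
  for (nm in c("butane", "biphenyl", "thiolLig")) {
    lig <- ligandTemplate(nm)
    tt <- buildTorsionTree(lig)
    X0 <- coords(lig)
    for (k in seq_len(nrot(tt))) {
      X1 <- applyTorsion(X0, tt, k, 0.9)
      moved <- which(rowSums(abs(X1 - X0)) > 1e-12)
      t <- tt@torsions[[k]]
      ## atoms on the rotation axis line stay put even inside the moving set
      u <- X0[t$b, ] - X0[t$a, ]; u <- u / sqrt(sum(u^2))
      rel <- sweep(X0, 2, X0[t$b, ])
      distToAxis <- sqrt(rowSums((rel - outer(rel %*% u, u)[, 1, ])^2))
      offAxis <- which(distToAxis > 1e-9)
      expect_true(all(moved %in% t$moving))
      expect_true(all(intersect(t$moving, offAxis) %in% moved))
    }
  }
})

test_that("a disconnected ligand graph is rejected", {
  frag <- newTypedMolecule(c("C", "C"), rbind(c(0, 0, 0), c(8, 0, 0)))
  expect_error(buildTorsionTree(frag), "disconnected")
})

test_that("the toy complex generator is deterministic and honors sizes", {
  a <- generateToyComplex(11, 60, "benzene")
  b <- generateToyComplex(11, 60, "benzene")
  expect_identical(coords(a$receptor), coords(b$receptor))
  expect_identical(a$referencePose@coords, b$referencePose@coords)
  expect_equal(natoms(generateToyComplex(2, 50)$receptor), 50L)
  expect_warning(generateToyComplex(2, 5), "clamped")
})

test_that("the reference pose scores better than a pose 8 Angstrom away", {
  cx <- toyCx(1)
  far <- sweep(cx$referencePose@coords, 2, c(8, 0, 0), `+`)
  sRef <- scorePose(cx$receptor, cx$ligand, cx$referencePose)$finalScore
  sFar <- scorePose(cx$receptor, cx$ligand, far)$finalScore
  expect_lt(sRef, sFar)
})

test_that("pose SDF output carries the standard scoring data tags", {
  cx <- toyCx(1)
  p <- cx$referencePose
  p@empiricalScore <- -5.43210
  p@cnnScore <- 0.87
  p@cnnAffinity <- 6.1
  f <- tempfile(fileext = ".sdf")
  writePoses(cx$ligand, list(p), f)
  txt <- readLines(f)
  expect_true(any(grepl("^>  <minimizedAffinity>$", txt)))
  expect_true(any(grepl("^>  <CNNscore>$", txt)))
  expect_true(any(grepl("^>  <CNNaffinity>$", txt)))
  expect_equal(txt[which(grepl("minimizedAffinity", txt)) + 1], "-5.43210")
})
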