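test_that("SMARTS matching finds warhead atoms and rejects bad patterns", {
  expect_equal(findLigandCovalentAtoms(ligandTemplate("dmds"), "[SX2H0]"),
               c(2L, 3L))
  expect_equal(findLigandCovalentAtoms(ligandTemplate("methane"), "[C]"), 1L)
  expect_error(findLigandCovalentAtoms(ligandTemplate("benzene"), "[Au]"),
               "no ligand atom matches")
  expect_error(findLigandCovalentAtoms(ligandTemplate("benzene"), "[S"),
               "invalid SMARTS")
  expect_error(findLigandCovalentAtoms(ligandTemplate("benzene"), "C(("),
               "invalid SMARTS")
  ## chains, connectivity and H counts
  expect_equal(findLigandCovalentAtoms(ligandTemplate("thiolLig"), "[SX1]"), 1L)
  expect_equal(findLigandCovalentAtoms(ligandTemplate("thiolLig"), "[OX2H1]"), 5L)
  expect_equal(findLigandCovalentAtoms(ligandTemplate("dmds"), "CS[SX2]"),
               c(1L, 4L))
})

test_that("receptor atom addressing resolves, lists near misses, flags duplicates", {
  cx <- toyCx(1)
  idx <- locateReceptorAtom(cx$receptor, "A:145:SG")
  a <- cx$receptor@atoms[idx, ]
  expect_equal(a$element, "S")
  expect_equal(a$resname, "CYS")
  expect_error(locateReceptorAtom(cx$receptor, "B:145:SG"), "not found")
  expect_error(locateReceptorAtom(cx$receptor, "A:145:XX"),
               "residue has atoms")
  dup <- cx$receptor
  dup@atoms <- rbind(dup@atoms, dup@atoms[idx, ])
  dup@atoms[nrow(dup@atoms), c("x")] <- 99
  expect_error(locateReceptorAtom(dup, "A:145:SG"), "ambiguous")
})

test_that("the bond-vector heuristic follows the negative neighbor sum", {
  ## atom with three neighbors along +x, +y, +z
  m <- assignAtomTypes(newTypedMolecule(
    c("C", "C", "C", "C"),
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0, 0, 1.5)),
    rbind(c(1L, 2L, 1L), c(1L, 3L, 1L), c(1L, 4L, 1L))))
  nbv <- newBondVector(m, 1)
  expect_equal(nbv$direction, -c(1, 1, 1) / sqrt(3), tolerance = 1e-12)
  ## single neighbor along +x
  m2 <- assignAtomTypes(newTypedMolecule(c("S", "C"),
    rbind(c(0, 0, 0), c(1.8, 0, 0)), rbind(c(1L, 2L, 1L))))
  nbv2 <- newBondVector(m2, 1, partnerCovalentRadius = 1.05)
  expect_equal(nbv2$direction, c(-1, 0, 0))
  expect_equal(nbv2$position, c(-(1.05 + 1.05), 0, 0))
  ## isolated atom falls back to +x
  iso <- assignAtomTypes(newTypedMolecule("S", matrix(c(1, 2, 3), 1)))
  expect_equal(newBondVector(iso, 1)$direction, c(1, 0, 0))
  ## a hydrogen is discounted before summing
  m3 <- assignAtomTypes(newTypedMolecule(c("S", "C", "H"),
    rbind(c(0, 0, 0), c(1.8, 0, 0), c(-0.6, 1.1, 0)),
    rbind(c(1L, 2L, 1L), c(1L, 3L, 1L))))
  nbv3 <- newBondVector(m3, 1)
  expect_equal(nbv3$direction, c(-1, 0, 0))
  expect_equal(nbv3$droppedHydrogen, 3L)
})

test_that("rigid covalent placement hits the target with sane bond geometry", {
  lig <- ligandTemplate("methylthiol")  # C-S-H, S is atom 2
  target <- c(1, 2, 3)
  dir <- c(0, 0, 1)
  p <- placeLigand(lig, 2, target, dir)
  expect_lt(sqrt(sum((p@coords[2, ] - target)^2)), 1e-6)
  ## intra-ligand distances preserved (rigidity)
  d0 <- dist(coords(lig)); d1 <- dist(p@coords)
  expect_lt(max(abs(d0 - d1)), 1e-9)
  ## mean neighbor direction anti-aligns with the bond direction
  nbr <- c(1, 3)
  m <- colSums(sweep(p@coords[nbr, ], 2, p@coords[2, ]) /
               sqrt(rowSums(sweep(p@coords[nbr, ], 2, p@coords[2, ])^2)))
  m <- m / sqrt(sum(m^2))
  ang <- acos(sum(m * -dir)) * 180 / pi
  expect_lt(ang, 15)
})

test_that("the construct counts bonds correctly and keeps ligand identity", {
  cx <- toyCx(3)
  lig <- ligandTemplate("thiolLig")
  recIdx <- locateReceptorAtom(cx$receptor, "A:145:SG")
  nbv <- newBondVector(cx$receptor, recIdx,
                       partnerCovalentRadius = lig@atoms$covr[1])
  pose <- placeLigand(lig, 1, nbv$position, nbv$direction)
  cc <- makeCovalentConstruct(cx$receptor, pose, lig, 1, recIdx)
  resBonds <- sum(cx$receptor@bonds[, 1] %in% cc$residueIdx &
                  cx$receptor@bonds[, 2] %in% cc$residueIdx)
  expect_equal(nrow(cc$construct@bonds), resBonds + nrow(lig@bonds) + 1L)
  expect_true(all(cc$construct@atoms$isLigand[-seq_len(length(cc$residueIdx))]))
  expect_false(any(cc$construct@atoms$isLigand[seq_len(length(cc$residueIdx))]))
  ## placement guard: a far-away ligand is rejected with advice
  farPose <- MiniDock:::.mkPose(sweep(coords(lig), 2, c(30, 0, 0), `+`))
  expect_error(makeCovalentConstruct(cx$receptor, farPose, lig, 1, recIdx),
               "place the ligand")
})

test_that("100 construct mutations never move the receptor anchor atom", {
  cx <- toyCx(3)
  res <- covalentDock(cx$receptor, ligandTemplate("thiolLig"),
                      covalentSpec("[SX1]", "A:145:SG"),
                      samplerConfig(exhaustiveness = 1, steps = 0, seed = 2))
  pr <- res$pairings[[1]]
  X <- pr$poses[[1]]@coords
  anchor0 <- X[pr$recAtomLocal, ]
  cfg <- samplerConfig(covalentMode = TRUE)
  set.seed(12)
  for (k in 1:100) {
    p <- mutatePose(X, pr$tree, cfg)
    expect_identical(p@coords[pr$recAtomLocal, ], anchor0)
    X <- p@coords
  }
})

test_that("covalent docking expands over SMARTS pairings with bonded geometry", {
  cx <- toyCx(3)
  cfg <- samplerConfig(exhaustiveness = 1, steps = 8, seed = 4, numModes = 3)
  res <- covalentDock(cx$receptor, ligandTemplate("dmds"),
                      covalentSpec("[SX2H0]", "A:145:SG"), cfg)
  expect_length(res$pairings, 2)           # expansion = number of matches
  expect_lte(length(res$poses), 2 * cfg$numModes)
  for (pr in res$pairings) {
    target <- pr$construct@atoms$covr[pr$recAtomLocal] +
      pr$construct@atoms$covr[pr$ligAtomLocal]
    for (p in pr$poses) {
      bl <- sqrt(sum((p@coords[pr$ligAtomLocal, ] -
                      p@coords[pr$recAtomLocal, ])^2))
      expect_lt(abs(bl - target), 0.2)
      expect_equal(p@provenance$covalent_pairing, pr$label)
    }
  }
})

test_that("an explicit covalent atom position is honored", {
  cx <- toyCx(3)
  recIdx <- locateReceptorAtom(cx$receptor, "A:145:SG")
  sg <- coords(cx$receptor)[recIdx, ]
  pos <- sg + c(2.0, 0.3, 0.2)
  res <- covalentDock(cx$receptor, ligandTemplate("thiolLig"),
                      covalentSpec("[SX1]", "A:145:SG", explicitPosition = pos),
                      samplerConfig(exhaustiveness = 1, steps = 0, seed = 6))
  pr <- res$pairings[[1]]
  ## pre-minimization placement is exact; sampled poses keep the bond length
  nbv <- newBondVector(cx$receptor, recIdx,
                       partnerCovalentRadius = ligandTemplate("thiolLig")@atoms$covr[1])
  placed <- placeLigand(ligandTemplate("thiolLig"), 1, pos, nbv$direction)
  expect_lt(sqrt(sum((placed@coords[1, ] - pos)^2)), 1e-6)
  for (p in pr$poses)
    expect_lt(abs(sqrt(sum((p@coords[pr$ligAtomLocal, ] - sg)^2)) -
                  sqrt(sum((pos - sg)^2))), 0.1)
})

test_that("junction relaxation restores the covalent-radius bond length", {
  cx <- toyCx(3)
  recIdx <- locateReceptorAtom(cx$receptor, "A:145:SG")
  lig <- ligandTemplate("thiolLig")
  nbv <- newBondVector(cx$receptor, recIdx, partnerCovalentRadius = lig@atoms$covr[1])
  ## place slightly long, then relax
  stretched <- nbv$position + 0.4 * nbv$direction
  pose <- placeLigand(lig, 1, stretched, nbv$direction)
  cc <- makeCovalentConstruct(cx$receptor, pose, lig, 1, recIdx)
  relaxed <- MiniDock:::.relaxJunction(cc$construct, cc$recAtomLocal, cc$ligAtomLocal)
  target <- cc$construct@atoms$covr[cc$recAtomLocal] +
    cc$construct@atoms$covr[cc$ligAtomLocal]
  bl <- sqrt(sum((coords(relaxed)[cc$ligAtomLocal, ] -
                  coords(relaxed)[cc$recAtomLocal, ])^2))
  expect_equal(bl, target, tolerance = 1e-9)
})
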