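test_that("atom density closed forms and continuity at the breakpoints", {
  expect_equal(atomDensity(0, 1.9), 1)
  r <- 1.7
  expect_equal(atomDensity(r, r), exp(-2), tolerance = 1e-12)
  ## quadratic tail evaluated at d = r equals the Gaussian branch
  e2 <- exp(2)
  tail_at_r <- 4 / (e2 * r^2) * r^2 - 12 / (e2 * r) * r + 9 / e2
  expect_equal(tail_at_r, exp(-2), tolerance = 1e-12)
  expect_equal(atomDensity(1.5 * r, r), 0, tolerance = 1e-12)
  ## numeric continuity of value and first derivative at r and 1.5r
  eps <- 1e-6
  for (bp in c(r, 1.5 * r)) {
    expect_lt(abs(atomDensity(bp - eps, r) - atomDensity(bp + eps, r)), 1e-5)
    dLeft <- (atomDensity(bp - eps, r) - atomDensity(bp - 3 * eps, r)) / (2 * eps)
    dRight <- (atomDensity(bp + 3 * eps, r) - atomDensity(bp + eps, r)) / (2 * eps)
    expect_lt(abs(dLeft - dRight), 1e-4)
  }
  expect_error(atomDensity(-0.1, 1), "d >= 0")
})

test_that("voxelization puts unit density at an atom on a voxel center", {
  spec <- gridSpec(resolution = 0.5, points = 16, channels = "full")
  ## voxel centers are center + (i - (N-1)/2) * res: put the atom on one
  lig <- oneAtomLigand(c(0.25, 0.25, 0.25))
  g <- voxelize(new("TypedMolecule"), lig, spec = spec, center = c(0, 0, 0))
  ligC <- spec$channelMap[["HydrophobicC|lig"]]
  expect_equal(max(g@values[ligC, , , ]), 1.0)
  expect_true(all(g@values >= 0))
  ## other channels stay empty
  expect_equal(sum(g@values[-ligC, , , ]), 0)
})

test_that("voxelization is additive over atoms", {
  spec <- gridSpec(resolution = 0.5, points = 12, channels = "full")
  lig1 <- oneAtomLigand(c(0.2, -0.1, 0.3))
  two <- assignAtomTypes(newTypedMolecule(c("C", "C"),
    rbind(c(0.2, -0.1, 0.3), c(0.2, -0.1, 0.3)), isLigand = TRUE))
  g1 <- voxelize(new("TypedMolecule"), lig1, spec = spec, center = c(0, 0, 0))
  g2 <- voxelize(new("TypedMolecule"), two, spec = spec, center = c(0, 0, 0))
  expect_equal(g2@values, 2 * g1@values, tolerance = 1e-12)
})

test_that("a lattice-aligned shift of the atom shifts the grid by one voxel", {
  spec <- gridSpec(resolution = 0.5, points = 16, channels = "full")
  ligA <- oneAtomLigand(c(0, 0, 0))
  ligB <- oneAtomLigand(c(0.5, 0, 0))   # exactly one voxel pitch in x
  gA <- voxelize(new("TypedMolecule"), ligA, spec = spec, center = c(0, 0, 0))@values
  gB <- voxelize(new("TypedMolecule"), ligB, spec = spec, center = c(0, 0, 0))@values
  ## interior voxels: gB[, i, , ] == gA[, i-1, , ]
  expect_equal(gB[, 2:16, , ], gA[, 1:15, , ], tolerance = 1e-12)
})

test_that("receptor and ligand atoms land in disjoint channel blocks", {
  cx <- toyCx(1)
  spec <- gridSpec(resolution = 1.0, points = 12, channels = "coarse")
  g <- voxelize(cx$receptor, cx$ligand, spec = spec, center = c(0, 0, 0))
  nPer <- spec$nchannels / 2
  recBlock <- g@values[seq_len(nPer), , , ]
  ligBlock <- g@values[nPer + seq_len(nPer), , , ]
  expect_gt(sum(recBlock), 0)
  expect_gt(sum(ligBlock), 0)
  ## ligand-only voxelization reproduces the ligand block exactly
  gL <- voxelize(new("TypedMolecule"), cx$ligand, spec = spec, center = c(0, 0, 0))
  expect_equal(gL@values[nPer + seq_len(nPer), , , ], ligBlock, tolerance = 1e-12)
  expect_equal(sum(gL@values[seq_len(nPer), , , ]), 0)
})

test_that("covalent constructs route ligand-origin atoms to ligand channels", {
  cx <- toyCx(3)
  res <- covalentDock(cx$receptor, ligandTemplate("thiolLig"),
                      covalentSpec("[SX1]", "A:145:SG"),
                      samplerConfig(exhaustiveness = 1, steps = 0, seed = 2))
  pr <- res$pairings[[1]]
  spec <- gridSpec(resolution = 1.0, points = 12, channels = "coarse")
  g <- voxelize(pr$restReceptor, pr$construct, pr$poses[[1]], spec,
                center = c(0, 0, 0))
  nPer <- spec$nchannels / 2
  ## ligand block contains the ligand-origin sulfur/oxygen density
  expect_gt(sum(g@values[nPer + seq_len(nPer), , , ]), 0)
  ## residue-origin atoms of the construct land in receptor channels
  onlyRes <- pr$construct
  onlyRes@atoms <- onlyRes@atoms[!onlyRes@atoms$isLigand, , drop = FALSE]
  onlyRes@bonds <- MiniDock:::.reindexBonds(pr$construct@bonds,
    which(!pr$construct@atoms$isLigand))
  gR <- voxelize(onlyRes, new("TypedMolecule",
    atoms = pr$construct@atoms[0, ], bonds = pr$construct@bonds[0, , drop = FALSE]),
    pose = matrix(numeric(0), 0, 3), spec = spec, center = c(0, 0, 0))
  expect_equal(sum(gR@values[nPer + seq_len(nPer), , , ]), 0)
})

test_that("voxelized mass is stable under rigid rotation of the complex", {
  cx <- toyCx(1)
  spec <- gridSpec(resolution = 0.5, points = 40, channels = "coarse")
  g0 <- voxelize(cx$receptor, cx$ligand, spec = spec, center = c(0, 0, 0))
  m0 <- sum(g0@values)
  set.seed(4)
  for (k in 1:3) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, 2 * pi)
    rec <- cx$receptor; coords(rec) <- MiniDock:::.rotateAbout(coords(rec), c(0, 0, 0), ax, ang)
    lig <- cx$ligand; coords(lig) <- MiniDock:::.rotateAbout(coords(lig), c(0, 0, 0), ax, ang)
    m1 <- sum(voxelize(rec, lig, spec = spec, center = c(0, 0, 0))@values)
    expect_lt(abs(m1 - m0) / m0, 0.01)
  }
})

test_that("an empty grid warns and grid export round-trips", {
  lig <- oneAtomLigand(c(100, 100, 100))
  expect_warning(g <- voxelize(new("TypedMolecule"), lig,
                               spec = gridSpec(points = 8), center = c(0, 0, 0)),
                 "no atoms")
  stem <- tempfile()
  cx <- toyCx(1)
  g2 <- voxelize(cx$receptor, cx$ligand, spec = rescoreGridSpec(),
                 center = c(0, 0, 0))
  exportGrid(g2, stem)
  vals <- readBin(paste0(stem, ".bin"), numeric(), n = length(g2@values))
  expect_equal(vals, as.numeric(g2@values))
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(unlist(meta$dim), dim(g2@values))
})
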