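## straight-line transcription of the five pair terms, kept deliberately
## independent of the package kernels: the oracle for term evaluation
oracleTerms <- function(d, hyd, hb) {
  g1 <- exp(-(d / 0.5)^2)
  g2 <- exp(-((d - 3) / 2)^2)
  rp <- ifelse(d < 0, d^2, 0)
  hp <- ifelse(hyd, ifelse(d <= 0.5, 1, ifelse(d >= 1.5, 0, 1.5 - d)), 0)
  hb <- ifelse(hb, ifelse(d <= -0.7, 1, ifelse(d >= 0, 0, -d / 0.7)), 0)
  cbind(g1, g2, rp, hp, hb)
}

test_that("surface distance is center distance minus vdW radii", {
  mk <- function(x) assignAtomTypes(newTypedMolecule("C", matrix(c(x, 0, 0), 1)))
  a <- mk(0)
  expect_equal(surfaceDistance(a, 1, mk(3.8), 1), 0)
  expect_equal(surfaceDistance(a, 1, mk(5.8), 1), 2)
  expect_equal(surfaceDistance(a, 1, mk(2.8), 1), -1)
  expect_equal(surfaceDistance(a, 1, mk(0), 1), -3.8)  # coincident centers
})

test_that("pair terms match hand-derived values at the worked points", {
  term <- function(d, tA, tB, which) unname(evaluatePairTerms(d, tA, tB)[1, which])
  expect_equal(term(0, "HydrophobicC", "HydrophobicC", "gauss1"), 1)
  expect_equal(term(0, "HydrophobicC", "HydrophobicC", "repulsion"), 0)
  expect_equal(term(0, "HydrophobicC", "HydrophobicC", "hydrophobic"), 1)
  expect_equal(term(0.5, "HydrophobicC", "HydrophobicC", "gauss1"), exp(-1))
  expect_equal(term(-0.35, "DonorN", "AcceptorO", "hbond"), 0.5)
  # eligibility gating: no hydrophobic term for mixed pairs, no hbond for C-C
  expect_equal(term(0.2, "HydrophobicC", "AcceptorO", "hydrophobic"), 0)
  expect_equal(term(-0.35, "HydrophobicC", "HydrophobicC", "hbond"), 0)
  # donor-donor is not an hbond pair, donor-acceptor works both ways
  expect_equal(term(-0.35, "DonorN", "DonorN", "hbond"), 0)
  expect_equal(term(-0.35, "AcceptorO", "DonorAcceptorN", "hbond"), 0.5)
})

test_that("pair terms agree with the independent transcription on 1000 random pairs", {
  set.seed(42)
  d <- runif(1000, -2.5, 6)
  hyd <- runif(1000) < 0.5
  hb <- !hyd & runif(1000) < 0.5
  tA <- ifelse(hyd, "HydrophobicC", ifelse(hb, "DonorN", "NonHydrophobicC"))
  tB <- ifelse(hyd, "HydrophobicC", ifelse(hb, "AcceptorO", "S"))
  got <- evaluatePairTerms(d, tA, tB)
  want <- oracleTerms(d, hyd, hb)
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("scorePose equals a brute-force double loop over pairs", {
  w <- termWeights()
  wv <- c(w$gauss1, w$gauss2, w$repulsion, w$hydrophobic, w$hbond)
  worst <- 0
  for (seed in 1:10) {
    cx <- generateToyComplex(seed, 40,
                             sample(c("benzene", "butane", "thiolLig"), 1))
    rep <- scorePose(cx$receptor, cx$ligand, weights = w)
    ra <- cx$receptor@atoms; la <- cx$ligand@atoms
    tot <- 0
    for (i in seq_len(nrow(la))) for (j in seq_len(nrow(ra))) {
      if (la$type[i] == "H" || ra$type[j] == "H") next
      dc <- sqrt(sum((c(la$x[i], la$y[i], la$z[i]) -
                      c(ra$x[j], ra$y[j], ra$z[j]))^2))
      if (dc > 8) next
      ds <- dc - (la$vdw[i] + ra$vdw[j])
      tv <- oracleTerms(ds,
        la$type[i] == "HydrophobicC" && ra$type[j] == "HydrophobicC",
        (grepl("Donor", la$type[i]) && grepl("Acceptor|DonorAcceptor", ra$type[j])) ||
        (grepl("Donor", ra$type[j]) && grepl("Acceptor|DonorAcceptor", la$type[i])))
      tot <- tot + sum(wv * tv)
    }
    nrotL <- nrot(buildTorsionTree(cx$ligand))
    worst <- max(worst, abs(tot / (1 + w$rot * nrotL) - rep$finalScore))
  }
  expect_lt(worst, 1e-9)
})

test_that("pairs beyond the 8 Angstrom cutoff contribute nothing", {
  cx <- toyCx(1)
  far <- sweep(cx$referencePose@coords, 2, c(60, 0, 0), `+`)
  rep <- scorePose(cx$receptor, cx$ligand, far)
  expect_equal(unname(rep$terms), rep(0, 5))
  expect_equal(rep$finalScore, 0)
})

test_that("zero rotatable bonds means no torsion penalty", {
  cx <- toyCx(1)  # benzene, rigid
  rep <- scorePose(cx$receptor, cx$ligand)
  expect_identical(rep$nrot, 0L)
  expect_equal(rep$finalScore, rep$weightedTotal)
  # with rotatable bonds the final score is divided down
  cxf <- toyCx(2, "thiolLig")
  repf <- scorePose(cxf$receptor, cxf$ligand)
  expect_gt(repf$nrot, 0L)
  expect_equal(repf$finalScore,
               repf$weightedTotal / (1 + termWeights()$rot * repf$nrot))
})

test_that("the score is invariant under joint rigid transforms", {
  cx <- toyCx(1, "thiolLig")
  s0 <- scorePose(cx$receptor, cx$ligand)$finalScore
  ax <- c(1, 2, 3) / sqrt(14)
  rot <- function(X) MiniDock:::.rotateAbout(X, c(1, -2, 0.5), ax, 1.1)
  rec2 <- cx$receptor; coords(rec2) <- rot(coords(cx$receptor)) + 5
  lig2 <- cx$ligand; coords(lig2) <- rot(coords(cx$ligand)) + 5
  s1 <- scorePose(rec2, lig2)$finalScore
  expect_lt(abs(s0 - s1), 1e-9)
})

test_that("an empty ligand is rejected", {
  cx <- toyCx(1)
  empty <- new("TypedMolecule")
  expect_error(scorePose(cx$receptor, empty), "empty")
})
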