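## shared fixtures, cached per test run

.fixtureCache <- new.env(parent = emptyenv())

toyCx <- function(seed = 1, lig = "benzene", n = 60) {
  key <- paste(seed, lig, n)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateToyComplex(seed, n, lig)
  .fixtureCache[[key]]
}

## isotropic spherical cage of carbons (symmetric pocket for the
## minimization oracle)
## R = 3.8 puts every wall contact at zero surface distance for a carbon at
## the center, so the center is the unique score minimum
sphericalPocket <- function(n = 48, R = 3.8) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- R * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  assignAtomTypes(newTypedMolecule(rep("C", n), xyz,
                                   chain = "A", resno = as.character(seq_len(n)),
                                   resname = "POC", atomName = "C1"))
}

oneAtomLigand <- function(at = c(0.3, 0.2, -0.1)) {
  assignAtomTypes(newTypedMolecule("C", matrix(at, 1), isLigand = TRUE))
}

## small shared grid dataset + quickly trained scorer for pipeline tests
sharedGridData <- function(n = 48, seed = 7) {
  key <- paste("ds", n, seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeGridDataset(n, seed = seed,
                                            spec = rescoreGridSpec())
  .fixtureCache[[key]]
}

sharedFastScorer <- function() {
  if (is.null(.fixtureCache[["fast"]])) {
    spec <- rescoreGridSpec()
    fit <- trainModel(modelSpec("default2018", width = 4L,
                                inChannels = spec$nchannels,
                                npts = spec$points, seed = 3L),
                      sharedGridData(), epochs = 6L, lr = 0.02)
    out <- list(fit$model)
    attr(out, "gridSpec") <- spec
    .fixtureCache[["fast"]] <- out
  }
  .fixtureCache[["fast"]]
}

expect_equal_tol <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)
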