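test_that("architectures expose the documented convolution counts", {
  d18 <- buildModel(modelSpec("default2018", width = 4, inChannels = 4, npts = 8))
  expect_equal(d18$nconv, 5L)
  expect_equal(sum(grepl("^conv[0-9]+\\.w$", names(d18$params))), 5L)
  dn <- buildModel(modelSpec("dense", width = 4, inChannels = 4, npts = 8))
  expect_equal(dn$nconv, 12L)
  expect_equal(sum(grepl("^conv[0-9]+\\.w$", names(dn$params))), 12L)
  ## dense blocks concatenate: channel counts grow by the growth rate
  expect_equal(dn$plan$ins[1:4], c(4L, 8L, 12L, 16L))
  expect_error(modelSpec("default2018", npts = 12), "divisible")
})

test_that("initialization is fully determined by the seed", {
  a <- buildModel(modelSpec("dense", width = 4, inChannels = 4, npts = 8, seed = 7))
  b <- buildModel(modelSpec("dense", width = 4, inChannels = 4, npts = 8, seed = 7))
  c <- buildModel(modelSpec("dense", width = 4, inChannels = 4, npts = 8, seed = 8))
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("pose cross entropy has its closed forms", {
  expect_equal(poseClassificationLoss(c(0.7, 0.7), TRUE), log(2))
  expect_equal(poseClassificationLoss(c(0.7, 0.7), FALSE), log(2))
  expect_lt(poseClassificationLoss(c(-20, 20), TRUE), 1e-8)
  set.seed(2)
  for (k in 1:50)
    expect_gte(poseClassificationLoss(rnorm(2, sd = 3), runif(1) < 0.5), 0)
})

test_that("the hinged affinity loss penalizes only over-prediction on bad poses", {
  expect_equal(hingedAffinityLoss(6.2, 6.2, TRUE), 0)
  expect_equal(hingedAffinityLoss(5.2, 6.2, FALSE), 0)
  expect_equal(hingedAffinityLoss(7.2, 6.2, FALSE), 1)
  expect_equal(hingedAffinityLoss(5.2, 6.2, TRUE), 1)
})

test_that("model outputs are valid probabilities, including on empty grids", {
  m <- buildModel(modelSpec("default2018", width = 4, inChannels = 8, npts = 8))
  zero <- array(0, c(8, 8, 8, 8))
  out <- cnnScoreGrid(m, zero)
  expect_gt(out$poseScore, 0); expect_lt(out$poseScore, 1)
  expect_equal(out$poseScore, MiniDock:::.softmax(out$logits)[2])
  ds <- sharedGridData(8)
  for (e in ds) {
    s <- cnnScoreGrid(m, e$grid)$poseScore
    expect_gt(s, 0); expect_lt(s, 1)
  }
})

test_that("zero training epochs return the initialized model unchanged", {
  spec <- modelSpec("default2018", width = 4, inChannels = 8, npts = 8, seed = 5)
  fit <- trainModel(spec, sharedGridData(8), epochs = 0)
  expect_identical(fit$model$params, buildModel(spec)$params)
  expect_null(fit$history)
})

test_that("training is reproducible for a fixed shuffle seed", {
  ds <- sharedGridData(16)
  spec <- modelSpec("default2018", width = 4, inChannels = 8, npts = 8, seed = 5)
  a <- trainModel(spec, ds, epochs = 2, shuffleSeed = 4)
  b <- trainModel(spec, ds, epochs = 2, shuffleSeed = 4)
  expect_equal(a$history$poseLoss, b$history$poseLoss, tolerance = 1e-6)
  expect_identical(a$model$params, b$model$params)
})

test_that("both families can overfit a 32-example set (capacity check)", {
  ds <- makeGridDataset(32, seed = 5)
  d18 <- trainModel(modelSpec("default2018", width = 8, inChannels = 8,
                              npts = 8, seed = 1),
                    ds, epochs = 50, lr = 0.02, batchSize = 4)
  expect_lt(tail(d18$history$poseLoss, 1), 0.1)
  expect_equal(tail(d18$history$accuracy, 1), 1)
  dn <- trainModel(modelSpec("dense", width = 4, inChannels = 8,
                             npts = 8, seed = 1),
                   ds, epochs = 25, lr = 0.02, batchSize = 4)
  expect_lt(tail(dn$history$poseLoss, 1), 0.1)
})

test_that("backpropagation matches numeric differentiation", {
  set.seed(3)
  for (family in c("default2018", "dense")) {
    m <- buildModel(modelSpec(family, width = 2, inChannels = 2, npts = 8, seed = 4))
    x <- array(runif(2 * 8^3, 0, 0.5), c(2, 8, 8, 8))
    lossOf <- function(mm) {
      fw <- MiniDock:::.cnnForward(mm, x)
      poseClassificationLoss(fw$logits, TRUE) +
        hingedAffinityLoss(fw$affinity, 5, TRUE)
    }
    fw <- MiniDock:::.cnnForward(m, x, keepCache = TRUE)
    p <- MiniDock:::.softmax(fw$logits)
    g <- MiniDock:::.cnnBackward(m, fw, p - c(0, 1), 2 * (fw$affinity - 5))
    for (nm in sample(names(m$params), 4)) {
      i <- which.max(abs(g[[nm]]))
      eps <- 1e-5
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (lossOf(mp) - lossOf(mm)) / (2 * eps)
      expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("ensemble scoring is the arithmetic mean and order-invariant", {
  ds <- sharedGridData(8)
  ms <- lapply(1:3, function(s)
    buildModel(modelSpec("default2018", width = 4, inChannels = 8, npts = 8,
                         seed = s)))
  g <- ds[[1]]$grid
  one <- ensembleScore(ms[1], g)
  expect_equal(one$poseScore, cnnScoreGrid(ms[[1]], g)$poseScore)
  full <- ensembleScore(ms, g)
  indiv <- vapply(ms, function(m) cnnScoreGrid(m, g)$poseScore, numeric(1))
  expect_equal(full$poseScore, mean(indiv))
  logitsMean <- rowMeans(vapply(ms, function(m) cnnScoreGrid(m, g)$logits,
                                numeric(2)))
  expect_equal(full$logits, logitsMean)
  perm <- ensembleScore(ms[c(3, 1, 2)], g)
  expect_equal(perm$poseScore, full$poseScore)
  expect_error(ensembleScore(list(), g), "empty")
})

test_that("checkpoints round-trip through save/load", {
  m <- trainModel(modelSpec("default2018", width = 4, inChannels = 8, npts = 8,
                            seed = 2),
                  sharedGridData(8), epochs = 1)$model
  f <- tempfile(fileext = ".ckpt")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(m$params, m2$params)
  g <- sharedGridData(8)[[1]]$grid
  expect_equal(cnnScoreGrid(m, g)$poseScore, cnnScoreGrid(m2, g)$poseScore)
})
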