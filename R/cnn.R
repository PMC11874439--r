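## ---- grid CNN scorers -------------------------------------------------
##
## Two architecture families ending in a two-task head (pose
## classification logits + affinity regression):
##   default2018 - a linear stack of five 3x3x3 convolutions with 2x max
##     pooling after the first three, widths w, 2w, 4w, 4w, 4w;
##   dense - three densely connected blocks of four convolutions each
##     (twelve in total, growth rate g), 2x pooling between blocks.
## Features are global-average-pooled before the heads. Forward and
## backward passes run on the Rcpp kernels; training is plain SGD with
## momentum. Widths are desk-scale - behavior is exercised via synthetic
## training, not released weights.

#' CNN model specification
#'
#' @param family "default2018" or "dense"
#' @param width base filter count (default2018) or growth rate (dense)
#' @param inChannels input channel count; must match the grid spec used
#' @param npts grid points per side; default2018 needs npts divisible by 8,
#'   dense by 4
#' @param seed initialization seed (fully determines the initial weights)
#' @return list of class "ModelSpec"
#' @export
modelSpec <- function(family = c("default2018", "dense"), width = 8L,
                      inChannels = 8L, npts = 8L, seed = 0L) {
  family <- match.arg(family)
  stopifnot(width >= 1, inChannels >= 1, npts >= 4)
  if (family == "default2018" && npts %% 8 != 0)
    stop("default2018 pools three times: npts must be divisible by 8")
  if (family == "dense" && npts %% 4 != 0)
    stop("dense pools twice: npts must be divisible by 4")
  structure(list(family = family, width = as.integer(width),
                 inChannels = as.integer(inChannels), npts = as.integer(npts),
                 seed = as.integer(seed)),
            class = "ModelSpec")
}

.heInit <- function(fanIn, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dim = dims)
}

## layer plans: list of conv layers (in, out) in forward order
.convPlan <- function(spec) {
  w <- spec$width; C <- spec$inChannels
  if (spec$family == "default2018") {
    ins <- c(C, w, 2L * w, 4L * w, 4L * w)
    outs <- c(w, 2L * w, 4L * w, 4L * w, 4L * w)
    list(ins = ins, outs = outs, poolAfter = c(TRUE, TRUE, TRUE, FALSE, FALSE),
         features = 4L * w)
  } else {
    ins <- integer(0); outs <- integer(0)
    cur <- C
    for (b in 1:3) {
      for (k in 1:4) { ins <- c(ins, cur); outs <- c(outs, w); cur <- cur + w }
    }
    list(ins = ins, outs = outs,
         poolAfter = rep(c(FALSE, FALSE, FALSE, TRUE), 3)[1:12] &
           c(rep(TRUE, 8), rep(FALSE, 4)),  # pool after blocks 1 and 2 only
         features = C + 12L * w)
  }
}

#' Build an initialized CNN scorer
#'
#' @param spec a \code{\link{modelSpec}}
#' @return list of class "CNNModel" with \code{spec}, \code{params} and
#'   \code{nconv} (convolution layer count, by introspection of the plan)
#' @export
buildModel <- function(spec) {
  plan <- .convPlan(spec)
  .withSeed(spec$seed, {
    params <- list()
    for (k in seq_along(plan$ins)) {
      fanIn <- plan$ins[k] * 27
      params[[paste0("conv", k, ".w")]] <-
        .heInit(fanIn, c(plan$outs[k], plan$ins[k], 3, 3, 3))
      params[[paste0("conv", k, ".b")]] <- numeric(plan$outs[k])
    }
    f <- plan$features
    params[["pose.w"]] <- .heInit(f, c(2, f))
    params[["pose.b"]] <- numeric(2)
    params[["aff.w"]] <- .heInit(f, c(1, f))
    params[["aff.b"]] <- numeric(1)
    structure(list(spec = spec, params = params, plan = plan,
                   nconv = length(plan$ins)),
              class = "CNNModel")
  })
}

#' @export
print.CNNModel <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("CNNModel [%s] %d conv layers, %d features, %d parameters\n",
              x$spec$family, x$nconv, x$plan$features, np))
  invisible(x)
}

.concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

## forward pass; keepCache=TRUE retains intermediates for the backward pass
.cnnForward <- function(model, x, keepCache = FALSE) {
  spec <- model$spec; plan <- model$plan; P <- model$params
  stopifnot(dim(x)[1] == spec$inChannels, dim(x)[2] == spec$npts)
  dense <- spec$family == "dense"
  cache <- list(inputs = list(), relu = list(), pool = list(),
                preconcat = list())
  for (k in seq_along(plan$ins)) {
    if (keepCache) cache$inputs[[k]] <- x
    y <- cpp_conv3d_fw(x, dim(x), P[[paste0("conv", k, ".w")]],
                       P[[paste0("conv", k, ".b")]], plan$outs[k])
    y <- array(pmax(y, 0), dim(y))
    if (keepCache) cache$relu[[k]] <- y
    x2 <- if (dense) .concatChannels(x, y) else y
    if (plan$poolAfter[k]) {
      mp <- cpp_maxpool_fw(x2, dim(x2))
      if (keepCache) { cache$pool[[k]] <- mp$argmax; cache$preconcat[[k]] <- dim(x2) }
      x <- mp$y
    } else x <- x2
  }
  feat <- rowMeans(matrix(x, nrow = dim(x)[1]))
  logits <- as.numeric(P$pose.w %*% feat) + as.numeric(P$pose.b)
  affinity <- as.numeric(P$aff.w %*% feat) + as.numeric(P$aff.b)
  out <- list(logits = logits, affinity = affinity, features = feat)
  if (keepCache) { out$cache <- cache; out$final <- x }
  out
}

## backward pass: gradients of (dlogits, daff) through the network
.cnnBackward <- function(model, fw, dlogits, daff) {
  spec <- model$spec; plan <- model$plan; P <- model$params
  dense <- spec$family == "dense"
  grads <- list()
  feat <- fw$features
  grads[["pose.w"]] <- outer(dlogits, feat)
  grads[["pose.b"]] <- dlogits
  grads[["aff.w"]] <- matrix(daff * feat, nrow = 1)
  grads[["aff.b"]] <- daff
  dfeat <- as.numeric(t(P$pose.w) %*% dlogits + t(P$aff.w) * daff)
  xF <- fw$final
  nvox <- prod(dim(xF)[2:4])
  gx <- array(rep(dfeat / nvox, times = nvox), dim = dim(xF))
  for (k in rev(seq_along(plan$ins))) {
    if (plan$poolAfter[k])
      gx <- cpp_maxpool_bw(fw$cache$pool[[k]], gx, fw$cache$preconcat[[k]])
    if (dense) {
      cin <- plan$ins[k]
      gSkip <- array(gx[seq_len(cin), , , ], c(cin, dim(gx)[2:4]))
      gy <- array(gx[cin + seq_len(plan$outs[k]), , , ],
                  c(plan$outs[k], dim(gx)[2:4]))
    } else { gSkip <- NULL; gy <- gx }
    gy <- gy * (fw$cache$relu[[k]] > 0)
    xin <- fw$cache$inputs[[k]]
    bw <- cpp_conv3d_bw(xin, dim(xin), P[[paste0("conv", k, ".w")]],
                        plan$outs[k], gy)
    grads[[paste0("conv", k, ".w")]] <- bw$gw
    grads[[paste0("conv", k, ".b")]] <- bw$gb
    gx <- if (dense) bw$gx + gSkip else bw$gx
  }
  grads
}

#' Score a density grid with a CNN model
#'
#' @param model a "CNNModel"
#' @param grid a \linkS4class{DensityGrid} or raw values array
#' @return list of class "PoseScoreOutput": \code{logits} (bad, good),
#'   \code{poseScore} = softmax probability of the good class (CNNscore),
#'   \code{affinity} (CNNaffinity, pK)
#' @export
cnnScoreGrid <- function(model, grid) {
  x <- if (is(grid, "DensityGrid")) grid@values else grid
  fw <- .cnnForward(model, x, keepCache = FALSE)
  structure(list(logits = fw$logits, poseScore = .softmax(fw$logits)[2],
                 affinity = fw$affinity),
            class = "PoseScoreOutput")
}

.softmax <- function(l) {
  e <- exp(l - max(l))
  e / sum(e)
}

#' Mean-combine an ensemble of CNN scorers
#'
#' Pose score and affinity are arithmetic means of the member outputs;
#' logits are reported as the mean pre-softmax logits.
#'
#' @param members non-empty list of "CNNModel"s
#' @param grid \linkS4class{DensityGrid} or values array
#' @return "PoseScoreOutput"
#' @export
ensembleScore <- function(members, grid) {
  if (length(members) == 0) stop("empty ensemble")
  outs <- lapply(members, cnnScoreGrid, grid = grid)
  structure(list(
    logits = Reduce(`+`, lapply(outs, `[[`, "logits")) / length(outs),
    poseScore = mean(vapply(outs, `[[`, numeric(1), "poseScore")),
    affinity = mean(vapply(outs, `[[`, numeric(1), "affinity"))),
    class = "PoseScoreOutput")
}

## random axis-aligned (octahedral) rotation of a channel-first grid array
.randomGridRotation <- function(x) {
  perm <- sample(2:4)
  x <- aperm(x, c(1, perm))
  for (d in 2:4) if (stats::runif(1) < 0.5)
    x <- switch(d - 1,
      x[, rev(seq_len(dim(x)[2])), , , drop = FALSE],
      x[, , rev(seq_len(dim(x)[3])), , drop = FALSE],
      x[, , , rev(seq_len(dim(x)[4])), drop = FALSE])
  array(x, dim(x))
}

#' Train a CNN scorer on pose-labeled grids
#'
#' Minimizes cross entropy on the pose label plus the hinged affinity MSE
#' by minibatch SGD with momentum. Deterministic for fixed spec seed and
#' \code{shuffleSeed}.
#'
#' @param spec a \code{\link{modelSpec}} (or a prebuilt "CNNModel" to
#'   continue training)
#' @param dataset list of examples: each \code{list(grid = array or
#'   DensityGrid, poseLabel = logical, affinity = pK, rmsd = numeric)}
#' @param epochs training epochs (0 returns the initialized model)
#' @param lr learning rate
#' @param momentum SGD momentum
#' @param batchSize minibatch size
#' @param augment apply a random axis-aligned grid rotation per draw
#' @param shuffleSeed seed for shuffling/augmentation
#' @param lossHook optional function(example, fwOutput) -> list(extraLoss,
#'   dlogits) injected into the objective (used for distillation)
#' @param clipNorm global gradient-norm clip per minibatch
#' @return list: \code{model} (trained "CNNModel"), \code{history}
#'   (data.frame epoch/poseLoss/affLoss/accuracy)
#' @export
trainModel <- function(spec, dataset, epochs = 20L, lr = 0.01,
                       momentum = 0.9, batchSize = 8L, augment = FALSE,
                       shuffleSeed = 1L, lossHook = NULL, clipNorm = 5) {
  model <- if (inherits(spec, "CNNModel")) spec else buildModel(spec)
  n <- length(dataset)
  stopifnot(n > 0)
  grids <- lapply(dataset, function(e)
    if (is(e$grid, "DensityGrid")) e$grid@values else e$grid)
  labels <- vapply(dataset, function(e) isTRUE(e$poseLabel), logical(1))
  affs <- vapply(dataset, function(e) e$affinity, numeric(1))
  vel <- lapply(model$params, function(p) p * 0)  # zero, same shape/class
  history <- NULL
  .withSeed(shuffleSeed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epPose <- 0; epAff <- 0; epAcc <- 0
      for (bStart in seq(1, n, by = batchSize)) {
        idx <- ord[bStart:min(bStart + batchSize - 1, n)]
        gacc <- NULL
        for (i in idx) {
          x <- grids[[i]]
          if (augment) x <- .randomGridRotation(x)
          fw <- .cnnForward(model, x, keepCache = TRUE)
          cls <- if (labels[i]) 2L else 1L
          pl <- poseClassificationLoss(fw$logits, labels[i])
          al <- hingedAffinityLoss(fw$affinity, affs[i], labels[i])
          if (!is.finite(pl) || !is.finite(al))
            stop("training diverged (non-finite loss) at epoch ", ep)
          p <- .softmax(fw$logits)
          dlogits <- p - c(cls == 1L, cls == 2L)
          daff <- if (labels[i]) 2 * (fw$affinity - affs[i])
                  else 2 * max(0, fw$affinity - affs[i])
          if (!is.null(lossHook)) {
            hk <- lossHook(dataset[[i]], fw)
            dlogits <- dlogits + hk$dlogits
          }
          g <- .cnnBackward(model, fw, dlogits, daff)
          gacc <- if (is.null(gacc)) g else mapply(`+`, gacc, g, SIMPLIFY = FALSE)
          epPose <- epPose + pl; epAff <- epAff + al
          epAcc <- epAcc + ((p[2] > 0.5) == labels[i])
        }
        gacc <- lapply(gacc, `/`, length(idx))
        ## global-norm gradient clipping keeps the shared trunk stable while
        ## the affinity head's error is still large
        gnorm <- sqrt(sum(vapply(gacc, function(g) sum(g^2), numeric(1))))
        if (is.finite(gnorm) && gnorm > clipNorm)
          gacc <- lapply(gacc, `*`, clipNorm / gnorm)
        for (nm in names(model$params)) {
          vel[[nm]] <- momentum * vel[[nm]] - lr * gacc[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, poseLoss = epPose / n, affLoss = epAff / n,
        accuracy = epAcc / n))
    }
  })
  list(model = model, history = history)
}

#' Save / load a model checkpoint
#'
#' Single-file container (RDS) holding the spec and the weights.
#' @param model "CNNModel"
#' @param path checkpoint file
#' @export
saveModel <- function(model, path) {
  saveRDS(list(spec = unclass(model$spec), params = model$params), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  spec <- do.call(modelSpec, x$spec)
  m <- buildModel(spec)
  stopifnot(identical(lapply(m$params, dim), lapply(x$params, dim)))
  m$params <- x$params
  m
}
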