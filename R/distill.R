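#' Distillation configuration
#'
#' @param kdWeight weight on the KD term (>= 0)
#' @param temperature softmax temperature for the KD term
#' @param mode "kl" (KL divergence of softened distributions) or
#'   "soft_ce" (soft-target cross entropy)
#' @param epochs,lr,momentum,batchSize student training hyperparameters
#' @param seed student initialization / shuffling seed
#' @return list of class "DistillConfig"
#' @export
distillConfig <- function(kdWeight = 1, temperature = 1,
                          mode = c("kl", "soft_ce"), epochs = 15L,
                          lr = 0.01, momentum = 0.9, batchSize = 8L,
                          seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(kdWeight >= 0, temperature > 0)
  structure(list(kdWeight = kdWeight, temperature = temperature, mode = mode,
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "DistillConfig")
}

## KL(student || ensemble-mean) of pose-score distributions, averaged over
## a grid set: the distillation fidelity measure
.meanKLToEnsemble <- function(model, teachers, grids) {
  kl <- vapply(grids, function(g) {
    qs <- .softmax(cnnScoreGrid(model, g)$logits)
    pe <- .softmax(ensembleScore(teachers, g)$logits)
    ## ensemble-mean probabilities, not mean logits, define the target
    pm <- rowMeans(vapply(teachers, function(t)
      .softmax(cnnScoreGrid(t, g)$logits), numeric(2)))
    sum(qs * (log(qs) - log(pm)))
  }, numeric(1))
  mean(kl)
}

#' Distill a teacher ensemble into a single student
#'
#' Trains the student on the teachers' training dataset with the total
#' loss kdWeight * KD + pose cross entropy + hinged affinity MSE. Only the
#' pose score is distilled; affinity is supervised by ground truth alone.
#' Teacher logits are precomputed once (teachers are fixed).
#'
#' @param teachers list of trained "CNNModel"s (>= 2 for ensemble KD)
#' @param dataset training examples (see \code{\link{trainModel}})
#' @param studentSpec \code{\link{modelSpec}} for the student
#' @param config a \code{\link{distillConfig}}
#' @param heldout optional list of grids (arrays or DensityGrids) for the
#'   fidelity report
#' @return list: \code{model} (the student), \code{history}, and
#'   \code{fidelity} = mean held-out KL(student || ensemble mean) when
#'   \code{heldout} is given
#' @export
distillStudent <- function(teachers, dataset, studentSpec,
                           config = distillConfig(), heldout = NULL) {
  if (length(teachers) < 2)
    stop("ensemble distillation needs at least 2 teachers")
  grids <- lapply(dataset, function(e)
    if (is(e$grid, "DensityGrid")) e$grid@values else e$grid)
  tLogits <- lapply(grids, function(g)
    lapply(teachers, function(t) cnnScoreGrid(t, g)$logits))
  for (i in seq_along(dataset)) dataset[[i]]$.teacherLogits <- tLogits[[i]]

  hook <- function(example, fw) {
    list(extraLoss = config$kdWeight *
           kdLoss(fw$logits, example$.teacherLogits, config$temperature,
                  config$mode),
         dlogits = config$kdWeight *
           .kdGrad(fw$logits, example$.teacherLogits, config$temperature))
  }
  spec <- studentSpec
  spec$seed <- config$seed
  fit <- trainModel(spec, dataset, epochs = config$epochs, lr = config$lr,
                    momentum = config$momentum, batchSize = config$batchSize,
                    shuffleSeed = config$seed + 1L, lossHook = hook)
  out <- list(model = fit$model, history = fit$history)
  if (!is.null(heldout)) {
    hg <- lapply(heldout, function(g)
      if (is(g, "DensityGrid")) g@values else g)
    out$fidelity <- .meanKLToEnsemble(fit$model, teachers, hg)
  }
  out
}
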