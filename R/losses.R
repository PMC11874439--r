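#' Two-class cross-entropy pose loss
#'
#' Standard cross entropy on the softmax of the (bad, good) logits against
#' the boolean pose label (good = RMSD at or below 2 Angstrom).
#'
#' @param logits numeric length-2 (bad, good)
#' @param label logical: TRUE for a good pose
#' @return non-negative loss value
#' @export
poseClassificationLoss <- function(logits, label) {
  stopifnot(length(logits) == 2, all(is.finite(logits)))
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  lse - logits[if (isTRUE(label)) 2L else 1L]
}

#' Hinged affinity MSE
#'
#' Squared error for good poses; for bad poses only over-prediction is
#' penalized: \code{max(0, predicted - true)^2}. An inaccurate pose should
#' not be rewarded for predicting the full binding affinity.
#'
#' @param predicted,true pK-scale affinities
#' @param poseLabel logical: TRUE when the pose is accurate
#' @export
hingedAffinityLoss <- function(predicted, true, poseLabel) {
  stopifnot(is.finite(predicted), is.finite(true))
  if (isTRUE(poseLabel)) (predicted - true)^2
  else max(0, predicted - true)^2
}

#' Knowledge-distillation loss against an ensemble of teachers
#'
#' Sum over teachers of the Kullback-Leibler divergence between the
#' temperature-softened teacher and student pose-score distributions,
#' computed from the raw (pre-softmax) logits:
#' \code{sum_t KL(softmax(t/T) || softmax(s/T))}. With
#' \code{mode = "soft_ce"} the soft-target cross entropy
#' \code{-sum p_t log q_s} is used instead (same gradient, offset by the
#' teacher entropy).
#'
#' @param studentLogits numeric length-2
#' @param teacherLogitsList list of numeric length-2 vectors
#' @param temperature softmax temperature (default 1)
#' @param mode "kl" or "soft_ce"
#' @return non-negative loss (kl mode)
#' @export
kdLoss <- function(studentLogits, teacherLogitsList, temperature = 1,
                   mode = c("kl", "soft_ce")) {
  mode <- match.arg(mode)
  qs <- .softmax(studentLogits / temperature)
  tot <- 0
  for (tl in teacherLogitsList) {
    stopifnot(length(tl) == length(studentLogits))
    pt <- .softmax(tl / temperature)
    tot <- tot + if (mode == "kl") sum(pt * (log(pt) - log(qs)))
                 else -sum(pt * log(qs))
  }
  tot
}

## gradient of kdLoss w.r.t. the student logits (same for both modes)
.kdGrad <- function(studentLogits, teacherLogitsList, temperature = 1) {
  qs <- .softmax(studentLogits / temperature)
  g <- numeric(length(studentLogits))
  for (tl in teacherLogitsList)
    g <- g + (qs - .softmax(tl / temperature)) / temperature
  g
}

#' Total distillation training loss
#'
#' \code{kdWeight * kdLoss + poseClassificationLoss + hingedAffinityLoss};
#' all component weights default to 1, mirroring a sum of the KD loss and
#' the ground-truth pose and affinity losses.
#'
#' @param studentLogits,studentAffinity student outputs
#' @param teacherLogitsList teacher pose logits
#' @param label pose label (logical)
#' @param trueAffinity ground-truth pK
#' @param config a \code{\link{distillConfig}}
#' @export
totalDistillLoss <- function(studentLogits, studentAffinity,
                             teacherLogitsList, label, trueAffinity,
                             config = distillConfig()) {
  config$kdWeight * kdLoss(studentLogits, teacherLogitsList,
                           config$temperature, config$mode) +
    poseClassificationLoss(studentLogits, label) +
    hingedAffinityLoss(studentAffinity, trueAffinity, label)
}
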