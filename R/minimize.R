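## ---- gradient-based local minimization over pose degrees of freedom ----
##
## Degrees of freedom: 3 translation + 3 rotation (axis-angle about the
## ligand centroid) + one angle per rotatable bond; covalent mode drops the
## rigid-body block. Minimization is quasi-Newton (BFGS) in the generator
## basis with incremental coordinate updates and an Armijo backtracking line
## search, so the objective never increases.

## objective = weighted inter-molecular + weighted intramolecular score,
## with d(objective)/d(ligand atom coordinates)
.poseObjective <- function(X, recXYZ, fl, fr, intraPairs, wv, cutoff,
                           grad = TRUE) {
  inter <- cpp_score_inter(X, fl$vdw, fl$act, fl$hyd, fl$don, fl$acc,
                           recXYZ, fr$vdw, fr$act, fr$hyd, fr$don, fr$acc,
                           wv, cutoff, grad)
  val <- inter$weighted
  g <- if (grad) inter$grad else NULL
  if (nrow(intraPairs)) {
    intra <- cpp_score_intra(X, fl$vdw, fl$hyd, fl$don, fl$acc,
                             intraPairs, wv, cutoff, grad)
    val <- val + intra$weighted
    if (grad) g <- g + intra$grad
  }
  list(value = val, grad = g)
}

#' Empirical minimization objective of a pose
#'
#' The quantity \code{\link{localMinimize}} descends: the weighted
#' inter-molecular score plus the conformation-dependent intramolecular
#' score (pairs separated by a rotatable bond, 1-4 and beyond).
#'
#' @inheritParams scorePose
#' @param pose Pose or coordinate matrix
#' @export
empiricalObjective <- function(receptor, ligand, pose = NULL,
                               weights = termWeights(), tree = NULL,
                               cutoff = 8) {
  X <- if (is.null(pose)) coords(ligand)
       else if (is(pose, "Pose")) pose@coords else pose
  if (is.null(tree)) tree <- buildTorsionTree(ligand)
  .poseObjective(X, coords(receptor), .scoreFlags(ligand),
                 .scoreFlags(receptor), .intraPairs(ligand, tree),
                 .wvec(weights), cutoff, grad = FALSE)$value
}

## projection of the atom-wise gradient onto the generator basis
.genGrad <- function(X, gAtoms, tree, rigid) {
  g <- numeric(0)
  if (rigid) {
    c0 <- colMeans(X)
    gt <- colSums(gAtoms)
    rel <- sweep(X, 2, c0)
    gr <- c(sum(rel[, 2] * gAtoms[, 3] - rel[, 3] * gAtoms[, 2]),
            sum(rel[, 3] * gAtoms[, 1] - rel[, 1] * gAtoms[, 3]),
            sum(rel[, 1] * gAtoms[, 2] - rel[, 2] * gAtoms[, 1]))
    g <- c(gt, gr)
  }
  for (t in tree@torsions) {
    u <- X[t$b, ] - X[t$a, ]
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) { g <- c(g, 0); next }
    u <- u / nu
    rel <- sweep(X[t$moving, , drop = FALSE], 2, X[t$b, ])
    cr <- cbind(rel[, 2] * gAtoms[t$moving, 3] - rel[, 3] * gAtoms[t$moving, 2],
                rel[, 3] * gAtoms[t$moving, 1] - rel[, 1] * gAtoms[t$moving, 3],
                rel[, 1] * gAtoms[t$moving, 2] - rel[, 2] * gAtoms[t$moving, 1])
    g <- c(g, sum(colSums(cr) * u))
  }
  g
}

## apply a step in the generator basis: torsions (listed order), then rigid
## rotation about the centroid, then translation
.applyStep <- function(X, d, tree, rigid) {
  off <- 0L
  if (rigid) off <- 6L
  nt <- nrot(tree)
  if (nt > 0)
    for (k in seq_len(nt))
      if (abs(d[off + k]) > 0) X <- applyTorsion(X, tree, k, d[off + k])
  if (rigid) {
    w <- d[4:6]
    ang <- sqrt(sum(w^2))
    if (ang > 1e-12) X <- .rotateAbout(X, colMeans(X), w / ang, ang)
    X <- sweep(X, 2, d[1:3], `+`)
  }
  X
}

#' Local minimization of a pose against the empirical score
#'
#' BFGS over the pose's degrees of freedom (6 rigid-body + torsions, or
#' torsions only in covalent mode), with analytic gradients and an Armijo
#' line search so the returned objective is never above the input one.
#'
#' @inheritParams scorePose
#' @param pose starting \linkS4class{Pose} or coordinate matrix
#' @param dof \code{"all"} (rigid + torsions) or \code{"torsion"} (covalent)
#' @param config list: \code{gtol} gradient infinity-norm stop (1e-4),
#'   \code{maxit} iteration cap (200), \code{ftol} relative-improvement
#'   stop (1e-8)
#' @return a \linkS4class{Pose}; \code{empiricalScore} holds the
#'   torsion-penalized final score, \code{provenance$objective} the
#'   minimized objective, \code{provenance$objective0} the starting one
#' @export
localMinimize <- function(receptor, ligand, pose, tree = NULL,
                          weights = termWeights(), dof = c("all", "torsion"),
                          config = list(), cutoff = 8) {
  dof <- match.arg(dof)
  gtol <- config$gtol %||% 1e-4
  maxit <- config$maxit %||% 200L
  ftol <- config$ftol %||% 1e-8
  X <- if (is(pose, "Pose")) pose@coords else pose
  if (is.null(tree)) tree <- buildTorsionTree(ligand)
  rigid <- dof == "all"
  m <- (if (rigid) 6L else 0L) + nrot(tree)
  fl <- .scoreFlags(ligand); fr <- .scoreFlags(receptor)
  recXYZ <- coords(receptor)
  ip <- .intraPairs(ligand, tree)
  wv <- .wvec(weights)
  obj <- .poseObjective(X, recXYZ, fl, fr, ip, wv, cutoff)
  f0 <- obj$value
  if (m == 0L) {  # nothing to move (covalent mode, rigid ligand)
    p <- .mkPose(X, provenance = list(objective = f0, objective0 = f0))
    p@empiricalScore <- scorePose(receptor, ligand, X, weights, tree, cutoff)$finalScore
    return(p)
  }
  f <- f0
  g <- .genGrad(X, obj$grad, tree, rigid)
  if (any(!is.finite(g))) stop("non-finite gradient at starting pose")
  H <- diag(m)
  for (iter in seq_len(maxit)) {
    if (max(abs(g)) < gtol) break
    p <- -as.numeric(H %*% g)
    if (sum(p * g) >= 0) { H <- diag(m); p <- -g }
    ## cap the first trial step at 1 A / 1 rad per coordinate
    alpha <- min(1, 1 / max(abs(p)))
    fNew <- Inf; XNew <- NULL
    for (half in 1:22) {
      XTry <- .applyStep(X, alpha * p, tree, rigid)
      fTry <- .poseObjective(XTry, recXYZ, fl, fr, ip, wv, cutoff, FALSE)$value
      if (is.finite(fTry) && fTry <= f + 1e-4 * alpha * sum(g * p)) {
        fNew <- fTry; XNew <- XTry; break
      }
      alpha <- alpha / 2
    }
    if (is.null(XNew)) break           # no descent direction left
    converged <- (f - fNew) < ftol * (abs(f) + 1)
    objNew <- .poseObjective(XNew, recXYZ, fl, fr, ip, wv, cutoff)
    gNew <- .genGrad(XNew, objNew$grad, tree, rigid)
    if (any(!is.finite(gNew))) stop("non-finite gradient during minimization")
    s <- alpha * p
    y <- gNew - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(m)
      V <- I - rho * outer(s, y)
      H <- V %*% H %*% t(V) + rho * outer(s, s)
    }
    X <- XNew; f <- fNew; g <- gNew
    if (converged) break               # relative improvement below ftol
  }
  out <- .mkPose(X, provenance = list(objective = f, objective0 = f0))
  out@empiricalScore <- scorePose(receptor, ligand, X, weights, tree, cutoff)$finalScore
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mkPose <- function(X, empiricalScore = NA_real_, provenance = list()) {
  new("Pose", coords = X, empiricalScore = empiricalScore,
      provenance = provenance)
}
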