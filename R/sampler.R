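#' Sampler configuration
#'
#' @param exhaustiveness number of independent MCMC chains
#' @param steps Monte Carlo steps per chain
#' @param amplitude translation mutation amplitude, Angstrom (torsion and
#'   rigid-rotation draws cover the full circle)
#' @param temperature Metropolis temperature in score units
#' @param seed base seed; chain c uses \code{seed + c}
#' @param numModes output pose count after diversity filtering
#' @param minPoseRmsd diversity filter threshold, Angstrom
#' @param covalentMode only torsion moves, no rigid-body transformations
#' @return list of class "SamplerConfig"
#' @export
samplerConfig <- function(exhaustiveness = 8L, steps = 200L, amplitude = 2,
                          temperature = 1.2, seed = 0L, numModes = 9L,
                          minPoseRmsd = 1.0, covalentMode = FALSE) {
  stopifnot(exhaustiveness >= 1, steps >= 0, amplitude > 0, temperature > 0,
            numModes >= 1, minPoseRmsd > 0)
  structure(list(exhaustiveness = as.integer(exhaustiveness),
                 steps = as.integer(steps), amplitude = amplitude,
                 temperature = temperature, seed = as.integer(seed),
                 numModes = as.integer(numModes), minPoseRmsd = minPoseRmsd,
                 covalentMode = isTRUE(covalentMode)),
            class = "SamplerConfig")
}

#' Randomly perturb a pose
#'
#' Applies exactly one move, chosen uniformly among rigid translation
#' (displacement of length at most the amplitude), rigid rotation about the
#' centroid (uniform axis, full-circle angle) and a single random torsion
#' change. In covalent mode only torsion moves are drawn; with no rotatable
#' bonds the pose is returned unchanged with a warning. Uses R's RNG -
#' callers seed it.
#'
#' @param pose \linkS4class{Pose} or coordinate matrix
#' @param tree the ligand's \linkS4class{TorsionTree}
#' @param config a \code{\link{samplerConfig}}
#' @return perturbed \linkS4class{Pose}
#' @export
mutatePose <- function(pose, tree, config = samplerConfig()) {
  X <- if (is(pose, "Pose")) pose@coords else pose
  nt <- nrot(tree)
  moves <- if (config$covalentMode) "torsion"
           else c("translate", "rotate", "torsion")
  if (nt == 0) {
    if (config$covalentMode) {
      warning("covalent mode with no rotatable bonds: pose unchanged")
      return(.mkPose(X))
    }
    moves <- setdiff(moves, "torsion")
  }
  mv <- if (length(moves) == 1) moves else sample(moves, 1)
  X <- switch(mv,
    translate = {
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2)) * stats::runif(1, 0, config$amplitude)
      sweep(X, 2, d, `+`)
    },
    rotate = {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      .rotateAbout(X, colMeans(X), ax, stats::runif(1, 0, 2 * pi))
    },
    torsion = applyTorsion(X, tree, sample.int(nt, 1),
                           stats::runif(1, -pi, pi)))
  .mkPose(X, provenance = list(move = mv))
}

#' Metropolis acceptance rule
#'
#' Accepts with probability \code{min(1, exp(-delta / temperature))}.
#'
#' @param delta score change (new - old)
#' @param temperature Metropolis temperature, > 0
#' @return logical
#' @export
metropolisAccept <- function(delta, temperature) {
  stopifnot(temperature > 0)
  delta <= 0 || stats::runif(1) < exp(-delta / temperature)
}

.inBox <- function(X, box, slack = 0) {
  ctr <- colMeans(X)
  all(abs(ctr - box$center) <= box$size / 2 + slack)
}

#' Run one Monte Carlo chain
#'
#' Each step mutates the pose, locally minimizes it against the empirical
#' score and applies the Metropolis rule on the minimized objective.
#' Minimized poses whose centroid stays inside the box are recorded.
#' Deterministic for a fixed \code{chainSeed}.
#'
#' @inheritParams scorePose
#' @param startPose starting \linkS4class{Pose}/matrix, centroid inside the box
#' @param box list(center =, size =), Angstrom
#' @param config \code{\link{samplerConfig}}
#' @param chainSeed integer seed for this chain
#' @return list of recorded \linkS4class{Pose}s (empirical scores set),
#'   best first
#' @export
runChain <- function(receptor, ligand, startPose, box, tree = NULL,
                     weights = termWeights(), config = samplerConfig(),
                     chainSeed = config$seed) {
  X0 <- if (is(startPose, "Pose")) startPose@coords else startPose
  if (!.inBox(X0, box)) stop("start pose centroid outside the search box")
  if (is.null(tree)) tree <- buildTorsionTree(ligand)
  dof <- if (config$covalentMode) "torsion" else "all"
  .withSeed(chainSeed, {
    cur <- localMinimize(receptor, ligand, X0, tree, weights, dof = dof)
    curObj <- cur@provenance$objective
    pool <- list(); objs <- numeric(0)
    record <- function(p, o) {
      if (.inBox(p@coords, box, slack = 0)) {
        pool[[length(pool) + 1L]] <<- p
        objs[length(objs) + 1L] <<- o
      }
    }
    record(cur, curObj)
    nt <- nrot(tree)
    if (config$steps > 0 && !(config$covalentMode && nt == 0)) {
      for (s in seq_len(config$steps)) {
        cand <- mutatePose(cur, tree, config)
        if (!.inBox(cand@coords, box, slack = config$amplitude)) next
        candMin <- localMinimize(receptor, ligand, cand@coords, tree,
                                 weights, dof = dof)
        cObj <- candMin@provenance$objective
        if (!.inBox(candMin@coords, box)) next
        record(candMin, cObj)
        if (metropolisAccept(cObj - curObj, config$temperature)) {
          cur <- candMin; curObj <- cObj
        }
      }
    }
    ord <- order(vapply(pool, function(p) p@empiricalScore, numeric(1)))
    lapply(pool[ord], function(p) {
      p@provenance$chainSeed <- chainSeed
      p
    })
  })
}

## greedy diversity filter on symmetry-corrected RMSD
.diversityFilter <- function(poses, ligand, minRmsd, numModes) {
  kept <- list()
  for (p in poses) {
    ok <- TRUE
    for (q in kept)
      if (symmetryRmsd(p@coords, q@coords, ligand) <= minRmsd) { ok <- FALSE; break }
    if (ok) kept[[length(kept) + 1L]] <- p
    if (length(kept) >= numModes) break
  }
  kept
}

#' Dock a ligand into a box
#'
#' Runs \code{exhaustiveness} Monte Carlo chains from random in-box starts,
#' pools their poses, sorts by empirical score and greedily keeps poses
#' mutually farther apart than \code{minPoseRmsd} (symmetry-corrected),
#' truncated to \code{numModes}. CNN rescoring, when requested, happens
#' downstream and only reorders.
#'
#' @inheritParams runChain
#' @return list of \linkS4class{Pose}s, best empirical score first; empty
#'   with a warning when no in-box pose was found
#' @export
runDocking <- function(receptor, ligand, box, weights = termWeights(),
                       config = samplerConfig(), tree = NULL) {
  if (is.null(tree)) tree <- buildTorsionTree(ligand)
  pool <- list()
  for (ch in seq_len(config$exhaustiveness)) {
    chainSeed <- as.integer((config$seed + ch) %% .Machine$integer.max)
    start <- .withSeed(chainSeed * 2L + 1L, {
      X <- coords(ligand)
      if (!config$covalentMode) {
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        X <- .rotateAbout(X, colMeans(X), ax, stats::runif(1, 0, 2 * pi))
        tgt <- box$center + stats::runif(3, -0.25, 0.25) * box$size
        X <- sweep(X, 2, tgt - colMeans(X), `+`)
      } else {
        nt <- nrot(tree)
        if (nt > 0)
          for (k in seq_len(nt))
            X <- applyTorsion(X, tree, k, stats::runif(1, -pi, pi))
      }
      X
    })
    pool <- c(pool, runChain(receptor, ligand, start, box, tree, weights,
                             config, chainSeed))
  }
  if (!length(pool)) {
    warning("no in-box pose found")
    return(list())
  }
  ord <- order(vapply(pool, function(p) p@empiricalScore, numeric(1)))
  .diversityFilter(pool[ord], ligand, config$minPoseRmsd, config$numModes)
}
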