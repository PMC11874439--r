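#' Empirical scoring term weights
#'
#' Defaults are the published AutoDock Vina weights for the five
#' inter-molecular terms plus the rotatable-bond penalty coefficient.
#'
#' @param gauss1,gauss2,repulsion,hydrophobic,hbond term weights
#' @param rot rotatable-bond penalty coefficient
#' @return named list of class "TermWeights"
#' @export
termWeights <- function(gauss1 = -0.035579, gauss2 = -0.005156,
                        repulsion = 0.840245, hydrophobic = -0.035069,
                        hbond = -0.587439, rot = 0.05846) {
  w <- list(gauss1 = gauss1, gauss2 = gauss2, repulsion = repulsion,
            hydrophobic = hydrophobic, hbond = hbond, rot = rot)
  stopifnot(all(vapply(w, is.finite, logical(1))))
  structure(w, class = "TermWeights")
}

.wvec <- function(w) c(w$gauss1, w$gauss2, w$repulsion, w$hydrophobic, w$hbond)

#' Surface distance between two atoms
#'
#' Center distance minus the sum of the van der Waals radii; negative when
#' the spheres interpenetrate.
#'
#' @param mol1,mol2 TypedMolecules
#' @param i,j atom indices into mol1 and mol2
#' @return Angstrom, possibly negative
#' @export
surfaceDistance <- function(mol1, i, mol2, j) {
  a <- mol1@atoms[i, ]; b <- mol2@atoms[j, ]
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2) - (a$vdw + b$vdw)
}

#' Evaluate the five empirical pair terms at a surface distance
#'
#' gauss1 = exp(-(d/0.5)^2); gauss2 = exp(-((d-3)/2)^2); repulsion = d^2 for
#' d < 0 else 0; hydrophobic ramps 1 -> 0 over d in [0.5, 1.5] and applies
#' only to HydrophobicC pairs; hbond ramps 1 -> 0 over d in [-0.7, 0] and
#' applies only to donor-acceptor pairs.
#'
#' @param dsurf surface distance(s), Angstrom
#' @param typeA,typeB interaction types of the pair (recycled)
#' @return matrix with columns gauss1, gauss2, repulsion, hydrophobic, hbond
#' @export
evaluatePairTerms <- function(dsurf, typeA, typeB) {
  n <- length(dsurf)
  typeA <- rep_len(typeA, n); typeB <- rep_len(typeB, n)
  hydPair <- typeA == "HydrophobicC" & typeB == "HydrophobicC"
  hbPair <- (.isDonorType(typeA) & .isAcceptorType(typeB)) |
            (.isDonorType(typeB) & .isAcceptorType(typeA))
  cpp_pair_terms(as.numeric(dsurf), hydPair, hbPair)
}

## per-atom role flags for the C++ kernels; hydrogens are inactive
.scoreFlags <- function(mol) {
  t <- mol@atoms$type
  if (anyNA(t)) stop("atom types not assigned; call assignAtomTypes() first")
  list(act = as.integer(t != "H"),
       hyd = as.integer(t == "HydrophobicC"),
       don = as.integer(.isDonorType(t)),
       acc = as.integer(.isAcceptorType(t)),
       vdw = mol@atoms$vdw)
}

## intramolecular pair list: heavy-atom pairs in different rigid fragments
## (their distance depends on torsions) that are 1-4 or more apart
.intraPairs <- function(mol, tree) {
  if (nrot(tree) == 0) return(matrix(integer(0), ncol = 2))
  n <- natoms(mol)
  el <- mol@atoms$element
  frag <- integer(n)
  frag[tree@rootAtoms] <- 0L
  for (k in seq_along(tree@torsions)) {
    mv <- tree@torsions[[k]]$moving
    frag[mv] <- k  # deepest torsion wins: listed later = farther from root
  }
  g <- .molGraph(mol)
  topo <- igraph::distances(g)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- el[pairs[, 1]] != "H" & el[pairs[, 2]] != "H" &
    frag[pairs[, 1]] != frag[pairs[, 2]] &
    topo[pairs] >= 3
  unname(as.matrix(pairs[keep, , drop = FALSE]))
}

#' Score a ligand pose against a receptor
#'
#' Sums the five weighted terms over all receptor-ligand heavy-atom pairs
#' within the 8 Angstrom center-to-center cutoff and divides by
#' \code{1 + w_rot * N_rot}.
#'
#' @param receptor,ligand typed \linkS4class{TypedMolecule}s
#' @param pose optional \linkS4class{Pose} or coordinate matrix for the
#'   ligand (default: the ligand's own coordinates)
#' @param weights \code{\link{termWeights}}
#' @param tree optional \linkS4class{TorsionTree} supplying N_rot (default:
#'   built from the ligand)
#' @param cutoff pair cutoff, Angstrom
#' @return list of class "ScoringReport": per-term sums, \code{weightedTotal}
#'   (inter-molecular), \code{finalScore} (torsion-penalized), \code{npairs},
#'   \code{nrot}
#' @export
scorePose <- function(receptor, ligand, pose = NULL, weights = termWeights(),
                      tree = NULL, cutoff = 8) {
  if (natoms(ligand) == 0) stop("empty ligand")
  X <- if (is.null(pose)) coords(ligand)
       else if (is(pose, "Pose")) pose@coords else pose
  stopifnot(nrow(X) == natoms(ligand))
  if (is.null(tree)) tree <- buildTorsionTree(ligand)
  fl <- .scoreFlags(ligand); fr <- .scoreFlags(receptor)
  res <- cpp_score_inter(X, fl$vdw, fl$act, fl$hyd, fl$don, fl$acc,
                         coords(receptor), fr$vdw, fr$act, fr$hyd, fr$don,
                         fr$acc, .wvec(weights), cutoff, FALSE)
  nr <- nrot(tree)
  structure(list(terms = res$terms, weightedTotal = res$weighted,
                 finalScore = res$weighted / (1 + weights$rot * nr),
                 npairs = res$npairs, nrot = nr),
            class = "ScoringReport")
}

#' @export
print.ScoringReport <- function(x, ...) {
  cat("ScoringReport\n  terms:",
      paste(names(x$terms), sprintf("%.4f", x$terms), sep = "=", collapse = " "),
      sprintf("\n  weighted inter %.4f | final %.4f (nrot=%d, %d pairs)\n",
              x$weightedTotal, x$finalScore, x$nrot, x$npairs))
  invisible(x)
}
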