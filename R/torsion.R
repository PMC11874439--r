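.molGraph <- function(mol, heavyOnly = FALSE) {
  n <- natoms(mol)
  b <- mol@bonds
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(b)) g <- igraph::add_edges(g, as.vector(t(b[, 1:2, drop = FALSE])))
  if (heavyOnly) {
    keepv <- which(mol@atoms$element != "H")
    g <- igraph::induced_subgraph(g, keepv)
  }
  g
}

#' Build the torsion tree of a molecule
#'
#' Rotatable bonds are acyclic (bridge) single bonds with at least one heavy
#' substituent beyond the axis on both sides; ring bonds and terminal bonds
#' never rotate. The root is the largest rigid fragment (most atoms, ties
#' broken by lowest atom index) unless \code{rootAtom} forces the fragment
#' containing that atom - covalent docking roots the tree at the receptor
#' anchor so the backbone stays immobile.
#'
#' @param mol a \linkS4class{TypedMolecule}; the heavy-atom graph must be
#'   connected
#' @param rootAtom optional atom index whose rigid fragment becomes the root
#' @return a \linkS4class{TorsionTree}; each torsion's moving set is the
#'   atom set on the far side of the axis from the root (hydrogens included)
#' @export
buildTorsionTree <- function(mol, rootAtom = NULL) {
  n <- natoms(mol)
  el <- mol@atoms$element
  g <- .molGraph(mol)
  heavy <- which(el != "H")
  gh <- igraph::induced_subgraph(g, heavy)
  if (length(heavy) > 1 && !igraph::is_connected(gh))
    stop("disconnected heavy-atom graph; torsion tree undefined")

  b <- mol@bonds
  bridges <- igraph::bridges(g)
  bridgePairs <- if (length(bridges)) igraph::ends(g, bridges) else
    matrix(integer(0), ncol = 2)
  isBridge <- logical(nrow(b))
  if (nrow(bridgePairs)) {
    bk <- paste(pmin(bridgePairs[, 1], bridgePairs[, 2]),
                pmax(bridgePairs[, 1], bridgePairs[, 2]))
    isBridge <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])) %in% bk
  }

  deg <- igraph::degree(g)
  heavyNbr <- function(v, excl) {
    nb <- as.integer(igraph::neighbors(g, v))
    sum(el[setdiff(nb, excl)] != "H")
  }
  rot <- integer(0)
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    if (b[k, 3] != 1L || !isBridge[k]) next
    if (el[i] == "H" || el[j] == "H") next
    if (heavyNbr(i, j) >= 1L && heavyNbr(j, i) >= 1L) rot <- c(rot, k)
  }

  ## rigid fragments = components after deleting rotatable bonds
  g2 <- g
  if (length(rot)) {
    eids <- igraph::get_edge_ids(g, as.vector(t(b[rot, 1:2, drop = FALSE])))
    g2 <- igraph::delete_edges(g, eids)
  }
  comp <- igraph::components(g2)$membership
  fragOf <- comp
  if (is.null(rootAtom)) {
    sizes <- tabulate(comp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      firstAtom <- vapply(best, function(f) min(which(comp == f)), integer(1))
      best <- best[which.min(firstAtom)]
    }
    rootFrag <- best[1]
  } else {
    stopifnot(rootAtom >= 1, rootAtom <= n)
    rootFrag <- comp[rootAtom]
  }
  rootAtoms <- which(comp == rootFrag)

  ## orient each rotatable bond: a = root side, moving set = far side of b
  torsions <- list()
  for (k in rot) {
    i <- b[k, 1]; j <- b[k, 2]
    eid <- igraph::get_edge_ids(g, c(i, j))
    gcut <- igraph::delete_edges(g, eid)
    cc <- igraph::components(gcut)$membership
    if (cc[rootAtoms[1]] == cc[i]) { a <- i; bb <- j } else { a <- j; bb <- i }
    moving <- which(cc == cc[bb])
    torsions[[length(torsions) + 1L]] <-
      list(a = as.integer(a), b = as.integer(bb), moving = as.integer(moving))
  }
  ## stable order: by root-side atom index then far atom
  if (length(torsions)) {
    o <- order(vapply(torsions, `[[`, integer(1), "a"),
               vapply(torsions, `[[`, integer(1), "b"))
    torsions <- torsions[o]
  }
  new("TorsionTree", rootAtoms = as.integer(rootAtoms), torsions = torsions,
      natoms = as.integer(n))
}

## Rodrigues rotation of points about axis through 'origin' with unit dir u
.rotateAbout <- function(xyz, origin, u, angle) {
  p <- sweep(xyz, 2, origin)
  c1 <- cos(angle); s1 <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  R <- diag(3) + s1 * K + (1 - c1) * (K %*% K)
  sweep(p %*% t(R), 2, origin, `+`)
}

#' Rotate one torsion of a conformation
#'
#' @param xyz n x 3 coordinate matrix
#' @param tree a \linkS4class{TorsionTree} for the same molecule
#' @param k torsion index (1..nrot)
#' @param angle radians; positive = right-hand rule about the a->b axis
#' @return new coordinate matrix; only the torsion's moving set changes
#' @export
applyTorsion <- function(xyz, tree, k, angle) {
  t <- tree@torsions[[k]]
  aPos <- xyz[t$a, ]; bPos <- xyz[t$b, ]
  u <- bPos - aPos
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) return(xyz)  # degenerate axis: no-op
  u <- u / nu
  xyz[t$moving, ] <- .rotateAbout(xyz[t$moving, , drop = FALSE], bPos, u, angle)
  xyz
}
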