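#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib MiniDock, .registration = TRUE
NULL

#' TypedMolecule: atoms, bonds and interaction types
#'
#' The central molecular container. Atoms live in a data.frame with one row
#' per atom (element symbol, Cartesian coordinates in Angstrom, interaction
#' type, van der Waals and covalent radii, a ligand/receptor identity flag,
#' and - for receptor atoms - PDB-style residue metadata). Bonds are stored
#' as an integer matrix with columns \code{i}, \code{j}, \code{order}
#' (1-based atom indices).
#'
#' The \code{isLigand} flag survives covalent construct building: atoms that
#' entered as ligand atoms keep the flag even after they become part of a
#' flexible residue-ligand construct, so CNN channel assignment still routes
#' them to ligand channels.
#'
#' @slot atoms data.frame of per-atom records (see Details).
#' @slot bonds integer matrix, columns i, j, order.
#' @export
.emptyAtoms <- data.frame(
  element = character(0), x = numeric(0), y = numeric(0), z = numeric(0),
  type = character(0), vdw = numeric(0), covr = numeric(0),
  isLigand = logical(0), chain = character(0), resno = character(0),
  resname = character(0), atomName = character(0), stringsAsFactors = FALSE)

setClass("TypedMolecule",
  representation(atoms = "data.frame", bonds = "matrix"),
  prototype(atoms = .emptyAtoms, bonds = matrix(integer(0), ncol = 3L,
    dimnames = list(NULL, c("i", "j", "order"))))
)

setValidity("TypedMolecule", function(object) {
  a <- object@atoms
  b <- object@bonds
  msgs <- character(0)
  need <- colnames(.emptyAtoms)
  if (nrow(a) > 0 && !all(need %in% names(a)))
    msgs <- c(msgs, paste("atoms lacks columns:",
                          paste(setdiff(need, names(a)), collapse = ", ")))
  if (ncol(b) != 3L) msgs <- c(msgs, "bonds must have 3 columns (i, j, order)")
  if (nrow(b) > 0) {
    if (any(b[, 1:2] < 1L) || any(b[, 1:2] > nrow(a)))
      msgs <- c(msgs, "bond endpoints out of range")
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bonds")
    if (any(b[, 1] == b[, 2])) msgs <- c(msgs, "self-bonds not allowed")
  }
  if (nrow(a) > 0) {
    if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
      msgs <- c(msgs, "non-finite coordinates")
    typed <- !is.na(a$type)
    if (any(a$vdw[typed] <= 0)) msgs <- c(msgs, "vdw radius must be > 0")
    if (any(a$covr[typed] <= 0)) msgs <- c(msgs, "covalent radius must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' TorsionTree: rigid root plus rotatable bonds
#'
#' Decomposition of a molecule into a rigid root fragment and a list of
#' rotatable bonds, each carrying its axis atoms \code{(a, b)} and the set
#' of atoms that move when the torsion turns (the subtree on the \code{b}
#' side). Rotating one torsion changes only its moving set.
#'
#' @slot rootAtoms integer vector, atoms of the rigid root fragment.
#' @slot torsions list; each element is list(a =, b =, moving = integer()).
#' @slot natoms integer, atom count of the molecule the tree refers to.
#' @export
setClass("TorsionTree",
  representation(rootAtoms = "integer", torsions = "list", natoms = "integer"))

setValidity("TorsionTree", function(object) {
  msgs <- character(0)
  for (t in object@torsions) {
    if (!all(c("a", "b", "moving") %in% names(t)))
      msgs <- c(msgs, "torsion entries need a, b, moving")
    else if (t$a %in% t$moving)
      msgs <- c(msgs, "axis atom a must not be in its own moving set")
  }
  if (length(object@rootAtoms) == 0 && object@natoms > 0)
    msgs <- c(msgs, "empty root fragment")
  if (length(msgs)) msgs else TRUE
})

#' Pose: one ligand conformation with its scores
#'
#' @slot coords numeric matrix n x 3 (Angstrom), rows match ligand atom order.
#' @slot empiricalScore numeric, Vina-form score (lower is better); NA until scored.
#' @slot cnnScore numeric in [0,1], CNN pose score ("CNNscore"); NA until rescored.
#' @slot cnnAffinity numeric, predicted pK ("CNNaffinity"); NA until rescored.
#' @slot rmsdToRef numeric, heavy-atom RMSD to a reference pose when known.
#' @slot provenance list (chain id, seed, covalent pairing label, ...).
#' @export
setClass("Pose",
  representation(coords = "matrix", empiricalScore = "numeric",
    cnnScore = "numeric", cnnAffinity = "numeric", rmsdToRef = "numeric",
    provenance = "list"),
  prototype(empiricalScore = NA_real_, cnnScore = NA_real_,
    cnnAffinity = NA_real_, rmsdToRef = NA_real_, provenance = list()))

setValidity("Pose", function(object) {
  msgs <- character(0)
  if (ncol(object@coords) != 3L) msgs <- c(msgs, "coords must be n x 3")
  if (any(!is.finite(object@coords))) msgs <- c(msgs, "coords must be finite")
  cs <- object@cnnScore
  if (!is.na(cs) && (cs < 0 || cs > 1))
    msgs <- c(msgs, "cnnScore must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' DensityGrid: channels x N^3 Gaussian atom-type densities
#'
#' @slot values numeric array, dim c(channels, N, N, N); all values >= 0.
#' @slot center numeric length-3 grid center (Angstrom).
#' @slot spec list, the GridSpec used (see \code{\link{gridSpec}}).
#' @export
setClass("DensityGrid",
  representation(values = "array", center = "numeric", spec = "list"))

setValidity("DensityGrid", function(object) {
  msgs <- character(0)
  if (length(dim(object@values)) != 4L)
    msgs <- c(msgs, "values must be a 4-d array (channel, x, y, z)")
  if (any(!is.finite(object@values))) msgs <- c(msgs, "non-finite densities")
  else if (any(object@values < 0)) msgs <- c(msgs, "densities must be >= 0")
  if (length(object@center) != 3L) msgs <- c(msgs, "center must be length 3")
  if (length(msgs)) msgs else TRUE
})
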