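#' Coordinates of a molecule or pose
#'
#' @param x a TypedMolecule or Pose
#' @return numeric matrix, n x 3, Angstrom
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @param value replacement coordinate matrix
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Number of atoms
#' @param x a TypedMolecule, TorsionTree or Pose
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))

#' Bond table accessor
#' @param x a TypedMolecule
#' @return integer matrix with columns i, j, order
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' Per-atom interaction types
#' @param x a TypedMolecule
#' @export
setGeneric("atomTypes", function(x) standardGeneric("atomTypes"))

#' Number of rotatable bonds
#' @param x a TorsionTree
#' @export
setGeneric("nrot", function(x) standardGeneric("nrot"))

#' @describeIn coords coordinates of the atoms of a TypedMolecule
#' @export
setMethod("coords", "TypedMolecule", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @export
setReplaceMethod("coords", "TypedMolecule", function(x, value) {
  stopifnot(is.matrix(value), ncol(value) == 3L, nrow(value) == nrow(x@atoms))
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  validObject(x)
  x
})

#' @describeIn coords coordinates of a Pose
#' @export
setMethod("coords", "Pose", function(x) x@coords)

#' @export
setReplaceMethod("coords", "Pose", function(x, value) {
  x@coords <- value
  validObject(x)
  x
})

#' @export
setMethod("natoms", "TypedMolecule", function(x) nrow(x@atoms))
#' @export
setMethod("natoms", "Pose", function(x) nrow(x@coords))
#' @export
setMethod("natoms", "TorsionTree", function(x) x@natoms)

#' @export
setMethod("bonds", "TypedMolecule", function(x) x@bonds)

#' @export
setMethod("atomTypes", "TypedMolecule", function(x) x@atoms$type)

#' @export
setMethod("nrot", "TorsionTree", function(x) length(x@torsions))

setMethod("show", "TypedMolecule", function(object) {
  a <- object@atoms
  nl <- sum(a$isLigand)
  cat("TypedMolecule:", nrow(a), "atoms (", nl, "ligand ),",
      nrow(object@bonds), "bonds\n")
  if (nrow(a)) {
    tt <- table(a$type, useNA = "ifany")
    cat("  types:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
  }
})

setMethod("show", "TorsionTree", function(object) {
  cat("TorsionTree:", length(object@rootAtoms), "root atoms,",
      length(object@torsions), "rotatable bonds\n")
})

setMethod("show", "Pose", function(object) {
  cat(sprintf("Pose: %d atoms | empirical %.4f | CNNscore %.4f | CNNaffinity %.3f\n",
      nrow(object@coords), object@empiricalScore, object@cnnScore,
      object@cnnAffinity))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid: %d channels, %dx%dx%d voxels @ %.2f A, center (%.2f, %.2f, %.2f)\n",
      d[1], d[2], d[3], d[4], object@spec$resolution,
      object@center[1], object@center[2], object@center[3]))
})
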