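#' Construct a TypedMolecule from raw pieces
#'
#' Low-level constructor used by the readers and fixture generators.
#'
#' @param element character vector of element symbols
#' @param xyz n x 3 coordinate matrix (Angstrom)
#' @param bonds integer matrix (i, j, order), 1-based; may have zero rows
#' @param isLigand logical flag (scalar or per atom)
#' @param chain,resno,resname,atomName optional receptor residue metadata
#'   (resno is character so insertion codes can ride along, e.g. "52A")
#' @param type optional pre-assigned interaction types
#' @return a \linkS4class{TypedMolecule} (untyped unless \code{type} given;
#'   call \code{\link{assignAtomTypes}})
#' @export
newTypedMolecule <- function(element, xyz, bonds = NULL, isLigand = FALSE,
                             chain = NA_character_, resno = NA_character_,
                             resname = NA_character_, atomName = NA_character_,
                             type = NA_character_) {
  n <- length(element)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  stopifnot(nrow(xyz) == n)
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- matrix(integer(0), ncol = 3L)
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3L)
  }
  colnames(bonds) <- c("i", "j", "order")
  el <- .normElement(element)
  atoms <- data.frame(
    element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    type = rep_len(type, n), vdw = .vdwRadius(el), covr = .covRadius(el),
    isLigand = rep_len(isLigand, n),
    chain = rep_len(as.character(chain), n),
    resno = rep_len(as.character(resno), n),
    resname = rep_len(as.character(resname), n),
    atomName = rep_len(as.character(atomName), n),
    stringsAsFactors = FALSE)
  new("TypedMolecule", atoms = atoms, bonds = bonds)
}

## Distance-based bond perception for receptors (PDB has no CONECT for most
## atoms). Two heavy atoms are bonded when closer than the sum of their
## covalent radii plus 0.45 A; X-H when closer than sum + 0.4.
.inferBonds <- function(el, xyz) {
  n <- length(el)
  if (n < 2) return(matrix(integer(0), ncol = 3L))
  covr <- .covRadius(el)
  out <- vector("list", n)
  ## cell-list style pruning via cut on x keeps this near-linear at our sizes
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    dx <- xyz[j, 1] - xyz[i, 1]
    close <- which(abs(dx) < 2.6)
    if (!length(close)) next
    j <- j[close]
    d <- sqrt((xyz[j, 1] - xyz[i, 1])^2 + (xyz[j, 2] - xyz[i, 2])^2 +
              (xyz[j, 3] - xyz[i, 3])^2)
    tol <- ifelse(el[i] == "H" | el[j] == "H", 0.40, 0.45)
    hit <- j[d < covr[i] + covr[j] + tol & !(el[i] == "H" & el[j] == "H")]
    if (length(hit)) out[[i]] <- cbind(i, hit, 1L)
  }
  b <- do.call(rbind, out)
  if (is.null(b)) b <- matrix(integer(0), ncol = 3L)
  colnames(b) <- c("i", "j", "order")
  b
}

#' Read a receptor structure from PDB
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}. Waters are excluded by
#' default; alternate locations are resolved to the highest-occupancy copy
#' (ties keep the first seen). Insertion codes are appended to the residue
#' number for addressing ("52A"). Bonds are perceived by covalent-radius
#' distance and atom types assigned on return.
#'
#' @param path PDB file
#' @param keepWaters keep HOH/WAT residues (default FALSE)
#' @return a typed \linkS4class{TypedMolecule} with residue metadata
#' @export
readReceptor <- function(path, keepWaters = FALSE) {
  if (!file.exists(path)) stop("receptor file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("PDB parse failure in '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure: no ATOM/HETATM records in ", path)
  if (!keepWaters) a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure after water removal in ", path)

  ## altLoc: within each (chain, resno, insert, atom name) group keep the
  ## highest occupancy record, ties -> first seen
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  occ <- ifelse(is.na(a$o), 1, a$o)
  keep <- !logical(nrow(a))
  for (g in split(seq_len(nrow(a)), key)) {
    if (length(g) > 1L) {
      best <- g[which.max(occ[g])]
      keep[setdiff(g, best)] <- FALSE
    }
  }
  a <- a[keep, , drop = FALSE]

  el <- a$elesy
  miss <- is.na(el) | el == ""
  if (any(miss)) el[miss] <- substr(gsub("[^A-Za-z].*", "", a$elety[miss]), 1, 1)
  el <- .normElement(el)
  xyz <- cbind(a$x, a$y, a$z)
  resno <- paste0(a$resno, ifelse(is.na(a$insert), "", a$insert))
  mol <- newTypedMolecule(el, xyz, bonds = .inferBonds(el, xyz),
                          isLigand = FALSE, chain = a$chain, resno = resno,
                          resname = a$resid, atomName = a$elety)
  assignAtomTypes(mol)
}

#' Read ligands from an SDF file
#'
#' One \linkS4class{TypedMolecule} per valid record, bond orders preserved,
#' hydrogens retained as parsed. Unparseable records are skipped with a
#' warning; a file whose coordinates are all-zero in z triggers a 2D
#' warning but is still returned.
#'
#' @param path SDF file (V2000)
#' @return list of typed \linkS4class{TypedMolecule}s, named by record title
#' @export
readLigands <- function(path) {
  if (!file.exists(path)) stop("ligand file not found: ", path)
  nRec <- sum(grepl("^\\$\\$\\$\\$", readLines(path, warn = FALSE)))
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  ok <- ChemmineR::validSDF(sdf)
  sdf <- sdf[ok]
  nBad <- max(nRec, length(ok)) - length(sdf)
  if (nBad > 0)
    warning(nBad, " unparseable SDF record(s) skipped", call. = FALSE)
  out <- vector("list", length(sdf))
  nm <- character(length(sdf))
  for (k in seq_along(sdf)) {
    rec <- sdf[[k]]
    ab <- ChemmineR::atomblock(rec)
    bb <- ChemmineR::bondblock(rec)
    el <- sub("_.*$", "", rownames(ab))
    xyz <- unname(ab[, 1:3, drop = FALSE])
    bonds <- if (NROW(bb)) cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                                 as.integer(bb[, 3])) else NULL
    if (all(abs(xyz[, 3]) < 1e-9) && nrow(xyz) > 1)
      warning("record ", k, " looks 2D (all z = 0)", call. = FALSE)
    m <- newTypedMolecule(el, xyz, bonds = bonds, isLigand = TRUE)
    out[[k]] <- assignAtomTypes(m)
    nm[k] <- ChemmineR::sdfid(rec)
  }
  names(out) <- nm
  out
}

## fixed-format V2000 block for one conformation; deterministic to the byte
.sdfBlock <- function(mol, xyz, title, tags = list()) {
  n <- nrow(xyz)
  b <- mol@bonds
  lines <- c(title, "  MiniDock          3D", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  el <- mol@atoms$element
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              xyz[i, 1], xyz[i, 2], xyz[i, 3], el[i]))
  if (nrow(b))
    for (k in seq_len(nrow(b)))
      lines <- c(lines, sprintf("%3d%3d%3d  0", b[k, 1], b[k, 2], b[k, 3]))
  lines <- c(lines, "M  END")
  for (tag in names(tags))
    lines <- c(lines, sprintf(">  <%s>", tag), as.character(tags[[tag]]), "")
  c(lines, "$$$$")
}

#' Write poses to a multi-record SDF
#'
#' Each pose becomes one record carrying the data tags
#' \code{minimizedAffinity} (empirical score), \code{CNNscore} and
#' \code{CNNaffinity}, plus \code{covalent_pairing} when the pose has a
#' pairing label. Output is byte-deterministic for identical input.
#'
#' @param ligand the \linkS4class{TypedMolecule} giving elements and bonds
#' @param poses list of \linkS4class{Pose}
#' @param path output file
#' @param title record title stem (default "pose")
#' @export
writePoses <- function(ligand, poses, path, title = "pose") {
  con <- file(path, open = "wb")  # fixed \n endings regardless of platform
  on.exit(close(con))
  for (k in seq_along(poses)) {
    p <- poses[[k]]
    tags <- list(minimizedAffinity = sprintf("%.5f", p@empiricalScore))
    if (!is.na(p@cnnScore)) tags$CNNscore <- sprintf("%.6f", p@cnnScore)
    if (!is.na(p@cnnAffinity)) tags$CNNaffinity <- sprintf("%.4f", p@cnnAffinity)
    if (!is.null(p@provenance$covalent_pairing))
      tags$covalent_pairing <- as.character(p@provenance$covalent_pairing)
    writeLines(.sdfBlock(ligand, p@coords, sprintf("%s_%d", title, k), tags),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write a single molecule to SDF (fixture/interchange helper)
#' @param mol a TypedMolecule
#' @param path output file
#' @param title record title
#' @export
writeMolecule <- function(mol, path, title = "mol") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(.sdfBlock(mol, coords(mol), title), con, sep = "\n")
  invisible(path)
}

## minimal fixture PDB writer (tests and toy complexes only)
.writeFixturePDB <- function(mol, path) {
  a <- mol@atoms
  lines <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    lines[i] <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      "ATOM", i, substr(a$atomName[i], 1, 4), "", a$resname[i], a$chain[i],
      as.integer(gsub("[A-Za-z]", "", a$resno[i])),
      gsub("[0-9]", "", a$resno[i]),
      a$x[i], a$y[i], a$z[i], 1.00, 0.00, toupper(a$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
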