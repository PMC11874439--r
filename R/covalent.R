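#' Covalent docking specification
#'
#' @param ligandSmarts SMARTS selecting the ligand's covalent atom(s); every
#'   match is paired with the receptor atom and docked
#' @param receptorAtom receptor atom address "chain:resno:atomname" (e.g.
#'   "A:145:SG") or list(chain =, resno =, atomName =)
#' @param bondOrder order of the new bond (1, 2 or 3; default 1)
#' @param explicitPosition optional Angstrom triple overriding the
#'   bond-vector heuristic for the covalent ligand atom
#' @param optimizeConstruct relax the junction bond length after placement
#' @param fixLigAtom freeze the covalent ligand atom during sampling (drops
#'   the receptor-side torsions that would move it)
#' @return list of class "CovalentSpec"
#' @export
covalentSpec <- function(ligandSmarts, receptorAtom, bondOrder = 1L,
                         explicitPosition = NULL, optimizeConstruct = FALSE,
                         fixLigAtom = FALSE) {
  .parseSmarts(ligandSmarts)  # fail fast on bad patterns
  if (is.character(receptorAtom)) {
    parts <- strsplit(receptorAtom, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop("receptorAtom address must be 'chain:resno:atomname'")
    receptorAtom <- list(chain = parts[1], resno = parts[2],
                         atomName = parts[3])
  }
  stopifnot(bondOrder %in% 1:3)
  if (!is.null(explicitPosition)) stopifnot(length(explicitPosition) == 3)
  structure(list(ligandSmarts = ligandSmarts, receptorAtom = receptorAtom,
                 bondOrder = as.integer(bondOrder),
                 explicitPosition = explicitPosition,
                 optimizeConstruct = isTRUE(optimizeConstruct),
                 fixLigAtom = isTRUE(fixLigAtom)),
            class = "CovalentSpec")
}

#' Locate a receptor atom by chain / residue number / atom name
#'
#' @param receptor typed receptor with residue metadata
#' @param address list(chain =, resno =, atomName =) or "A:145:SG" string
#' @return the atom index; errors list near-misses (same residue) when the
#'   address is absent, and error on a duplicated (corrupt) address
#' @export
locateReceptorAtom <- function(receptor, address) {
  if (is.character(address) && length(address) == 1) {
    parts <- strsplit(address, ":", fixed = TRUE)[[1]]
    address <- list(chain = parts[1], resno = parts[2], atomName = parts[3])
  }
  a <- receptor@atoms
  hit <- which(a$chain == address$chain &
               a$resno == as.character(address$resno) &
               a$atomName == address$atomName)
  if (length(hit) == 1) return(hit)
  if (length(hit) > 1)
    stop("ambiguous receptor atom address ", address$chain, ":",
         address$resno, ":", address$atomName, " (", length(hit),
         " atoms; corrupt input?)")
  near <- which(a$chain == address$chain & a$resno == as.character(address$resno))
  hint <- if (length(near))
    paste0("; residue has atoms: ", paste(a$atomName[near], collapse = " "))
  else ""
  stop("receptor atom ", address$chain, ":", address$resno, ":",
       address$atomName, " not found", hint)
}

#' Bond-vector heuristic for attaching a new substituent
#'
#' Direction is the normalized negative sum of unit vectors from the atom
#' to its bonded neighbors, after discounting one hydrogen if present (the
#' hydrogen that the new bond replaces); an isolated atom falls back to
#' +x. The suggested position places the partner at the sum of the two
#' covalent radii along that direction.
#'
#' @param mol a \linkS4class{TypedMolecule}
#' @param atomIndex the atom receiving the new bond
#' @param partnerCovalentRadius covalent radius of the incoming atom
#'   (Angstrom; default: carbon)
#' @return list(direction = unit vector, position = Angstrom triple,
#'   droppedHydrogen = index or NA)
#' @export
newBondVector <- function(mol, atomIndex, partnerCovalentRadius = 0.76) {
  a <- mol@atoms
  xyz <- coords(mol)
  b <- mol@bonds
  nbr <- c(b[b[, 1] == atomIndex, 2], b[b[, 2] == atomIndex, 1])
  dropped <- NA_integer_
  hn <- nbr[a$element[nbr] == "H"]
  if (length(hn)) { dropped <- hn[1]; nbr <- setdiff(nbr, dropped) }
  if (length(nbr) == 0) {
    dir <- c(1, 0, 0)
  } else {
    units <- sweep(xyz[nbr, , drop = FALSE], 2, xyz[atomIndex, ])
    units <- units / sqrt(rowSums(units^2))
    s <- -colSums(units)
    ns <- sqrt(sum(s^2))
    dir <- if (ns < 1e-9) c(1, 0, 0) else s / ns
  }
  len <- a$covr[atomIndex] + partnerCovalentRadius
  list(direction = dir, position = xyz[atomIndex, ] + dir * len,
       droppedHydrogen = dropped)
}

#' Rigidly place a ligand for covalent attachment
#'
#' Translates and rotates the ligand (internal geometry untouched) so the
#' covalent ligand atom lands on \code{targetPosition} and the mean
#' direction from that atom to its neighbors anti-aligns with
#' \code{targetDirection} - i.e. the new bond comes in along the target
#' direction with reasonable geometry.
#'
#' @param ligand a \linkS4class{TypedMolecule}
#' @param ligAtom index of the covalent ligand atom
#' @param targetPosition Angstrom triple
#' @param targetDirection unit vector along the new bond
#'   (receptor -> ligand)
#' @return a \linkS4class{Pose}
#' @export
placeLigand <- function(ligand, ligAtom, targetPosition, targetDirection) {
  X <- coords(ligand)
  u <- targetDirection / sqrt(sum(targetDirection^2))
  b <- ligand@bonds
  nbr <- c(b[b[, 1] == ligAtom, 2], b[b[, 2] == ligAtom, 1])
  if (length(nbr)) {
    m <- sweep(X[nbr, , drop = FALSE], 2, X[ligAtom, ])
    m <- colSums(m / sqrt(rowSums(m^2)))
    nm <- sqrt(sum(m^2))
    if (nm > 1e-9) {
      m <- m / nm
      ## rotate m onto -u about the ligand atom
      v <- pracmaCross(m, -u)
      s <- sqrt(sum(v^2)); cth <- sum(m * -u)
      if (s > 1e-12) {
        ax <- v / s
        X <- .rotateAbout(X, X[ligAtom, ], ax, atan2(s, cth))
      } else if (cth < 0) {
        ## anti-parallel: rotate pi about any perpendicular axis
        perp <- if (abs(m[1]) < 0.9) pracmaCross(m, c(1, 0, 0))
                else pracmaCross(m, c(0, 1, 0))
        X <- .rotateAbout(X, X[ligAtom, ], perp / sqrt(sum(perp^2)), pi)
      }
    }
  }
  X <- sweep(X, 2, as.numeric(targetPosition) - X[ligAtom, ], `+`)
  .mkPose(X, provenance = list(placement = "covalent"))
}

pracmaCross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Build the flexible residue-ligand construct
#'
#' Bonds the placed ligand to the receptor anchor atom and assembles one
#' molecule from the anchor residue plus the ligand, with a torsion tree
#' rooted at the residue backbone: only side-chain and ligand torsions
#' move, the backbone stays immobile. Ligand-origin atoms keep
#' \code{isLigand = TRUE} so CNN typing still routes them to ligand
#' channels.
#'
#' @param receptor typed receptor
#' @param ligandPose placed ligand \linkS4class{Pose} (see
#'   \code{\link{placeLigand}})
#' @param ligand the ligand \linkS4class{TypedMolecule}
#' @param ligAtom covalent ligand atom index (into the ligand)
#' @param recAtom covalent receptor atom index (into the receptor)
#' @param bondOrder new-bond order
#' @return list: \code{construct} (TypedMolecule), \code{tree}
#'   (TorsionTree), \code{ligAtomLocal}, \code{recAtomLocal} (indices into
#'   the construct), \code{restReceptor} (receptor minus the anchor
#'   residue), \code{residueIdx} (anchor-residue atom indices in the
#'   receptor)
#' @export
makeCovalentConstruct <- function(receptor, ligandPose, ligand, ligAtom,
                                  recAtom, bondOrder = 1L) {
  a <- receptor@atoms
  resSel <- which(a$chain == a$chain[recAtom] & a$resno == a$resno[recAtom] &
                  a$resname == a$resname[recAtom])
  XL <- if (is(ligandPose, "Pose")) ligandPose@coords else ligandPose
  dist <- sqrt(sum((XL[ligAtom, ] - coords(receptor)[recAtom, ])^2))
  target <- a$covr[recAtom] + ligand@atoms$covr[ligAtom]
  if (dist > 1.5 * target)
    stop(sprintf(paste("covalent atoms are %.2f Angstrom apart (target %.2f):",
                       "place the ligand first (placeLigand/newBondVector)"),
         dist, target))

  nRes <- length(resSel)
  recLocal <- match(recAtom, resSel)
  resAtoms <- a[resSel, ]
  ligAtoms <- ligand@atoms
  ligAtoms$x <- XL[, 1]; ligAtoms$y <- XL[, 2]; ligAtoms$z <- XL[, 3]
  atoms <- rbind(resAtoms, ligAtoms)
  rb <- receptor@bonds
  keep <- rb[, 1] %in% resSel & rb[, 2] %in% resSel
  resBonds <- rb[keep, , drop = FALSE]
  resBonds[, 1] <- match(resBonds[, 1], resSel)
  resBonds[, 2] <- match(resBonds[, 2], resSel)
  lb <- ligand@bonds
  if (nrow(lb)) { lb[, 1] <- lb[, 1] + nRes; lb[, 2] <- lb[, 2] + nRes }
  newBond <- c(recLocal, ligAtom + nRes, as.integer(bondOrder))
  bonds <- rbind(resBonds, lb, newBond)
  construct <- new("TypedMolecule", atoms = atoms,
                   bonds = matrix(as.integer(bonds), ncol = 3,
                                  dimnames = list(NULL, c("i", "j", "order"))))
  ## root at the backbone: CA if present, else N, else the anchor atom
  rootName <- intersect(c("CA", "N", "C"), resAtoms$atomName)
  rootAtom <- if (length(rootName)) which(atoms$atomName == rootName[1] &
                                          !atoms$isLigand)[1]
              else recLocal
  tree <- buildTorsionTree(construct, rootAtom = rootAtom)
  rest <- new("TypedMolecule",
              atoms = a[-resSel, , drop = FALSE],
              bonds = .reindexBonds(rb, setdiff(seq_len(nrow(a)), resSel)))
  list(construct = construct, tree = tree, ligAtomLocal = ligAtom + nRes,
       recAtomLocal = recLocal, restReceptor = rest, residueIdx = resSel)
}

.reindexBonds <- function(b, keepIdx) {
  keep <- b[, 1] %in% keepIdx & b[, 2] %in% keepIdx
  b <- b[keep, , drop = FALSE]
  b[, 1] <- match(b[, 1], keepIdx)
  b[, 2] <- match(b[, 2], keepIdx)
  matrix(as.integer(b), ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
}

## spin the placed ligand about the new-bond axis to the least-clashing of
## 12 evenly spaced angles (max-min heavy-atom distance to the receptor)
.spinScan <- function(pose, ligand, ligAtom, axisDir, receptor) {
  X0 <- pose@coords
  heavyL <- ligand@atoms$element != "H"
  heavyR <- receptor@atoms$element != "H"
  RX <- coords(receptor)[heavyR, , drop = FALSE]
  u <- axisDir / sqrt(sum(axisDir^2))
  best <- X0; bestScore <- -Inf
  for (k in 0:11) {
    ang <- k * pi / 6
    X <- if (k == 0) X0 else .rotateAbout(X0, X0[ligAtom, ], u, ang)
    dmin <- min(vapply(which(heavyL), function(i)
      min(sqrt(rowSums(sweep(RX, 2, X[i, ])^2))), numeric(1)))
    if (dmin > bestScore + 1e-9) { bestScore <- dmin; best <- X }
  }
  .mkPose(best, provenance = pose@provenance)
}

#' Covalent docking
#'
#' For every ligand atom matching the SMARTS pattern: position the ligand
#' with the bond-vector heuristic (or the user's explicit position), build
#' the flexible residue-ligand construct, and sample its torsions (no
#' rigid-body moves) with the Monte Carlo machinery. Output poses are
#' labeled by pairing; the pose list is the concatenation over pairings,
#' each contributing up to \code{numModes} poses.
#'
#' @param receptor typed receptor
#' @param ligand typed ligand (bound covalent form, 3D)
#' @param spec a \code{\link{covalentSpec}}
#' @param config a \code{\link{samplerConfig}} (covalentMode is forced on)
#' @param weights empirical score \code{\link{termWeights}}
#' @return list of class "CovalentDockResult": \code{poses} (flattened,
#'   each with \code{provenance$covalent_pairing}) and \code{pairings}
#'   (per-pairing list with construct, tree, local indices and poses)
#' @export
covalentDock <- function(receptor, ligand, spec,
                         config = samplerConfig(exhaustiveness = 2L,
                                                steps = 40L),
                         weights = termWeights()) {
  stopifnot(inherits(spec, "CovalentSpec"))
  config$covalentMode <- TRUE
  recIdx <- locateReceptorAtom(receptor, spec$receptorAtom)
  ligHits <- findLigandCovalentAtoms(ligand, spec$ligandSmarts)
  addrStr <- paste(spec$receptorAtom$chain, spec$receptorAtom$resno,
                   spec$receptorAtom$atomName, sep = ":")
  pairings <- list()
  for (la in ligHits) {
    nbv <- newBondVector(receptor, recIdx,
                         partnerCovalentRadius = ligand@atoms$covr[la])
    targetPos <- if (!is.null(spec$explicitPosition)) spec$explicitPosition
                 else nbv$position
    pose0 <- placeLigand(ligand, la, targetPos, nbv$direction)
    pose0 <- .spinScan(pose0, ligand, la, nbv$direction, receptor)
    cc <- makeCovalentConstruct(receptor, pose0, ligand, la, recIdx,
                                spec$bondOrder)
    tree <- cc$tree
    ## sample only torsions that move ligand atoms and leave the receptor
    ## anchor atom in place: the attachment point is part of the rigid
    ## environment, the ligand explores through the torsions distal to it
    isLig <- cc$construct@atoms$isLigand
    keep <- Filter(function(t) any(isLig[t$moving]) &&
                     !(cc$recAtomLocal %in% t$moving), tree@torsions)
    if (spec$fixLigAtom)
      keep <- Filter(function(t) !(cc$ligAtomLocal %in% setdiff(t$moving, t$b)),
                     keep)
    tree <- new("TorsionTree", rootAtoms = tree@rootAtoms,
                torsions = keep, natoms = tree@natoms)
    if (spec$optimizeConstruct)
      cc$construct <- .relaxJunction(cc$construct, cc$recAtomLocal,
                                     cc$ligAtomLocal)
    box <- list(center = colMeans(coords(cc$construct)),
                size = rep(2 * max(sqrt(rowSums(sweep(coords(cc$construct), 2,
                  colMeans(coords(cc$construct)))^2))) + 8, 3))
    poses <- runDocking(cc$restReceptor, cc$construct, box, weights, config,
                        tree = tree)
    label <- sprintf("lig%d>%s", la, addrStr)
    poses <- lapply(poses, function(p) {
      p@provenance$covalent_pairing <- label
      p
    })
    pairings[[label]] <- list(label = label, construct = cc$construct,
                              tree = tree, ligAtomLocal = cc$ligAtomLocal,
                              recAtomLocal = cc$recAtomLocal,
                              restReceptor = cc$restReceptor,
                              ligAtom = la, poses = poses)
  }
  structure(list(poses = unlist(lapply(pairings, `[[`, "poses"),
                               recursive = FALSE),
                 pairings = pairings),
            class = "CovalentDockResult")
}

## bonded-geometry relaxation at the junction: set the new bond to the
## covalent-radius sum by translating the ligand-origin atoms along the
## bond axis (internal geometries of both sides untouched)
.relaxJunction <- function(construct, recLocal, ligLocal) {
  X <- coords(construct)
  u <- X[ligLocal, ] - X[recLocal, ]
  d <- sqrt(sum(u^2))
  if (d < 1e-9) return(construct)
  target <- construct@atoms$covr[recLocal] + construct@atoms$covr[ligLocal]
  shift <- (target - d) * u / d
  sel <- construct@atoms$isLigand
  X[sel, ] <- sweep(X[sel, , drop = FALSE], 2, shift, `+`)
  coords(construct) <- X
  construct
}
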