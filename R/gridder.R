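#' Grid specification for CNN input
#'
#' Defines voxel geometry and the channel map from (interaction type,
#' molecule role) to channel index. The default follows common practice for
#' grid-based pose scoring: 0.5 Angstrom voxels, 48 points per side (a 23.5
#' Angstrom cube), densities truncated at 1.5 atom radii, and one channel
#' per interaction type and role (13 x 2 = 26). The \code{"coarse"} map
#' pools types into four element classes per role (8 channels), useful for
#' desk-scale training where full channel resolution is not needed.
#'
#' @param resolution Angstrom per voxel
#' @param points voxels per side (even values keep pooling exact)
#' @param radiusMultiple density cutoff as a multiple of the atom radius
#' @param channels \code{"full"} (26) or \code{"coarse"} (8)
#' @return list of class "GridSpec" with a \code{channelMap} (named integer
#'   vector over "type|role" keys) and \code{nchannels}
#' @export
gridSpec <- function(resolution = 0.5, points = 48L, radiusMultiple = 1.5,
                     channels = c("full", "coarse")) {
  channels <- match.arg(channels)
  stopifnot(resolution > 0, points >= 4, radiusMultiple > 0)
  types <- setdiff(.INTERACTION_TYPES, "H")  # hydrogens are not gridded
  if (channels == "full") {
    idx <- seq_along(types)
    perRole <- stats::setNames(idx, types)
  } else {
    cls <- c(HydrophobicC = 1, NonHydrophobicC = 1,
             DonorN = 2, AcceptorN = 2, DonorAcceptorN = 2,
             DonorO = 3, AcceptorO = 3, DonorAcceptorO = 3,
             S = 4, P = 4, Halogen = 4, Metal = 4)
    perRole <- stats::setNames(as.integer(cls[types]), types)
  }
  nPer <- max(perRole)
  cm <- c(stats::setNames(perRole, paste0(types, "|rec")),
          stats::setNames(perRole + nPer, paste0(types, "|lig")))
  structure(list(resolution = resolution, points = as.integer(points),
                 radiusMultiple = radiusMultiple, channels = channels,
                 channelMap = cm, nchannels = 2L * nPer),
            class = "GridSpec")
}

#' Gaussian atom density profile
#'
#' \code{exp(-2 d^2 / r^2)} out to the atom radius, a matching quadratic
#' tail out to \code{1.5 r} (continuous value and slope at \code{d = r}),
#' zero beyond.
#'
#' @param d distance from the atom center (Angstrom), \code{d >= 0}
#' @param r atom radius (Angstrom)
#' @return density value(s) in [0, 1]
#' @export
atomDensity <- function(d, r) {
  stopifnot(all(d >= 0), r > 0)
  vapply(d, cpp_atom_density, numeric(1), r = r)
}

#' Voxelize a receptor-ligand pose into a DensityGrid
#'
#' Each heavy atom adds its Gaussian density to the channel given by its
#' interaction type and molecule role (\code{isLigand} flag - atoms of a
#' covalent construct that entered as ligand atoms land in ligand
#' channels). Additive over atoms; deterministic.
#'
#' @param receptor typed receptor \linkS4class{TypedMolecule} (may have 0 rows)
#' @param ligand typed ligand \linkS4class{TypedMolecule}
#' @param pose optional \linkS4class{Pose}/matrix overriding ligand coordinates
#' @param spec a \code{\link{gridSpec}}
#' @param center grid center (Angstrom); defaults to the ligand centroid
#' @return a \linkS4class{DensityGrid}
#' @export
voxelize <- function(receptor, ligand, pose = NULL, spec = gridSpec(),
                     center = NULL) {
  X <- if (is.null(pose)) coords(ligand)
       else if (is(pose, "Pose")) pose@coords else pose
  if (is.null(center)) center <- colMeans(X)
  aR <- receptor@atoms; aL <- ligand@atoms
  role <- c(ifelse(aR$isLigand, "lig", "rec"), rep("lig", nrow(aL)))
  type <- c(aR$type, aL$type)
  key <- paste0(type, "|", role)
  chan <- spec$channelMap[key]           # NA for hydrogens
  chan[is.na(chan)] <- 0L
  xyz <- rbind(coords(receptor), X)
  vdw <- c(aR$vdw, aL$vdw)
  vals <- cpp_voxelize(xyz, vdw, as.integer(chan) - 1L, spec$nchannels,
                       spec$points, spec$resolution, as.numeric(center),
                       spec$radiusMultiple)
  if (sum(vals) == 0) warning("no atoms within the grid", call. = FALSE)
  new("DensityGrid", values = vals, center = as.numeric(center),
      spec = unclass(spec))
}

#' Export a grid to a portable array container (debug/inspection)
#'
#' Writes the raw values as a flat binary of doubles plus a JSON sidecar
#' with dimensions, center and grid spec.
#'
#' @param grid a \linkS4class{DensityGrid}
#' @param stem output path stem; writes \code{<stem>.bin} and \code{<stem>.json}
#' @export
exportGrid <- function(grid, stem) {
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(as.numeric(grid@values), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(grid@values), center = grid@center,
               resolution = grid@spec$resolution,
               radiusMultiple = grid@spec$radiusMultiple,
               channels = grid@spec$channels)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}
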