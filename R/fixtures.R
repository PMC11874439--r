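## ---- synthetic fixtures: ligand templates and toy pocket complexes ----
##
## Everything here is generated in code so the docking, covalent and CNN
## machinery can be exercised and tested with no external dataset. The toy
## receptor is a spherical hydrophobic cage with a cysteine-like anchor
## residue whose SG atom points into the cavity; the empirical score then
## has a funnel with its minimum at the cavity center.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Built-in small-molecule templates
#'
#' Idealized 3D geometries with bonds, built in code: \code{"methane"},
#' \code{"butane"}, \code{"benzene"}, \code{"biphenyl"},
#' \code{"methylthiol"}, \code{"dmds"} (dimethyl disulfide) and
#' \code{"thiolLig"} (a flexible S-C-C-C-O warhead-bearing chain for
#' covalent fixtures). Typed on return.
#'
#' @param name template id
#' @return a typed ligand \linkS4class{TypedMolecule}
#' @export
ligandTemplate <- function(name = c("benzene", "butane", "methane",
                                    "biphenyl", "methylthiol", "dmds",
                                    "thiolLig")) {
  name <- match.arg(name)
  d <- 1.09 / sqrt(3)
  mk <- function(el, xyz, bonds) {
    assignAtomTypes(newTypedMolecule(el, xyz, bonds, isLigand = TRUE))
  }
  switch(name,
    methane = mk(c("C", "H", "H", "H", "H"),
      rbind(c(0, 0, 0), c(d, d, d), c(-d, -d, d), c(-d, d, -d), c(d, -d, -d)),
      cbind(1L, 2:5, 1L)),
    butane = {
      ## anti conformation, C-C 1.53, angle 111 deg, centered at the origin
      xyz <- rbind(c(-1.928, 0.555, 0), c(-0.635, -0.264, 0),
                   c(0.635, 0.264, 0), c(1.928, -0.555, 0))
      xyz <- sweep(xyz, 2, colMeans(xyz))
      mk(rep("C", 4), xyz, cbind(1:3, 2:4, 1L))
    },
    benzene = {
      ang <- (0:5) * pi / 3
      xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
      mk(rep("C", 6), xyz,
         cbind(1:6, c(2:6, 1L), rep(c(1L, 2L), 3)))
    },
    biphenyl = {
      ang <- (0:5) * pi / 3
      ringA <- cbind(1.39 * cos(ang) - 2.135, 1.39 * sin(ang), 0)
      ## second ring twisted 45 degrees about the inter-ring x axis
      yb <- 1.39 * sin(ang) * cos(pi / 4)
      zb <- 1.39 * sin(ang) * sin(pi / 4)
      ringB <- cbind(1.39 * cos(ang) + 2.135, yb, zb)
      bonds <- rbind(cbind(1:6, c(2:6, 1L), rep(c(1L, 2L), 3)),
                     cbind(7:12, c(8:12, 7L), rep(c(1L, 2L), 3)),
                     c(1L, 7L, 1L))  # atoms 1 and 7 sit at x = +/-0.745
      mk(rep("C", 12), rbind(ringA, ringB), bonds)
    },
    methylthiol = mk(c("C", "S", "H"),
      rbind(c(-0.905, 0, 0), c(0.905, 0, 0), c(1.35, 1.25, 0)),
      rbind(c(1L, 2L, 1L), c(2L, 3L, 1L))),
    dmds = mk(c("C", "S", "S", "C"),
      rbind(c(-2.25, 0.55, 0), c(-1.02, -0.75, 0),
            c(1.02, 0.75, 0.25), c(2.25, -0.55, 0.25)),
      rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L))),
    thiolLig = {
      ## S-C-C-C-O zig-zag with a hydroxyl hydrogen; two backbone torsions
      xyz <- rbind(c(-2.55, 0.35, 0), c(-1.10, -0.55, 0), c(0.20, 0.30, 0),
                   c(1.50, -0.55, 0), c(2.65, 0.30, 0), c(3.45, -0.15, 0.65))
      mk(c("S", "C", "C", "C", "O", "H"), xyz,
         rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L), c(4L, 5L, 1L),
               c(5L, 6L, 1L)))
    })
}

## Fibonacci sphere: near-uniform deterministic points on the unit sphere
.fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## cysteine-like anchor residue (heavy atoms only, PDB style) with SG at
## pocket radius pointing into the cavity along -x
.anchorResidue <- function(radius) {
  xyz <- rbind(
    N  = c(-radius - 3.45, 1.30, 0.40),
    CA = c(-radius - 2.60, 0.15, 0.30),
    C  = c(-radius - 3.30, -1.15, 0.55),
    O  = c(-radius - 4.35, -1.35, 1.15),
    CB = c(-radius - 1.40, 0.25, -0.65),
    SG = c(-radius + 0.40, 0.15, -0.30))
  list(el = c("N", "C", "C", "O", "C", "S"),
       xyz = xyz,
       atomName = c("N", "CA", "C", "O", "CB", "SG"))
}

#' Generate a synthetic receptor pocket with a bound ligand
#'
#' Builds a rigid cage of hydrophobic carbons (each its own POC
#' pseudo-residue) on an oblate ellipsoid around the origin (semi-axes
#' \code{pocketRadius * c(1, 0.88, 0.73)}), with one cysteine-like residue
#' (chain A, residue 145, heavy atoms N/CA/C/O/CB/SG) embedded in the wall
#' so its SG points into the cavity and can serve as a covalent anchor. The
#' flattened cavity gives the empirical score a single central basin for
#' the planar/linear ligand templates, so the ground-truth pose is
#' well-defined. The ligand is placed at the center in a seed-dependent
#' in-plane orientation and locally minimized; the minimized placement is
#' the reference pose. Deterministic for a fixed seed.
#'
#' @param seed integer seed
#' @param nPocketAtoms total receptor heavy atoms (anchor residue included);
#'   clamped to [20, 500] with a warning
#' @param ligandSpec template id, see \code{\link{ligandTemplate}}
#' @param pocketRadius long semi-axis in Angstrom; clamped to [4, 12]
#' @return list with \code{receptor}, \code{ligand} (at the reference
#'   placement), \code{referencePose}, \code{box} (docking box spec) and
#'   \code{pocketRadius}
#' @export
generateToyComplex <- function(seed = 0, nPocketAtoms = 60,
                               ligandSpec = "benzene", pocketRadius = 5.2) {
  if (nPocketAtoms < 20 || nPocketAtoms > 500) {
    warning("nPocketAtoms clamped to [20, 500]")
    nPocketAtoms <- min(max(nPocketAtoms, 20), 500)
  }
  if (pocketRadius < 4 || pocketRadius > 12) {
    warning("pocketRadius clamped to [4, 12]")
    pocketRadius <- min(max(pocketRadius, 4), 12)
  }
  .withSeed(seed, {
    axes <- pocketRadius * c(1, 0.88, 0.73)
    anc <- .anchorResidue(pocketRadius)
    nShell <- nPocketAtoms - nrow(anc$xyz)
    pts <- .fibSphere(max(nShell + 12, 24))
    pts <- sweep(pts, 2, axes, `*`)
    ## drop shell points that crowd the anchor side chain entry
    dAnc <- apply(pts, 1, function(p)
      min(sqrt(colSums((t(anc$xyz) - p)^2))))
    pts <- pts[dAnc > 2.2, , drop = FALSE][seq_len(nShell), , drop = FALSE]
    el <- c(anc$el, rep("C", nShell))
    xyz <- rbind(anc$xyz, pts)
    receptor <- newTypedMolecule(el, xyz,
      bonds = .inferBonds(el, xyz), isLigand = FALSE,
      chain = "A",
      resno = c(rep("145", 6), as.character(200 + seq_len(nShell))),
      resname = c(rep("CYS", 6), rep("POC", nShell)),
      atomName = c(anc$atomName, rep("C1", nShell)))
    receptor <- assignAtomTypes(receptor)

    ligand <- ligandTemplate(ligandSpec)
    ## seed-dependent in-plane orientation; the templates lie in z ~ 0,
    ## matching the flattened cavity
    ang <- stats::runif(1, 0, 2 * pi)
    X <- .rotateAbout(coords(ligand), colMeans(coords(ligand)), c(0, 0, 1), ang)
    X <- sweep(X, 2, colMeans(X))
    refMin <- localMinimize(receptor, ligand, X)
    coords(ligand) <- refMin@coords
    ref <- .mkPose(refMin@coords,
                   empiricalScore = refMin@empiricalScore,
                   provenance = list(label = "reference", seed = seed))
    box <- list(center = c(0, 0, 0),
                size = rep(2 * pocketRadius - 2, 3))
    list(receptor = receptor, ligand = ligand, referencePose = ref,
         box = box, pocketRadius = pocketRadius)
  })
}

#' Write the toy receptor to a PDB file (fixture helper)
#' @param complex output of \code{\link{generateToyComplex}}
#' @param path file to write
#' @export
writeToyReceptorPDB <- function(complex, path) {
  .writeFixturePDB(complex$receptor, path)
}

#' Synthetic pose-labeled grid dataset
#'
#' Generates toy complexes, draws good poses (small jitter of the
#' reference, RMSD <= 2) and bad poses (displaced and rotated, RMSD > 2),
#' voxelizes each against its receptor and attaches pose labels and a
#' per-complex ground-truth pK drawn uniformly from [5, 8]. Good and bad
#' poses are geometrically separable by construction, which is the point:
#' the set probes CNN capacity, not real-data generalization.
#'
#' @param n number of examples (half good, half bad)
#' @param seed RNG seed
#' @param spec grid specification (default: coarse channels, 8 points of
#'   1.25 Angstrom - a desk-scale training resolution)
#' @param nComplexes distinct toy complexes to draw poses from
#' @param ligandSpec ligand template id
#' @return list of examples: \code{grid} (values array), \code{poseLabel},
#'   \code{affinity}, \code{rmsd}
#' @export
makeGridDataset <- function(n = 200, seed = 0,
                            spec = gridSpec(resolution = 1.25, points = 8L,
                                            channels = "coarse"),
                            nComplexes = 4, ligandSpec = "benzene") {
  .withSeed(seed, {
    cxs <- lapply(seq_len(nComplexes), function(i)
      generateToyComplex(seed * 131 + i, 60, ligandSpec))
    pKs <- stats::runif(nComplexes, 5, 8)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- ((i - 1) %% nComplexes) + 1
      cx <- cxs[[ci]]
      ref <- cx$referencePose@coords
      good <- i <= n / 2
      repeat {
        X <- ref
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        if (good) {
          X <- .rotateAbout(X, colMeans(X), ax, stats::runif(1, 0, 0.25))
          X <- sweep(X, 2, stats::rnorm(3, 0, 0.25), `+`)
        } else {
          X <- .rotateAbout(X, colMeans(X), ax, stats::runif(1, 0, pi))
          d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
          X <- sweep(X, 2, d * stats::runif(1, 2.6, 4.5), `+`)
        }
        r <- symmetryRmsd(X, ref, cx$ligand)
        if ((good && r <= 2) || (!good && r > 2)) break
      }
      g <- voxelize(cx$receptor, cx$ligand, X, spec, center = cx$box$center)
      out[[i]] <- list(grid = g@values, poseLabel = good,
                       affinity = pKs[ci], rmsd = r)
    }
    ## interleave so minibatches see both classes even without shuffling
    out[order(rep(seq_len(ceiling(n / 2)), 2, length.out = n))]
  })
}
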