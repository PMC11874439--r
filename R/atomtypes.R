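## Reduced 13-type interaction vocabulary used for scoring terms and CNN
## channels. Coarser than full smina typing but sufficient for the five
## empirical terms (hydrophobic and donor/acceptor distinctions) and for
## per-element density channels.

.INTERACTION_TYPES <- c(
  "HydrophobicC", "NonHydrophobicC",
  "DonorN", "AcceptorN", "DonorAcceptorN",
  "DonorO", "AcceptorO", "DonorAcceptorO",
  "S", "P", "Halogen", "Metal", "H")

## Fixed built-in vdW radii (Angstrom); self-contained, no runtime lookup.
.VDW_RADII <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
                F = 1.8, Cl = 1.8, Br = 2.0, I = 2.0, H = 1.0,
                Zn = 1.2, Fe = 1.2, Mg = 1.2, Mn = 1.2, Ca = 1.2,
                Na = 1.2, K = 1.2, Cu = 1.2, Ni = 1.2, Co = 1.2)

## Single-bond covalent radii (Cordero et al. consensus values), Angstrom.
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39,
                Zn = 1.22, Fe = 1.32, Mg = 1.41, Mn = 1.39, Ca = 1.76,
                Na = 1.66, K = 2.03, Cu = 1.32, Ni = 1.24, Co = 1.26)

.METALS <- c("Zn", "Fe", "Mg", "Mn", "Ca", "Na", "K", "Cu", "Ni", "Co")

.normElement <- function(el) {
  el <- gsub("[^A-Za-z]", "", el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

.vdwRadius <- function(el) {
  r <- .VDW_RADII[el]
  r[is.na(r)] <- 1.2  # unknown elements treated like a generic metal
  unname(r)
}

.covRadius <- function(el) {
  r <- .COV_RADII[el]
  r[is.na(r)] <- 1.3
  unname(r)
}

#' Assign interaction types to every atom
#'
#' Applies the reduced typing scheme: carbons bonded only to carbon or
#' hydrogen become \code{HydrophobicC}, all other carbons
#' \code{NonHydrophobicC}; oxygens with a bonded hydrogen are
#' \code{DonorAcceptorO}, otherwise \code{AcceptorO}; nitrogens with a
#' bonded hydrogen are donors (\code{DonorN}, or \code{DonorAcceptorN} when
#' a lone pair remains available, i.e. fewer than three connections),
#' hydrogen-free nitrogens are \code{AcceptorN}; S, P, halogens and metals
#' map to their element classes; hydrogens are typed \code{H} and carry no
#' interaction terms. Unknown elements are typed \code{Metal} with a
#' warning. Idempotent.
#'
#' @param mol a \linkS4class{TypedMolecule} with elements and bonds assigned
#' @return the molecule with the \code{type}, \code{vdw} and \code{covr}
#'   columns filled in
#' @export
assignAtomTypes <- function(mol) {
  stopifnot(is(mol, "TypedMolecule"))
  a <- mol@atoms
  n <- nrow(a)
  if (n == 0) return(mol)
  el <- .normElement(a$element)
  b <- mol@bonds
  nbrs <- vector("list", n)
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1]; j <- b[k, 2]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  hN  <- vapply(nbrs, function(v) sum(el[v] == "H"), integer(1))
  conn <- lengths(nbrs)

  type <- character(n)
  for (i in seq_len(n)) {
    e <- el[i]
    type[i] <- switch(e,
      H = "H",
      C = {
        heavy <- nbrs[[i]][el[nbrs[[i]]] != "H"]
        if (length(heavy) == 0 || all(el[heavy] == "C"))
          "HydrophobicC" else "NonHydrophobicC"
      },
      N = {
        donor <- hN[i] >= 1
        # lone pair taken as available when under three connections or no H
        acceptor <- if (donor) conn[i] < 3L else TRUE
        if (donor && acceptor) "DonorAcceptorN"
        else if (donor) "DonorN"
        else "AcceptorN"
      },
      O = if (hN[i] >= 1) "DonorAcceptorO" else "AcceptorO",
      S = "S",
      P = "P",
      F = , Cl = , Br = , I = "Halogen",
      {
        if (!(e %in% .METALS))
          warning("unknown element '", e, "' typed as Metal", call. = FALSE)
        "Metal"
      })
  }
  a$element <- el
  a$type <- type
  a$vdw <- .vdwRadius(el)
  a$covr <- .covRadius(el)
  mol@atoms <- a
  validObject(mol)
  mol
}

.isDonorType <- function(t)
  t %in% c("DonorN", "DonorO", "DonorAcceptorN", "DonorAcceptorO", "Metal")
.isAcceptorType <- function(t)
  t %in% c("AcceptorN", "AcceptorO", "DonorAcceptorN", "DonorAcceptorO")

## integer codes used by the C++ scoring kernel
.typeCode <- function(t) match(t, .INTERACTION_TYPES)
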