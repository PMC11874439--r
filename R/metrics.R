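#' Symmetry-corrected RMSD between two poses of the same molecule
#'
#' Minimum heavy-atom root-mean-square deviation over molecular-graph
#' automorphisms that preserve elements and connectivity (bond orders are
#' ignored so Kekule-alternating rings keep their symmetry). Poses are
#' compared in the same frame: no superposition is performed. The
#' automorphism search is capped at 10^4 mappings; beyond that the identity
#' mapping is used with a warning.
#'
#' @param poseA,poseB \linkS4class{Pose}s or coordinate matrices (same atom
#'   order as \code{mol})
#' @param mol the \linkS4class{TypedMolecule} giving the molecular graph
#' @param naive skip symmetry correction (identity mapping only)
#' @return RMSD in Angstrom
#' @export
symmetryRmsd <- function(poseA, poseB, mol, naive = FALSE) {
  A <- if (is(poseA, "Pose")) poseA@coords else poseA
  B <- if (is(poseB, "Pose")) poseB@coords else poseB
  stopifnot(nrow(A) == natoms(mol), nrow(B) == natoms(mol))
  heavy <- which(mol@atoms$element != "H")
  A <- A[heavy, , drop = FALSE]; B <- B[heavy, , drop = FALSE]
  rms <- function(map) sqrt(mean(rowSums((A - B[map, , drop = FALSE])^2)))
  if (naive) return(rms(seq_along(heavy)))

  g <- .molGraph(mol, heavyOnly = TRUE)
  el <- mol@atoms$element[heavy]
  colr <- as.integer(factor(el))
  nAuto <- tryCatch(
    igraph::count_isomorphisms(g, g, method = "vf2",
                               vertex.color1 = colr, vertex.color2 = colr),
    error = function(e) Inf)
  if (!is.finite(nAuto) || nAuto > 1e4) {
    warning("automorphism count exceeds cap; using identity mapping")
    return(rms(seq_along(heavy)))
  }
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = colr, vertex.color2 = colr)
  ## bond orders are deliberately ignored: alternating Kekule assignments
  ## of an aromatic ring must not break its rotational symmetry
  best <- Inf
  for (m in maps) best <- min(best, rms(as.integer(m)))
  if (!is.finite(best)) best <- rms(seq_along(heavy))
  best
}

#' TopN pose-recovery percentage
#'
#' Percentage of targets whose best RMSD within the first \code{n} ranked
#' poses is at or below the threshold.
#'
#' @param rankedRmsds list with one numeric vector per target: RMSDs of its
#'   ranked poses, best-ranked first
#' @param n number of top poses to consider (vectors shorter than n are
#'   used whole)
#' @param threshold success cutoff in Angstrom (default 2)
#' @return percentage in [0, 100]
#' @export
topN <- function(rankedRmsds, n, threshold = 2.0) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(length(rankedRmsds) > 0, all(lengths(rankedRmsds) > 0))
  hit <- vapply(rankedRmsds, function(r)
    min(r[seq_len(min(n, length(r)))]) <= threshold, logical(1))
  100 * mean(hit)
}

#' Rank-based ROC AUC
#'
#' Probability that a random active outscores a random inactive, ties
#' counted half (Mann-Whitney statistic).
#'
#' @param records data.frame with columns \code{score} (higher = more
#'   active-like) and \code{active} (logical)
#' @return AUC in [0, 1]
#' @export
rocAuc <- function(records) {
  s <- records$score; a <- as.logical(records$active)
  stopifnot(all(is.finite(s)))
  na <- sum(a); nn <- sum(!a)
  if (na == 0 || nn == 0) stop("need at least one active and one inactive")
  r <- rank(s)  # average ranks handle ties as half-wins
  (sum(r[a]) - na * (na + 1) / 2) / (na * nn)
}

## actives found in the top k = ceil(fraction * N) of the ranking, with
## ties at the cutoff broken by stable input order
.topkActives <- function(records, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  N <- nrow(records)
  k <- ceiling(fraction * N)
  ord <- order(-records$score)  # stable for ties
  sum(as.logical(records$active)[ord][seq_len(k)])
}

#' Enrichment factor at a screening fraction
#'
#' Ratio of the active rate in the top \code{fraction} of the ranking to
#' the active rate of the whole library (EF1\% by default).
#'
#' @inheritParams rocAuc
#' @param fraction top fraction of the ranked library (default 0.01)
#' @export
enrichmentFactor <- function(records, fraction = 0.01) {
  A <- sum(as.logical(records$active))
  if (A == 0) stop("no actives in the screen")
  N <- nrow(records)
  k <- ceiling(fraction * N)
  (.topkActives(records, fraction) / k) / (A / N)
}

#' Normalized enrichment factor
#'
#' \code{\link{enrichmentFactor}} divided by the enrichment factor of a
#' perfect ranking of the same label multiset, so the value lies in [0, 1]
#' and is comparable across targets with different active rates.
#'
#' @inheritParams enrichmentFactor
#' @export
normalizedEnrichmentFactor <- function(records, fraction = 0.01) {
  A <- sum(as.logical(records$active))
  if (A == 0) stop("no actives in the screen")
  N <- nrow(records)
  k <- ceiling(fraction * N)
  best <- (min(k, A) / k) / (A / N)
  enrichmentFactor(records, fraction) / best
}
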