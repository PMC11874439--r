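## ---- SMARTS subset matcher --------------------------------------------
##
## Self-contained matcher for the substructure patterns used to select
## covalent attachment atoms. Supported subset:
##   * organic-subset atoms (B, C, N, O, P, S, F, Cl, Br, I), '*', and
##     aromatic lowercase (c, n, o, s, p) interpreted as "element + in ring"
##     (no aromaticity perception is done);
##   * bracket atoms combining primitives: element symbol, '#<Z>' atomic
##     number, 'X<d>' total connectivity, 'H<d>' explicit-hydrogen count,
##     'R' ring membership, '+'/'-' formal charge (all atoms here carry
##     charge 0), '*', with '!' negation, '&'/';' conjunction and ','
##     disjunction;
##   * bonds '-', '=', '#' (orders 1-3), '~' and ':' (any), default any;
##   * branches '(...)' and ring-closure digits.
## Unsupported syntax raises a parse error rather than matching wrongly.

.ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                Cl = 17, Br = 35, I = 53)

.smartsError <- function(pattern, why)
  stop("invalid SMARTS '", pattern, "': ", why, call. = FALSE)

## one primitive -> list(kind, value, negate)
.parsePrimitives <- function(expr, pattern) {
  prims <- list()
  i <- 1L
  n <- nchar(expr)
  while (i <= n) {
    neg <- FALSE
    ch <- substr(expr, i, i)
    if (ch == "!") { neg <- TRUE; i <- i + 1L; ch <- substr(expr, i, i) }
    if (i > n) .smartsError(pattern, "dangling '!'")
    rest <- substr(expr, i, n)
    m <- regmatches(rest, regexpr(
      "^(#[0-9]+|X[0-9]+|H[0-9]*|R[0-9]*|\\+[0-9]*|-[0-9]*|\\*|[A-Z][a-z]?|[cnops])",
      rest))
    if (length(m) == 0) .smartsError(pattern, paste0("unsupported primitive at '", rest, "'"))
    tok <- m[1]
    i <- i + nchar(tok)
    p <- if (tok == "*") list(kind = "any")
    else if (startsWith(tok, "#"))
      list(kind = "element", value = names(.ELEMENT_Z)[match(as.integer(substring(tok, 2)), .ELEMENT_Z)])
    else if (grepl("^X", tok))
      list(kind = "connectivity", value = as.integer(substring(tok, 2)))
    else if (grepl("^H", tok) && tok != "He" && !tok %in% names(.ELEMENT_Z)[0])
      list(kind = "hcount", value = if (nchar(tok) > 1) as.integer(substring(tok, 2)) else 1L)
    else if (grepl("^R", tok))
      list(kind = "ring", value = TRUE)
    else if (grepl("^\\+", tok) || grepl("^-", tok)) {
      num <- substring(tok, 2)
      q <- if (nchar(num)) as.integer(num) else 1L
      list(kind = "charge", value = if (startsWith(tok, "-")) -q else q)
    }
    else if (tok %in% c("c", "n", "o", "s", "p"))
      list(kind = "aromatic_element", value = toupper(tok))
    else {
      if (!tok %in% names(.ELEMENT_Z) && !tok %in% names(.COV_RADII))
        list(kind = "element", value = tok)  # uncommon element, exact match
      else list(kind = "element", value = tok)
    }
    p$negate <- neg
    prims[[length(prims) + 1L]] <- p
  }
  prims
}

## bracket body -> list of AND-groups (ORed together)
.parseBracket <- function(body, pattern) {
  orParts <- strsplit(body, ",", fixed = TRUE)[[1]]
  if (length(orParts) == 0) .smartsError(pattern, "empty bracket atom")
  lapply(orParts, function(part) {
    part <- gsub("[&;]", "", part)
    if (!nchar(part)) .smartsError(pattern, "empty bracket clause")
    .parsePrimitives(part, pattern)
  })
}

#' @keywords internal
.parseSmarts <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || !nchar(pattern))
    stop("SMARTS pattern must be a non-empty string")
  atoms <- list(); bonds <- list()
  prev <- NA_integer_; pending <- NULL
  stack <- integer(0); ringOpen <- list()
  addAtom <- function(constraint) {
    atoms[[length(atoms) + 1L]] <<- constraint
    idx <- length(atoms)
    if (!is.na(prev))
      bonds[[length(bonds) + 1L]] <<- list(a = prev, b = idx, bond = pending)
    pending <<- NULL
    prev <<- idx
  }
  i <- 1L; n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (!length(stack)) .smartsError(pattern, "unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "~", ":")) {
      ## '#' here is a bond only outside brackets (triple bond)
      pending <- ch; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) .smartsError(pattern, "ring closure before any atom")
      key <- ch
      if (!is.null(ringOpen[[key]])) {
        bonds[[length(bonds) + 1L]] <- list(a = ringOpen[[key]]$atom, b = prev,
                                            bond = ringOpen[[key]]$bond %||% pending)
        ringOpen[[key]] <- NULL
      } else ringOpen[[key]] <- list(atom = prev, bond = pending)
      pending <- NULL
      i <- i + 1L
    } else if (ch == "[") {
      close <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      if (close < 0) .smartsError(pattern, "unclosed '['")
      body <- substr(pattern, i + 1L, i + close - 2L)
      addAtom(.parseBracket(body, pattern))
      i <- i + close
    } else {
      two <- substr(pattern, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        addAtom(list(list(list(kind = "element", value = two, negate = FALSE))))
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        addAtom(list(list(list(kind = "element", value = ch, negate = FALSE))))
        i <- i + 1L
      } else if (ch %in% c("c", "n", "o", "s", "p")) {
        addAtom(list(list(list(kind = "aromatic_element", value = toupper(ch),
                               negate = FALSE))))
        i <- i + 1L
      } else if (ch == "*") {
        addAtom(list(list(list(kind = "any", negate = FALSE))))
        i <- i + 1L
      } else .smartsError(pattern, paste0("unsupported token '", ch, "'"))
    }
  }
  if (length(stack)) .smartsError(pattern, "unbalanced '('")
  if (length(Filter(Negate(is.null), ringOpen)))
    .smartsError(pattern, "unclosed ring bond")
  if (!length(atoms)) .smartsError(pattern, "no atoms")
  list(atoms = atoms, bonds = bonds)
}

## per-molecule info the primitives test against
.smartsMolInfo <- function(mol) {
  n <- natoms(mol)
  el <- mol@atoms$element
  b <- mol@bonds
  nbrs <- vector("list", n)
  orders <- vector("list", n)
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    nbrs[[b[k, 1]]] <- c(nbrs[[b[k, 1]]], b[k, 2])
    nbrs[[b[k, 2]]] <- c(nbrs[[b[k, 2]]], b[k, 1])
  }
  inRing <- rep(FALSE, n)
  if (nrow(b)) {
    g <- .molGraph(mol)
    br <- igraph::bridges(g)
    ringEdges <- setdiff(seq_len(nrow(b)), as.integer(br))
    for (k in ringEdges) inRing[b[k, 1:2]] <- TRUE
  }
  list(el = el, degree = lengths(nbrs),
       hcount = vapply(nbrs, function(v) sum(el[v] == "H"), integer(1)),
       inRing = inRing, nbrs = nbrs, bonds = b)
}

.atomMatches <- function(constraint, ai, info) {
  for (group in constraint) {
    ok <- TRUE
    for (p in group) {
      hit <- switch(p$kind,
        any = TRUE,
        element = !is.na(p$value) && info$el[ai] == p$value,
        aromatic_element = info$el[ai] == p$value && info$inRing[ai],
        connectivity = info$degree[ai] == p$value,
        hcount = info$hcount[ai] == p$value,
        ring = info$inRing[ai],
        charge = p$value == 0L,  # all atoms carry formal charge 0
        FALSE)
      if (isTRUE(p$negate)) hit <- !hit
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.bondMatches <- function(bondSym, order) {
  if (is.null(bondSym) || bondSym %in% c("~", ":")) return(TRUE)
  order == switch(bondSym, "-" = 1L, "=" = 2L, "#" = 3L, -1L)
}

#' Find ligand atoms matching a SMARTS pattern
#'
#' Returns the molecule-atom index bound to the pattern's first atom for
#' every complete match, deduplicated in stable (input) order. See the
#' source header for the supported SMARTS subset.
#'
#' @param ligand a \linkS4class{TypedMolecule} with bonds
#' @param pattern SMARTS string
#' @return integer vector of atom indices (1-based)
#' @export
findLigandCovalentAtoms <- function(ligand, pattern) {
  pat <- .parseSmarts(pattern)
  info <- .smartsMolInfo(ligand)
  nPat <- length(pat$atoms)
  ## adjacency of the pattern
  padj <- vector("list", nPat)
  for (bd in pat$bonds) {
    padj[[bd$a]] <- c(padj[[bd$a]], list(bd))
    padj[[bd$b]] <- c(padj[[bd$b]], list(list(a = bd$b, b = bd$a, bond = bd$bond)))
  }
  molOrder <- function(i, j) {
    b <- info$bonds
    k <- which((b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i))
    if (length(k)) b[k[1], 3] else NA_integer_
  }
  firstHits <- integer(0)
  assign <- integer(nPat)
  extend <- function(pi) {
    if (pi > nPat) { firstHits <<- c(firstHits, assign[1]); return(invisible()) }
    ## pattern atoms arrive in input order, so every bond back to an
    ## already-placed pattern atom constrains the candidate
    reqBonds <- Filter(function(bd) bd$b < pi, padj[[pi]])
    cands <- seq_along(info$el)
    for (mi in cands) {
      if (mi %in% assign[seq_len(pi - 1L)]) next
      if (!.atomMatches(pat$atoms[[pi]], mi, info)) next
      ok <- TRUE
      for (bd in reqBonds) {
        o <- molOrder(mi, assign[bd$b])
        if (is.na(o) || !.bondMatches(bd$bond, o)) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[pi] <<- mi
      extend(pi + 1L)
      assign[pi] <<- 0L
    }
  }
  extend(1L)
  hits <- unique(firstHits)
  if (!length(hits))
    stop("no ligand atom matches SMARTS pattern '", pattern, "'", call. = FALSE)
  hits
}
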