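## A documented SMARTS subset sufficient for tether queries: organic-subset
## element symbols (aromatic in lower case), bracket atoms with element,
## charge and wildcards (*, A, a), bond symbols - = # : ~ (default bond =
## single-or-aromatic), branches and ring closures (1-9, %nn). Recursive
## SMARTS, H-counts, degree/valence primitives are not supported. Matching
## is non-induced subgraph isomorphism (LAD) with per-atom compatibility
## domains, followed by a bond-order compatibility filter.

#' Parse a SMARTS (subset) query
#'
#' @param smarts query string.
#' @return a query object: list with \code{atoms} (data.frame: element,
#'   aromatic, charge) and \code{bonds} (data.frame: i, j, type).
#' @export
parseSmarts <- function(smarts) {
  chars <- strsplit(smarts, "")[[1]]
  atoms <- data.frame(element = character(), aromatic = logical(),
                      charge = numeric(), stringsAsFactors = FALSE)
  bonds <- data.frame(i = integer(), j = integer(), type = character(),
                      stringsAsFactors = FALSE)
  stack <- integer()        # branch points
  prev <- NA_integer_
  pendingBond <- NA_character_
  ringOpen <- list()        # digit -> c(atom, bondType)
  pos <- 1
  addAtom <- function(el, aromatic, charge) {
    atoms[nrow(atoms) + 1L, ] <<- list(el, aromatic, charge)
    idx <- nrow(atoms)
    if (!is.na(prev)) {
      bonds[nrow(bonds) + 1L, ] <<- list(prev, idx,
        if (is.na(pendingBond)) "default" else pendingBond)
    }
    pendingBond <<- NA_character_
    prev <<- idx
  }
  twoLetter <- c("Cl", "Br")
  while (pos <= length(chars)) {
    ch <- chars[pos]
    nxt <- if (pos < length(chars)) chars[pos + 1] else ""
    if (ch == "(") {
      stack <- c(stack, prev); pos <- pos + 1
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMARTS: ", smarts)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pendingBond <- ch; pos <- pos + 1
    } else if (ch == "[") {
      close <- pos
      while (close <= length(chars) && chars[close] != "]") close <- close + 1
      if (close > length(chars)) stop("unbalanced '[' in SMARTS: ", smarts)
      body <- paste(chars[(pos + 1):(close - 1)], collapse = "")
      parts <- regmatches(body,
        regexec("^([A-Za-z*][a-z]?)(H[0-9]?)?([+-][0-9]?)?$", body))[[1]]
      if (!length(parts)) stop("unsupported bracket atom [", body, "]")
      sym <- parts[2]
      chg <- parts[4]
      charge <- NA_real_
      if (nzchar(chg)) {
        sign <- if (substr(chg, 1, 1) == "-") -1 else 1
        mag <- if (nchar(chg) > 1) as.numeric(substr(chg, 2, 2)) else 1
        charge <- sign * mag
      }
      if (sym == "*") { el <- "*"; aromFlag <- NA }
      else if (sym == "A") { el <- "*"; aromFlag <- FALSE }
      else if (sym == "a") { el <- "*"; aromFlag <- TRUE }
      else if (sym %in% c("b", "c", "n", "o", "s", "p")) {
        el <- toupper(sym); aromFlag <- TRUE
      } else {
        el <- paste0(toupper(substr(sym, 1, 1)),
                     if (nchar(sym) > 1) substr(sym, 2, 2) else "")
        aromFlag <- FALSE
      }
      addAtom(el, isTRUE(aromFlag), charge)
      atoms$aromatic[nrow(atoms)] <- aromFlag
      pos <- close + 1
    } else if (paste0(ch, nxt) %in% twoLetter) {
      addAtom(paste0(ch, nxt), FALSE, NA_real_)
      pos <- pos + 2
    } else if (ch %in% c("B", "C", "N", "O", "S", "P", "F", "I")) {
      addAtom(ch, FALSE, NA_real_); pos <- pos + 1
    } else if (ch %in% c("b", "c", "n", "o", "s", "p")) {
      addAtom(toupper(ch), TRUE, NA_real_); pos <- pos + 1
    } else if (ch == "*") {
      addAtom("*", FALSE, NA_real_)
      atoms$aromatic[nrow(atoms)] <- NA
      pos <- pos + 1
    } else if (ch == "A") {
      addAtom("*", FALSE, NA_real_); pos <- pos + 1
    } else if (ch == "a") {
      addAtom("*", TRUE, NA_real_); pos <- pos + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        digit <- paste(chars[(pos + 1):(pos + 2)], collapse = "")
        pos <- pos + 3
      } else {
        digit <- ch
        pos <- pos + 1
      }
      if (is.null(ringOpen[[digit]])) {
        ringOpen[[digit]] <- list(atom = prev, bond = pendingBond)
      } else {
        open <- ringOpen[[digit]]
        bt <- if (!is.na(pendingBond)) pendingBond
          else if (!is.na(open$bond)) open$bond else "default"
        bonds[nrow(bonds) + 1L, ] <- list(open$atom, prev, bt)
        ringOpen[[digit]] <- NULL
      }
      pendingBond <- NA_character_
    } else if (ch == ".") {
      stop("disconnected SMARTS components are not supported")
    } else {
      stop("unsupported SMARTS token '", ch, "' in: ", smarts)
    }
  }
  if (!nrow(atoms)) stop("empty SMARTS query")
  if (length(stack)) stop("unbalanced '(' in SMARTS: ", smarts)
  if (length(Filter(Negate(is.null), ringOpen)))
    stop("unclosed ring bond in SMARTS: ", smarts)
  list(atoms = atoms, bonds = bonds)
}

bondTypeCompatible <- function(queryType, targetOrder, targetAromatic) {
  switch(queryType,
    "~" = TRUE,
    "-" = targetOrder %in% c("1", "am") && !targetAromatic,
    "=" = targetOrder == "2",
    "#" = targetOrder == "3",
    ":" = targetOrder == "ar" || targetAromatic,
    "default" = targetOrder %in% c("1", "am") || targetOrder == "ar" ||
      targetAromatic,
    FALSE)
}

#' Find substructure matches of a SMARTS query in a molecule
#'
#' Non-induced subgraph matching with element/aromaticity/charge
#' compatibility and bond-type filtering. Every distinct correspondence is
#' returned once (a symmetric query therefore yields one entry per
#' automorphic embedding, each defining its own tether alignment).
#'
#' @param mol a [Molecule-class] (or [Ligand-class]).
#' @param query SMARTS string or a parsed query from [parseSmarts()].
#' @return list of integer vectors; element k of a match is the molecule
#'   atom matched by query atom k. Empty list when there is no match.
#' @export
matchSmarts <- function(mol, query) {
  if (is(mol, "Ligand")) mol <- molecule(mol)
  if (is.character(query)) query <- parseSmarts(query)
  qa <- query$atoms
  qb <- query$bonds
  n <- nAtoms(mol)
  if (n == 0 || nrow(qa) > n) return(list())
  arom <- aromaticAtomMask(mol)
  el <- mol@atoms$element
  fc <- mol@atoms$formalCharge
  domains <- lapply(seq_len(nrow(qa)), function(k) {
    ok <- rep(TRUE, n)
    if (qa$element[k] != "*") ok <- ok & el == qa$element[k]
    if (!is.na(qa$aromatic[k]))
      ok <- ok & (arom == qa$aromatic[k])
    if (!is.na(qa$charge[k])) ok <- ok & fc == qa$charge[k]
    which(ok)
  })
  if (any(vapply(domains, length, 1L) == 0)) return(list())
  if (nrow(qb) == 0 && nrow(qa) == 1) {
    raw <- lapply(domains[[1]], function(i) i)
  } else {
    qg <- igraph::graph_from_data_frame(qb[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(qa))))
    tg <- moleculeGraph(mol)
    iso <- igraph::subgraph_isomorphisms(qg, tg, method = "lad",
                                         induced = FALSE,
                                         domains = domains)
    ## pattern vertices are created in query-atom order, so each mapping's
    ## names are the matched target atoms in query-atom order
    raw <- lapply(iso, function(m) as.integer(names(m))[
      order(as.integer(igraph::V(qg)$name))])
    ## bond-type filter
    bd <- mol@bonds
    bondKey <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j), sep = "-")
    bondArom <- logical(nrow(bd))
    for (r in mol@rings) {
      ringsArom <- arom[r]
      if (all(ringsArom)) {
        nr <- length(r)
        for (q in seq_len(nr)) {
          key <- paste(sort(c(r[q], r[if (q == nr) 1L else q + 1L])),
                       collapse = "-")
          bondArom[match(key, bondKey)] <- TRUE
        }
      }
    }
    raw <- Filter(function(m) {
      for (k in seq_len(nrow(qb))) {
        t1 <- m[qb$i[k]]; t2 <- m[qb$j[k]]
        hit <- match(paste(min(t1, t2), max(t1, t2), sep = "-"), bondKey)
        if (is.na(hit)) return(FALSE)
        if (!bondTypeCompatible(qb$type[k], bd$order[hit], bondArom[hit]))
          return(FALSE)
      }
      TRUE
    }, raw)
  }
  if (!length(raw)) return(list())
  ## one entry per distinct (matched-atom set, correspondence) pair; every
  ## distinct correspondence defines a different tether alignment of the
  ## whole molecule, so symmetric embeddings are kept individually
  keys <- vapply(raw, paste, "", collapse = ",")
  raw[!duplicated(keys)]
}
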