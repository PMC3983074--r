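## Post-docking analysis: topological-symmetry-aware RMSD, SD-record
## filtering / sorting / reporting, and virtual-screening enrichment
## metrics.

#' Enumerate graph automorphisms of a molecule
#'
#' Element- and bond-order-preserving automorphisms, enumerated by VF2
#' refinement-based matching (via igraph) with a cap on the number of
#' mappings returned. Aromatic rings written in Kekule notation are
#' canonicalised to aromatic bonds first, so a relabelling that swaps the
#' two Kekule forms counts as an automorphism.
#'
#' @param mol a [Molecule-class] or [Ligand-class].
#' @param heavyOnly restrict to the heavy-atom subgraph (default TRUE).
#' @param cap maximum number of mappings (default 1e5); exceeding it drops
#'   the excess with a warning.
#' @return list of integer permutations over the selected atoms (positions
#'   index into the selected-atom vector, which is returned as the
#'   \code{"atoms"} attribute).
#' @export
molAutomorphisms <- function(mol, heavyOnly = TRUE, cap = 1e5) {
  if (is(mol, "Ligand")) mol <- molecule(mol)
  sel <- if (heavyOnly) which(mol@atoms$element != "H")
         else seq_len(nAtoms(mol))
  n <- length(sel)
  if (n == 0) stop("no atoms selected")
  bd <- canonicalBondOrders(mol)
  keep <- bd$i %in% sel & bd$j %in% sel
  bd <- bd[keep, , drop = FALSE]
  remap <- match(seq_len(nAtoms(mol)), sel)
  if (nrow(bd) == 0) {
    ## no bonds: any element-preserving permutation; enumerate only for
    ## tiny systems, else identity
    if (n == 1) {
      out <- list(1L)
    } else {
      out <- list(seq_len(n))
    }
    attr(out, "atoms") <- sel
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(i = remap[bd$i], j = remap[bd$j]), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  vcol <- as.integer(factor(mol@atoms$element[sel]))
  ecol <- as.integer(factor(bd$order, levels = c("1", "2", "3", "ar", "am")))
  iso <- igraph::isomorphisms(g, g, method = "vf2",
                              vertex.color1 = vcol, vertex.color2 = vcol,
                              edge.color1 = ecol, edge.color2 = ecol)
  ord <- order(as.integer(igraph::V(g)$name))
  out <- lapply(iso, function(m) as.integer(names(m))[ord])
  if (length(out) > cap) {
    warning("automorphism count ", length(out), " exceeds cap ", cap,
            "; using the first ", cap)
    out <- out[seq_len(cap)]
  }
  attr(out, "atoms") <- sel
  out
}

## bond orders with Kekule aromatic rings canonicalised to "ar", so that
## the two Kekule structures of one aromatic ring are equivalent
canonicalBondOrders <- function(mol) {
  bd <- mol@bonds
  if (!nrow(bd)) return(bd)
  arom <- aromaticAtomMask(mol)
  if (any(arom)) {
    key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j), sep = "-")
    for (r in mol@rings) {
      if (!all(arom[r])) next
      m <- length(r)
      for (q in seq_len(m)) {
        e <- sort(c(r[q], r[if (q == m) 1L else q + 1L]))
        hit <- match(paste(e, collapse = "-"), key)
        if (!is.na(hit)) bd$order[hit] <- "ar"
      }
    }
  }
  bd
}

sameGraph <- function(a, b) {
  ea <- sort(a@atoms$element); eb <- sort(b@atoms$element)
  if (!identical(ea, eb)) return(FALSE)
  key <- function(m) {
    bd <- canonicalBondOrders(m)
    el <- m@atoms$element
    sort(paste(pmin(el[bd$i], el[bd$j]), pmax(el[bd$i], el[bd$j]),
               bd$order))
  }
  identical(key(a), key(b))
}

#' Symmetry-corrected RMSD between two poses of one molecule
#'
#' Minimum heavy-atom RMSD over all element- and bond-order-preserving graph
#' automorphisms. No re-superposition is performed: coordinates are compared
#' in the docking frame, matching reference-versus-docked-pose semantics.
#'
#' @param ref reference [Ligand-class].
#' @param pose docked [Ligand-class] with the same molecular graph (same
#'   atom order).
#' @param includeH also compare hydrogens (default FALSE).
#' @param cap automorphism cap (see [molAutomorphisms()]).
#' @return RMSD in Angstroms; never larger than the naive index-matched
#'   RMSD.
#' @export
symmetryRmsd <- function(ref, pose, includeH = FALSE, cap = 1e5) {
  mr <- molecule(ref); mp <- molecule(pose)
  if (!sameGraph(mr, mp))
    stop("molecular graphs differ (element or bond multiset mismatch)")
  auts <- molAutomorphisms(mr, heavyOnly = !includeH, cap = cap)
  sel <- attr(auts, "atoms")
  X <- coords(mr)[sel, , drop = FALSE]
  Y <- coords(mp)[sel, , drop = FALSE]
  best <- Inf
  for (p in auts) {
    r <- sqrt(mean(rowSums((X[p, , drop = FALSE] - Y)^2)))
    if (r < best) best <- r
  }
  best
}

#' Naive index-matched RMSD
#'
#' @inheritParams symmetryRmsd
#' @return RMSD in Angstroms under the identity atom mapping.
#' @export
naiveRmsd <- function(ref, pose, includeH = FALSE) {
  sel <- if (includeH) seq_len(nAtoms(ref)) else which(isHeavy(ref))
  X <- coords(ref)[sel, , drop = FALSE]
  Y <- coords(pose)[sel, , drop = FALSE]
  sqrt(mean(rowSums((X - Y)^2)))
}

## ---- SD record utilities -------------------------------------------------

recordField <- function(rec, name) {
  f <- sdFields(rec)
  if (name %in% names(f)) f[[name]] else NA_character_
}

#' Filter SD records by a data-field expression
#'
#' Expressions combine comparisons (\code{<, <=, >, >=, ==, !=}) of field
#' names against literals with \code{and}/\code{or}/\code{not} (also
#' \code{& | !}) and parentheses. A comparison is numeric when both sides
#' parse as numbers, lexicographic otherwise. Records referencing a missing
#' field are excluded, with one warning.
#'
#' @param records list of [Ligand-class] (as returned by [readSdf()]).
#' @param expression filter expression, e.g. \code{"SCORE < -20"}.
#' @return the order-preserving subset of records for which the expression
#'   is true.
#' @export
filterRecords <- function(records, expression) {
  pred <- parseFilterExpression(expression)
  missingSeen <- FALSE
  keep <- vapply(records, function(r) {
    v <- pred(r)
    if (is.na(v)) {
      missingSeen <<- TRUE
      FALSE
    } else v
  }, logical(1))
  if (missingSeen)
    warning("records referencing a missing field were excluded")
  records[keep]
}

parseFilterExpression <- function(expression) {
  rx <- paste0("\\s*(", paste(c("<=", ">=", "==", "!=", "<", ">", "\\(",
                                "\\)", "&&", "\\|\\|", "&", "\\|", "!",
                                "'[^']*'", "\"[^\"]*\"",
                                "[A-Za-z_][A-Za-z0-9._]*",
                                "-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?"),
                              collapse = "|"), ")")
  toks <- character()
  rest <- expression
  while (nzchar(trimws(rest))) {
    m <- regexpr(rx, rest, perl = TRUE)
    if (m != 1) stop("malformed filter expression near: ", rest)
    tok <- trimws(regmatches(rest, m))
    toks <- c(toks, tok)
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  pos <- 1
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  advance <- function() {
    if (pos > length(toks))
      stop("malformed filter expression: unexpected end of input")
    t <- toks[pos]; pos <<- pos + 1; t
  }
  parseOperand <- function() {
    t <- advance()
    if (grepl("^['\"]", t)) {
      list(type = "literal", value = gsub("^['\"]|['\"]$", "", t))
    } else if (grepl("^-?[0-9]", t)) {
      list(type = "literal", value = t)
    } else {
      list(type = "field", value = t)
    }
  }
  parseComparison <- function() {
    lhs <- parseOperand()
    op <- advance()
    if (!op %in% c("<", "<=", ">", ">=", "==", "!="))
      stop("expected comparison operator, got '", op, "'")
    rhs <- parseOperand()
    function(rec) {
      getv <- function(o) {
        if (o$type == "field") recordField(rec, o$value) else o$value
      }
      a <- getv(lhs); b <- getv(rhs)
      if (is.na(a) || is.na(b)) return(NA)
      an <- suppressWarnings(as.numeric(a))
      bn <- suppressWarnings(as.numeric(b))
      if (!is.na(an) && !is.na(bn)) { a <- an; b <- bn }
      switch(op, "<" = a < b, "<=" = a <= b, ">" = a > b, ">=" = a >= b,
             "==" = a == b, "!=" = a != b)
    }
  }
  parseFactor <- function() {
    t <- peek()
    if (t %in% c("!", "not")) {
      advance()
      f <- parseFactor()
      function(rec) !f(rec)
    } else if (t == "(") {
      advance()
      e <- parseOr()
      if (advance() != ")") stop("expected ')'")
      e
    } else parseComparison()
  }
  combine <- function(f, g, orElse) {
    force(f); force(g); force(orElse)
    function(rec) if (orElse) f(rec) | g(rec) else f(rec) & g(rec)
  }
  parseAnd <- function() {
    f <- parseFactor()
    while (peek() %in% c("&", "&&")) {
      advance()
      f <- combine(f, parseFactor(), orElse = FALSE)
    }
    f
  }
  parseOr <- function() {
    f <- parseAnd()
    while (peek() %in% c("|", "||")) {
      advance()
      f <- combine(f, parseAnd(), orElse = TRUE)
    }
    f
  }
  ## treat bare words and/or/not as operators: remap before parsing
  toks[toks == "and"] <- "&"; toks[toks == "or"] <- "|"
  toks[toks == "not"] <- "!"
  out <- parseOr()
  if (pos <= length(toks))
    stop("trailing tokens in filter expression: ",
         paste(toks[pos:length(toks)], collapse = " "))
  out
}

#' Sort SD records by a data field
#'
#' Stable sort; records missing the field sort last.
#'
#' @param records list of [Ligand-class].
#' @param field data-field name.
#' @param numeric sort numerically (default TRUE).
#' @param descending sort direction.
#' @return the reordered record list.
#' @export
sortRecords <- function(records, field, numeric = TRUE,
                        descending = FALSE) {
  vals <- vapply(records, recordField, "", name = field)
  key <- if (numeric) suppressWarnings(as.numeric(vals)) else vals
  ord <- order(key, na.last = TRUE, decreasing = descending,
               method = "radix")
  records[ord]
}

#' Report SD data fields as tabular text
#'
#' @param records list of [Ligand-class].
#' @param fields character vector of field names.
#' @param format "tsv" (default) or RFC-4180-style "csv".
#' @return character vector of lines: header plus one row per record;
#'   missing values are empty cells.
#' @export
reportRecords <- function(records, fields, format = c("tsv", "csv")) {
  format <- match.arg(format)
  rows <- lapply(records, function(r) {
    v <- vapply(fields, recordField, "", rec = r)
    v[is.na(v)] <- ""
    v
  })
  fmtRow <- function(v) {
    if (format == "tsv") return(paste(v, collapse = "\t"))
    quoted <- vapply(v, function(x) {
      if (grepl('[",\n]', x))
        paste0('"', gsub('"', '""', x), '"') else x
    }, "")
    paste(quoted, collapse = ",")
  }
  c(fmtRow(fields), vapply(rows, fmtRow, ""))
}

## ---- enrichment metrics --------------------------------------------------

#' Virtual-screening enrichment metrics
#'
#' ROC by sweeping the score threshold with tied scores processed as a
#' block (making the AUC equal to the Mann-Whitney statistic), the
#' semilogarithmic AUC (TPR against log10 FPR on [1e-3, 1], normalised by
#' log10(1000) so a random ranking gives about 0.1446), enrichment factors
#' at the requested fractions and the maximal enrichment factor over all
#' top-k prefixes.
#'
#' @param scores data.frame with columns \code{id}, \code{score},
#'   \code{active} (logical or 0/1).
#' @param fractions fractions of the ranked collection for EF (default 1%
#'   and 20%).
#' @param lowerIsBetter lower scores rank first (default TRUE).
#' @return a [VSMetrics-class]; absence of actives or of decoys is an
#'   error.
#' @export
vsMetrics <- function(scores, fractions = c(0.01, 0.2),
                      lowerIsBetter = TRUE) {
  act <- as.logical(scores$active)
  if (!any(act) || all(act))
    stop("need at least one active and one decoy")
  s <- scores$score
  if (!lowerIsBetter) s <- -s
  ord <- order(s)
  act <- act[ord]
  s <- s[ord]
  nA <- sum(act); nD <- sum(!act); N <- length(act)

  ## tie blocks
  blocks <- split(seq_len(N), match(s, unique(s)))
  fpr <- 0; tpr <- 0
  roc <- matrix(c(0, 0), 1, 2)
  for (b in blocks) {
    tpr <- tpr + sum(act[b]) / nA
    fpr <- fpr + sum(!act[b]) / nD
    roc <- rbind(roc, c(fpr, tpr))
  }
  colnames(roc) <- c("fpr", "tpr")
  auc <- sum(diff(roc[, 1]) * (head(roc[, 2], -1) + tail(roc[, 2], -1)) / 2)
  auc <- min(1, max(0, auc))  # guard against trapezoid rounding

  ## log AUC with floor 1e-3
  lam <- 1e-3
  la <- 0
  for (k in seq_len(nrow(roc) - 1)) {
    x1 <- roc[k, 1]; x2 <- roc[k + 1, 1]
    y1 <- roc[k, 2]; y2 <- roc[k + 1, 2]
    xa <- max(x1, lam); xb <- min(x2, 1)
    if (xb <= xa) next
    b <- (y2 - y1) / (x2 - x1)
    a <- y1 - b * x1
    la <- la + (a * log(xb / xa) + b * (xb - xa)) / log(10)
  }
  logAuc <- unname(la / log10(1 / lam))

  cumAct <- cumsum(act)
  efAt <- function(k) (cumAct[k] / nA) / (k / N)
  ef <- vapply(fractions, function(f) {
    k <- max(1L, min(N, as.integer(round(f * N))))
    efAt(k)
  }, numeric(1))
  names(ef) <- formatC(fractions * 100, format = "g")
  efMax <- max(vapply(seq_len(N), efAt, numeric(1)))

  new("VSMetrics", auc = auc, logAuc = logAuc, ef = ef, efMax = efMax,
      rocPoints = roc)
}
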