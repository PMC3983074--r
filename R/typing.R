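## Interaction typing. Classes feed the polar term and the pharmacophore
## feature detector. Rules follow common medicinal-chemistry conventions and
## are a pure function of the molecular graph plus formal charges; the
## element-level defaults (metals, halogens, vdW radii) are read from the
## shipped parameter tables under inst/extdata/params so users can extend
## them.

metalElements <- function() {
  p <- elementParams()
  p$element[p$class == "metal"]
}

## Cached copy of extdata/params/elements.csv.
elementParams <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "params", "elements.csv",
                          package = "moldock")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

elementParamRow <- function(el) {
  p <- elementParams()
  i <- match(el, p$element)
  i[is.na(i)] <- match("*", p$element)
  p[i, , drop = FALSE]
}

#' Assign an interaction class to every atom
#'
#' Classes: \code{donor.H} (polar hydrogen on N/O/S), \code{acceptor}
#' (O always; N unless amide-type, aromatic N-H or positively charged; S),
#' \code{polar.H.carrier} (heavy atom carrying a polar hydrogen that is not
#' itself an acceptor), \code{apolar} (carbon, halogens and their hydrogens),
#' \code{metal}, \code{other}. Charged centres are flagged separately:
#' nitrogen with four substituents or formal charge +1 is a positive centre
#' (its hydrogens are donors), carboxylate-type oxygens are acceptors with a
#' negative flag, as is any atom with negative formal charge.
#'
#' @param mol a [Molecule-class] with bonds and formal charges present.
#' @return the molecule with \code{iclass} and \code{chargeFlag} columns
#'   filled; unknown elements get class "other" with a warning.
#' @export
assignInteractionClasses <- function(mol) {
  at <- mol@atoms
  n <- nrow(at)
  if (n == 0) return(mol)
  adj <- adjacencyList(mol)
  el <- at$element
  arom <- aromaticAtomMask(mol)
  known <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
             metalElements())
  if (any(!el %in% known))
    warning("unknown element(s) ", paste(unique(el[!el %in% known]),
                                         collapse = ", "),
            ": assigned class 'other'")

  iclass <- rep("other", n)
  chargeFlag <- rep("neutral", n)

  nbrEl <- function(i) el[adj[[i]]]
  ## double-bonded neighbour test (for amide / carboxylate perception)
  bd <- mol@bonds
  hasDoubleTo <- function(i, targetEl) {
    hits <- which((bd$i == i | bd$j == i) & bd$order == "2")
    any(el[ifelse(bd$i[hits] == i, bd$j[hits], bd$i[hits])] == targetEl)
  }

  for (i in seq_len(n)) {
    e <- el[i]
    nb <- adj[[i]]
    if (e == "H") {
      parent <- if (length(nb)) el[nb[1]] else ""
      iclass[i] <- if (parent %in% c("N", "O", "S")) "donor.H" else "apolar"
    } else if (e %in% c("C", "F", "Cl", "Br", "I")) {
      iclass[i] <- "apolar"
    } else if (e == "O") {
      iclass[i] <- "acceptor"
      ## carboxylate oxygen: O (single- or double-bonded) on a carbon that
      ## also bears another oxygen with a double bond or negative charge
      if (at$formalCharge[i] < 0) chargeFlag[i] <- "neg"
      for (c in nb[el[nb] == "C"]) {
        oSibs <- setdiff(adj[[c]][el[adj[[c]]] == "O"], i)
        if (length(oSibs) &&
            (hasDoubleTo(c, "O") &&
             any(at$formalCharge[c(i, oSibs)] < 0 |
                 vapply(c(i, oSibs), function(o)
                   sum(el[adj[[o]]] == "H") == 0, logical(1)))) &&
            sum(el[adj[[c]]] == "O") >= 2) {
          if (sum(el[adj[[i]]] == "H") == 0) chargeFlag[i] <- "neg"
        }
      }
    } else if (e == "N") {
      heavyNb <- nb[el[nb] != "H"]
      hNb <- nb[el[nb] == "H"]
      if (at$formalCharge[i] > 0 || length(nb) >= 4) {
        chargeFlag[i] <- "pos"
        iclass[i] <- if (length(hNb)) "polar.H.carrier" else "other"
      } else {
        amide <- any(vapply(heavyNb[el[heavyNb] == "C"],
                            function(c) hasDoubleTo(c, "O"), logical(1)))
        aromNH <- arom[i] && length(hNb) > 0
        if (amide || aromNH) {
          iclass[i] <- if (length(hNb)) "polar.H.carrier" else "other"
        } else {
          iclass[i] <- "acceptor"
        }
      }
      if (at$formalCharge[i] < 0) chargeFlag[i] <- "neg"
    } else if (e == "S") {
      iclass[i] <- "acceptor"
      if (at$formalCharge[i] < 0) chargeFlag[i] <- "neg"
    } else if (e %in% metalElements()) {
      iclass[i] <- "metal"
      chargeFlag[i] <- "pos"
    } else {
      iclass[i] <- "other"
      if (at$formalCharge[i] > 0) chargeFlag[i] <- "pos"
      if (at$formalCharge[i] < 0) chargeFlag[i] <- "neg"
    }
  }
  ## hydrogens on positive nitrogens are donors
  for (i in which(el == "H")) {
    nb <- adj[[i]]
    if (length(nb) && chargeFlag[nb[1]] == "pos" && el[nb[1]] == "N")
      iclass[i] <- "donor.H"
  }
  mol@atoms$iclass <- iclass
  mol@atoms$chargeFlag <- chargeFlag
  mol
}

## Heavy atoms that carry at least one polar hydrogen (hydrogen-bond donors).
donorHeavyAtoms <- function(mol) {
  adj <- adjacencyList(mol)
  donorH <- which(mol@atoms$iclass == "donor.H")
  unique(vapply(donorH, function(h) adj[[h]][1], integer(1)))
}

## Table of (H index, donor heavy index) pairs for the polar term.
donorHPairs <- function(mol) {
  adj <- adjacencyList(mol)
  hIdx <- which(mol@atoms$iclass == "donor.H")
  if (!length(hIdx))
    return(data.frame(h = integer(), d = integer()))
  data.frame(h = hIdx,
             d = vapply(hIdx, function(h) adj[[h]][1], integer(1)))
}

## Acceptor atoms with one attached heavy atom (lone-pair root) each, used
## for the acceptor-side angular term; isolated acceptors get root 0.
acceptorRoots <- function(mol) {
  adj <- adjacencyList(mol)
  acc <- which(mol@atoms$iclass == "acceptor")
  if (!length(acc)) return(data.frame(a = integer(), root = integer()))
  root <- vapply(acc, function(a) {
    nb <- adj[[a]]
    nb <- nb[mol@atoms$element[nb] != "H"]
    if (length(nb)) nb[1] else 0L
  }, integer(1))
  data.frame(a = acc, root = root)
}
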