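## Tripos MOL2 receptor input (via bio3d) and a minimal MOL2 writer used by
## the toy-system generators. Waters, ions and cofactors in the file are kept
## as receptor atoms. MOL2 partial charges are read and carried on the atoms
## but are not used by scoring, which depends on formal charges; formal
## charges are derived from SYBYL atom types (N.4 -> +1; carboxylate-type
## O.co2 oxygens are flagged as negatively charged acceptors).

#' Read a receptor from a Tripos MOL2 file
#'
#' @param path MOL2 file path with \code{@<TRIPOS>MOLECULE}, \code{ATOM} and
#'   \code{BOND} records; a missing BOND section is an error (the engine
#'   requires a bonded model).
#' @param cavity optional [CavityGrid-class]: restricts flexible torsions to
#'   groups within \code{margin} of the docking volume.
#' @param margin expansion margin for receptor flexibility, Angstroms.
#' @return a [Receptor-class] with interaction classes assigned and
#'   \code{flexibleDihedrals} populated by [perceiveReceptorFlexibility()].
#' @export
readMol2 <- function(path, cavity = NULL, margin = 2.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("@<TRIPOS>MOLECULE", lines, fixed = TRUE)))
    stop("not a MOL2 file (no @<TRIPOS>MOLECULE record): ", path)
  if (!any(grepl("@<TRIPOS>BOND", lines, fixed = TRUE)))
    stop("MOL2 file has no @<TRIPOS>BOND section (bonded model required): ",
         path)
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) stop("malformed MOL2 record in ", path,
                                         ": ", conditionMessage(e)))
  at <- m$atom
  elety <- at$elety
  element <- vapply(strsplit(elety, ".", fixed = TRUE), `[[`, "", 1)
  ## SYBYL types encode some formal charges
  formal <- integer(nrow(at))
  formal[elety == "N.4"] <- 1L
  bondOrder <- as.character(m$bond$type)
  bondOrder[!bondOrder %in% c("1", "2", "3", "ar", "am")] <- "1"
  mol <- buildMolecule(element, cbind(at$x, at$y, at$z),
                       data.frame(i = m$bond$origin, j = m$bond$target,
                                  order = bondOrder,
                                  stringsAsFactors = FALSE),
                       formalCharges = formal,
                       partialCharges = at$charge,
                       name = if (length(m$name)) m$name[1] else "")
  mol@atoms$chargeFlag[elety == "O.co2"] <- "neg"
  rec <- new("Receptor", molecule = mol)
  rec@flexibleDihedrals <- perceiveReceptorFlexibility(rec, cavity, margin)
  rec
}

#' Write a molecule to a Tripos MOL2 file
#'
#' Minimal writer (MOLECULE/ATOM/BOND/SUBSTRUCTURE records) used to emit toy
#' receptors; SYBYL atom types are reconstructed from elements and formal
#' charges.
#'
#' @param x a [Molecule-class], [Receptor-class] or [Ligand-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeMol2 <- function(x, path) {
  if (is(x, "Receptor") || is(x, "Ligand")) x <- molecule(x)
  at <- x@atoms
  bd <- x@bonds
  sybyl <- vapply(seq_len(nrow(at)), function(i) {
    e <- at$element[i]
    if (e == "N" && at$formalCharge[i] > 0) "N.4"
    else if (e == "O" && at$chargeFlag[i] == "neg") "O.co2"
    else if (e %in% c("C", "N", "O", "S", "P")) paste0(e, ".3")
    else e
  }, "")
  lines <- c("@<TRIPOS>MOLECULE",
             if (nzchar(x@name)) x@name else "MOL",
             sprintf(" %d %d 1", nrow(at), nrow(bd)),
             "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM")
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, sprintf(
      "%7d %-8s %9.4f %9.4f %9.4f %-7s %3d %-8s %9.4f",
      i, paste0(at$element[i], i), at$x[i], at$y[i], at$z[i], sybyl[i],
      1L, "SITE1", at$partialCharge[i]))
  }
  lines <- c(lines, "@<TRIPOS>BOND")
  for (k in seq_len(nrow(bd))) {
    lines <- c(lines, sprintf("%6d %5d %5d %s", k, bd$i[k], bd$j[k],
                              bd$order[k]))
  }
  lines <- c(lines, "@<TRIPOS>SUBSTRUCTURE",
             "     1 SITE1       1 GROUP")
  writeLines(lines, path)
  invisible(path)
}
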