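## Torsion perception and manipulation. Only exocyclic single bonds are ever
## rotated; ring-internal geometry is fixed (flexible rings are expected as
## pregenerated conformer records in the input SDF).

#' Perceive the rotatable dihedrals of a molecule
#'
#' Returns one [Dihedral-class] per rotatable bond: acyclic single bonds
#' between two non-terminal heavy atoms. Bonds whose rotation moves only
#' hydrogens are excluded unless a moved hydrogen is polar (hydroxyl, amine:
#' those rotors change the polar score). Amide C-N bonds are excluded. The
#' rotated set is the smaller side of the bond.
#'
#' @param mol a [Molecule-class] with rings perceived.
#' @return list of [Dihedral-class] (possibly empty).
#' @export
perceiveRotatableDihedrals <- function(mol) {
  bd <- mol@bonds
  if (!nrow(bd)) return(list())
  el <- mol@atoms$element
  adj <- adjacencyList(mol)
  ringKeys <- ringBondKeys(mol)
  out <- list()
  for (k in seq_len(nrow(bd))) {
    if (bd$order[k] != "1") next
    b <- bd$i[k]; c <- bd$j[k]
    if (el[b] == "H" || el[c] == "H") next
    key <- paste(sort(c(b, c)), collapse = "-")
    if (key %in% ringKeys) next
    if (isAmideBond(mol, adj, b, c)) next
    ## both pivots need a further neighbour to define the torsion
    if (length(adj[[b]]) < 2 || length(adj[[c]]) < 2) next
    sideC <- componentAfterBondDeletion(mol, b, c, c)
    sideB <- setdiff(seq_along(el), sideC)
    ## orient so the rotated set is the smaller side
    if (length(sideB) < length(sideC)) {
      tmp <- b; b <- c; c <- tmp
      rotated <- sideB
    } else {
      rotated <- sideC
    }
    moved <- setdiff(rotated, c)
    if (!length(moved)) next
    movedEl <- el[moved]
    if (all(movedEl == "H")) {
      polarH <- any(mol@atoms$iclass[moved] == "donor.H")
      if (!polarH) next
    }
    a <- chooseTorsionNeighbour(adj, el, b, exclude = c, inSet = NULL)
    d <- chooseTorsionNeighbour(adj, el, c, exclude = b, inSet = rotated)
    if (is.na(a) || is.na(d)) next
    out[[length(out) + 1L]] <- Dihedral(c(a, b, c, d), rotated)
  }
  out
}

## Deterministic reference-atom choice: lowest-index heavy neighbour,
## falling back to lowest-index hydrogen.
chooseTorsionNeighbour <- function(adj, el, pivot, exclude, inSet = NULL) {
  nb <- setdiff(adj[[pivot]], exclude)
  if (!is.null(inSet)) nb <- intersect(nb, inSet)
  if (!length(nb)) return(NA_integer_)
  heavy <- nb[el[nb] != "H"]
  if (length(heavy)) min(heavy) else min(nb)
}

isAmideBond <- function(mol, adj, b, c) {
  el <- mol@atoms$element
  bd <- mol@bonds
  pair <- sort(c(b, c))
  hit <- which(pmin(bd$i, bd$j) == pair[1] & pmax(bd$i, bd$j) == pair[2])
  if (length(hit) && any(bd$order[hit] == "am")) return(TRUE)
  isCN <- (el[b] == "C" && el[c] == "N") || (el[b] == "N" && el[c] == "C")
  if (!isCN) return(FALSE)
  cAtom <- if (el[b] == "C") b else c
  hits <- which((bd$i == cAtom | bd$j == cAtom) & bd$order == "2")
  others <- ifelse(bd$i[hits] == cAtom, bd$j[hits], bd$i[hits])
  any(el[others] %in% c("O", "S"))
}

#' Perceive flexible receptor torsions (terminal OH and NH3+ groups)
#'
#' The only receptor flexibility supported during docking. A terminal
#' hydroxyl is an O bonded to exactly one heavy atom and one hydrogen; a
#' terminal ammonium is a positively charged N bonded to one heavy atom and
#' three hydrogens. Water O-H bonds are not treated as flexible by default.
#' When a cavity is supplied, only groups whose heavy atom lies within
#' \code{margin} Angstroms of the docking volume are kept.
#'
#' @param rec a [Receptor-class] (interaction classes assigned).
#' @param cavity optional [CavityGrid-class] used for the margin filter.
#' @param margin expansion margin, Angstroms (default 2).
#' @param includeWater logical; also treat water O-H bonds as flexible.
#' @return list of [Dihedral-class].
#' @export
perceiveReceptorFlexibility <- function(rec, cavity = NULL, margin = 2.0,
                                        includeWater = FALSE) {
  mol <- rec@molecule
  el <- mol@atoms$element
  adj <- adjacencyList(mol)
  out <- list()
  for (i in seq_along(el)) {
    nb <- adj[[i]]
    heavyNb <- nb[el[nb] != "H"]
    hNb <- nb[el[nb] == "H"]
    isOH <- el[i] == "O" && length(heavyNb) == 1 && length(hNb) == 1
    isWater <- el[i] == "O" && length(heavyNb) == 0 && length(hNb) >= 1
    isNH3 <- el[i] == "N" && mol@atoms$chargeFlag[i] == "pos" &&
      length(heavyNb) == 1 && length(hNb) == 3
    if (!(isOH || isNH3 || (includeWater && isWater))) next
    if (isWater) next  # waters have no heavy parent to define a torsion
    b <- heavyNb[1]
    a <- chooseTorsionNeighbour(adj, el, b, exclude = i)
    if (is.na(a)) next
    if (!is.null(cavity)) {
      p <- unlist(mol@atoms[i, c("x", "y", "z")])
      if (distanceToCavity(cavity, p) > margin) next
    }
    rotated <- c(i, hNb)
    out[[length(out) + 1L]] <- Dihedral(c(a, b, i, min(hNb)), rotated)
  }
  out
}

#' Measure a dihedral angle on a coordinate set
#'
#' @param xyz n x 3 coordinate matrix.
#' @param dihedral a [Dihedral-class].
#' @return angle in degrees in (-180, 180].
#' @export
dihedralAngle <- function(xyz, dihedral) {
  a <- dihedral@atoms
  normalizeAngle(dihedralAngleXYZ(xyz[a[1], ], xyz[a[2], ], xyz[a[3], ],
                                  xyz[a[4], ]))
}

#' Set a dihedral to a target angle
#'
#' Rotates the dihedral's rotated set about the b-c bond so that the a-b-c-d
#' torsion equals \code{angle}; atoms outside the rotated set never move.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param dihedral a [Dihedral-class].
#' @param angle target angle, degrees.
#' @return the updated coordinate matrix.
#' @export
setDihedralAngle <- function(xyz, dihedral, angle) {
  delta <- angle - dihedralAngle(xyz, dihedral)
  rotateDihedral(xyz, dihedral, delta)
}

#' Rotate a dihedral by an angular increment
#'
#' @inheritParams setDihedralAngle
#' @param delta rotation increment, degrees (positive increases the measured
#'   torsion angle).
#' @return the updated coordinate matrix.
#' @export
rotateDihedral <- function(xyz, dihedral, delta) {
  a <- dihedral@atoms
  axis <- xyz[a[3], ] - xyz[a[2], ]
  ## a right-hand rotation of the far side about b->c decreases the
  ## measured torsion, hence the sign flip
  R <- axisAngleMatrix(axis, -delta)
  set <- dihedral@rotatedSet
  pivot <- xyz[a[2], ]
  xyz[set, ] <- sweep(sweep(xyz[set, , drop = FALSE], 2, pivot) %*% t(R),
                      2, pivot, "+")
  xyz
}
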