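## Bias terms: pharmacophore tolerance spheres, tethered templates, cavity
## containment and distance (NOE-style) restraints. Penalty proportionality
## constants default to 1 per restraint and are overridable per restraint.
## Tether bounds are enforced by the search's randomisation and mutation
## operators, not by a soft penalty; tetherViolation() exists to verify
## emitted poses.

#' Construct a pharmacophore restraint
#'
#' @param featureType one of [ph4FeatureTypes()].
#' @param center 3-vector, Angstroms.
#' @param radius tolerance sphere radius, Angstroms.
#' @param mandatory logical (default TRUE).
#' @param weight penalty constant (default 1).
#' @return a [PharmacophoreRestraint-class].
#' @export
pharmacophoreRestraint <- function(featureType, center, radius,
                                   mandatory = TRUE, weight = 1) {
  new("PharmacophoreRestraint", featureType = featureType,
      center = as.numeric(center), radius = radius,
      mandatory = mandatory, weight = weight)
}

#' Construct a restraint set
#'
#' @param pharmacophores list of [PharmacophoreRestraint-class].
#' @param nOpt number of optional pharmacophore restraints that must be met.
#' @param tether a [TetherSpec-class] or NULL.
#' @param distanceRestraints list of [DistanceRestraint-class].
#' @param cavityWeight weight of the cavity containment penalty (default 1).
#' @return a [RestraintSet-class].
#' @export
restraintSet <- function(pharmacophores = list(), nOpt = 0,
                         tether = NULL, distanceRestraints = list(),
                         cavityWeight = 1) {
  new("RestraintSet", pharmacophores = pharmacophores,
      nOpt = as.integer(nOpt), tether = tether,
      distanceRestraints = distanceRestraints, cavityWeight = cavityWeight)
}

#' Construct a tether specification
#'
#' @param smarts substructure query (SMARTS subset, see [parseSmarts()]).
#' @param referenceCoords k x 3 matrix of reference coordinates in
#'   query-atom order.
#' @param transTol,rotTol maximum substructure centre-of-mass translation
#'   (Angstroms) and rotation (degrees) allowed during docking.
#' @return a [TetherSpec-class].
#' @export
tetherSpec <- function(smarts, referenceCoords, transTol = 0.1,
                       rotTol = 1.0) {
  parseSmarts(smarts)  # validate before any docking
  new("TetherSpec", smarts = smarts,
      referenceCoords = as.matrix(referenceCoords),
      transTol = transTol, rotTol = rotTol)
}

#' Construct a distance restraint
#'
#' @param ligandAtoms,receptorAtoms integer atom index vectors; only the
#'   minimum-distance pair across the two selections is penalised.
#' @param bound distance bound, Angstroms.
#' @param weight penalty weight.
#' @param semantics "upper" (default, NOE-style) or "lower".
#' @return a [DistanceRestraint-class].
#' @export
distanceRestraint <- function(ligandAtoms, receptorAtoms, bound,
                              weight = 1, semantics = "upper") {
  if (!length(ligandAtoms) || !length(receptorAtoms))
    stop("empty atom selector in distance restraint")
  new("DistanceRestraint", ligandSelector = as.integer(ligandAtoms),
      receptorSelector = as.integer(receptorAtoms), bound = bound,
      weight = weight, semantics = semantics)
}

## feature candidates as atom indices / ring indices per feature type
featureCandidates <- function(lig) {
  mol <- if (is(lig, "Ligand")) molecule(lig) else lig
  at <- mol@atoms
  heavy <- which(at$element != "H")
  arom <- aromaticAtomMask(mol)
  donors <- donorHeavyAtoms(mol)
  aromRings <- which(vapply(mol@rings, function(r) all(arom[r]), logical(1)))
  apolar <- heavy[at$iclass[heavy] == "apolar"]
  list(
    hba = list(atoms = intersect(which(at$iclass == "acceptor"),
                                 which(at$chargeFlag == "neutral")),
               rings = integer()),
    hbd = list(atoms = donors[at$chargeFlag[donors] == "neutral"],
               rings = integer()),
    hydrophobic = list(atoms = apolar, rings = integer()),
    aliphatic = list(atoms = apolar[!arom[apolar]], rings = integer()),
    aromatic = list(atoms = integer(), rings = aromRings),
    negative = list(atoms = heavy[at$chargeFlag[heavy] == "neg"],
                    rings = integer()),
    positive = list(atoms = heavy[at$chargeFlag[heavy] == "pos"],
                    rings = integer()),
    any = list(atoms = heavy, rings = integer()))
}

#' Detect pharmacophore features of a ligand
#'
#' Feature types: neutral hydrogen-bond acceptors and donors (heavy-atom
#' centres), hydrophobic (apolar heavy atoms), hydrophobic aliphatic
#' (non-aromatic subset), hydrophobic aromatic (aromatic ring centroids),
#' negatively and positively charged centres, and any heavy atom.
#'
#' @param lig a [Ligand-class] or [Molecule-class].
#' @return named list mapping each feature type to a (possibly empty)
#'   n x 3 matrix of feature positions.
#' @export
detectFeatures <- function(lig) {
  mol <- if (is(lig, "Ligand")) molecule(lig) else lig
  xyz <- coords(mol)
  cand <- featureCandidates(lig)
  lapply(cand, function(cc) {
    pos <- xyz[cc$atoms, , drop = FALSE]
    if (length(cc$rings)) {
      cent <- t(vapply(mol@rings[cc$rings],
                       function(r) colMeans(xyz[r, , drop = FALSE]),
                       numeric(3)))
      pos <- rbind(pos, cent)
    }
    unname(pos)
  })
}

#' Pharmacophore restraint penalty
#'
#' For each restraint the distance from the nearest matching ligand feature
#' to the sphere surface is squared and weighted; features inside the sphere
#' contribute zero. The total is the sum over mandatory restraints plus the
#' \code{nOpt} lowest-scoring optional restraints.
#'
#' @param features output of [detectFeatures()] for the posed ligand, or a
#'   posed [Ligand-class].
#' @param rs a [RestraintSet-class].
#' @return penalty, score units; a required feature type with no features at
#'   all contributes +Inf with a warning (such ligands should have been
#'   screened out).
#' @export
pharmacophorePenalty <- function(features, rs) {
  if (is(features, "Ligand")) features <- detectFeatures(features)
  mand <- 0
  opt <- numeric()
  for (r in rs@pharmacophores) {
    pos <- features[[r@featureType]]
    if (is.null(pos) || nrow(pos) == 0) {
      warning("ligand has no '", r@featureType,
              "' feature for a pharmacophore restraint")
      pen <- Inf
    } else {
      d <- sqrt(colSums((t(pos) - r@center)^2))
      excess <- max(0, min(d) - r@radius)
      pen <- r@weight * excess^2
    }
    if (r@mandatory) mand <- mand + pen else opt <- c(opt, pen)
  }
  mand + sum(sort(opt)[seq_len(min(rs@nOpt, length(opt)))])
}

#' Screen a ligand against a restraint set before docking
#'
#' A ligand is dockable when, for every feature type, its feature count is
#' at least the number of mandatory restraints of that type, and at least
#' \code{nOpt} optional restraints have a matching feature in the best case.
#'
#' @param lig a [Ligand-class].
#' @param rs a [RestraintSet-class].
#' @return TRUE when the ligand can satisfy the restraint set.
#' @export
screenLigandFeatures <- function(lig, rs) {
  feats <- detectFeatures(lig)
  counts <- vapply(feats, nrow, integer(1))
  types <- vapply(rs@pharmacophores, slot, "", "featureType")
  mandatory <- vapply(rs@pharmacophores, slot, logical(1), "mandatory")
  for (t in unique(types[mandatory])) {
    if (counts[[t]] < sum(types == t & mandatory)) return(FALSE)
  }
  satisfiable <- sum(counts[types[!mandatory]] >= 1)
  satisfiable >= rs@nOpt
}

#' Match a tether query and replicate multi-match ligands
#'
#' Ligands without a substructure match are dropped (with a message); a
#' ligand with several geometrically distinct matches appears once per
#' match, so that every possible substructure alignment is docked.
#'
#' @param ligands list of [Ligand-class].
#' @param spec a [TetherSpec-class].
#' @return list of entries \code{list(ligand =, mapping =)} where
#'   \code{mapping[k]} is the ligand atom matched by query atom k.
#' @export
matchAndReplicate <- function(ligands, spec) {
  if (is(ligands, "Ligand")) ligands <- list(ligands)
  query <- parseSmarts(spec@smarts)
  out <- list()
  for (lig in ligands) {
    matches <- matchSmarts(lig, query)
    if (!length(matches)) {
      message("tether: no substructure match for ligand '",
              molName(lig), "' - rejected")
      next
    }
    for (m in matches)
      out[[length(out) + 1L]] <- list(ligand = lig, mapping = m)
  }
  out
}

#' Prealign a matched ligand onto the tether reference coordinates
#'
#' Least-squares rigid superposition (Kabsch) of the matched substructure
#' atoms onto the reference coordinates, applied to the whole molecule.
#'
#' @param lig a [Ligand-class].
#' @param mapping integer vector from [matchAndReplicate()].
#' @param spec a [TetherSpec-class].
#' @return the transformed [Ligand-class].
#' @export
prealign <- function(lig, mapping, spec) {
  ref <- spec@referenceCoords
  if (length(mapping) < 3) stop("tether needs >= 3 matched atoms")
  X <- coords(lig)[mapping, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  if (qr(Xc)$rank < 2)
    stop("matched tether atoms are collinear: orientation under-determined")
  fit <- kabsch(X, ref)
  all <- coords(lig)
  allNew <- sweep(sweep(all, 2, fit$centerX) %*% t(fit$R), 2, fit$centerY,
                  "+")
  coords(lig) <- allNew
  lig
}

#' Tether deviation of a pose
#'
#' @param pose a posed [Ligand-class] (or n x 3 coordinate matrix).
#' @param spec a [TetherSpec-class].
#' @param mapping integer mapping from [matchAndReplicate()].
#' @return named numeric: \code{trans} = substructure centre-of-mass
#'   deviation (Angstroms), \code{rot} = angle of the optimal rigid rotation
#'   between the substructure and the reference (degrees).
#' @export
tetherViolation <- function(pose, spec, mapping) {
  X <- if (is(pose, "Ligand")) coords(pose) else as.matrix(pose)
  X <- X[mapping, , drop = FALSE]
  ref <- spec@referenceCoords
  trans <- sqrt(sum((colMeans(X) - colMeans(ref))^2))
  fit <- kabsch(X, ref)
  c(trans = trans, rot = rotationAngle(fit$R))
}

#' Cavity containment penalty
#'
#' Sum over ligand heavy atoms of the squared distance to the docking
#' volume (zero for atoms inside), weighted.
#'
#' @param pose a posed [Ligand-class] (or coordinate matrix with an
#'   \code{elements} attribute handled by the caller).
#' @param grid a [CavityGrid-class].
#' @param W penalty weight (default 1).
#' @return penalty, score units; zero iff every heavy atom is inside.
#' @export
cavityPenalty <- function(pose, grid, W = 1) {
  X <- coords(pose)[isHeavy(pose), , drop = FALSE]
  d <- distanceToCavity(grid, X)
  W * sum(d^2)
}

#' Distance (NOE-style) restraint penalty
#'
#' The minimum distance over all selected ligand/receptor atom pairs is
#' compared with the bound; the excess (upper semantics) or shortfall
#' (lower semantics) is squared and weighted.
#'
#' @param pose a posed [Ligand-class].
#' @param rec a [Receptor-class].
#' @param dr a [DistanceRestraint-class].
#' @return penalty, score units.
#' @export
nmrDistancePenalty <- function(pose, rec, dr) {
  XL <- coords(pose)[dr@ligandSelector, , drop = FALSE]
  XR <- coords(rec)[dr@receptorSelector, , drop = FALSE]
  d2 <- outer(rowSums(XL^2), rowSums(XR^2), "+") - 2 * XL %*% t(XR)
  d <- sqrt(max(0, min(d2)))
  v <- if (dr@semantics == "upper") d - dr@bound else dr@bound - d
  if (v > 0) dr@weight * v^2 else 0
}

#' Read a pharmacophore restraint file
#'
#' Plain-text format: an optional \code{NOPT n} header line, then one
#' restraint per line: \code{x y z radius type [MANDATORY|OPTIONAL]}
#' (type from [ph4FeatureTypes()]; default MANDATORY).
#'
#' @param path file path.
#' @param cavityWeight passed through to [restraintSet()].
#' @return a [RestraintSet-class].
#' @export
readPharmacophores <- function(path, cavityWeight = 1) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nOpt <- 0L
  ph <- list()
  for (ln in lines) {
    toks <- strsplit(ln, "\\s+")[[1]]
    if (toupper(toks[1]) == "NOPT") {
      nOpt <- as.integer(toks[2])
      next
    }
    if (length(toks) < 5) stop("bad restraint line: ", ln)
    mand <- length(toks) < 6 || toupper(toks[6]) != "OPTIONAL"
    ph[[length(ph) + 1L]] <- pharmacophoreRestraint(
      featureType = toks[5], center = as.numeric(toks[1:3]),
      radius = as.numeric(toks[4]), mandatory = mand)
  }
  restraintSet(pharmacophores = ph, nOpt = nOpt,
               cavityWeight = cavityWeight)
}
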