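## A dock context caches everything constant across pose evaluations of one
## ligand / receptor / cavity / restraint combination and hands it to the
## C++ kernels behind an external pointer. scorePose() is the user-facing
## single-pose entry; the search module evaluates chromosomes against the
## same context.

graphDistances <- function(mol, cap = 99L) {
  n <- nAtoms(mol)
  if (n == 0) return(matrix(integer(), 0, 0))
  if (nrow(mol@bonds) == 0) {
    d <- matrix(cap, n, n); diag(d) <- 0L
    storage.mode(d) <- "integer"
    return(d)
  }
  d <- igraph::distances(moleculeGraph(mol))
  d[!is.finite(d)] <- cap
  d <- d[as.character(seq_len(n)), as.character(seq_len(n))]
  storage.mode(d) <- "integer"
  unname(d)
}

## Atoms connected without crossing any rotatable central bond move as one
## rigid unit; vdW pairs inside a unit are constant and skipped.
rigidUnitLabels <- function(mol, dihedrals) {
  g <- moleculeGraph(mol)
  for (dh in dihedrals) {
    eid <- igraph::get_edge_ids(g, as.character(dh@atoms[2:3]))
    eid <- eid[eid > 0]
    if (length(eid)) g <- igraph::delete_edges(g, eid)
  }
  comp <- igraph::components(g)$membership
  unname(comp[as.character(seq_len(nAtoms(mol)))])
}

polarSiteTable <- function(mol) {
  dp <- donorHPairs(mol)
  ar <- acceptorRoots(mol)
  metals <- which(mol@atoms$iclass == "metal")
  atom <- c(dp$d, ar$a, metals)
  aux <- c(dp$h, ar$root, rep(0L, length(metals)))
  kind <- c(rep(0L, nrow(dp)), rep(1L, nrow(ar)), rep(2L, length(metals)))
  charged <- mol@atoms$chargeFlag[atom] != "neutral"
  ## atoms acting as both donor and acceptor (hydroxyl O, amine N with H)
  ## are exempt from same-polarity repulsion
  ambi <- atom %in% intersect(dp$d, ar$a)
  list(atom = as.integer(atom), aux = as.integer(aux),
       kind = as.integer(kind), charged = as.logical(charged),
       ambi = as.logical(ambi))
}

dihedralSpecList <- function(mol, dihedrals) {
  el <- mol@atoms$element
  lapply(dihedrals, function(dh) {
    list(atoms = dh@atoms, set = dh@rotatedSet,
         barrier = torsionBarrierFor(el[dh@atoms[2]], el[dh@atoms[3]]))
  })
}

vdwPairList <- function(mol, dist, units, scale14) {
  n <- nAtoms(mol)
  p <- vdwAtomParams(mol@atoms$element, mol@atoms$iclass)
  i <- integer(); j <- integer()
  if (n >= 2) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    gd <- dist[idx]
    sameUnit <- units[idx[, 1]] == units[idx[, 2]]
    keep <- gd >= 3 & !sameUnit
    idx <- idx[keep, , drop = FALSE]
    i <- idx[, 1]; j <- idx[, 2]
    gd <- gd[keep]
  } else {
    gd <- integer()
  }
  list(i = as.integer(i), j = as.integer(j),
       r0 = p$radius[i] + p$radius[j],
       eps = sqrt(p$eps[i] * p$eps[j]),
       scale = ifelse(gd == 3, scale14, 1))
}

## receptor pairs involving at least one moving atom (flexible torsions)
sitePairList <- function(mol, dihedrals, dist, scale14) {
  moving <- sort(unique(unlist(lapply(dihedrals, slot, "rotatedSet"))))
  if (!length(moving))
    return(list(i = integer(), j = integer(), r0 = numeric(),
                eps = numeric(), scale = numeric()))
  ## unit labels with the flexible bonds removed
  units <- rigidUnitLabels(mol, dihedrals)
  p <- vdwAtomParams(mol@atoms$element, mol@atoms$iclass)
  n <- nAtoms(mol)
  ii <- integer(); jj <- integer(); gg <- integer()
  for (a in moving) {
    for (b in seq_len(n)) {
      if (b <= a && b %in% moving) next  # avoid double counting
      if (b == a) next
      if (units[a] == units[b]) next
      if (dist[a, b] < 3) next
      ii <- c(ii, a); jj <- c(jj, b); gg <- c(gg, dist[a, b])
    }
  }
  list(i = as.integer(ii), j = as.integer(jj),
       r0 = p$radius[ii] + p$radius[jj],
       eps = sqrt(p$eps[ii] * p$eps[jj]),
       scale = ifelse(gg == 3, scale14, 1))
}

configForContext <- function(cfg) {
  w <- cfg@weights
  list(inter = w[["inter"]], intra = w[["intra"]], site = w[["site"]],
       restraint = w[["restraint"]], vdw = w[["vdw"]],
       polar = w[["polar"]], desolv = w[["desolv"]],
       dihedral = w[["dihedral"]], vdwCap = cfg@vdwCap,
       polarLo = cfg@polarDistWindow[1], polarHi = cfg@polarDistWindow[2],
       polarDistTol = cfg@polarDistTol,
       donorAngleEdge = polarAngleEdges[["donor"]],
       acceptorAngleEdge = polarAngleEdges[["acceptor"]],
       polarAngleTol = cfg@polarAngleTol,
       chargedScale = cfg@chargedScale)
}

stageVector <- function(cfg, useGrid = FALSE) {
  ex <- vdwFormExponents(cfg@vdwForm)
  c(ex[["n"]], ex[["m"]], cfg@toleranceScale, cfg@dihedralWeightScale,
    as.numeric(cfg@polarMode == "attractive+repulsive"),
    as.numeric(cfg@useDesolvation), as.numeric(useGrid))
}

gridSetForContext <- function(grids, lig) {
  if (is.null(grids)) return(NULL)
  ml <- molecule(lig)
  key <- vdwClassKey(ml@atoms$element, ml@atoms$iclass)
  cls <- match(key, names(grids@grids))
  if (anyNA(cls))
    stop("grid set lacks classes for: ",
         paste(unique(key[is.na(cls)]), collapse = ", "))
  list(origin = grids@origin, spacing = grids@spacing,
       dims = grids@dims, grids = unname(grids@grids),
       atomClass = as.integer(cls))
}

#' Build a docking evaluation context
#'
#' Precomputes pair parameters, polar site tables, exclusion masks,
#' restraint candidates and the intramolecular reference energies of the
#' input conformation. The returned object is consumed by [scorePose()],
#' [dock()] and the other search entry points.
#'
#' @param lig input [Ligand-class] (its coordinates define the reference
#'   conformation for the relative intramolecular score).
#' @param rec a [Receptor-class].
#' @param cfg a [ScoringConfig-class].
#' @param cavity optional [CavityGrid-class] (enables the cavity penalty and
#'   COM sampling).
#' @param restraints optional [RestraintSet-class].
#' @param grids optional list with elements \code{"6-12"} and/or
#'   \code{"4-8"}, each a [VdwGridSet-class], enabling grid-mode
#'   intermolecular vdW.
#' @param tetherAtoms optional integer vector of ligand atoms held by the
#'   tether (normally supplied by [dock()] from the tether mapping).
#' @return a dock context (list with the external pointer and layout
#'   metadata).
#' @export
dockContext <- function(lig, rec, cfg = scoringConfig(), cavity = NULL,
                        restraints = NULL, grids = NULL,
                        tetherAtoms = NULL) {
  if (is(grids, "VdwGridSet"))
    grids <- stats::setNames(list(grids), cfg@vdwForm)
  ml <- molecule(lig); mr <- molecule(rec)
  ligDihedrals <- rotatableDihedrals(lig)
  tethered <- !is.null(tetherAtoms) && length(tetherAtoms) > 0
  frozen <- logical(length(ligDihedrals))
  if (tethered) {
    allAtoms <- seq_len(nAtoms(ml))
    adjusted <- list()
    for (k in seq_along(ligDihedrals)) {
      dh <- ligDihedrals[[k]]
      inSet <- tetherAtoms %in% dh@rotatedSet
      if (all(inSet)) {
        ## flip: rotate the complement side instead
        comp <- setdiff(allAtoms, dh@rotatedSet)
        dh <- Dihedral(rev(dh@atoms), comp)
        inSet <- tetherAtoms %in% dh@rotatedSet
      }
      if (any(inSet)) frozen[k] <- TRUE else adjusted[[length(adjusted) + 1]] <- dh
    }
    ligDihedrals <- adjusted
  }
  recDihedrals <- flexibleDihedrals(rec)
  distL <- graphDistances(ml)
  unitsL <- rigidUnitLabels(ml, ligDihedrals)
  pairPar <- vdwPairParams(ml@atoms$element, mr@atoms$element,
                           ml@atoms$iclass, mr@atoms$iclass)
  distR <- graphDistances(mr)

  rs <- if (is.null(restraints)) new("RestraintSet") else restraints
  ph4 <- lapply(rs@pharmacophores, function(r) {
    cand <- featureCandidates(lig)[[r@featureType]]
    list(center = r@center, radius = r@radius, weight = r@weight,
         mandatory = r@mandatory, atoms = as.integer(cand$atoms),
         rings = as.integer(cand$rings))
  })
  distRes <- lapply(rs@distanceRestraints, function(r) {
    list(lig = r@ligandSelector, rec = r@receptorSelector, bound = r@bound,
         weight = r@weight, upper = r@semantics == "upper")
  })

  desolv <- NULL
  if (cfg@useDesolvation) {
    pl <- elementParamRow(ml@atoms$element)
    pr <- elementParamRow(mr@atoms$element)
    desolv <- list(radL = pl$radius, radR = pr$radius,
                   pL = pl$haselP, pR = pr$haselP,
                   wL = desolvWeightByClass(ml@atoms$iclass),
                   wR = desolvWeightByClass(mr@atoms$iclass),
                   rsolv = 1.4, recDist = distR)
  }

  cavPts <- if (is.null(cavity)) matrix(0, 0, 3) else cavity@cavityPoints
  cavSpacing <- if (is.null(cavity)) 0.5 else cavity@spacing
  cavWeight <- if (is.null(cavity)) 0 else rs@cavityWeight

  args <- list(
    L0 = coords(ml), Rec0 = coords(mr),
    ligDih = dihedralSpecList(ml, ligDihedrals),
    recDih = dihedralSpecList(mr, recDihedrals),
    ligHeavy = which(isHeavy(ml)),
    R0pair = pairPar$r0, EPSpair = pairPar$eps,
    intraPairs = vdwPairList(ml, distL, unitsL, cfg@scale14),
    sitePairs = sitePairList(mr, recDihedrals, distR, cfg@scale14),
    ligPolar = polarSiteTable(ml), recPolar = polarSiteTable(mr),
    ligDist = distL, config = configForContext(cfg),
    desolv = desolv, rings = ml@rings, ph4 = ph4, nOpt = rs@nOpt,
    distRestraints = distRes, cavPts = cavPts, cavSpacing = cavSpacing,
    cavWeight = cavWeight, tethered = tethered,
    tetherAtoms = if (tethered) as.integer(tetherAtoms) else integer(),
    grid48 = gridSetForContext(grids[["4-8"]], lig),
    grid612 = gridSetForContext(grids[["6-12"]], lig))
  ptr <- cpp_build_context(args)
  cpp_finalize_context(ptr)
  structure(list(ptr = ptr, lig = lig, rec = rec, cfg = cfg,
                 cavity = cavity, restraints = rs,
                 ligDihedrals = ligDihedrals, recDihedrals = recDihedrals,
                 frozenDihedrals = frozen, tethered = tethered,
                 tetherAtoms = tetherAtoms,
                 nChrom = 6L + length(ligDihedrals) + length(recDihedrals),
                 hasGrids = !is.null(grids)),
            class = "dockContext")
}

#' @export
print.dockContext <- function(x, ...) {
  cat(sprintf(
    "dockContext: ligand %d atoms (%d free dihedrals%s), receptor %d atoms (%d dihedrals)\n",
    nAtoms(x$lig), length(x$ligDihedrals),
    if (x$tethered) ", tethered" else "", nAtoms(x$rec),
    length(x$recDihedrals)))
  invisible(x)
}

breakdownFromVector <- function(v, cfg) {
  new("ScoreBreakdown", total = v[["total"]], inter = v[["inter"]],
      intra = v[["intra"]], site = v[["site"]],
      restraint = v[["restraint"]], terms = v[-(1:5)],
      weights = cfg@weights[c("inter", "intra", "site", "restraint")])
}

#' Score a ligand pose
#'
#' Evaluates the composite scoring function for one pose: intermolecular
#' (vdW + polar, plus desolvation under SF5), ligand intramolecular and
#' flexible-site terms relative to the input conformations, and the
#' restraint penalties. A rigid ligand has zero intramolecular score in
#' every pose by construction.
#'
#' @param pose a [Ligand-class] carrying the pose coordinates, or an n x 3
#'   coordinate matrix.
#' @param context a context from [dockContext()]; alternatively pass
#'   \code{rec}, \code{cfg}, \code{cavity}, \code{restraints}, \code{grids}
#'   and a context is built with \code{pose} as the input conformation.
#' @param rec,cfg,cavity,restraints,grids see [dockContext()].
#' @param recDihAngles receptor flexible torsion angles, degrees (default:
#'   input angles).
#' @param useGrid evaluate intermolecular vdW from the precalculated grids.
#' @return a [ScoreBreakdown-class].
#' @export
scorePose <- function(pose, context = NULL, rec = NULL,
                      cfg = scoringConfig(), cavity = NULL,
                      restraints = NULL, grids = NULL,
                      recDihAngles = NULL, useGrid = FALSE) {
  if (is.null(context)) {
    if (is.null(rec)) stop("either a context or a receptor is required")
    if (!is(pose, "Ligand")) stop("pose must be a Ligand when no context is given")
    context <- dockContext(pose, rec, cfg, cavity, restraints, grids)
  }
  if (missing(cfg)) cfg <- context$cfg
  if (useGrid && !context$hasGrids)
    stop("grid-mode scoring requested but the context has no grids")
  X <- if (is(pose, "Ligand")) coords(pose) else as.matrix(pose)
  if (is.null(recDihAngles)) {
    recDihAngles <- vapply(context$recDihedrals,
                           function(dh) dihedralAngle(coords(context$rec), dh),
                           numeric(1))
  }
  v <- cpp_score_coords(context$ptr, X, as.numeric(recDihAngles),
                        stageVector(cfg, useGrid))
  breakdownFromVector(v, context$cfg)  # component weights are baked in
}

#' Precalculate receptor vdW grids
#'
#' One scalar lattice per ligand interaction class (element), each value the
#' capped sum of pair vdW energies between a probe atom of that class at the
#' lattice point and all receptor atoms (Lorentz-Berthelot mixing). Lookup
#' during scoring is trilinear.
#'
#' @param rec a [Receptor-class].
#' @param cavity a [CavityGrid-class]; the lattice covers its bounding box
#'   plus \code{margin}.
#' @param spacing lattice spacing, Angstroms (default 0.3).
#' @param cfg a [ScoringConfig-class] (supplies the functional form and cap).
#' @param classes ligand vdW classes to precompute (default: C, N, O, H,
#'   polar H, S, F, Cl).
#' @param margin bounding-box margin, Angstroms.
#' @return a [VdwGridSet-class].
#' @export
buildVdwGrids <- function(rec, cavity, spacing = 0.3,
                          cfg = scoringConfig(),
                          classes = c("C", "N", "O", "H", "H.polar", "S",
                                      "F", "Cl"),
                          margin = 3) {
  stopifnot(is(cavity, "CavityGrid"))
  pts <- cavity@cavityPoints
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  gx <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  lattice <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  mr <- molecule(rec)
  recPar <- vdwAtomParams(mr@atoms$element, mr@atoms$iclass)
  ex <- vdwFormExponents(cfg@vdwForm)
  grids <- list()
  for (cl in classes) {
    p <- vdwAtomParams(cl)
    vals <- cpp_vdw_field(lattice, coords(mr),
                          p$radius + recPar$radius,
                          sqrt(p$eps * recPar$eps),
                          ex[["n"]], ex[["m"]], cfg@vdwCap)
    grids[[cl]] <- array(vals, dim = dims)
  }
  if (nAtoms(mr) == 0)
    grids <- lapply(grids, function(g) array(0, dim = dims))
  new("VdwGridSet", origin = as.numeric(lo), spacing = spacing,
      dims = dims, grids = grids)
}
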