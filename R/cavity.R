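## Docking-volume definition. Two mappers: the accessible volume within a
## given distance of a reference ligand, and a two-probe-sphere method in
## which a small probe defines reachable space and a large probe rolled in
## from the search-sphere boundary defines open (bulk-solvent) space that is
## excluded. Both produce a CavityGrid with an exact distance transform.

latticeCoords <- function(origin, dims, spacing) {
  gx <- origin[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- origin[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  as.matrix(expand.grid(x = gx, y = gy, z = gz))
}

## distance-based mask: TRUE where any centre is within its radius
withinRadiusMask <- function(pts, centres, radii) {
  out <- logical(nrow(pts))
  if (!is.null(dim(centres)) && nrow(centres) == 0) return(out)
  centres <- matrix(centres, ncol = 3)
  radii <- rep_len(radii, nrow(centres))
  for (k in seq_len(nrow(centres))) {
    d2 <- (pts[, 1] - centres[k, 1])^2 + (pts[, 2] - centres[k, 2])^2 +
      (pts[, 3] - centres[k, 3])^2
    out <- out | (d2 <= radii[k]^2)
  }
  out
}

## connected components of a logical lattice (6-connectivity); returns an
## integer array of labels (0 outside)
latticeComponents <- function(inside, dims) {
  lab <- integer(length(inside))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nxy <- nx * ny
  remaining <- which(inside)
  cur <- 0L
  insideV <- as.logical(inside)
  while (length(remaining)) {
    cur <- cur + 1L
    frontier <- remaining[1]
    lab[frontier] <- cur
    while (length(frontier)) {
      i0 <- ((frontier - 1L) %% nx)
      j0 <- ((frontier - 1L) %/% nx) %% ny
      k0 <- (frontier - 1L) %/% nxy
      nbrs <- c(frontier[i0 > 0] - 1L, frontier[i0 < nx - 1L] + 1L,
                frontier[j0 > 0] - nx, frontier[j0 < ny - 1L] + nx,
                frontier[k0 > 0] - nxy, frontier[k0 < nz - 1L] + nxy)
      nbrs <- unique(nbrs)
      nbrs <- nbrs[insideV[nbrs] & lab[nbrs] == 0L]
      lab[nbrs] <- cur
      frontier <- nbrs
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  array(lab, dim = dims)
}

newCavityGrid <- function(origin, dims, spacing, insideArr) {
  pts <- latticeCoords(origin, dims, spacing)
  cav <- pts[as.logical(insideArr), , drop = FALSE]
  dl <- array(cpp_distance_lattice(as.logical(insideArr), dims, spacing),
              dim = dims)
  new("CavityGrid", origin = as.numeric(origin), spacing = spacing,
      dims = as.integer(dims), inside = array(insideArr, dim = dims),
      distanceLattice = dl, cavityPoints = unname(as.matrix(cav)))
}

#' Map the docking volume around a reference ligand
#'
#' A grid point belongs to the cavity when it lies within \code{radius} of a
#' reference-ligand heavy atom and is sterically accessible (no receptor
#' heavy atom closer than its vdW radius plus the probe allowance).
#' Connected components that do not overlap the reference ligand are
#' discarded.
#'
#' @param rec a [Receptor-class].
#' @param ref the reference [Ligand-class] (>= 1 heavy atom).
#' @param radius mapping distance, Angstroms (default 6, the standard
#'   reference-ligand distance).
#' @param spacing lattice spacing, Angstroms (default 0.5).
#' @param probe steric probe allowance, Angstroms (default 1.4).
#' @return a [CavityGrid-class]; an empty cavity is an error.
#' @export
mapReferenceLigand <- function(rec, ref, radius = 6, spacing = 0.5,
                               probe = 1.4) {
  stopifnot(radius > 0, spacing > 0)
  mref <- molecule(ref)
  refXYZ <- coords(mref)[isHeavy(mref), , drop = FALSE]
  if (nrow(refXYZ) == 0) stop("reference ligand has no heavy atoms")
  origin <- apply(refXYZ, 2, min) - radius - spacing
  hi <- apply(refXYZ, 2, max) + radius + spacing
  dims <- as.integer(ceiling((hi - origin) / spacing)) + 1L
  pts <- latticeCoords(origin, dims, spacing)
  nearRef <- withinRadiusMask(pts, refXYZ, radius)
  mr <- molecule(rec)
  heavyR <- which(isHeavy(mr))
  blocked <- logical(nrow(pts))
  if (length(heavyR)) {
    radii <- vdwAtomParams(mr@atoms$element[heavyR])$radius + probe
    blocked <- withinRadiusMask(pts, coords(mr)[heavyR, , drop = FALSE],
                                radii)
  }
  inside <- nearRef & !blocked
  if (!any(inside)) stop("no accessible volume within ", radius,
                         " A of the reference ligand")
  insideArr <- array(inside, dim = dims)
  lab <- latticeComponents(insideArr, dims)
  nearTouch <- withinRadiusMask(pts, refXYZ, 2.0)
  keep <- unique(lab[nearTouch & inside])
  keep <- keep[keep > 0]
  if (length(keep)) insideArr[!(lab %in% keep)] <- FALSE
  if (!any(insideArr)) stop("no accessible volume overlapping the reference ligand")
  if (sum(insideArr) < 10)
    warning("near-empty cavity (", sum(insideArr), " grid points)")
  newCavityGrid(origin, dims, spacing, insideArr)
}

#' Map a cavity with the two-probe-sphere method
#'
#' Points reachable by the small probe but sheltered from bulk solvent:
#' lattice points where a large probe can sit define candidate open space;
#' the subset connected to the search-box boundary is dilated by the large
#' probe radius to give the open (bulk) region. The cavity is the
#' small-probe-accessible space outside the open region, within the search
#' sphere around \code{center}.
#'
#' @param rec a [Receptor-class].
#' @param center 3-vector, search sphere centre (Angstroms).
#' @param searchRadius search sphere radius (default 10).
#' @param rLarge large probe radius (default 6.0); must exceed
#'   \code{rSmall}.
#' @param rSmall small probe radius (default 1.5).
#' @param spacing lattice spacing (default 0.5).
#' @return a [CavityGrid-class]; no sheltered volume is an error.
#' @export
mapTwoSphere <- function(rec, center, searchRadius = 10, rLarge = 6.0,
                         rSmall = 1.5, spacing = 0.5) {
  if (!(rLarge > rSmall && rSmall > 0))
    stop("need rLarge > rSmall > 0")
  center <- as.numeric(center)
  origin <- center - searchRadius - spacing
  dims <- as.integer(ceiling(rep(2 * (searchRadius + spacing), 3) /
                               spacing)) + 1L
  pts <- latticeCoords(origin, dims, spacing)
  mr <- molecule(rec)
  heavyR <- which(isHeavy(mr))
  recXYZ <- coords(mr)[heavyR, , drop = FALSE]
  radii <- vdwAtomParams(mr@atoms$element[heavyR])$radius
  smallBlocked <- withinRadiusMask(pts, recXYZ, radii + rSmall)
  largeBlocked <- withinRadiusMask(pts, recXYZ, radii + rLarge)
  largeOK <- array(!largeBlocked, dim = dims)
  ## flood the large-probe centres from the box boundary
  lab <- latticeComponents(largeOK, dims)
  boundary <- array(FALSE, dim = dims)
  boundary[c(1, dims[1]), , ] <- TRUE
  boundary[, c(1, dims[2]), ] <- TRUE
  boundary[, , c(1, dims[3])] <- TRUE
  openLabels <- unique(lab[boundary & largeOK])
  openLabels <- openLabels[openLabels > 0]
  openCentre <- array(lab %in% openLabels, dim = dims)
  if (any(openCentre)) {
    dOpen <- cpp_distance_lattice(as.logical(openCentre), dims, spacing)
    open <- dOpen <= rLarge
  } else {
    open <- rep(FALSE, length(pts) / 3)
  }
  inSphere <- withinRadiusMask(pts, matrix(center, 1), searchRadius)
  inside <- !smallBlocked & !open & inSphere
  if (!any(inside))
    stop("no sheltered volume: empty cavity for the two-probe mapping")
  newCavityGrid(origin, dims, spacing, array(inside, dim = dims))
}

#' Distance from a point to the docking volume
#'
#' Zero when the point lies within half a lattice spacing of a cavity point,
#' otherwise the exact (brute-force) Euclidean distance to the nearest
#' cavity point. Points outside the lattice are allowed.
#'
#' @param grid a [CavityGrid-class].
#' @param p a 3-vector or an n x 3 matrix of points.
#' @return numeric vector of distances, Angstroms.
#' @export
distanceToCavity <- function(grid, p) {
  p <- if (is.null(dim(p))) matrix(p, 1) else as.matrix(p)
  d <- as.numeric(cpp_min_dist(grid@cavityPoints, p))
  d[d <= grid@spacing / 2] <- 0
  d
}

#' Write / read a cavity file
#'
#' Portable JSON container: a header with the lattice geometry and the
#' occupancy as a 0/1 vector in column-major order (first index fastest).
#'
#' @param grid a [CavityGrid-class].
#' @param path file path.
#' @return `writeCavity`: invisibly, the path; `readCavity`: the
#'   reconstructed [CavityGrid-class].
#' @export
writeCavity <- function(grid, path) {
  obj <- list(format = "moldock-cavity-1",
              origin = grid@origin, spacing = grid@spacing,
              dims = grid@dims, inside = as.integer(grid@inside))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCavity
#' @export
readCavity <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "moldock-cavity-1"))
    stop("not a cavity file: ", path)
  dims <- as.integer(obj$dims)
  newCavityGrid(as.numeric(obj$origin), dims, as.numeric(obj$spacing),
                array(as.logical(obj$inside), dim = dims))
}
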