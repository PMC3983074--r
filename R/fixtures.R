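## Synthetic toy systems with engineered optima. A toy complex is a closed
## (apart from a small aperture) spherical cage of carbon pseudo-atoms with
## hydrogen-bonding sites placed exactly complementary to the ligand's
## donors and acceptors in a designed pose, so the designed pose sits in a
## deep constructed funnel. Pseudo-atoms carry real element labels (C, N,
## O) so the typing rules apply unchanged; geometry is idealised.

## bond lengths (A)
BL <- c(CC = 1.54, CH = 1.09, CO = 1.43, COd = 1.22, OH = 0.96,
        CN = 1.47, NH = 1.01, CAr = 1.39)

unitv <- function(v) v / sqrt(sum(v^2))

anyPerp <- function(v) {
  v <- unitv(v)
  p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(p - sum(p * v) * v)
}

## n directions on a cone of given half-angle about -axis (for terminal
## hydrogens: angle is measured from the existing bond direction)
coneDirs <- function(axis, n, angleDeg = 109.47, phase = 0) {
  a <- unitv(axis)
  p <- anyPerp(a)
  q <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
         a[1] * p[2] - a[2] * p[1])
  t <- deg2rad(angleDeg)
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    ph <- deg2rad(phase + 360 * (k - 1) / n)
    out[k, ] <- a * cos(t) + sin(t) * (p * cos(ph) + q * sin(ph))
  }
  out
}

## the two remaining tetrahedral directions given two neighbour directions
tetraDirs <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  e1 <- unitv(-(a + b))
  n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  n <- unitv(n)
  beta <- deg2rad(54.735)
  rbind(e1 * cos(beta) + n * sin(beta),
        e1 * cos(beta) - n * sin(beta))
}

## incremental molecule builder used by the generators
newBuilder <- function() {
  env <- new.env(parent = emptyenv())
  env$el <- character(); env$xyz <- matrix(0, 0, 3)
  env$bi <- integer(); env$bj <- integer(); env$bo <- character()
  env$fc <- integer()
  env
}
addAtomB <- function(b, el, pos, fc = 0L) {
  b$el <- c(b$el, el)
  b$xyz <- rbind(b$xyz, as.numeric(pos))
  b$fc <- c(b$fc, as.integer(fc))
  length(b$el)
}
addBondB <- function(b, i, j, order = "1") {
  b$bi <- c(b$bi, i); b$bj <- c(b$bj, j); b$bo <- c(b$bo, order)
}
finishBuilder <- function(b, name) {
  buildMolecule(b$el, b$xyz,
                data.frame(i = b$bi, j = b$bj, order = b$bo,
                           stringsAsFactors = FALSE),
                formalCharges = b$fc, name = name)
}

bondOrderValue <- function(o) switch(o, "1" = 1, "2" = 2, "3" = 3,
                                     "ar" = 1.5, "am" = 1, 1)

## fill hydrogens so that valences are satisfied (C 4, N 3 (+charge), O 2)
fillHydrogens <- function(b) {
  valence <- c(C = 4, N = 3, O = 2, S = 2)
  n <- length(b$el)
  for (i in seq_len(n)) {
    e <- b$el[i]
    if (!e %in% names(valence)) next
    nb <- c(b$bj[b$bi == i], b$bi[b$bj == i])
    ords <- c(b$bo[b$bi == i], b$bo[b$bj == i])
    used <- sum(vapply(ords, bondOrderValue, numeric(1)))
    need <- round(valence[[e]] + b$fc[i] - used)
    if (need <= 0) next
    dirs <- t(apply(b$xyz[nb, , drop = FALSE], 1,
                    function(p) unitv(p - b$xyz[i, ])))
    blh <- if (e == "C") BL[["CH"]] else if (e == "N") BL[["NH"]]
           else BL[["OH"]]
    if (nrow(dirs) == 1) {
      hd <- coneDirs(dirs[1, ], need)
    } else if (nrow(dirs) == 2 && need >= 2) {
      hd <- tetraDirs(dirs[1, ], dirs[2, ])[seq_len(min(need, 2)), ,
                                            drop = FALSE]
    } else if (nrow(dirs) >= 2) {
      ## single H opposite the mean of all neighbour directions
      hd <- matrix(unitv(-colSums(dirs)), 1)
    } else {
      hd <- coneDirs(c(0, 0, 1), need)
    }
    for (k in seq_len(need)) {
      h <- addAtomB(b, "H", b$xyz[i, ] + blh * hd[min(k, nrow(hd)), ])
      addBondB(b, i, h)
    }
  }
  b
}

#' Generate a toy ligand with a controlled rotor and feature inventory
#'
#' Builds an all-anti zig-zag carbon chain decorated with one substituent
#' per interior carbon: hydroxyl (\code{"hbd"}: +1 heavy atom, +1 rotor),
#' carbonyl oxygen (\code{"hba"}: +1 heavy, rigid), ammonium
#' (\code{"positive"}: +1 heavy, +1 rotor, formal +1), carboxylate
#' (\code{"negative"}: +3 heavy, +1 rotor, formal -1) or phenyl
#' (\code{"aromatic"}: +6 heavy, +1 rotor); methyl pads absorb any heavy
#' atoms left over. Requested combinations that cannot be realised on such
#' a scaffold (wrong heavy-atom budget, not enough interior positions, or a
#' rotor count below the features' own rotors) are an error.
#'
#' @param seed integer seed (geometry jitter; the topology is
#'   deterministic).
#' @param nHeavy total heavy atoms (>= 1).
#' @param nRotatable exact number of rotatable dihedrals.
#' @param features character vector of feature types to install.
#' @return a [Ligand-class]; [perceiveRotatableDihedrals()] on it yields
#'   exactly \code{nRotatable} dihedrals.
#' @export
makeToyLigand <- function(seed, nHeavy, nRotatable = 0,
                          features = character()) {
  stopifnot(nHeavy >= 1)
  set.seed(seed)
  cost <- list(hbd = c(h = 1, r = 1), hba = c(h = 1, r = 0),
               positive = c(h = 1, r = 1), negative = c(h = 3, r = 1),
               aromatic = c(h = 6, r = 1), hydrophobic = c(h = 0, r = 0),
               aliphatic = c(h = 0, r = 0), any = c(h = 0, r = 0))
  bad <- setdiff(features, names(cost))
  if (length(bad)) stop("unsupported feature type(s): ",
                        paste(bad, collapse = ", "))
  features <- features[vapply(features, function(f) cost[[f]][["h"]] > 0,
                              logical(1))]
  fh <- sum(vapply(features, function(f) cost[[f]][["h"]], numeric(1)))
  fr <- sum(vapply(features, function(f) cost[[f]][["r"]], numeric(1)))
  rc <- nRotatable - fr
  if (rc < 0)
    stop("infeasible: features alone contribute more rotors than requested")
  nChain <- if (rc > 0) rc + 3 else max(1, min(3, nHeavy - fh))
  if (length(features) && nChain < 3) nChain <- 3
  pads <- nHeavy - fh - nChain
  if (pads < 0)
    stop("infeasible: heavy-atom budget too small for the requested ",
         "features/rotors")
  slots <- max(0, nChain - 2)
  if (length(features) + pads > slots)
    stop("infeasible: not enough interior positions (",
         slots, ") for ", length(features), " features + ", pads, " pads")

  b <- newBuilder()
  half <- deg2rad(35.264)
  step <- BL[["CC"]]
  chain <- integer(nChain)
  for (i in seq_len(nChain)) {
    pos <- c((i - 1) * step * cos(half),
             step * sin(half) * (i %% 2), 0)
    chain[i] <- addAtomB(b, "C", pos)
    if (i > 1) addBondB(b, chain[i - 1], chain[i])
  }
  interior <- if (nChain >= 3) chain[2:(nChain - 1)] else integer()
  jobs <- c(as.list(features), rep(list("pad"), pads))
  for (k in seq_along(jobs)) {
    ci <- interior[k]
    nb <- c(chain[match(ci, chain) - 1], chain[match(ci, chain) + 1])
    dirs <- tetraDirs(b$xyz[nb[1], ] - b$xyz[ci, ],
                      b$xyz[nb[2], ] - b$xyz[ci, ])
    d <- dirs[1 + (k %% 2), ]
    f <- jobs[[k]]
    p0 <- b$xyz[ci, ]
    if (f == "pad") {
      c1 <- addAtomB(b, "C", p0 + BL[["CC"]] * d)
      addBondB(b, ci, c1)
    } else if (f == "hba") {
      o <- addAtomB(b, "O", p0 + BL[["COd"]] * d)
      addBondB(b, ci, o, "2")
    } else if (f == "hbd") {
      o <- addAtomB(b, "O", p0 + BL[["CO"]] * d)
      addBondB(b, ci, o)
      ## point the O-H away from the molecule so its hydrogen-bond axis is
      ## unobstructed
      away <- b$xyz[o, ] - colMeans(b$xyz)
      perp <- away - sum(away * d) * d
      perp <- if (sqrt(sum(perp^2)) > 1e-6) unitv(perp) else anyPerp(d)
      hd <- unitv(d * 0.25 + perp * 0.968)
      h <- addAtomB(b, "H", b$xyz[o, ] + BL[["OH"]] * hd)
      addBondB(b, o, h)
    } else if (f == "positive") {
      nn <- addAtomB(b, "N", p0 + BL[["CN"]] * d, fc = 1L)
      addBondB(b, ci, nn)
    } else if (f == "negative") {
      cc <- addAtomB(b, "C", p0 + BL[["CC"]] * d)
      addBondB(b, ci, cc)
      p <- anyPerp(d)
      o1 <- addAtomB(b, "O", b$xyz[cc, ] + BL[["COd"]] * (0.5 * d + 0.866 * p))
      addBondB(b, cc, o1, "2")
      o2 <- addAtomB(b, "O", b$xyz[cc, ] + 1.29 * (0.5 * d - 0.866 * p),
                     fc = -1L)
      addBondB(b, cc, o2)
    } else if (f == "aromatic") {
      p <- anyPerp(d)
      centre <- p0 + (BL[["CC"]] + BL[["CAr"]]) * d
      ringIdx <- integer(6)
      for (q in 0:5) {
        ang <- deg2rad(60 * q + 180)  # first atom towards the chain
        pos <- centre + BL[["CAr"]] * (cos(ang) * d + sin(ang) * p)
        ringIdx[q + 1] <- addAtomB(b, "C", pos)
      }
      for (q in 1:6)
        addBondB(b, ringIdx[q], ringIdx[q %% 6 + 1],
                 ifelse(q %% 2 == 1, "2", "1"))
      addBondB(b, ci, ringIdx[1])
    }
  }
  b <- fillHydrogens(b)
  ## small deterministic jitter keeps principal moments non-degenerate
  b$xyz <- b$xyz + matrix(stats::runif(3 * length(b$el), -0.02, 0.02),
                          ncol = 3)
  mol <- finishBuilder(b, sprintf("toy-ligand-%d", seed))
  lig <- new("Ligand", molecule = mol,
             rotatableDihedrals = perceiveRotatableDihedrals(mol))
  if (length(rotatableDihedrals(lig)) != nRotatable)
    stop("internal generator error: achieved ",
         length(rotatableDihedrals(lig)), " rotors, requested ",
         nRotatable)
  relaxLigandTorsions(lig)
}

## vacuum torsional relaxation: the emitted conformer is a low-energy
## structure (substituent clashes relieved), mirroring pregenerated
## conformer input
relaxLigandTorsions <- function(lig) {
  dhs <- rotatableDihedrals(lig)
  if (!length(dhs)) return(lig)
  cfg <- scoringConfig()
  energy <- function(xyz) {
    ml <- molecule(lig)
    coords(ml) <- xyz
    dist <- graphDistances(ml)
    units <- rigidUnitLabels(ml, dhs)
    pl <- vdwPairList(ml, dist, units, cfg@scale14)
    e <- 0
    for (k in seq_along(pl$i)) {
      d <- sqrt(sum((xyz[pl$i[k], ] - xyz[pl$j[k], ])^2))
      e <- e + pl$scale[k] * vdwPairEnergy(d, pl$r0[k], pl$eps[k])
    }
    e + ligandDihedralEnergy(lig, cfg, xyz)
  }
  xyz <- coords(lig)
  ## cyclic coordinate descent on a 30-degree torsion grid, then fine pass
  for (pass in 1:2) {
    stepGrid <- if (pass == 1) seq(-180, 150, by = 30) else seq(-15, 15, by = 5)
    for (k in seq_along(dhs)) {
      cur <- dihedralAngle(xyz, dhs[[k]])
      cand <- if (pass == 1) stepGrid else normalizeAngle(cur + stepGrid)
      best <- cur; bestE <- energy(xyz)
      for (a in cand) {
        x2 <- setDihedralAngle(xyz, dhs[[k]], a)
        e2 <- energy(x2)
        if (e2 < bestE - 1e-9) { best <- a; bestE <- e2 }
      }
      xyz <- setDihedralAngle(xyz, dhs[[k]], best)
    }
  }
  coords(lig) <- xyz
  lig
}

addAcceptorSite <- function(b, posO, dirOut, charged = FALSE) {
  o <- addAtomB(b, "O", posO, fc = if (charged) -1L else 0L)
  c1 <- addAtomB(b, "C", posO + BL[["COd"]] * dirOut)
  addBondB(b, c1, o, if (charged) "1" else "2")
  c(o, c1)
}

addDonorSite <- function(b, posO, dirIn, charged = FALSE) {
  if (charged) {
    ## ammonium-type donor: N(+) with three hydrogens, one on the bond axis
    n <- addAtomB(b, "N", posO, fc = 1L)
    c1 <- addAtomB(b, "C", posO - BL[["CN"]] * dirIn)
    addBondB(b, c1, n)
    h1 <- addAtomB(b, "H", posO + BL[["NH"]] * dirIn)
    addBondB(b, n, h1)
    idx <- c(n, h1, c1)
    for (hd in seq_len(2)) {
      d2 <- coneDirs(-dirIn, 2, 109.47, phase = 60)[hd, ]
      h <- addAtomB(b, "H", posO + BL[["NH"]] * d2)
      addBondB(b, n, h)
      idx <- c(idx, h)
    }
    idx
  } else {
    o <- addAtomB(b, "O", posO)
    h <- addAtomB(b, "H", posO + BL[["OH"]] * dirIn)
    c1 <- addAtomB(b, "C", posO - BL[["CO"]] * dirIn)
    addBondB(b, c1, o)
    addBondB(b, o, h)
    c(o, h, c1)
  }
}

#' Generate a toy receptor cage
#'
#' A spherical shell of apolar carbon pseudo-atoms with a small aperture
#' (so a large probe cannot enter), optionally with hydrogen-bonding sites
#' at the pocket wall: either \code{polarSites} randomly placed
#' donor/acceptor groups, or explicit \code{siteSpecs}.
#'
#' @param seed integer seed.
#' @param pocketRadius accessible pocket radius, Angstroms (default 6).
#' @param nShellAtoms shell atom count (>= 20, default 60).
#' @param polarSites number of randomly placed polar sites (alternating
#'   donor hydroxyl / acceptor carbonyl groups).
#' @param openAngle half-angle (degrees) of the aperture about +z.
#' @param siteSpecs optional list of site specifications, each
#'   \code{list(kind = "donor"|"acceptor", pos =, dir =, charged =)} (dir
#'   points into the pocket for donors, out of it for acceptors).
#' @param moldTo optional n x 3 matrix of coordinates: each shell atom is
#'   pulled inward along its ray until it sits at vdW-contact distance
#'   (\code{contact}) from the nearest of these atoms, moulding the pocket
#'   snugly around a designed pose.
#' @param contact moulding contact distance, Angstroms (default 3.4).
#' @return a [Receptor-class] (rigid; run [perceiveReceptorFlexibility()]
#'   to enable terminal-OH torsions).
#' @export
makeToyCage <- function(seed, pocketRadius = 6, nShellAtoms = 60,
                        polarSites = 0, openAngle = 25, siteSpecs = NULL,
                        moldTo = NULL, contact = 3.4) {
  stopifnot(nShellAtoms >= 20)
  set.seed(seed)
  rShell <- pocketRadius + 3.1
  ## Fibonacci sphere
  k <- seq_len(nShellAtoms)
  phi <- acos(1 - 2 * (k - 0.5) / nShellAtoms)
  theta <- pi * (1 + sqrt(5)) * k
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  dirs <- dirs[phi > deg2rad(openAngle), , drop = FALSE]
  b <- newBuilder()
  placed <- matrix(0, 0, 3)
  for (i in seq_len(nrow(dirs))) {
    jit <- stats::runif(3, -0.15, 0.15)
    pos <- dirs[i, ] * rShell + jit
    if (!is.null(moldTo)) {
      for (t in seq(rShell, 1, by = -0.05)) {
        p <- dirs[i, ] * t + jit
        if (min(sqrt(rowSums(sweep(moldTo, 2, p)^2))) <= contact) {
          pos <- p
          break
        }
      }
      if (nrow(placed) &&
          min(sqrt(rowSums(sweep(placed, 2, pos)^2))) < 1.5) next
    }
    placed <- rbind(placed, pos)
    addAtomB(b, "C", pos)
  }
  if (polarSites > 0 && is.null(siteSpecs)) {
    pick <- sample.int(nrow(dirs), polarSites)
    siteSpecs <- lapply(seq_len(polarSites), function(s) {
      d <- unitv(dirs[pick[s], ])
      if (s %% 2 == 1)
        list(kind = "acceptor", pos = d * pocketRadius, dir = d)
      else
        list(kind = "donor", pos = d * pocketRadius, dir = -d)
    })
  }
  siteAtoms <- integer()
  for (s in siteSpecs) {
    charged <- isTRUE(s$charged)
    idx <- if (s$kind == "acceptor")
      addAcceptorSite(b, s$pos, unitv(s$dir), charged)
    else
      addDonorSite(b, s$pos, unitv(s$dir), charged)
    siteAtoms <- c(siteAtoms, idx)
  }
  ## drop shell atoms clashing with site atoms
  if (length(siteAtoms)) {
    shell <- setdiff(seq_along(b$el), siteAtoms)
    keep <- rep(TRUE, length(b$el))
    for (i in shell) {
      d <- sqrt(rowSums(sweep(b$xyz[siteAtoms, , drop = FALSE], 2,
                              b$xyz[i, ])^2))
      if (min(d) < 2.3) keep[i] <- FALSE
    }
    sel <- which(keep)
    remap <- match(seq_along(b$el), sel)
    b2 <- newBuilder()
    for (i in sel) addAtomB(b2, b$el[i], b$xyz[i, ], b$fc[i])
    for (q in seq_along(b$bi)) {
      if (keep[b$bi[q]] && keep[b$bj[q]])
        addBondB(b2, remap[b$bi[q]], remap[b$bj[q]], b$bo[q])
    }
    b <- b2
  }
  mol <- finishBuilder(b, sprintf("toy-cage-%d", seed))
  new("Receptor", molecule = mol)
}

## Complementary site specs for a ligand in its current (designed) pose.
## Each ligand donor gets an acceptor site near the extension of its D-H
## axis, each ligand acceptor a donor group near the extension of its
## root->A axis; when the ideal position clashes with the ligand, nearby
## directions on widening cones are scanned (the polar angular windows
## tolerate these deviations). Charged ligand groups receive charged
## counter-sites, which makes the designed pairing strictly preferred.
complementarySites <- function(lig, maxSites = 5) {
  mol <- molecule(lig)
  xyz <- coords(mol)
  at <- mol@atoms
  specs <- list()
  siteAtomPositions <- function(s) {
    if (s$kind == "acceptor")
      rbind(s$pos, s$pos + BL[["COd"]] * s$dir)
    else
      rbind(s$pos, s$pos + BL[["OH"]] * s$dir, s$pos - 1.45 * s$dir)
  }
  clashFree <- function(s, partner) {
    pts <- siteAtomPositions(s)
    others <- xyz[-partner, , drop = FALSE]
    for (q in seq_len(nrow(pts))) {
      if (min(sqrt(rowSums(sweep(others, 2, pts[q, ])^2))) < 2.2)
        return(FALSE)
    }
    TRUE
  }
  placeWithScan <- function(makeSpec, baseDir, partner, cones) {
    cand <- rbind(baseDir,
                  do.call(rbind, lapply(cones, function(a)
                    coneDirs(baseDir, 8, a))))
    for (q in seq_len(nrow(cand))) {
      s <- makeSpec(unitv(cand[q, ]))
      if (clashFree(s, partner)) return(s)
    }
    NULL
  }
  dp <- donorHPairs(mol)
  dp <- dp[!duplicated(dp$d), , drop = FALSE]  # one site per donor heavy
  for (k in seq_len(nrow(dp))) {
    d0 <- unitv(xyz[dp$h[k], ] - xyz[dp$d[k], ])
    charged <- at$chargeFlag[dp$d[k]] != "neutral"
    s <- placeWithScan(function(dd)
      list(kind = "acceptor", pos = xyz[dp$d[k], ] + 2.8 * dd, dir = dd,
           charged = charged),
      d0, c(dp$d[k], dp$h[k]), cones = c(10, 18))
    if (!is.null(s)) specs[[length(specs) + 1]] <- s
  }
  ar <- acceptorRoots(mol)
  for (k in seq_len(nrow(ar))) {
    root <- if (ar$root[k] > 0) xyz[ar$root[k], ] else c(0, 0, 0)
    d0 <- unitv(xyz[ar$a[k], ] - root)
    charged <- at$chargeFlag[ar$a[k]] != "neutral"
    s <- placeWithScan(function(dd)
      list(kind = "donor", pos = xyz[ar$a[k], ] + 2.8 * dd, dir = -dd,
           charged = charged),
      d0, ar$a[k], cones = c(15, 30, 45))
    if (!is.null(s)) specs[[length(specs) + 1]] <- s
  }
  specs[seq_len(min(length(specs), maxSites))]
}

#' Generate a suite of redocking toy complexes
#'
#' Each system pairs a toy ligand (rotor counts spanning 0-8 across the
#' suite) with a cage whose polar sites are exactly complementary to the
#' ligand's donors and acceptors in a designed pose, creating a deep
#' engineered optimum. The stored optimum is the designed pose after
#' Simplex refinement, cross-checked by a budgeted multi-start search
#' (random initialisation + Monte Carlo + Simplex); if the search finds a
#' better pose, that pose becomes the stored optimum.
#'
#' @param nSystems number of complexes (>= 1, default 20).
#' @param seed master seed.
#' @param rotorCounts optional integer vector (recycled) of rotor counts;
#'   the default spans 0-8 with most systems at 5 or fewer rotors.
#' @param verifyStarts multi-start budget for the optimum cross-check
#'   (default 8; 0 disables).
#' @return list of [ToyComplex-class].
#' @export
makeRedockingSuite <- function(nSystems = 20, seed = 1,
                               rotorCounts = NULL, verifyStarts = 8) {
  stopifnot(nSystems >= 1)
  if (is.null(rotorCounts))
    rotorCounts <- c(0, 0, 0, 1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 5, 5,
                     6, 6, 7, 8)
  rotorCounts <- rep_len(rotorCounts, nSystems)
  ## feature sets are type-diverse (mixing neutral and charged anchors) so
  ## that the designed pairing of ligand groups to their counter-sites is
  ## strictly preferred over any permuted engagement
  featuresFor <- function(r) {
    if (r == 0) list(f = c("hba"), nh = 4)
    else if (r == 1) list(f = c("hbd"), nh = 4)
    else if (r == 2) list(f = c("hbd", "hba"), nh = 6)
    else if (r == 3) list(f = c("positive", "hba"), nh = 7)
    else if (r == 4) list(f = c("positive", "hbd", "hba"), nh = 8)
    else if (r == 5) list(f = c("positive", "hbd", "hba"), nh = 9)
    else if (r == 6) list(f = c("positive", "hbd", "hba", "hba"), nh = 11)
    else if (r == 7) list(f = c("positive", "hbd", "hbd", "hba"), nh = 11)
    else list(f = c("positive", "hbd", "hba", "hba"), nh = 13)
  }
  out <- vector("list", nSystems)
  for (i in seq_len(nSystems)) {
    r <- rotorCounts[i]
    fs <- featuresFor(r)
    lig <- makeToyLigand(seed + 100 * i, fs$nh, r, fs$f)
    ## centre the designed pose at the origin
    mol <- molecule(lig)
    ctr <- colMeans(coords(mol)[isHeavy(mol), , drop = FALSE])
    coords(lig) <- sweep(coords(lig), 2, ctr)
    extent <- max(sqrt(rowSums(coords(lig)[isHeavy(lig), , drop = FALSE]^2)))
    sites <- complementarySites(lig)
    rec <- makeToyCage(seed + 100 * i + 1,
                       pocketRadius = extent + 2.4,
                       nShellAtoms = 60, siteSpecs = sites,
                       moldTo = coords(lig)[isHeavy(lig), , drop = FALSE])
    cavity <- mapReferenceLigand(rec, lig, radius = 5, spacing = 0.5)
    cfg <- scoringConfig()
    ctx <- dockContext(lig, rec, cfg, cavity,
                       restraints = restraintSet())
    finalCfg <- stageParams("MIN", cfg, ctx$nChrom)$cfg
    scorer <- makeScorer(ctx, finalCfg)
    ch0 <- encodeChromosome(ctx, lig)
    ref <- simplexMinimize(ch0, scorer)
    bestChrom <- ref$chrom; bestScore <- ref$score
    if (verifyStarts > 0) {
      set.seed(seed + 100 * i + 2)
      spMC <- stageParams("MC", cfg, ctx$nChrom)
      for (s in seq_len(verifyStarts)) {
        start <- initializePopulation(2, ctx)[1, ]
        mc <- mcRefine(start, scorer, spMC, ctx, nSteps = 100)
        mn <- simplexMinimize(mc$chrom, scorer)
        if (mn$score < bestScore - 0.1) {
          bestChrom <- mn$chrom; bestScore <- mn$score
        }
      }
    }
    pose <- decodeChromosome(ctx, bestChrom)
    out[[i]] <- new("ToyComplex", receptor = rec, ligand = lig,
                    cavity = cavity, optimalPose = coords(pose),
                    optimalScore = bestScore,
                    metadata = list(seed = seed, index = i, rotors = r,
                                    nHeavy = fs$nh, features = fs$f))
  }
  out
}
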