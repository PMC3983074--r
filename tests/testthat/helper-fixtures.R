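# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately avoid the code paths they check.

# -- tiny molecule builders -------------------------------------------------

molFromSpec <- function(elements, xyz, bonds = NULL, charges = NULL,
                        name = "m") {
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), order = character())
  buildMolecule(elements, xyz, bonds, formalCharges = charges, name = name)
}

# methane-like single carbon with 4 H
methaneMol <- function() {
  molFromSpec(c("C", "H", "H", "H", "H"),
              rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
                    c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89)),
              data.frame(i = 1, j = 2:5, order = "1"))
}

ethaneMol <- function() {
  molFromSpec(c("C", "C", "H", "H", "H", "H", "H", "H"),
              rbind(c(0, 0, 0), c(1.54, 0, 0),
                    c(-0.36, 1.03, 0), c(-0.36, -0.51, 0.89),
                    c(-0.36, -0.51, -0.89),
                    c(1.90, 1.03, 0), c(1.90, -0.51, 0.89),
                    c(1.90, -0.51, -0.89)),
              data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
                         j = c(2, 3, 4, 5, 6, 7, 8), order = "1"))
}

methanolMol <- function() {
  molFromSpec(c("C", "O", "H", "H", "H", "H"),
              rbind(c(0, 0, 0), c(1.43, 0, 0), c(1.76, 0.85, 0.3),
                    c(-0.36, 1.03, 0), c(-0.36, -0.51, 0.89),
                    c(-0.36, -0.51, -0.89)),
              data.frame(i = c(1, 2, 1, 1, 1), j = c(2, 3, 4, 5, 6),
                         order = "1"))
}

ammoniumMol <- function() {
  molFromSpec(c("N", "H", "H", "H", "H"),
              rbind(c(0, 0, 0), c(1.01, 0, 0), c(-0.34, 0.95, 0),
                    c(-0.34, -0.48, 0.83), c(-0.34, -0.48, -0.83)),
              data.frame(i = 1, j = 2:5, order = "1"),
              charges = c(1L, 0L, 0L, 0L, 0L))
}

benzeneMol <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  xyzC <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  xyzH <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  molFromSpec(c(rep("C", 6), rep("H", 6)), rbind(xyzC, xyzH),
              data.frame(i = c(1:6, 1:6),
                         j = c(2:6, 1, 7:12),
                         order = c(rep(c("2", "1"), 3), rep("1", 6))))
}

nAlkaneMol <- function(n) {
  half <- 35.264 * pi / 180
  xyz <- t(vapply(seq_len(n), function(i)
    c((i - 1) * 1.54 * cos(half), 1.54 * sin(half) * (i %% 2), 0),
    numeric(3)))
  bonds <- data.frame(i = seq_len(n - 1), j = 2:n, order = "1")
  mol <- molFromSpec(rep("C", n), xyz, bonds)
  # add hydrogens crudely: 2 per interior, 3 per terminal
  el <- rep("C", n)
  hx <- NULL; hb <- NULL
  for (i in seq_len(n)) {
    nH <- if (i %in% c(1, n)) 3 else 2
    for (k in seq_len(nH)) {
      hx <- rbind(hx, xyz[i, ] + 1.09 * c(0, (-1)^(i + k) * 0.5,
                                          0.87 * (-1)^k))
      hb <- rbind(hb, c(i, n + nrow(hx) - 0))
    }
  }
  hb[, 2] <- n + seq_len(nrow(hb))
  molFromSpec(c(el, rep("H", nrow(hx))), rbind(xyz, hx),
              rbind(bonds, data.frame(i = hb[, 1], j = hb[, 2],
                                      order = "1")))
}

ligandFromMol <- function(mol) {
  new("Ligand", molecule = mol,
      rotatableDihedrals = perceiveRotatableDihedrals(mol))
}

# a small standard toy complex shared by several test files
standardToyComplex <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeRedockingSuite(1, seed = 424, rotorCounts = 2,
                                   verifyStarts = 0)[[1]]
    cache
  }
})

# the expensive 20-system docking campaign, shared by the redocking,
# convergence and GA-vs-random checks (computed once per test run)
redockCampaign <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    suite <- makeRedockingSuite(20, seed = 11)
    runs <- lapply(seq_along(suite), function(i) {
      tc <- suite[[i]]
      dock(tc@ligand, tc@receptor, tc@cavity, nRuns = 50, seed = 1000 + i)
    })
    cache <<- list(suite = suite, runs = runs)
    cache
  }
})

# -- independent oracles ----------------------------------------------------

# numerical Shrake-Rupley SASA on a deterministic spherical point set
shrakeRupleySasa <- function(xyz, radii, rsolv = 1.4, nPoints = 400) {
  n <- nrow(xyz)
  k <- seq_len(nPoints)
  phi <- acos(1 - 2 * (k - 0.5) / nPoints)
  theta <- pi * (1 + sqrt(5)) * k
  sphere <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  out <- numeric(n)
  for (i in seq_len(n)) {
    R <- radii[i] + rsolv
    pts <- sweep(sphere * R, 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in seq_len(n)) {
      if (j == i) next
      Rj <- radii[j] + rsolv
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 > Rj^2
    }
    out[i] <- 4 * pi * R^2 * mean(free)
  }
  out
}

# Monte-Carlo estimate of a union-of-spheres volume
mcSphereUnionVolume <- function(centres, radius, nSamples = 2e5, seed = 99) {
  set.seed(seed)
  lo <- apply(centres, 2, min) - radius
  hi <- apply(centres, 2, max) + radius
  pts <- cbind(runif(nSamples, lo[1], hi[1]), runif(nSamples, lo[2], hi[2]),
               runif(nSamples, lo[3], hi[3]))
  inside <- rep(FALSE, nSamples)
  for (k in seq_len(nrow(centres))) {
    inside <- inside |
      rowSums(sweep(pts, 2, centres[k, ])^2) <= radius^2
  }
  prod(hi - lo) * mean(inside)
}

# brute-force element/bond-preserving automorphism enumeration by raw
# permutation search with pruning (independent of igraph)
bruteAutomorphisms <- function(mol, heavyOnly = TRUE) {
  sel <- if (heavyOnly) which(mol@atoms$element != "H")
         else seq_len(nrow(mol@atoms))
  n <- length(sel)
  el <- mol@atoms$element[sel]
  # same aromatic-equivalence convention as the implementation, arrived at
  # independently: mark ring bonds of fully aromatic rings as "ar"
  bd <- mol@bonds
  arom <- moldock:::aromaticAtomMask(mol)
  if (any(arom)) {
    bkey <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j), sep = "-")
    for (r in ringList(mol)) {
      if (!all(arom[r])) next
      m <- length(r)
      for (q in seq_len(m)) {
        e <- sort(c(r[q], r[if (q == m) 1L else q + 1L]))
        hit <- match(paste(e, collapse = "-"), bkey)
        if (!is.na(hit)) bd$order[hit] <- "ar"
      }
    }
  }
  keep <- bd$i %in% sel & bd$j %in% sel
  bd <- bd[keep, , drop = FALSE]
  adj <- matrix("", n, n)
  remap <- match(seq_len(nrow(mol@atoms)), sel)
  for (k in seq_len(nrow(bd))) {
    a <- remap[bd$i[k]]; b <- remap[bd$j[k]]
    adj[a, b] <- adj[b, a] <- bd$order[k]
  }
  res <- list()
  perm <- integer(n)
  used <- logical(n)
  recurse <- function(pos) {
    if (pos > n) {
      res[[length(res) + 1]] <<- perm
      return(invisible())
    }
    for (cand in seq_len(n)) {
      if (used[cand] || el[cand] != el[pos]) next
      ok <- TRUE
      for (prev in seq_len(pos - 1)) {
        if (adj[pos, prev] != adj[cand, perm[prev]]) { ok <- FALSE; break }
      }
      if (!ok) next
      perm[pos] <<- cand
      used[cand] <<- TRUE
      recurse(pos + 1)
      used[cand] <<- FALSE
    }
  }
  recurse(1)
  attr(res, "atoms") <- sel
  res
}

# exhaustive confusion-matrix ROC/EF oracle
vsMetricsOracle <- function(scores) {
  act <- as.logical(scores$active)
  ord <- order(scores$score)
  act <- act[ord]
  s <- scores$score[ord]
  nA <- sum(act); nD <- sum(!act)
  thr <- unique(s)
  pts <- t(vapply(thr, function(t) {
    sel <- s <= t
    c(fpr = sum(!act & sel) / nD, tpr = sum(act & sel) / nA)
  }, numeric(2)))
  pts <- rbind(c(0, 0), pts)
  auc <- sum(diff(pts[, 1]) * (head(pts[, 2], -1) + tail(pts[, 2], -1)) / 2)
  N <- length(act)
  ef <- function(f) {
    k <- max(1, round(f * N))
    (sum(act[seq_len(k)]) / nA) / (k / N)
  }
  list(auc = auc, ef = ef)
}

# geometric clash filter used by the grid-fidelity checks: a pose counts as
# clash-free when every ligand-receptor pair sits at or beyond its vdW
# equilibrium distance (the attractive tail, where the lattice resolves the
# field smoothly)
poseClashFree <- function(X, recXYZ, r0mat) {
  for (i in seq_len(nrow(X))) {
    d <- sqrt(rowSums(sweep(recXYZ, 2, X[i, ])^2))
    if (any(d < r0mat[i, ])) return(FALSE)
  }
  TRUE
}
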