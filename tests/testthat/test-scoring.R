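# The composite scoring function and its components.

test_that("vdW closed forms: minima and analytic zero crossings", {
  r0 <- 3.41; eps <- 0.23
  for (form in c("6-12", "4-8")) {
    expect_equal(vdwPairEnergy(r0, r0, eps, form), -eps, tolerance = 1e-12)
    # numeric minimum is at r0
    rs <- seq(0.8 * r0, 1.3 * r0, by = 1e-3)
    expect_equal(rs[which.min(vdwPairEnergy(rs, r0, eps, form))], r0,
                 tolerance = 2e-3)
  }
  expect_equal(vdwPairEnergy(r0 * 2^(-1/6), r0, eps, "6-12"), 0,
               tolerance = 1e-9)
  expect_equal(vdwPairEnergy(r0 * 2^(-1/4), r0, eps, "4-8"), 0,
               tolerance = 1e-9)
  # short-range cap and domain error
  expect_equal(vdwPairEnergy(0.01, r0, eps, "6-12", cap = 100), 100)
  expect_error(vdwPairEnergy(0, r0, eps), "r must be")
  expect_equal(vdwPairEnergy(1e3 * r0, r0, eps, "6-12"), 0,
               tolerance = 1e-12)
})

test_that("polar pair term: ramps, signs and mode switches", {
  cfg <- scoringConfig()           # SF3: attractive+repulsive, W = 4
  W <- cfg@weights[["polar"]]
  donor <- list(pos = c(0, 0, 0), h = c(0.96, 0, 0), kind = "donor",
                charged = FALSE)
  acceptor <- list(pos = c(2.8, 0, 0), root = c(4.02, 0, 0),
                   kind = "acceptor", charged = FALSE)
  # ideal geometry: linear D-H...A, in-window distance
  expect_equal(polarPairEnergy(donor, acceptor, cfg), -W)
  # beyond the distance window + tolerance: zero
  farA <- acceptor; farA$pos <- c(4.5, 0, 0); farA$root <- c(5.7, 0, 0)
  expect_equal(polarPairEnergy(donor, farA, cfg), 0)
  # two acceptors at contact: repulsive under SF3, zero attractive-only
  acc2 <- list(pos = c(2.8, 0, 0), root = c(4.0, 0, 0), kind = "acceptor",
               charged = FALSE)
  accA <- list(pos = c(0, 0, 0), root = c(-1.2, 0, 0), kind = "acceptor",
               charged = FALSE)
  expect_gt(polarPairEnergy(accA, acc2, cfg), 0)
  cfg5 <- scoringConfig("SF5")
  expect_equal(polarPairEnergy(accA, acc2, cfg5), 0)
  # charged pair scaling
  dc <- donor; dc$charged <- TRUE
  ac <- acceptor; ac$charged <- TRUE
  expect_equal(polarPairEnergy(dc, ac, cfg), -W * cfg@chargedScale)
  # ambivalent atoms are exempt from repulsion
  accAmbi <- accA; accAmbi$ambi <- TRUE
  expect_equal(polarPairEnergy(accAmbi, acc2, cfg), 0)
})

test_that("probabilistic SASA matches limits and the numerical oracle", {
  # isolated atom: exact closed form
  a <- haselSasa(matrix(0, 1, 3), elements = "C")
  expect_equal(a, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)

  # symmetric two-atom system
  two <- haselSasa(rbind(c(0, 0, 0), c(1.54, 0, 0)),
                   elements = c("C", "C"), bonds = cbind(1, 2))
  expect_equal(two[1], two[2], tolerance = 1e-9)

  # atom caged by a tight shell of neighbours is nearly buried
  k <- 1:24
  phi <- acos(1 - 2 * (k - 0.5) / 24)
  theta <- pi * (1 + sqrt(5)) * k
  shell <- 2.4 * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                       cos(phi))
  caged <- haselSasa(rbind(c(0, 0, 0), shell), elements = rep("C", 25))
  expect_lt(caged[1] / (4 * pi * 3.1^2), 0.05)

  # correlation with a numerical sphere-sampling oracle across molecules
  set.seed(8)
  approxA <- c(); exactA <- c()
  specs <- list(list(4, 0, "hba"), list(4, 1, "hbd"),
                list(6, 2, c("hbd", "hba")), list(7, 3, c("hbd", "hba")),
                list(5, 2, character()), list(9, 4, c("hbd", "hba", "hba")))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    lig <- makeToyLigand(500 + k, sp[[1]], sp[[2]], sp[[3]])
    mol <- molecule(lig)
    p <- moldock:::elementParamRow(atomTable(mol)$element)
    approxA <- c(approxA, haselSasa(mol))
    exactA <- c(exactA, shrakeRupleySasa(coords(mol), p$radius))
  }
  expect_gt(cor(approxA, exactA), 0.95)
})

test_that("desolvation: zero at infinite separation, favourable apolar burial", {
  tc <- standardToyComplex()
  ligFar <- tc@ligand
  coords(ligFar) <- coords(ligFar) + 500
  expect_equal(desolvationScore(ligFar, tc@receptor), 0, tolerance = 1e-9)
  # apolar chain buried in an apolar cage: favourable (negative)
  apolarLig <- ligandFromMol(ethaneMol())
  cage <- makeToyCage(9, pocketRadius = 3.5, nShellAtoms = 60)
  d1 <- desolvationScore(apolarLig, cage)
  expect_lt(d1, 0)
  # determinism
  expect_identical(d1, desolvationScore(apolarLig, cage))
})

test_that("ligand dihedral potential is a scaled 3-fold cosine", {
  but <- ligandFromMol(nAlkaneMol(4))
  xyzAnti <- setDihedralAngle(coords(but),
                              rotatableDihedrals(but)[[1]], 180)
  xyzEcl <- setDihedralAngle(coords(but),
                             rotatableDihedrals(but)[[1]], 0)
  cfg <- scoringConfig()
  eAnti <- ligandDihedralEnergy(but, cfg, xyzAnti)
  eEcl <- ligandDihedralEnergy(but, cfg, xyzEcl)
  expect_equal(eAnti, 0, tolerance = 1e-9)     # cosine minimum
  expect_gt(eEcl, eAnti)
  cfg0 <- scoringConfig(dihedralWeightScale = 0)
  expect_equal(ligandDihedralEnergy(but, cfg0, xyzEcl), 0)
})

test_that("score components behave at reference and far separation", {
  tc <- standardToyComplex()
  ctx <- dockContext(tc@ligand, tc@receptor, scoringConfig())
  # far pose, no cavity/restraints: everything ~0
  far <- coords(tc@ligand) + 500
  sb <- scorePose(far, context = ctx)
  expect_equal(scoreTotal(sb), 0, tolerance = 1e-6)
  expect_equal(sb@intra, 0, tolerance = 1e-9)
  # intra is exactly zero at the input conformation
  sb0 <- scorePose(coords(tc@ligand), context = ctx)
  expect_identical(sb0@intra, 0)
  # rigid ligand: intra is zero for every pose
  rigid <- makeRedockingSuite(1, seed = 77, rotorCounts = 0,
                              verifyStarts = 0)[[1]]
  rctx <- dockContext(rigid@ligand, rigid@receptor, scoringConfig(),
                      rigid@cavity)
  set.seed(4)
  pop <- initializePopulation(5, rctx)
  for (k in 1:5) {
    p <- decodeChromosome(rctx, pop[k, ])
    expect_identical(scorePose(coords(p), context = rctx)@intra, 0)
  }
  # purity: identical inputs give bit-identical outputs
  s1 <- scorePose(coords(tc@ligand), context = ctx)
  s2 <- scorePose(coords(tc@ligand), context = ctx)
  expect_identical(scoreTotal(s1), scoreTotal(s2))
})

test_that("scores are invariant under rigid motion of the whole system", {
  tc <- standardToyComplex()
  cfg <- scoringConfig()
  ctx1 <- dockContext(tc@ligand, tc@receptor, cfg)
  sb1 <- scorePose(coords(tc@ligand), context = ctx1)
  R <- eulerMatrix(21, -35, 110)
  shift <- c(5, -3, 7)
  lig2 <- tc@ligand
  coords(lig2) <- sweep(coords(tc@ligand) %*% t(R), 2, shift, "+")
  rec2 <- tc@receptor
  coords(rec2) <- sweep(coords(tc@receptor) %*% t(R), 2, shift, "+")
  ctx2 <- dockContext(lig2, rec2, cfg)
  sb2 <- scorePose(coords(lig2), context = ctx2)
  expect_equal(scoreComponents(sb1), scoreComponents(sb2),
               tolerance = 1e-6)
  expect_equal(scoreTerms(sb1), scoreTerms(sb2), tolerance = 1e-6)
})

test_that("vdW grids reproduce the direct sum", {
  tc <- standardToyComplex()
  cfg <- scoringConfig()
  g <- buildVdwGrids(tc@receptor, tc@cavity, spacing = 0.4, cfg = cfg)
  # lattice-point value equals the direct sum exactly (by definition)
  mr <- molecule(tc@receptor)
  p <- moldock:::vdwAtomParams("C")
  rp <- moldock:::vdwAtomParams(atomTable(mr)$element,
                                atomTable(mr)$iclass)
  pt <- g@origin + g@spacing * c(5, 6, 7)
  direct <- sum(vdwPairEnergy(
    sqrt(rowSums(sweep(coords(mr), 2, pt)^2)),
    p$radius + rp$radius, sqrt(p$eps * rp$eps), "6-12", cfg@vdwCap))
  expect_equal(g@grids[["C"]][6, 7, 8], direct, tolerance = 1e-9)

  # empty receptor: all-zero grids
  emptyRec <- new("Receptor",
                  molecule = molFromSpec(character(), matrix(0, 0, 3)))
  g0 <- buildVdwGrids(emptyRec, tc@cavity, spacing = 0.6, cfg = cfg)
  expect_true(all(vapply(g0@grids, function(x) all(x == 0), logical(1))))
})

test_that("grid-mode inter vdW tracks the direct sum over random poses", {
  probe <- ligandFromMol(methaneMol())
  cage <- makeToyCage(121, pocketRadius = 5, nShellAtoms = 60,
                      polarSites = 2)
  cav <- mapTwoSphere(cage, c(0, 0, 0), searchRadius = 7)
  cfg <- scoringConfig()
  grids <- list("6-12" = buildVdwGrids(cage, cav, spacing = 0.3,
                                       cfg = cfg))
  ctx <- dockContext(probe, cage, cfg, cav, grids = grids)
  mprobe <- molecule(probe); mcage <- molecule(cage)
  r0mat <- moldock:::vdwPairParams(atomTable(mprobe)$element,
                                   atomTable(mcage)$element,
                                   atomTable(mprobe)$iclass,
                                   atomTable(mcage)$iclass)$r0
  set.seed(12)
  pop <- initializePopulation(400, ctx)
  errs <- c()
  for (k in seq_len(nrow(pop))) {
    X <- coords(decodeChromosome(ctx, pop[k, ]))
    if (!poseClashFree(X, coords(cage), r0mat)) next
    sd1 <- scorePose(X, context = ctx, useGrid = FALSE)
    sd2 <- scorePose(X, context = ctx, useGrid = TRUE)
    errs <- c(errs, abs(scoreTerms(sd1)[["inter.vdw"]] -
                          scoreTerms(sd2)[["inter.vdw"]]))
  }
  expect_gt(length(errs), 50)
  expect_lt(max(errs), 0.25)
})

test_that("grid files round-trip", {
  tc <- standardToyComplex()
  g <- buildVdwGrids(tc@receptor, tc@cavity, spacing = 0.6,
                     classes = c("C", "O"))
  path <- tempfile(fileext = ".json")
  writeVdwGrids(g, path)
  back <- readVdwGrids(path)
  expect_equal(back@grids, g@grids)
  expect_equal(back@origin, g@origin)
})
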