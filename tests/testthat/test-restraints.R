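# Pharmacophore, tether, cavity and distance restraints.

test_that("feature detection follows the rule table", {
  benz <- detectFeatures(ligandFromMol(benzeneMol()))
  expect_equal(nrow(benz$aromatic), 1)          # one ring centroid
  expect_equal(benz$aromatic[1, ], c(0, 0, 0), tolerance = 1e-6)
  expect_equal(nrow(benz$any), 6)
  expect_equal(nrow(benz$hydrophobic), 6)
  expect_equal(nrow(benz$aliphatic), 0)

  # acetate anion: two negatively charged acceptor oxygens
  acet <- molFromSpec(c("C", "C", "O", "O", "H", "H", "H"),
                      rbind(c(0, 0, 0), c(1.52, 0, 0), c(2.15, 1.06, 0),
                            c(2.16, -1.14, 0), c(-0.4, 1, 0),
                            c(-0.4, -0.5, 0.9), c(-0.4, -0.5, -0.9)),
                      data.frame(i = c(1, 2, 2, 1, 1, 1),
                                 j = c(2, 3, 4, 5, 6, 7),
                                 order = c("1", "2", "1", "1", "1", "1")),
                      charges = c(0L, 0L, 0L, -1L, 0L, 0L, 0L))
  f <- detectFeatures(acet)
  expect_equal(nrow(f$negative), 2)

  # methane: only "any heavy atom"
  f2 <- detectFeatures(methaneMol())
  expect_equal(nrow(f2$any), 1)
  expect_equal(sum(vapply(f2[setdiff(names(f2), c("any", "hydrophobic",
                                                  "aliphatic"))],
                          nrow, integer(1))), 0)
})

test_that("pharmacophore penalty is exact and selects k smallest optionals", {
  lig <- ligandFromMol(methanolMol())
  feats <- detectFeatures(lig)
  oPos <- feats$hba[1, ]
  # feature inside the sphere: zero
  rs <- restraintSet(list(pharmacophoreRestraint("hba", oPos + 0.3, 1)))
  expect_identical(pharmacophorePenalty(feats, rs), 0)
  # nearest feature 2 A outside the surface, W = 1: penalty 4
  rs2 <- restraintSet(list(pharmacophoreRestraint("hba", oPos + c(3, 0, 0),
                                                  1)))
  expect_equal(pharmacophorePenalty(feats, rs2), 4, tolerance = 1e-9)
  # optional selection: penalties {0, 1, 9}, nOpt = 2 -> 1
  mk <- function(offset) pharmacophoreRestraint(
    "hba", oPos + c(offset, 0, 0), 1, mandatory = FALSE)
  rs3 <- restraintSet(list(mk(0.5), mk(2), mk(4)), nOpt = 2)
  expect_equal(pharmacophorePenalty(feats, rs3), 0 + 1, tolerance = 1e-9)
  # absent feature type: +Inf with warning
  rs4 <- restraintSet(list(pharmacophoreRestraint("positive", c(0, 0, 0),
                                                  1)))
  expect_warning(p <- pharmacophorePenalty(feats, rs4), "no 'positive'")
  expect_identical(p, Inf)
})

test_that("optional-restraint totals are monotone in nOpt", {
  lig <- makeToyLigand(21, 6, 2, c("hbd", "hba"))
  feats <- detectFeatures(lig)
  mk <- function(off) pharmacophoreRestraint("any", c(off, 0, 0), 0.5,
                                             mandatory = FALSE)
  ph <- lapply(c(1, 3, 5, 8), mk)
  tot <- vapply(0:4, function(k)
    pharmacophorePenalty(feats, restraintSet(ph, nOpt = k)), numeric(1))
  expect_true(all(diff(tot) >= 0))
})

test_that("feasibility screening counts features against restraints", {
  noHbd <- ligandFromMol(ethaneMol())
  rsHbd <- restraintSet(list(pharmacophoreRestraint("hbd", c(0, 0, 0), 1)))
  expect_false(screenLigandFeatures(noHbd, rsHbd))
  withHbd <- ligandFromMol(methanolMol())
  expect_true(screenLigandFeatures(withHbd, rsHbd))
  # optional best case: HBA-only ligand vs {HBA, negative}, nOpt = 1
  rsOpt <- restraintSet(list(
    pharmacophoreRestraint("hba", c(0, 0, 0), 1, mandatory = FALSE),
    pharmacophoreRestraint("negative", c(0, 0, 0), 1, mandatory = FALSE)),
    nOpt = 1)
  expect_true(screenLigandFeatures(withHbd, rsOpt))
  rsOpt2 <- restraintSet(rsOpt@pharmacophores, nOpt = 2)
  expect_false(screenLigandFeatures(withHbd, rsOpt2))
})

test_that("restraint files parse into restraint sets", {
  path <- tempfile(fileext = ".ph4")
  writeLines(c("# test restraints", "NOPT 1",
               "1.0 2.0 3.0 1.5 hba MANDATORY",
               "0.0 0.0 0.0 2.0 hydrophobic OPTIONAL",
               "4.0 0.0 0.0 2.0 positive OPTIONAL"), path)
  rs <- readPharmacophores(path)
  expect_length(rs@pharmacophores, 3)
  expect_equal(rs@nOpt, 1L)
  expect_true(rs@pharmacophores[[1]]@mandatory)
  expect_false(rs@pharmacophores[[2]]@mandatory)
  expect_equal(rs@pharmacophores[[1]]@center, c(1, 2, 3))
})

test_that("SMARTS matching, replication and deduplication", {
  # para-disubstituted benzene: O and N para on the ring
  ang <- seq(0, 300, by = 60) * pi / 180
  xyzC <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  par <- molFromSpec(c(rep("C", 6), "O", "N", "H", "H", "H"),
                     rbind(xyzC, c(2.8, 0, 0), c(-2.8, 0, 0),
                           c(3.3, 0.8, 0), c(-3.3, 0.8, 0),
                           c(-3.3, -0.8, 0)),
                     data.frame(i = c(1:6, 1, 4, 7, 8, 8),
                                j = c(2:6, 1, 7, 8, 9, 10, 11),
                                order = c(rep(c("2", "1"), 3), "1", "1",
                                          "1", "1", "1")))
  lig <- ligandFromMol(par)
  # both orientations of the para query are distinct embeddings
  m <- matchSmarts(lig, "Oc1ccc(N)cc1")
  expect_length(m, 2)
  expect_false(identical(m[[1]], m[[2]]))
  # a fully symmetric query yields one entry per automorphic embedding
  expect_length(matchSmarts(lig, "c1ccccc1"), 12)
  # no match: rejected with a log message
  spec <- tetherSpec("OCCCO", matrix(0, 5, 3))
  expect_message(out <- matchAndReplicate(list(lig), spec), "rejected")
  expect_length(out, 0)
  # replication count = number of distinct matches
  spec2 <- tetherSpec("Oc1ccc(N)cc1",
                      coords(lig)[m[[1]], , drop = FALSE])
  out2 <- matchAndReplicate(list(lig, ligandFromMol(ethaneMol())), spec2)
  expect_length(out2, 2)
  # invalid SMARTS fails before docking
  expect_error(tetherSpec("C(((", matrix(0, 1, 3)), "unbalanced")
})

test_that("prealignment is a least-squares rigid superposition", {
  lig <- makeToyLigand(33, 6, 2, c("hbd", "hba"))
  q <- "CCC"
  m <- matchSmarts(lig, q)[[1]]
  ref <- coords(lig)[m, , drop = FALSE]
  spec <- tetherSpec(q, ref)
  # already aligned: identity
  out <- prealign(lig, m, spec)
  expect_equal(coords(out), coords(lig), tolerance = 1e-9)
  # rotated 90 degrees: prealign recovers the minimum-RMSD superposition
  rot <- lig
  coords(rot) <- coords(lig) %*% t(eulerMatrix(90, 0, 0)) + 3
  out2 <- prealign(rot, m, spec)
  expect_lt(kabsch(coords(out2)[m, ], ref)$rmsd, 1e-6)
  expect_equal(tetherViolation(out2, spec, m)[["trans"]], 0,
               tolerance = 1e-6)
  # under-determined: fewer than 3 matched atoms
  spec2 <- tetherSpec("CC", ref[1:2, ])
  expect_error(prealign(lig, m[1:2], spec2), ">= 3 matched atoms")
})

test_that("tether violation measures COM shift and rotation angle", {
  lig <- makeToyLigand(33, 6, 2, c("hbd", "hba"))
  m <- matchSmarts(lig, "CCC")[[1]]
  spec <- tetherSpec("CCC", coords(lig)[m, , drop = FALSE])
  v0 <- tetherViolation(lig, spec, m)
  expect_equal(unname(v0), c(0, 0), tolerance = 1e-9)
  shifted <- lig
  coords(shifted) <- coords(lig) + rep(0.05 / sqrt(3), 3)
  expect_equal(tetherViolation(shifted, spec, m)[["trans"]], 0.05,
               tolerance = 1e-9)
})

test_that("cavity and distance penalties follow their formulas", {
  tc <- standardToyComplex()
  inside <- tc@ligand
  coords(inside) <- tc@optimalPose
  # a pose fully inside can still touch lattice gaps; build a strict case:
  single <- ligandFromMol(methaneMol())
  pt <- cavityPoints(tc@cavity)[1, ]
  coords(single) <- sweep(coords(single), 2,
                          pt - coords(single)[1, ], "+")
  expect_equal(cavityPenalty(single, tc@cavity), 0)
  # one heavy atom d outside: W * d^2 (hydrogens never count)
  far <- single
  coords(far) <- coords(single) + c(100, 0, 0)
  dmin <- distanceToCavity(tc@cavity, coords(far)[1, ])
  expect_equal(cavityPenalty(far, tc@cavity, W = 1), dmin^2,
               tolerance = 1e-9)
  expect_equal(cavityPenalty(far, tc@cavity, W = 2.5), 2.5 * dmin^2,
               tolerance = 1e-9)

  # distance restraint: upper-bound semantics
  dr <- distanceRestraint(1, 1, bound = 3)
  rec1 <- new("Receptor", molecule = molFromSpec("O", matrix(c(5, 0, 0),
                                                             1)))
  ligAt0 <- ligandFromMol(methaneMol())
  expect_equal(nmrDistancePenalty(ligAt0, rec1, dr), (5 - 3)^2,
               tolerance = 1e-9)
  drWide <- distanceRestraint(1, 1, bound = 6)
  expect_equal(nmrDistancePenalty(ligAt0, rec1, drWide), 0)
  # multiple ligand atoms: only the minimum pair counts
  drAll <- distanceRestraint(1:5, 1, bound = 3, weight = 2)
  dmin2 <- min(sqrt(rowSums(sweep(coords(ligAt0), 2, c(5, 0, 0))^2)))
  expect_equal(nmrDistancePenalty(ligAt0, rec1, drAll),
               2 * max(0, dmin2 - 3)^2, tolerance = 1e-9)
  # lower-bound semantics
  drLow <- distanceRestraint(1, 1, bound = 6, semantics = "lower")
  expect_equal(nmrDistancePenalty(ligAt0, rec1, drLow), 1,
               tolerance = 1e-9)
  expect_error(distanceRestraint(integer(), 1, 3), "empty")
})

test_that("tethered docking keeps every pose within the tolerances", {
  tc <- standardToyComplex()
  lig <- tc@ligand
  q <- "CCC"
  mm <- matchSmarts(lig, q)
  spec <- tetherSpec(q, coords(lig)[mm[[1]], , drop = FALSE],
                     transTol = 0.1, rotTol = 1.0)
  rs <- restraintSet(tether = spec)
  ctx <- dockContext(lig, tc@receptor, scoringConfig(), tc@cavity, rs,
                     tetherAtoms = mm[[1]])
  set.seed(99)
  pop <- initializePopulation(120, ctx)
  # mutate each individual a few times, decode, verify the hard guarantee
  worstTrans <- 0; worstRot <- 0
  for (k in seq_len(nrow(pop))) {
    ch <- pop[k, ]
    for (s in 1:5) ch <- mutateChromosome(ch, c(0.05, 0.05, 0.05, 0.5,
                                                0.5, 0.5, 30), ctx)
    v <- tetherViolation(decodeChromosome(ctx, ch), spec, mm[[1]])
    worstTrans <- max(worstTrans, v[["trans"]])
    worstRot <- max(worstRot, v[["rot"]])
  }
  expect_lte(worstTrans, 0.1 + 1e-6)
  expect_lte(worstRot, 1.0 + 1e-6)
})
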