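# Molecular model, file I/O, typing and torsion perception.

test_that("MOL2 receptors parse with atoms, bonds and flexible torsions", {
  # water: smallest valid input, O-H bonds not receptor-flexible
  waterFile <- tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "water", " 3 2 1", "SMALL",
               "USER_CHARGES", "@<TRIPOS>ATOM",
               " 1 O  0.0000 0.0000 0.0000 O.3 1 HOH1 -0.834",
               " 2 H1 0.9572 0.0000 0.0000 H   1 HOH1  0.417",
               " 3 H2 -0.2400 0.9270 0.0000 H  1 HOH1  0.417",
               "@<TRIPOS>BOND", " 1 1 2 1", " 2 1 3 1"), waterFile)
  rec <- readMol2(waterFile)
  expect_equal(nAtoms(rec), 3)
  expect_equal(length(flexibleDihedrals(rec)), 0)
  expect_equal(atomTable(rec)$element, c("O", "H", "H"))
  # partial charges carried but informational
  expect_equal(atomTable(rec)$partialCharge[1], -0.834)

  # a serine-like fragment: C-C-O-H -> exactly one flexible OH torsion
  serFile <- tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "ser", " 5 4 1", "SMALL", "NO_CHARGES",
               "@<TRIPOS>ATOM",
               " 1 C1 0.0000 0.0000 0.0000 C.3 1 SER1 0.0",
               " 2 C2 1.5400 0.0000 0.0000 C.3 1 SER1 0.0",
               " 3 O1 2.0500 1.3500 0.0000 O.3 1 SER1 0.0",
               " 4 H1 3.0100 1.3300 0.0000 H   1 SER1 0.0",
               " 5 H2 -0.5100 0.9800 0.0000 H   1 SER1 0.0",
               "@<TRIPOS>BOND",
               " 1 1 2 1", " 2 2 3 1", " 3 3 4 1", " 4 1 5 1"), serFile)
  rec2 <- readMol2(serFile)
  expect_equal(length(flexibleDihedrals(rec2)), 1)
  dh <- flexibleDihedrals(rec2)[[1]]
  expect_equal(dh@atoms[3], 3L)  # the hydroxyl oxygen is the pivot
  expect_true(all(c(3L, 4L) %in% dh@rotatedSet))

  # missing BOND section is an error: a bonded model is required
  noBond <- tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "x", " 1 0 1", "SMALL", "NO_CHARGES",
               "@<TRIPOS>ATOM",
               " 1 C1 0.0 0.0 0.0 C.3 1 X 0.0"), noBond)
  expect_error(readMol2(noBond), "BOND")
})

test_that("SDF records parse with charges, fields and rotor perception", {
  sdf <- tempfile(fileext = ".sdf")
  benz <- benzeneMol()
  writeSdf(ligandFromMol(benz), sdf)
  ligs <- readSdf(sdf)
  expect_length(ligs, 1)
  expect_equal(nAtoms(ligs[[1]]), 12)
  expect_length(rotatableDihedrals(ligs[[1]]), 0)  # rigid aromatic

  # n-butane: exactly one rotatable dihedral (C2-C3)
  but <- nAlkaneMol(4)
  lig <- ligandFromMol(but)
  expect_length(rotatableDihedrals(lig), 1)
  expect_setequal(rotatableDihedrals(lig)[[1]]@atoms[2:3] |> sort(),
                  c(2L, 3L))

  # formal charges survive the M CHG round trip
  amm <- ligandFromMol(ammoniumMol())
  writeSdf(amm, sdf)
  back <- readSdf(sdf)[[1]]
  expect_equal(atomTable(back)$formalCharge, c(1L, 0L, 0L, 0L, 0L))

  # counts-line mismatch errors with the record index
  bad <- tempfile(fileext = ".sdf")
  writeLines(c("m", "", "", " 99  0  0  0  0  0  0  0  0  0999 V2000",
               "M  END", "$$$$"), bad)
  expect_error(readSdf(bad), "record 1")

  # empty file: empty list with a warning
  empty <- tempfile(fileext = ".sdf")
  writeLines(character(), empty)
  expect_warning(out <- readSdf(empty), "empty")
  expect_length(out, 0)
})

test_that("SDF data fields round-trip byte-identically across records", {
  ligs <- list(ligandFromMol(methanolMol()), ligandFromMol(ethaneMol()),
               ligandFromMol(benzeneMol()))
  for (k in seq_along(ligs)) {
    f <- c(Affinity = sprintf("%.2f", k * 1.5), Series = paste0("S", k))
    sdFields(ligs[[k]]) <- f
  }
  path <- tempfile(fileext = ".sdf")
  writeSdf(ligs, path)
  back <- readSdf(path)
  expect_length(back, 3)
  for (k in seq_along(ligs)) {
    expect_identical(sdFields(back[[k]]), sdFields(ligs[[k]]))
    expect_equal(coords(back[[k]]), coords(ligs[[k]]), tolerance = 1e-4)
    expect_equal(bondTable(back[[k]])$order, bondTable(ligs[[k]])$order)
  }
  # writing the same records twice gives identical bytes (determinism)
  path2 <- tempfile(fileext = ".sdf")
  writeSdf(back, path2)
  path3 <- tempfile(fileext = ".sdf")
  writeSdf(readSdf(path2), path3)
  expect_identical(readLines(path2), readLines(path3))
})

test_that("pose output appends the five score fields and keeps input fields", {
  lig <- ligandFromMol(methanolMol())
  sdFields(lig) <- c(A = "1", B = "two")
  sb <- new("ScoreBreakdown", total = -25, inter = -20, intra = -3,
            site = -1, restraint = -1, terms = c(x = 0),
            weights = c(inter = 1, intra = 1, site = 1, restraint = 1))
  path <- tempfile(fileext = ".sdf")
  writeSdf(list(lig), path, list(sb))
  back <- readSdf(path)[[1]]
  f <- sdFields(back)
  expect_true(all(c("A", "B", "SCORE", "SCORE.INTER", "SCORE.INTRA",
                    "SCORE.SITE", "SCORE.RESTR") %in% names(f)))
  expect_equal(as.numeric(f[["SCORE"]]), -25)
  expect_equal(as.numeric(f[["SCORE.INTER"]]), -20)

  # empty pose list still yields a readable (empty) file
  writeSdf(list(), path)
  expect_warning(expect_length(readSdf(path), 0))
})

test_that("interaction classes follow the documented rule table", {
  met <- methanolMol()
  at <- atomTable(met)
  expect_equal(at$iclass[at$element == "O"], "acceptor")
  expect_equal(at$iclass[3], "donor.H")          # H on O
  expect_true(all(at$iclass[c(1, 4, 5, 6)] == "apolar"))

  amm <- ammoniumMol()
  at <- atomTable(amm)
  expect_equal(at$chargeFlag[1], "pos")
  expect_true(all(at$iclass[2:5] == "donor.H"))

  eth <- atomTable(ethaneMol())
  expect_true(all(eth$iclass == "apolar"))

  # classes follow atoms under reordering
  m <- methanolMol()
  perm <- c(3, 1, 6, 2, 5, 4)
  at0 <- atomTable(m)
  bd <- bondTable(m)
  inv <- order(perm)
  m2 <- buildMolecule(at0$element[perm],
                      coords(m)[perm, ],
                      data.frame(i = inv[bd$i], j = inv[bd$j],
                                 order = bd$order))
  expect_identical(atomTable(m2)$iclass, at0$iclass[perm])

  # unknown element warns and gets class "other"
  expect_warning(
    m3 <- molFromSpec(c("Xx"), matrix(0, 1, 3)), "unknown element")
  expect_equal(atomTable(m3)$iclass, "other")
})

test_that("rotatable-dihedral perception excludes rings, amides, methyls", {
  # cyclohexane: all bonds in a ring
  ang <- seq(0, 300, by = 60) * pi / 180
  cyc <- molFromSpec(rep("C", 6),
                     cbind(1.5 * cos(ang), 1.5 * sin(ang),
                           0.25 * rep(c(1, -1), 3)),
                     data.frame(i = 1:6, j = c(2:6, 1), order = "1"))
  expect_length(perceiveRotatableDihedrals(cyc), 0)

  # n-pentane: 2 rotatable bonds
  expect_length(perceiveRotatableDihedrals(nAlkaneMol(5)), 2)

  # acetamide: amide C-N excluded, methyl terminal
  ace <- molFromSpec(c("C", "C", "O", "N", "H", "H", "H", "H", "H"),
                     rbind(c(0, 0, 0), c(1.52, 0, 0), c(2.15, 1.05, 0),
                           c(2.15, -1.2, 0), c(1.7, -2.1, 0),
                           c(3.16, -1.2, 0), c(-0.4, 1.0, 0),
                           c(-0.4, -0.5, 0.9), c(-0.4, -0.5, -0.9)),
                     data.frame(i = c(1, 2, 2, 4, 4, 1, 1, 1),
                                j = c(2, 3, 4, 5, 6, 7, 8, 9),
                                order = c("1", "2", "1", "1", "1", "1",
                                          "1", "1")))
  expect_length(perceiveRotatableDihedrals(ace), 0)

  # hydroxyl rotors are kept (polar hydrogen moves)
  expect_length(perceiveRotatableDihedrals(methanolMol()), 1)
})

test_that("receptor flexibility is limited to terminal OH/NH3+ in range", {
  # lysine-like fragment: C-C-N(+H3) -> one rotor
  lys <- molFromSpec(c("C", "C", "N", "H", "H", "H", "H"),
                     rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.1, 1.3, 0),
                           c(3.11, 1.3, 0), c(1.75, 1.82, 0.8),
                           c(1.75, 1.82, -0.8), c(-0.5, 0.9, 0)),
                     data.frame(i = c(1, 2, 3, 3, 3, 1),
                                j = c(2, 3, 4, 5, 6, 7), order = "1"),
                     charges = c(0L, 0L, 1L, 0L, 0L, 0L, 0L))
  rec <- new("Receptor", molecule = lys)
  expect_length(perceiveReceptorFlexibility(rec), 1)

  # phenylalanine-like: no OH/NH3+
  phe <- new("Receptor", molecule = benzeneMol())
  expect_length(perceiveReceptorFlexibility(phe), 0)

  # margin filter: hydroxyl far from the cavity is frozen
  tc <- standardToyComplex()
  ser <- molFromSpec(c("C", "C", "O", "H"),
                     rbind(c(90, 0, 0), c(91.5, 0, 0), c(92, 1.35, 0),
                           c(92.9, 1.35, 0)),
                     data.frame(i = c(1, 2, 3), j = c(2, 3, 4),
                                order = "1"))
  recFar <- new("Receptor", molecule = ser)
  expect_length(perceiveReceptorFlexibility(recFar, tc@cavity,
                                            margin = 2), 0)
  expect_length(perceiveReceptorFlexibility(recFar), 1)
})

test_that("dihedral rotations are exact, local and reversible", {
  lig <- makeToyLigand(3, 7, 3, c("hbd", "hba"))
  xyz <- coords(lig)
  for (dh in rotatableDihedrals(lig)) {
    th <- 73.2
    fwd <- rotateDihedral(xyz, dh, th)
    back <- rotateDihedral(fwd, dh, -th)
    expect_lt(max(abs(back - xyz)), 1e-9)
    outside <- setdiff(seq_len(nrow(xyz)), dh@rotatedSet)
    expect_equal(fwd[outside, ], xyz[outside, ])
    expect_equal(dihedralAngle(setDihedralAngle(xyz, dh, -120), dh), -120,
                 tolerance = 1e-9)
  }
})
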