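# Symmetry-aware RMSD, SD utilities and enrichment metrics.

test_that("symmetry RMSD absorbs automorphic relabellings", {
  benz <- ligandFromMol(benzeneMol())
  expect_equal(symmetryRmsd(benz, benz), 0)
  # relabel the ring by a 60-degree graph rotation, coordinates unchanged
  perm <- c(2, 3, 4, 5, 6, 1, 8, 9, 10, 11, 12, 7)
  at <- atomTable(benz)
  bd <- bondTable(benz)
  inv <- order(perm)
  rot <- buildMolecule(at$element[perm], coords(benz)[perm, ],
                       data.frame(i = inv[bd$i], j = inv[bd$j],
                                  order = bd$order))
  rotLig <- ligandFromMol(rot)
  expect_gt(naiveRmsd(benz, rotLig), 1)
  expect_equal(symmetryRmsd(benz, rotLig), 0, tolerance = 1e-9)
  # graph mismatch errors
  expect_error(symmetryRmsd(benz, ligandFromMol(ethaneMol())),
               "graphs differ")
})

test_that("symmetry RMSD equals the brute-force automorphism minimum", {
  mols <- list(benzeneMol(), methanolMol(), nAlkaneMol(5),
               molecule(makeToyLigand(61, 6, 2, c("hbd", "hba"))),
               molecule(makeToyLigand(62, 9, 4,
                                      c("hbd", "hba", "hba"))))
  set.seed(14)
  for (mol in mols) {
    ref <- ligandFromMol(mol)
    pose <- ref
    # a perturbed pose of the same molecule
    coords(pose) <- coords(ref) %*% t(eulerMatrix(15, 40, -30)) +
      matrix(rnorm(3 * nAtoms(ref), sd = 0.3), ncol = 3)
    auts <- bruteAutomorphisms(mol)
    sel <- attr(auts, "atoms")
    X <- coords(ref)[sel, , drop = FALSE]
    Y <- coords(pose)[sel, , drop = FALSE]
    brute <- min(vapply(auts, function(p)
      sqrt(mean(rowSums((X[p, , drop = FALSE] - Y)^2))), numeric(1)))
    expect_equal(symmetryRmsd(ref, pose), brute, tolerance = 1e-9)
    expect_lte(symmetryRmsd(ref, pose), naiveRmsd(ref, pose) + 1e-12)
    # symmetry in the arguments
    expect_equal(symmetryRmsd(ref, pose), symmetryRmsd(pose, ref),
                 tolerance = 1e-9)
  }
})

makeRecords <- function(scores, extra = NULL) {
  lapply(seq_along(scores), function(k) {
    lig <- ligandFromMol(methaneMol())
    f <- c(SCORE = as.character(scores[k]))
    if (!is.null(extra)) f <- c(f, extra[[k]])
    sdFields(lig) <- f
    lig
  })
}

test_that("record filtering follows comparison and boolean semantics", {
  recs <- makeRecords(c(-25, -15))
  kept <- filterRecords(recs, "SCORE < -20")
  expect_length(kept, 1)
  expect_equal(sdFields(kept[[1]])[["SCORE"]], "-25")
  # tautology preserves everything in order
  all <- filterRecords(recs, "SCORE < 100 | SCORE > 100")
  expect_length(all, 2)
  expect_identical(vapply(all, function(r) sdFields(r)[["SCORE"]], ""),
                   c("-25", "-15"))
  # boolean combinations
  expect_length(filterRecords(recs, "SCORE < -10 and SCORE > -20"), 1)
  expect_length(filterRecords(recs, "not (SCORE < -20)"), 1)
  # missing field: excluded with a warning
  expect_warning(none <- filterRecords(recs, "MISSING > 0"), "missing")
  expect_length(none, 0)
  # malformed expression fails before any records are touched
  expect_error(filterRecords(recs, "SCORE <"), "comparison|malformed")
  # numeric vs lexicographic comparison
  recs2 <- makeRecords(c("10", "9"))
  expect_length(filterRecords(recs2, "SCORE < 9.5"), 0 + 1)
})

test_that("record sorting is stable with missing fields last", {
  recs <- makeRecords(c(3, 1, 2))
  out <- sortRecords(recs, "SCORE")
  expect_identical(vapply(out, function(r) sdFields(r)[["SCORE"]], ""),
                   c("1", "2", "3"))
  # equal keys keep input order (tag records to observe stability)
  recs2 <- makeRecords(c(1, 1, 1),
                       extra = list(c(TAG = "a"), c(TAG = "b"),
                                    c(TAG = "c")))
  out2 <- sortRecords(recs2, "SCORE")
  expect_identical(vapply(out2, function(r) sdFields(r)[["TAG"]], ""),
                   c("a", "b", "c"))
  # numeric vs lexicographic
  recs3 <- makeRecords(c("10", "9"))
  expect_identical(vapply(sortRecords(recs3, "SCORE", numeric = TRUE),
                          function(r) sdFields(r)[["SCORE"]], ""),
                   c("9", "10"))
  expect_identical(vapply(sortRecords(recs3, "SCORE", numeric = FALSE),
                          function(r) sdFields(r)[["SCORE"]], ""),
                   c("10", "9"))
  # records without the field sort last
  recs4 <- c(makeRecords(5), list(ligandFromMol(methaneMol())))
  out4 <- sortRecords(recs4, "SCORE")
  expect_length(sdFields(out4[[2]]), 0)
})

test_that("reporting produces parseable TSV and RFC-style CSV", {
  recs <- makeRecords(c(-1.5, 2),
                      extra = list(c(NAME = "plain"),
                                   c(NAME = "with,comma")))
  tsv <- reportRecords(recs, c("SCORE", "NAME"))
  expect_length(tsv, 3)
  expect_identical(tsv[1], "SCORE\tNAME")
  csv <- reportRecords(recs, c("SCORE", "NAME"), format = "csv")
  expect_identical(csv[3], "2,\"with,comma\"")
  # round trip through a CSV parser recovers the values
  parsed <- read.csv(text = paste(csv, collapse = "\n"),
                     colClasses = "character")
  expect_identical(parsed$NAME, c("plain", "with,comma"))
  expect_identical(parsed$SCORE, c("-1.5", "2"))
  # missing values are empty cells
  m <- reportRecords(list(ligandFromMol(methaneMol())), c("SCORE"))
  expect_identical(m[2], "")
})

test_that("enrichment metrics match closed forms on designed rankings", {
  # perfect ranking: all actives first
  perfect <- data.frame(id = 1:100, score = 1:100,
                        active = rep(c(TRUE, FALSE), c(10, 90)))
  vm <- vsMetrics(perfect)
  expect_equal(vm@auc, 1.0)
  # inverted ranking
  inverted <- perfect
  inverted$score <- rev(inverted$score)
  expect_equal(vsMetrics(inverted)@auc, 0.0)
  expect_equal(unname(vsMetrics(inverted)@ef[["1"]]), 0)
  # 10 actives in the top 10 of 1000: EF(1%) = 100
  big <- data.frame(id = 1:1000, score = 1:1000,
                    active = rep(c(TRUE, FALSE), c(10, 990)))
  vmBig <- vsMetrics(big, fractions = c(0.01, 0.2, 1))
  expect_equal(unname(vmBig@ef[["1"]]), 100)
  expect_equal(unname(vmBig@ef[["100"]]), 1)
  expect_equal(vmBig@efMax, 100)
  # logAUC of the perfect ranking is 1 by normalisation
  expect_equal(vmBig@logAuc, 1, tolerance = 1e-9)
  # errors without both classes
  expect_error(vsMetrics(data.frame(id = 1, score = 1, active = TRUE)),
               "at least one")
})

test_that("AUC is invariant under monotone score transforms and matches
          the exhaustive sweep oracle", {
  set.seed(23)
  for (k in 1:25) {
    n <- sample(20:200, 1)
    inst <- data.frame(id = seq_len(n), score = rnorm(n),
                       active = runif(n) < 0.3)
    if (!any(inst$active) || all(inst$active)) next
    vm <- vsMetrics(inst, fractions = c(0.1, 0.5))
    oracle <- vsMetricsOracle(inst)
    expect_equal(vm@auc, oracle$auc, tolerance = 1e-12)
    expect_equal(unname(vm@ef[["10"]]), oracle$ef(0.1), tolerance = 1e-12)
    expect_equal(unname(vm@ef[["50"]]), oracle$ef(0.5), tolerance = 1e-12)
    # strictly monotone transform leaves the ROC unchanged
    inst2 <- inst
    inst2$score <- exp(inst$score / 2)
    expect_equal(vsMetrics(inst2)@auc, vm@auc, tolerance = 1e-12)
  }
  # tie handling equals the Mann-Whitney statistic
  tied <- data.frame(id = 1:6, score = c(1, 1, 1, 2, 2, 3),
                     active = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  w <- wilcox.test(tied$score[!tied$active], tied$score[tied$active],
                   exact = FALSE)$statistic
  expect_equal(vsMetrics(tied)@auc,
               unname(w) / (sum(tied$active) * sum(!tied$active)),
               tolerance = 1e-12)
})
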