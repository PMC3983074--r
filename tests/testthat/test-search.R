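# Chromosome encoding, GA machinery, MC, Simplex and the docking protocol.

test_that("chromosome decoding: identity, translation, periodicity", {
  tc <- standardToyComplex()
  ctx <- dockContext(tc@ligand, tc@receptor, scoringConfig(), tc@cavity)
  ch0 <- encodeChromosome(ctx, tc@ligand)
  # identity: decode(encode(input)) reproduces the input pose
  expect_lt(max(abs(coords(decodeChromosome(ctx, ch0)) -
                      coords(tc@ligand))), 1e-6)
  # COM shift moves every atom rigidly
  ch1 <- ch0
  ch1[1] <- ch1[1] + 1
  d <- coords(decodeChromosome(ctx, ch1)) - coords(tc@ligand)
  expect_equal(unname(colMeans(d)), c(1, 0, 0), tolerance = 1e-6)
  expect_lt(max(abs(sweep(d, 2, colMeans(d)))), 1e-6)
  # heading is periodic with period 360
  ch2 <- ch0; ch2[4] <- ch2[4] + 360
  expect_lt(max(abs(coords(decodeChromosome(ctx, ch2)) -
                      coords(decodeChromosome(ctx, ch0)))), 1e-6)
  # random pose round trip and length checking
  set.seed(2)
  chR <- initializePopulation(2, ctx)[1, ]
  pose <- decodeChromosome(ctx, chR)
  chE <- encodeChromosome(ctx, pose)
  expect_lt(max(abs(coords(decodeChromosome(ctx, chE)) - coords(pose))),
            1e-6)
  expect_error(decodeChromosome(ctx, chR[-1]), "length")
})

test_that("initial populations sample the cavity and are reproducible", {
  tc <- standardToyComplex()
  ctx <- dockContext(tc@ligand, tc@receptor, scoringConfig(), tc@cavity)
  set.seed(7)
  pop <- initializePopulation(200, ctx)
  # every COM is a cavity grid point
  expect_true(all(distanceToCavity(tc@cavity, pop[, 1:3]) == 0))
  d <- moldock:::cpp_min_dist(cavityPoints(tc@cavity), pop[, 1:3])
  expect_true(all(d < 1e-9))
  # same seed, same population
  set.seed(7)
  expect_identical(initializePopulation(200, ctx), pop)
  # dihedral genes pass a uniformity KS test at alpha = 0.01
  set.seed(1234)
  big <- initializePopulation(10000, ctx)
  for (g in 7:ncol(big)) {
    p <- ks.test(big[, g], "punif", -180, 180)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("mutation changes exactly one DOF by a bounded uniform delta", {
  tc <- standardToyComplex()
  ctx <- dockContext(tc@ligand, tc@receptor, scoringConfig(), tc@cavity)
  set.seed(5)
  ch <- initializePopulation(2, ctx)[1, ]
  for (k in 1:50) {
    mut <- mutateChromosome(ch, widths = 2, context = ctx)
    expect_equal(sum(mut != ch), 1)
  }
  # width -> 0 limit: output equals input
  expect_identical(mutateChromosome(ch, widths = 0, context = ctx), ch)
  # empirical deltas on the x-COM gene are uniform on [-1, 1]
  set.seed(77)
  deltas <- replicate(4000, {
    m <- mutateChromosome(ch, widths = 2, context = ctx)
    if (m[1] != ch[1]) m[1] - ch[1] else NA_real_
  })
  deltas <- deltas[!is.na(deltas)]
  expect_gt(length(deltas), 100)
  expect_gt(ks.test(deltas, "punif", -1, 1)$p.value, 0.01)
})

# quadratic "bowl" scorer over the COM genes: analytic optimum for search
# machinery checks, independent of the energy model
bowlScorer <- function(target) {
  function(ch) sum((ch[1:3] - target)^2)
}

test_that("GA converges on the bowl and terminates on uniform populations", {
  tc <- standardToyComplex()
  ctx <- dockContext(tc@ligand, tc@receptor, scoringConfig(), tc@cavity)
  target <- colMeans(cavityPoints(tc@cavity))
  scorer <- bowlScorer(target)
  sp <- stageParams("GA3", scoringConfig(), ctx$nChrom)
  set.seed(10)
  pop <- initializePopulation(40, ctx)
  ga <- runGaStage(pop, scorer, sp, ctx)
  # best trace is non-increasing (elitism) and ends near the optimum
  expect_true(all(diff(ga$bestTrace) <= 0))
  expect_lt(ga$scores[1], scorer(pop[which.min(apply(pop, 1, scorer)), ]) +
              1e-12)
  best <- ga$pop[1, ]
  expect_lt(sqrt(sum((best[1:3] - target)^2)), 1.0)  # mutation-width scale

  # a uniform population at the optimum terminates within 3 generations
  flat <- matrix(rep(c(target, 0, 0, 0,
                       numeric(ctx$nChrom - 6)), each = 20), nrow = 20)
  ga2 <- runGaStage(flat, scorer, sp, ctx)
  expect_lte(ga2$generations, 3)
})

test_that("MC refinement is monotone in the best-seen sense", {
  tc <- standardToyComplex()
  ctx <- dockContext(tc@ligand, tc@receptor, scoringConfig(), tc@cavity)
  target <- colMeans(cavityPoints(tc@cavity))
  scorer <- bowlScorer(target)
  sp <- stageParams("MC", scoringConfig(), ctx$nChrom)
  set.seed(3)
  start <- initializePopulation(2, ctx)[1, ]
  out <- mcRefine(start, scorer, sp, ctx, nSteps = 300)
  expect_lte(out$score, scorer(start))
  # temperature zero: every accepted move is downhill
  sp0 <- sp; sp0$mcTemperature <- 0
  cur <- start; curS <- scorer(cur)
  set.seed(4)
  trace <- c(curS)
  for (k in 1:100) {
    cand <- mutateChromosome(cur, sp0$mutationWidths, ctx)
    s <- scorer(cand)
    if (s <= curS) { cur <- cand; curS <- s }
    trace <- c(trace, curS)
  }
  expect_true(all(diff(trace) <= 0))
  # near-optimum starts tighten on average over seeds
  improvements <- vapply(1:25, function(sd) {
    set.seed(sd)
    st <- c(target + runif(3, -0.3, 0.3), runif(3, -5, 5),
            numeric(ctx$nChrom - 6))
    scorer(st) - mcRefine(st, scorer, sp, ctx, nSteps = 150)$score
  }, numeric(1))
  expect_gt(mean(improvements), 0)
})

test_that("Simplex minimisation reaches the bowl optimum", {
  tc <- standardToyComplex()
  ctx <- dockContext(tc@ligand, tc@receptor, scoringConfig(), tc@cavity)
  target <- colMeans(cavityPoints(tc@cavity))
  scorer <- bowlScorer(target)
  # fixed point: starting at the optimum returns it
  at <- c(target, 10, -20, 30, numeric(ctx$nChrom - 6))
  out <- simplexMinimize(at, scorer)
  expect_lte(out$score, scorer(at))
  expect_lt(out$score, 1e-4)
  # random starts reach the analytic minimum
  set.seed(6)
  for (k in 1:5) {
    st <- initializePopulation(2, ctx)[1, ]
    res <- simplexMinimize(st, scorer)
    expect_lte(res$score, scorer(st))
    expect_lt(res$score, 1e-3)
  }
})

test_that("the stage schedule obeys its invariants", {
  tols <- vapply(c("GA1", "GA2", "GA3", "MC", "MIN"), function(s)
    stageParams(s)$cfg@toleranceScale, numeric(1))
  dihs <- vapply(c("GA1", "GA2", "GA3", "MC", "MIN"), function(s)
    stageParams(s)$cfg@dihedralWeightScale, numeric(1))
  forms <- vapply(c("GA1", "GA2", "GA3", "MC", "MIN"), function(s)
    stageParams(s)$cfg@vdwForm, character(1))
  expect_equal(unname(forms), c("4-8", "4-8", "6-12", "6-12", "6-12"))
  expect_true(all(diff(tols[1:4]) <= 0))
  expect_true(all(diff(dihs[1:4]) >= 0))
  expect_equal(unname(tols[4:5]), c(1, 1))
  expect_equal(unname(dihs[4:5]), c(1, 1))
})

test_that("dock returns sorted results and supports direct entry points", {
  tc <- standardToyComplex()
  res1 <- dock(tc@ligand, tc@receptor, tc@cavity, nRuns = 1, seed = 5)
  expect_length(res1, 1)
  res3 <- dock(tc@ligand, tc@receptor, tc@cavity, nRuns = 3, seed = 5)
  sc <- vapply(res3, scoreTotal, numeric(1))
  expect_true(all(diff(sc) >= 0))
  # the best over a longer run prefix never deteriorates (same stream)
  expect_lte(min(vapply(res3, scoreTotal, numeric(1))),
             scoreTotal(res1[[1]]) + 1e-12)
  # score-only on a pre-docked pose
  scored <- dock(tc@ligand, tc@receptor, tc@cavity, protocol = "score")
  expect_length(scored, 1)
  expect_identical(scored[[1]]@breakdown@intra, 0)
  # minimise-only never worsens the input pose score
  minimised <- dock(tc@ligand, tc@receptor, tc@cavity,
                    protocol = "minimise")
  expect_lte(scoreTotal(minimised[[1]]), scoreTotal(scored[[1]]) + 1e-9)
})

test_that("docking is fully deterministic under a master seed", {
  tc <- standardToyComplex()
  r1 <- dock(tc@ligand, tc@receptor, tc@cavity, nRuns = 2, seed = 31)
  r2 <- dock(tc@ligand, tc@receptor, tc@cavity, nRuns = 2, seed = 31)
  expect_identical(lapply(r1, slot, "chromosome"),
                   lapply(r2, slot, "chromosome"))
  expect_identical(vapply(r1, scoreTotal, numeric(1)),
                   vapply(r2, scoreTotal, numeric(1)))
})

test_that("ligands failing restraint screening are refused", {
  tc <- standardToyComplex()
  rs <- restraintSet(list(pharmacophoreRestraint("positive", c(0, 0, 0),
                                                 2)))
  expect_error(dock(tc@ligand, tc@receptor, tc@cavity, restraints = rs,
                    nRuns = 1, seed = 1), "lacks the features")
})

test_that("HTVS staging eliminates exactly the ligands missing thresholds", {
  suite <- makeRedockingSuite(3, seed = 55, rotorCounts = c(0, 1, 2),
                              verifyStarts = 0)
  rec <- suite[[1]]@receptor
  cav <- suite[[1]]@cavity
  ligs <- lapply(suite, slot, "ligand")
  # dock every ligand in the first system's site; thresholds mid-spread
  probe <- vapply(seq_along(ligs), function(i) {
    scoreTotal(dock(ligs[[i]], rec, cav, nRuns = 2,
                    seed = moldock:::seedForRun(9, 100000 + i),
                    runOffset = 0)[[1]])
  }, numeric(1))
  thr1 <- sort(probe)[2] + 0.05   # two ligands pass stage 1
  protocol <- data.frame(runs = c(2, 4), threshold = c(thr1, NA))
  out <- runHtvs(ligs, rec, cav, protocol, seed = 9)
  expect_equal(which(!is.na(out$table$eliminatedAtStage)),
               which(probe > thr1))
  expect_true(all(out$table$runsDone[is.na(out$table$eliminatedAtStage)] ==
                    4))
  # survivors of stage k are a subset of stage k-1 survivors by design;
  # here: survivors all met the stage-1 threshold
  expect_true(all(out$table$bestScore[out$survivors] <= thr1))

  # a 1-stage protocol reproduces plain docking exactly
  p1 <- data.frame(runs = 3, threshold = NA)
  out1 <- runHtvs(ligs[1], rec, cav, p1, seed = 4)
  plain <- dock(ligs[[1]], rec, cav, nRuns = 3,
                seed = moldock:::seedForRun(4, 100001))
  expect_identical(out1$table$bestScore[1], scoreTotal(plain[[1]]))

  # malformed protocols are refused
  expect_error(runHtvs(ligs, rec, cav,
                       data.frame(runs = c(5, 5),
                                  threshold = c(-1, -2)), seed = 1),
               "strictly increasing")
  expect_error(runHtvs(ligs, rec, cav,
                       data.frame(runs = c(2, 4),
                                  threshold = c(-5, -5)), seed = 1),
               "strictly decreasing")
})

test_that("a GA run beats an equal-budget uniform random sample", {
  suite <- makeRedockingSuite(4, seed = 88, rotorCounts = c(0, 1, 2, 3),
                              verifyStarts = 0)
  wins <- 0
  for (i in seq_along(suite)) {
    tc <- suite[[i]]
    ctx <- dockContext(tc@ligand, tc@receptor, scoringConfig(),
                       tc@cavity, restraintSet())
    scorer <- moldock:::makeScorer(ctx, stageParams("MIN", scoringConfig(),
                                                    ctx$nChrom)$cfg)
    gaBest <- scoreTotal(dock(tc@ligand, tc@receptor, tc@cavity,
                              nRuns = 1, seed = 100 + i)[[1]])
    set.seed(200 + i)
    rnd <- initializePopulation(2000, ctx)
    rndBest <- min(apply(rnd, 1, scorer))
    if (gaBest <= rndBest) wins <- wins + 1
  }
  expect_gte(wins, 3)
})
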