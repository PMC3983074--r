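## Pose search. A chromosome is the numeric vector
## [COM (3), Euler heading/attitude/bank (3), ligand dihedrals, receptor
## dihedrals] (degrees); in tethered mode the first six genes are instead
## the substructure COM deviation and a rotation vector (axis * degrees)
## bounded by the tether tolerances. The standard protocol per run is
## GA1 -> GA2 -> GA3 -> MC -> MIN with the documented scoring schedule:
## the soft 4-8 vdW form, relaxed polar tolerances and a reduced dihedral
## weight early on, everything at its final value for MC/MIN.

#' The staged scoring schedule
#'
#' @param stage one of "GA1", "GA2", "GA3", "MC", "MIN".
#' @param cfg the base [ScoringConfig-class].
#' @param nDof number of chromosome degrees of freedom (sets the default
#'   population size, 50 plus 10 per rotatable dihedral).
#' @return list with the stage's scoring configuration (\code{cfg}),
#'   population size, per-DOF mutation widths and MC temperature.
#' @export
stageParams <- function(stage = c("GA1", "GA2", "GA3", "MC", "MIN"),
                        cfg = scoringConfig(), nDof = 6) {
  stage <- match.arg(stage)
  sched <- list(
    GA1 = list(vdwForm = "4-8",  tol = 2.0, dih = 0.25),
    GA2 = list(vdwForm = "4-8",  tol = 1.5, dih = 0.50),
    GA3 = list(vdwForm = "6-12", tol = 1.2, dih = 0.80),
    MC  = list(vdwForm = "6-12", tol = 1.0, dih = 1.00),
    MIN = list(vdwForm = "6-12", tol = 1.0, dih = 1.00))
  s <- sched[[stage]]
  scfg <- cfg
  scfg@vdwForm <- s$vdwForm
  scfg@toleranceScale <- s$tol
  scfg@dihedralWeightScale <- s$dih
  nDih <- max(0, nDof - 6)
  widths <- c(rep(1.0, 3), rep(30, 3), rep(30, nDih))
  if (stage == "MC") widths <- c(rep(0.2, 3), rep(5, 3), rep(5, nDih))
  list(stage = stage, cfg = scfg,
       populationSize = 50L + 10L * nDih,
       mutationWidths = widths, mcTemperature = 0.3)
}

assertSchedule <- function() {
  tols <- vapply(c("GA1", "GA2", "GA3", "MC"), function(s)
    stageParams(s)$cfg@toleranceScale, numeric(1))
  dihs <- vapply(c("GA1", "GA2", "GA3", "MC"), function(s)
    stageParams(s)$cfg@dihedralWeightScale, numeric(1))
  forms <- vapply(c("GA1", "GA2", "GA3", "MC", "MIN"), function(s)
    stageParams(s)$cfg@vdwForm, character(1))
  stopifnot(all(diff(tols) <= 0), all(diff(dihs) >= 0),
            tols[["MC"]] == 1, dihs[["MC"]] == 1,
            forms[["GA1"]] == "4-8", forms[["GA2"]] == "4-8",
            all(forms[c("GA3", "MC", "MIN")] == "6-12"))
}

#' Encode a pose as a chromosome
#'
#' @param context a context from [dockContext()].
#' @param pose a posed [Ligand-class] or coordinate matrix.
#' @param recDihAngles receptor torsion angles, degrees.
#' @return numeric chromosome; [decodeChromosome()] reproduces the pose
#'   coordinates.
#' @export
encodeChromosome <- function(context, pose, recDihAngles = NULL) {
  X <- if (is(pose, "Ligand")) coords(pose) else as.matrix(pose)
  angles <- vapply(context$ligDihedrals, function(dh) dihedralAngle(X, dh),
                   numeric(1))
  if (is.null(recDihAngles))
    recDihAngles <- vapply(context$recDihedrals,
                           function(dh) dihedralAngle(coords(context$rec), dh),
                           numeric(1))
  if (context$tethered) {
    ## deviations of the tethered substructure from its input placement
    T0 <- coords(context$lig)[context$tetherAtoms, , drop = FALSE]
    T1 <- X[context$tetherAtoms, , drop = FALSE]
    dev <- colMeans(T1) - colMeans(T0)
    fit <- kabsch(sweep(T0, 2, colMeans(T0)), sweep(T1, 2, colMeans(T1)))
    ang <- rotationAngle(fit$R)
    if (ang > 1e-9) {
      ax <- c(fit$R[3, 2] - fit$R[2, 3], fit$R[1, 3] - fit$R[3, 1],
              fit$R[2, 1] - fit$R[1, 2])
      ax <- ax / sqrt(sum(ax^2))
    } else ax <- c(1, 0, 0)
    head6 <- c(dev, ax * ang)
  } else {
    com <- colMeans(X)
    pa <- principalAxes(X)
    eul <- matrixToEuler(t(pa$axes))
    head6 <- c(com, eul)
  }
  as.numeric(c(head6, angles, recDihAngles))
}

#' Decode a chromosome to a ligand pose
#'
#' @param context a context from [dockContext()].
#' @param chrom numeric chromosome.
#' @return the posed [Ligand-class] (receptor torsions are available via
#'   [decodeReceptorCoords()]).
#' @export
decodeChromosome <- function(context, chrom) {
  if (length(chrom) != context$nChrom)
    stop("chromosome length ", length(chrom), " does not match context (",
         context$nChrom, ")")
  lig <- context$lig
  coords(lig) <- cpp_decode_ligand(context$ptr, as.numeric(chrom))
  lig
}

#' @rdname decodeChromosome
#' @export
decodeReceptorCoords <- function(context, chrom) {
  cpp_decode_receptor(context$ptr, as.numeric(chrom))
}

## uniform point in the unit ball (rejection-free via radius transform)
runifBall <- function(radius) {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  v * radius * stats::runif(1)^(1/3)
}

#' Initialise a random population
#'
#' The ligand centre of mass is drawn uniformly from the cavity grid
#' points; Euler angles and all dihedral angles are uniform over their
#' ranges. In tethered mode the six rigid-body genes are drawn inside the
#' tether tolerances instead.
#'
#' @param n population size (>= 2).
#' @param context a context from [dockContext()] built with a cavity.
#' @return matrix with one chromosome per row (uses R's RNG stream).
#' @export
initializePopulation <- function(n, context) {
  stopifnot(n >= 2)
  nDih <- context$nChrom - 6L
  pop <- matrix(0, n, context$nChrom)
  if (context$tethered) {
    tol <- context$restraints@tether
    for (i in seq_len(n)) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      pop[i, 1:3] <- runifBall(tol@transTol)
      pop[i, 4:6] <- ax * stats::runif(1, 0, tol@rotTol)
    }
  } else {
    if (is.null(context$cavity)) stop("population needs a cavity")
    pts <- context$cavity@cavityPoints
    idx <- sample.int(nrow(pts), n, replace = TRUE)
    pop[, 1:3] <- pts[idx, , drop = FALSE]
    pop[, 4] <- stats::runif(n, -180, 180)
    pop[, 5] <- stats::runif(n, -90, 90)
    pop[, 6] <- stats::runif(n, -180, 180)
  }
  if (nDih > 0)
    pop[, 6 + seq_len(nDih)] <- stats::runif(n * nDih, -180, 180)
  pop
}

#' Mutate a single degree of freedom
#'
#' Exactly one randomly selected gene changes, by a delta drawn from a
#' rectangular distribution of the given width; angular genes are
#' renormalised to (-180, 180]. Tethered rigid-body genes are clamped back
#' inside the tether tolerances.
#'
#' @param chrom numeric chromosome.
#' @param widths per-DOF mutation widths (recycled).
#' @param context a context from [dockContext()].
#' @return the mutated chromosome.
#' @export
mutateChromosome <- function(chrom, widths, context) {
  n <- length(chrom)
  widths <- rep_len(widths, n)
  k <- sample.int(n, 1)
  delta <- stats::runif(1, -widths[k] / 2, widths[k] / 2)
  chrom[k] <- chrom[k] + delta
  if (context$tethered) {
    tol <- context$restraints@tether
    if (k <= 3) {
      d <- sqrt(sum(chrom[1:3]^2))
      if (d > tol@transTol) chrom[1:3] <- chrom[1:3] * tol@transTol / d
    } else if (k <= 6) {
      a <- sqrt(sum(chrom[4:6]^2))
      if (a > tol@rotTol) chrom[4:6] <- chrom[4:6] * tol@rotTol / a
    } else chrom[k] <- normalizeAngle(chrom[k])
  } else if (k >= 4) {
    chrom[k] <- normalizeAngle(chrom[k])
  }
  chrom
}

#' Run one genetic-algorithm stage
#'
#' Steady-state GA with rank-based parent selection, per-gene uniform
#' crossover, single-DOF mutation and replace-worst insertion (the best
#' individual is therefore never lost). A generation has passed when a
#' population's worth of new individuals has been created. The stage
#' terminates when the best score has improved by less than
#' \code{convTol} over the last three generations, or at
#' \code{maxGenerations}.
#'
#' @param pop chromosome matrix (one individual per row).
#' @param scorer function(chromosome) -> score (lower is better).
#' @param stage a list from [stageParams()] (used for mutation widths).
#' @param context a context from [dockContext()].
#' @param convTol convergence threshold on the best score (default 0.1).
#' @param maxGenerations hard cap (default 100).
#' @return list: \code{pop} (sorted by score), \code{scores},
#'   \code{bestTrace} (best score per generation, starting at generation 0),
#'   \code{generations}, \code{nEvals}.
#' @export
runGaStage <- function(pop, scorer, stage, context, convTol = 0.1,
                       maxGenerations = 100) {
  n <- nrow(pop)
  stopifnot(n >= 1)
  scores <- apply(pop, 1, scorer)
  nEvals <- n
  bestTrace <- min(scores)
  widths <- stage$mutationWidths
  ## linear rank weights: best rank gets weight n
  gen <- 0
  repeat {
    gen <- gen + 1
    rk <- rank(scores, ties.method = "first")
    w <- n - rk + 1
    for (child in seq_len(n)) {
      par <- sample.int(n, 2, replace = TRUE, prob = w)
      mask <- stats::runif(ncol(pop)) < 0.5
      off <- ifelse(mask, pop[par[1], ], pop[par[2], ])
      off <- mutateChromosome(off, widths, context)
      s <- scorer(off)
      nEvals <- nEvals + 1
      worst <- which.max(scores)
      if (s < scores[worst]) {
        pop[worst, ] <- off
        scores[worst] <- s
        rk <- rank(scores, ties.method = "first")
        w <- n - rk + 1
      }
    }
    bestTrace <- c(bestTrace, min(scores))
    g <- length(bestTrace) - 1
    if (g >= 3 &&
        (bestTrace[g - 3 + 1] - bestTrace[g + 1]) < convTol) break
    if (g >= maxGenerations) break
  }
  ord <- order(scores)
  list(pop = pop[ord, , drop = FALSE], scores = scores[ord],
       bestTrace = bestTrace, generations = gen, nEvals = nEvals)
}

#' Low-temperature Monte Carlo refinement
#'
#' Metropolis acceptance over single-DOF moves; the best pose seen is
#' returned, so the result never scores worse than the input.
#'
#' @param chrom starting chromosome.
#' @param scorer function(chromosome) -> score.
#' @param stage a list from [stageParams()] (mutation widths and
#'   temperature).
#' @param context a context from [dockContext()].
#' @param nSteps number of MC steps (default 500).
#' @return list: \code{chrom} (best seen), \code{score}, \code{accepted}.
#' @export
mcRefine <- function(chrom, scorer, stage = stageParams("MC"), context,
                     nSteps = 500) {
  cur <- chrom
  curS <- scorer(cur)
  best <- cur; bestS <- curS
  acc <- 0L
  temp <- stage$mcTemperature
  for (k in seq_len(nSteps)) {
    cand <- mutateChromosome(cur, stage$mutationWidths, context)
    s <- scorer(cand)
    dE <- s - curS
    if (dE <= 0 || (temp > 0 && stats::runif(1) < exp(-dE / temp))) {
      cur <- cand; curS <- s; acc <- acc + 1L
      if (s < bestS) { best <- cand; bestS <- s }
    }
  }
  list(chrom = best, score = bestS, accepted = acc)
}

#' Simplex (Nelder-Mead) minimisation of a chromosome
#'
#' Runs Nelder-Mead over the chromosome vector until the score spread falls
#' below the tolerance or the evaluation cap is reached; the returned score
#' never exceeds the input score.
#'
#' @param chrom starting chromosome.
#' @param scorer function(chromosome) -> score.
#' @param tol convergence tolerance, score units (default 1e-4).
#' @param maxEvals maximum function evaluations (default 2000).
#' @return list: \code{chrom}, \code{score}.
#' @export
simplexMinimize <- function(chrom, scorer, tol = 1e-4, maxEvals = 2000) {
  res <- stats::optim(chrom, scorer, method = "Nelder-Mead",
                      control = list(maxit = maxEvals, reltol = 1e-10,
                                     abstol = tol))
  s0 <- scorer(chrom)
  if (res$value <= s0) list(chrom = as.numeric(res$par), score = res$value)
  else list(chrom = chrom, score = s0)
}

seedForRun <- function(seed, run) {
  as.integer((as.numeric(seed) + 7919 * run) %% 2147483647)
}

makeScorer <- function(context, cfg, useGrid = FALSE) {
  sv <- stageVector(cfg, useGrid)
  ptr <- context$ptr
  function(ch) cpp_score_chrom(ptr, ch, sv)
}

#' Dock a ligand
#'
#' Runs \code{nRuns} independent GA1/GA2/GA3/MC/MIN pipelines and returns
#' the results sorted by final score (evaluated at the final-stage scoring
#' parameters). The minimisation stage can be accessed directly
#' (\code{protocol = "minimise"}), or a pre-docked pose simply scored
#' (\code{protocol = "score"}).
#'
#' @param lig input [Ligand-class] (must pass restraint screening).
#' @param rec a [Receptor-class].
#' @param cavity a [CavityGrid-class].
#' @param restraints optional [RestraintSet-class].
#' @param cfg base [ScoringConfig-class].
#' @param nRuns number of independent runs (default 50, the exhaustive
#'   docking default).
#' @param seed integer master seed; every run derives its own stream from
#'   it, so results are fully reproducible.
#' @param protocol "dock" (default), "minimise" or "score".
#' @param grids optional precalculated vdW grids (see [dockContext()]).
#' @param popSize GA population size (default from [stageParams()]).
#' @param tetherMapping integer mapping for tethered docking (from
#'   [matchAndReplicate()]; the ligand must already be prealigned).
#' @param mcSteps Monte Carlo steps per run.
#' @param runOffset run-index offset: run r uses the seed stream of run
#'   \code{runOffset + r}, so a docking campaign can be resumed or staged
#'   (used by [runHtvs()]).
#' @return list of [DockResult-class], best first.
#' @export
dock <- function(lig, rec, cavity, restraints = NULL,
                 cfg = scoringConfig(), nRuns = 50, seed = NULL,
                 protocol = c("dock", "minimise", "score"), grids = NULL,
                 popSize = NULL, tetherMapping = NULL, mcSteps = 500,
                 runOffset = 0L) {
  protocol <- match.arg(protocol)
  assertSchedule()
  rs <- if (is.null(restraints)) NULL else restraints
  if (!is.null(rs) && length(rs@pharmacophores) &&
      !screenLigandFeatures(lig, rs))
    stop("ligand '", molName(lig),
         "' lacks the features required by the restraint set")
  context <- dockContext(lig, rec, cfg, cavity, rs, grids,
                         tetherAtoms = tetherMapping)
  useGrid <- context$hasGrids
  nDof <- context$nChrom
  finalStage <- stageParams("MIN", cfg, nDof)
  finalScorer <- makeScorer(context, finalStage$cfg, useGrid)
  finalSv <- stageVector(finalStage$cfg, useGrid)

  buildResult <- function(chrom, run, gens) {
    v <- cpp_score_chrom_full(context$ptr, chrom, finalSv)
    pose <- decodeChromosome(context, chrom)
    nLigDih <- length(context$ligDihedrals)
    recAngles <- if (length(context$recDihedrals))
      chrom[6 + nLigDih + seq_along(context$recDihedrals)] else numeric()
    new("DockResult", pose = pose, receptorDihedrals = recAngles,
        chromosome = as.numeric(chrom),
        breakdown = breakdownFromVector(v, cfg),
        runIndex = as.integer(run), convergedGeneration = as.integer(gens))
  }

  if (protocol == "score") {
    ## evaluate the supplied coordinates directly (no decode round trip)
    recAngles <- vapply(context$recDihedrals,
                        function(dh) dihedralAngle(coords(rec), dh),
                        numeric(1))
    v <- cpp_score_coords(context$ptr, coords(lig), recAngles, finalSv)
    return(list(new("DockResult", pose = lig,
                    receptorDihedrals = recAngles,
                    chromosome = encodeChromosome(context, lig),
                    breakdown = breakdownFromVector(v, cfg),
                    runIndex = 0L, convergedGeneration = 0L)))
  }
  if (protocol == "minimise") {
    chrom <- encodeChromosome(context, lig)
    m <- simplexMinimize(chrom, finalScorer)
    return(list(buildResult(m$chrom, 0L, 0L)))
  }

  results <- vector("list", nRuns)
  for (run in seq_len(nRuns)) {
    if (!is.null(seed)) set.seed(seedForRun(seed, runOffset + run))
    best <- NULL
    pop <- NULL
    for (sname in c("GA1", "GA2", "GA3")) {
      sp <- stageParams(sname, cfg, nDof)
      if (!is.null(popSize)) sp$populationSize <- popSize
      scorer <- makeScorer(context, sp$cfg, useGrid)
      if (is.null(pop)) pop <- initializePopulation(sp$populationSize,
                                                    context)
      ga <- runGaStage(pop, scorer, sp, context)
      pop <- ga$pop
      gens <- ga$generations
    }
    spMC <- stageParams("MC", cfg, nDof)
    mcScorer <- makeScorer(context, spMC$cfg, useGrid)
    mc <- mcRefine(pop[1, ], mcScorer, spMC, context, nSteps = mcSteps)
    mn <- simplexMinimize(mc$chrom, finalScorer)
    results[[run]] <- buildResult(mn$chrom, runOffset + run, gens)
  }
  ord <- order(vapply(results, scoreTotal, numeric(1)))
  results[ord]
}

#' Multi-step high-throughput virtual screening protocol
#'
#' Staged docking: every ligand receives the stage-1 run count; only
#' ligands whose best score meets a stage's threshold advance to the next
#' (cumulative) run count. Per-ligand, per-run seed streams are shared with
#' [dock()], so a single-stage protocol reproduces plain docking exactly.
#'
#' @param ligands list of [Ligand-class].
#' @param rec,cavity,restraints,cfg,grids as for [dock()].
#' @param protocol data.frame with columns \code{runs} (cumulative, strictly
#'   increasing) and \code{threshold} (strictly decreasing; the last may be
#'   NA, meaning the final stage filters nothing).
#' @param seed master seed.
#' @param ... further arguments passed to [dock()].
#' @return list with \code{table} (data.frame: ligand, bestScore,
#'   runsDone, eliminatedAtStage (NA = survivor)), \code{survivors}
#'   (ligand indices, ranked by best score) and \code{results} (per-ligand
#'   best [DockResult-class]).
#' @export
runHtvs <- function(ligands, rec, cavity, protocol, restraints = NULL,
                    cfg = scoringConfig(), seed = 1, grids = NULL, ...) {
  protocol <- as.data.frame(protocol)
  if (!all(c("runs", "threshold") %in% names(protocol)))
    stop("protocol needs columns 'runs' and 'threshold'")
  if (nrow(protocol) < 1) stop("empty protocol")
  if (any(diff(protocol$runs) <= 0))
    stop("protocol run counts must be strictly increasing")
  thr <- protocol$threshold[!is.na(protocol$threshold)]
  if (any(diff(thr) >= 0))
    stop("protocol thresholds must be strictly decreasing")
  nL <- length(ligands)
  bestScore <- rep(NA_real_, nL)
  runsDone <- rep(0L, nL)
  elim <- rep(NA_integer_, nL)
  bestRes <- vector("list", nL)
  active <- seq_len(nL)
  for (st in seq_len(nrow(protocol))) {
    target <- protocol$runs[st]
    for (li in active) {
      ligSeed <- seedForRun(seed, 100000 + li)
      res <- dock(ligands[[li]], rec, cavity, restraints = restraints,
                  cfg = cfg, grids = grids,
                  nRuns = target - runsDone[li],
                  seed = ligSeed, runOffset = runsDone[li], ...)
      runsDone[li] <- target
      top <- res[[1]]
      if (is.na(bestScore[li]) || scoreTotal(top) < bestScore[li]) {
        bestScore[li] <- scoreTotal(top)
        bestRes[[li]] <- top
      }
    }
    th <- protocol$threshold[st]
    if (!is.na(th)) {
      dropped <- active[bestScore[active] > th]
      elim[dropped] <- st
      active <- setdiff(active, dropped)
    }
    if (!length(active)) break
  }
  ord <- order(bestScore)
  survivors <- ord[ord %in% active]
  list(table = data.frame(ligand = seq_len(nL), bestScore = bestScore,
                          runsDone = runsDone, eliminatedAtStage = elim),
       survivors = survivors, results = bestRes)
}
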