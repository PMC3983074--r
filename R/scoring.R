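## The composite scoring function. The master score is a weighted sum of
## intermolecular, ligand intramolecular, flexible-site and restraint
## components; the constituent potentials are a soft-core n/2n van der Waals
## term, an empirical polar term built from trapezoidal distance and angular
## ramps, an optional pairwise-approximation desolvation term and a 3-fold
## ligand dihedral potential. All numeric parameters live in the shipped
## tables under inst/extdata/params; the values are this package's own
## calibration, not the original program's.

polarAngleEdges <- c(donor = 150, acceptor = 90)

#' Scoring configuration
#'
#' @param sf scoring-function preset: "SF3" (default; repulsive polar term,
#'   no desolvation) or "SF5" (desolvation term, attractive-only polar).
#' @param vdwForm "6-12" or "4-8".
#' @param weights named numeric overriding any of inter, intra, site,
#'   restraint, vdw, polar, desolv, dihedral. The polar weight is the well
#'   depth of an ideal neutral hydrogen bond (score units).
#' @param polarDistWindow ideal donor-acceptor heavy-atom distance window
#'   (Angstroms).
#' @param polarDistTol,polarAngleTol base ramp widths (Angstroms / degrees).
#' @param toleranceScale stage relaxation multiplier (>= 1).
#' @param dihedralWeightScale stage scale of the ligand dihedral term.
#' @param vdwCap per-pair short-range cap, score units.
#' @param scale14 scale for 1-4 intramolecular vdW pairs.
#' @param chargedScale multiplier for charged-charged polar pairs.
#' @return a [ScoringConfig-class].
#' @export
scoringConfig <- function(sf = c("SF3", "SF5"), vdwForm = "6-12",
                          weights = c(), polarDistWindow = c(2.5, 3.1),
                          polarDistTol = 0.6, polarAngleTol = 30,
                          toleranceScale = 1, dihedralWeightScale = 1,
                          vdwCap = 100, scale14 = 0.5, chargedScale = 2) {
  sf <- match.arg(sf)
  w <- c(inter = 1, intra = 1, site = 1, restraint = 1,
         vdw = 1, polar = 4, desolv = 1, dihedral = 1)
  if (length(weights)) w[names(weights)] <- weights
  new("ScoringConfig", weights = w, vdwForm = vdwForm,
      polarMode = if (sf == "SF3") "attractive+repulsive"
                  else "attractive-only",
      useDesolvation = sf == "SF5",
      polarDistWindow = polarDistWindow, polarDistTol = polarDistTol,
      polarAngleTol = polarAngleTol, toleranceScale = toleranceScale,
      dihedralWeightScale = dihedralWeightScale, vdwCap = vdwCap,
      scale14 = scale14, chargedScale = chargedScale)
}

vdwFormExponents <- function(form) {
  switch(form, "6-12" = c(n = 12, m = 6), "4-8" = c(n = 8, m = 4),
         stop("unknown vdW form: ", form))
}

#' Pairwise van der Waals energy
#'
#' \code{E = eps * ((r0/r)^n - 2 (r0/r)^m)} with n = 2m: the 6-12 form has
#' (n, m) = (12, 6), the softer 4-8 form (8, 4). The minimum is -eps at
#' r = r0; the analytic zero crossing lies at \code{r0 * 2^(-1/m)}. Energies
#' are capped at \code{cap} at short range.
#'
#' @param r interatomic distance, Angstroms (> 0).
#' @param r0 pair equilibrium distance, Angstroms.
#' @param eps pair well depth, score units.
#' @param form "6-12" or "4-8".
#' @param cap short-range cap (default 100).
#' @return energy in score units (vectorised over \code{r}).
#' @export
vdwPairEnergy <- function(r, r0, eps, form = "6-12", cap = 100) {
  if (any(r <= 0)) stop("r must be > 0")
  ex <- vdwFormExponents(form)
  q <- r0 / r
  pmin(eps * (q^ex[["n"]] - 2 * q^ex[["m"]]), cap)
}

## vdW class key: polar (donor) hydrogens get a reduced radius so that
## hydrogen-bond approach distances are not penalised by steric repulsion
vdwClassKey <- function(elements, iclass = NULL) {
  key <- elements
  if (!is.null(iclass)) key[elements == "H" & iclass == "donor.H"] <- "H.polar"
  key
}

## per-atom vdW parameters from the element table
vdwAtomParams <- function(elements, iclass = NULL) {
  p <- elementParamRow(vdwClassKey(elements, iclass))
  list(radius = p$radius, eps = p$eps)
}

## Lorentz-Berthelot-style mixing: r0 = sum of radii, eps geometric mean.
vdwPairParams <- function(elementsA, elementsB, iclassA = NULL,
                          iclassB = NULL) {
  pa <- vdwAtomParams(elementsA, iclassA)
  pb <- vdwAtomParams(elementsB, iclassB)
  list(r0 = outer(pa$radius, pb$radius, "+"),
       eps = sqrt(outer(pa$eps, pb$eps)))
}

trapezoidRamp <- function(d, lo, hi, tol) {
  f <- numeric(length(d))
  f[d >= lo & d <= hi] <- 1
  up <- d > lo - tol & d < lo
  f[up] <- (d[up] - (lo - tol)) / tol
  dn <- d > hi & d < hi + tol
  f[dn] <- ((hi + tol) - d[dn]) / tol
  f
}

angleRamp <- function(theta, edge, tol) {
  f <- numeric(length(theta))
  f[theta >= edge] <- 1
  mid <- theta > edge - tol & theta < edge
  f[mid] <- (theta[mid] - (edge - tol)) / tol
  f
}

vectorAngle <- function(p, q, r) {
  u <- p - q; v <- r - q
  c0 <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  rad2deg(acos(min(1, max(-1, c0))))
}

#' Empirical polar pair energy
#'
#' \code{E = sign * W * f_dist(d) * f_angle(theta) * f_angle(phi)} where the
#' ramps are 1 inside the ideal window and fall linearly to 0 across the
#' tolerance band (tolerances scaled by the stage relaxation factor). The
#' sign is negative (favourable) for donor-acceptor pairs and positive
#' (repulsive; "attractive+repulsive" mode only) for donor-donor and
#' acceptor-acceptor contacts, for which a one-sided contact ramp is used.
#' Pairs of two formally charged partners are scaled by the charged
#' multiplier.
#'
#' @param donor list describing the first site: \code{pos} (heavy-atom
#'   position), \code{h} (attached polar H position, may be NULL),
#'   \code{kind} ("donor", "acceptor" or "metal"), \code{charged} logical,
#'   optional \code{ambi} logical (atom is both donor and acceptor, e.g. a
#'   hydroxyl oxygen; such atoms are exempt from same-polarity repulsion).
#' @param acceptor list describing the second site: \code{pos}, \code{root}
#'   (attached heavy-atom position or NULL), \code{kind}, \code{charged}.
#' @param cfg a [ScoringConfig-class].
#' @return energy in score units.
#' @export
polarPairEnergy <- function(donor, acceptor, cfg) {
  W <- cfg@weights[["polar"]]
  s <- cfg@toleranceScale
  dtol <- cfg@polarDistTol * s
  atol <- cfg@polarAngleTol * s
  lo <- cfg@polarDistWindow[1]; hi <- cfg@polarDistWindow[2]
  mul <- if (isTRUE(donor$charged) && isTRUE(acceptor$charged))
    cfg@chargedScale else 1
  kinds <- c(donor$kind, acceptor$kind)
  d <- sqrt(sum((donor$pos - acceptor$pos)^2))
  isPair <- ("acceptor" %in% kinds) && any(kinds %in% c("donor", "metal"))
  if (isPair) {
    if (donor$kind == "acceptor") { tmp <- donor; donor <- acceptor; acceptor <- tmp }
    fd <- trapezoidRamp(d, lo, hi, dtol)
    if (fd == 0) return(0)
    fth <- 1; fph <- 1
    if (donor$kind == "donor" && !is.null(donor$h)) {
      th <- vectorAngle(donor$pos, donor$h, acceptor$pos)
      fth <- angleRamp(th, polarAngleEdges[["donor"]], atol)
      if (!is.null(acceptor$root)) {
        ph <- vectorAngle(acceptor$root, acceptor$pos, donor$h)
        fph <- angleRamp(ph, polarAngleEdges[["acceptor"]], atol)
      }
    } else if (!is.null(acceptor$root)) {
      ph <- vectorAngle(acceptor$root, acceptor$pos, donor$pos)
      fph <- angleRamp(ph, polarAngleEdges[["acceptor"]], atol)
    }
    return(-W * mul * fd * fth * fph)
  }
  if (cfg@polarMode != "attractive+repulsive") return(0)
  if (isTRUE(donor$ambi) || isTRUE(acceptor$ambi)) return(0)
  if (all(kinds == "donor") || all(kinds == "acceptor")) {
    f <- if (d >= hi + dtol) 0 else if (d <= hi) 1 else ((hi + dtol) - d) / dtol
    return(W * mul * f)
  }
  0
}

#' Probabilistic (pairwise-product) solvent accessible surface area
#'
#' Approximates per-atom SASA as
#' \code{A_i = S_i * prod_j (1 - p_i p_ij b_ij / S_i)} with
#' \code{S_i = 4 pi (r_i + r_solv)^2} and \code{b_ij} the sphere-overlap
#' area of the solvent-inflated spheres. \code{p_i} comes from the shipped
#' element table and \code{p_ij} is a connectivity-class constant (1.0296
#' for 1-2 pairs, 0 for 1-3 pairs, 0.2631 otherwise); both were calibrated
#' in-package against numerical sphere-sampling areas. An isolated atom
#' returns exactly \code{S_i}.
#'
#' @param x a [Molecule-class], or an n x 3 coordinate matrix.
#' @param elements element symbols (required when \code{x} is a matrix).
#' @param bonds optional two-column matrix of bonded pairs (matrix input).
#' @param rsolv solvent probe radius, Angstroms (default 1.4).
#' @param dfloor distance floor for overlapping centres (default 0.1).
#' @return numeric vector of per-atom areas, square Angstroms, each in
#'   \code{[0, S_i]}.
#' @export
haselSasa <- function(x, elements = NULL, bonds = NULL, rsolv = 1.4,
                      dfloor = 0.1) {
  if (is(x, "Molecule") || is(x, "Ligand") || is(x, "Receptor")) {
    if (is(x, "Ligand") || is(x, "Receptor")) x <- molecule(x)
    elements <- x@atoms$element
    bonds <- as.matrix(x@bonds[, c("i", "j")])
    x <- coords(x)
  }
  n <- nrow(x)
  p <- elementParamRow(elements)
  pij <- pijFromBonds(n, bonds)
  as.numeric(cpp_hasel_sasa(as.matrix(x), p$radius, p$haselP, pij, rsolv,
                            dfloor))
}

## connectivity-class p_ij matrix from a bond list (calibrated constants:
## 1-2 pairs 1.0296, 1-3 pairs 0, more distant pairs 0.2631)
pijFromBonds <- function(n, bonds) {
  pij <- matrix(0.2631, n, n)
  diag(pij) <- 0
  if (is.null(bonds) || nrow(bonds) == 0) return(pij)
  g <- igraph::graph_from_data_frame(
    data.frame(i = bonds[, 1], j = bonds[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  gd <- igraph::distances(g)
  gd <- gd[as.character(seq_len(n)), as.character(seq_len(n))]
  pij[gd == 1] <- 1.0296
  pij[gd == 2] <- 0.0
  diag(pij) <- 0
  pij
}

desolvWeights <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "params", "desolvation.csv",
                          package = "moldock")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

desolvWeightByClass <- function(iclass) {
  w <- desolvWeights()
  i <- match(iclass, w$iclass)
  i[is.na(i)] <- match("other", w$iclass)
  w$weight[i]
}

#' Desolvation score of a ligand pose against a receptor
#'
#' Weighted change in approximate solvent accessible surface area on
#' binding: \code{sum_i w_class(i) (A_i^bound - A_i^free)} over ligand and
#' receptor atoms, with areas from [haselSasa()]. With the shipped weights,
#' burial of apolar surface is favourable (negative) and burial of polar
#' surface unfavourable.
#'
#' @param lig a [Ligand-class] pose.
#' @param rec a [Receptor-class].
#' @param rsolv solvent probe radius, Angstroms.
#' @return desolvation score, score units.
#' @export
desolvationScore <- function(lig, rec, rsolv = 1.4) {
  ml <- molecule(lig); mr <- molecule(rec)
  nL <- nAtoms(ml); nR <- nAtoms(mr)
  X <- rbind(coords(ml), coords(mr))
  el <- c(ml@atoms$element, mr@atoms$element)
  p <- elementParamRow(el)
  pij <- matrix(0.2631, nL + nR, nL + nR)
  pij[seq_len(nL), seq_len(nL)] <-
    pijFromBonds(nL, as.matrix(ml@bonds[, c("i", "j")]))
  pij[nL + seq_len(nR), nL + seq_len(nR)] <-
    pijFromBonds(nR, as.matrix(mr@bonds[, c("i", "j")]))
  diag(pij) <- 0
  Ab <- as.numeric(cpp_hasel_sasa(X, p$radius, p$haselP, pij, rsolv, 0.1))
  Afl <- haselSasa(ml, rsolv = rsolv)
  Afr <- haselSasa(mr, rsolv = rsolv)
  w <- desolvWeightByClass(c(ml@atoms$iclass, mr@atoms$iclass))
  sum(w * (Ab - c(Afl, Afr)))
}

torsionBarriers <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "params", "torsions.csv",
                          package = "moldock")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

torsionBarrierFor <- function(elB, elC) {
  tb <- torsionBarriers()
  key <- paste(sort(c(elB, elC)), collapse = "-")
  i <- match(key, tb$central)
  if (is.na(i)) i <- match("*", tb$central)
  tb$barrier[i]
}

#' Ligand dihedral (torsional strain) energy
#'
#' Sum over rotatable dihedrals of a 3-fold cosine potential,
#' \code{V/2 (1 + cos 3 phi)}, with the barrier V looked up by the central
#' bond's element pair in the shipped torsion table, scaled by the stage
#' dihedral weight.
#'
#' @param lig a [Ligand-class].
#' @param cfg a [ScoringConfig-class] (uses \code{dihedralWeightScale}).
#' @param xyz optional coordinates to evaluate (default: current ligand
#'   coordinates).
#' @return torsional energy, score units.
#' @export
ligandDihedralEnergy <- function(lig, cfg = scoringConfig(), xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(lig)
  el <- molecule(lig)@atoms$element
  e <- 0
  for (dh in rotatableDihedrals(lig)) {
    phi <- deg2rad(dihedralAngle(xyz, dh))
    V <- torsionBarrierFor(el[dh@atoms[2]], el[dh@atoms[3]])
    e <- e + 0.5 * V * (1 + cos(3 * phi))
  }
  e * cfg@dihedralWeightScale
}
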