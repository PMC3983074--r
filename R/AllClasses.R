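## Central S4 containers. Atom tables are plain data.frames (one row per atom,
## input order preserved); coordinates are Angstroms in a right-handed frame;
## atom indices are 1-based at the R surface and in file I/O.

#' Dihedral degree of freedom
#'
#' A torsion a-b-c-d together with the set of atoms that move when the angle
#' changes. The rotated set is one connected component of the molecule after
#' deleting the b-c bond; it contains c and d and excludes a and b.
#'
#' @slot atoms integer(4), atom indices a, b, c, d (1-based).
#' @slot rotatedSet integer vector of atom indices moved by the rotation.
#' @export
setClass("Dihedral",
  representation(atoms = "integer", rotatedSet = "integer"),
  validity = function(object) {
    if (length(object@atoms) != 4L) return("atoms must have length 4")
    a <- object@atoms
    if (a[1] %in% object@rotatedSet || a[2] %in% object@rotatedSet)
      return("atoms a, b must not be in the rotated set")
    if (!(a[3] %in% object@rotatedSet) || !(a[4] %in% object@rotatedSet))
      return("atoms c, d must be in the rotated set")
    TRUE
  })

Dihedral <- function(atoms, rotatedSet) {
  new("Dihedral", atoms = as.integer(atoms), rotatedSet = as.integer(rotatedSet))
}

#' Molecular graph with coordinates
#'
#' @slot name molecule name (SDF/MOL2 title line).
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{formalCharge}, \code{partialCharge}, \code{iclass}
#'   (interaction class), \code{chargeFlag} ("pos", "neg" or "neutral").
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order} (character: "1", "2", "3", "ar", "am").
#' @slot rings list of integer vectors, the smallest set of smallest rings.
#' @slot sdFields named character vector of SD data items, order preserved.
#' @export
setClass("Molecule",
  representation(name = "character", atoms = "data.frame",
                 bonds = "data.frame", rings = "list", sdFields = "character"),
  prototype(name = "", rings = list(), sdFields = character()),
  validity = function(object) {
    at <- object@atoms
    bd <- object@bonds
    need <- c("element", "x", "y", "z", "formalCharge")
    if (!all(need %in% names(at)))
      return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(at) > 0 && !all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
      return("atom positions must be finite")
    if (nrow(at) > 0 && !all(at$formalCharge %in% (-4):4))
      return("formal charges must be integers in [-4, 4]")
    if (nrow(bd) > 0) {
      if (!all(c(bd$i, bd$j) %in% seq_len(nrow(at))))
        return("bond endpoints must be valid atom indices")
    }
    if (length(object@rings) &&
        !all(unlist(object@rings) %in% seq_len(nrow(at))))
      return("ring atom indices out of range")
    TRUE
  })

#' Receptor: a molecule plus its flexible terminal OH / NH3+ torsions
#'
#' @slot molecule a [Molecule-class].
#' @slot flexibleDihedrals list of [Dihedral-class]; every rotated moiety is a
#'   terminal hydroxyl or ammonium group.
#' @export
setClass("Receptor",
  representation(molecule = "Molecule", flexibleDihedrals = "list"),
  prototype(flexibleDihedrals = list()))

#' Ligand: a molecule plus its rotatable (exocyclic) dihedrals
#'
#' @slot molecule a [Molecule-class].
#' @slot rotatableDihedrals list of [Dihedral-class]; no central bond lies in
#'   a ring, so ring-internal geometry is never altered by the engine.
#' @export
setClass("Ligand",
  representation(molecule = "Molecule", rotatableDihedrals = "list"),
  prototype(rotatableDihedrals = list()),
  validity = function(object) {
    ringEdges <- ringBondKeys(object@molecule)
    for (dh in object@rotatableDihedrals) {
      key <- paste(sort(dh@atoms[2:3]), collapse = "-")
      if (key %in% ringEdges)
        return("rotatable dihedral central bond lies in a ring")
    }
    TRUE
  })

ringBondKeys <- function(mol) {
  out <- character()
  for (r in mol@rings) {
    n <- length(r)
    for (k in seq_len(n)) {
      e <- sort(c(r[k], r[if (k == n) 1L else k + 1L]))
      out <- c(out, paste(e, collapse = "-"))
    }
  }
  unique(out)
}

#' Docking volume as a boolean lattice with distance queries
#'
#' @slot origin Cartesian position of lattice index (1,1,1), Angstroms.
#' @slot spacing lattice spacing, Angstroms.
#' @slot dims integer(3) lattice shape.
#' @slot inside logical array, TRUE on cavity points.
#' @slot distanceLattice numeric array, Euclidean distance (A) from each
#'   lattice point to the nearest cavity point (0 inside).
#' @slot cavityPoints n x 3 matrix of Cartesian coordinates of cavity points.
#' @export
setClass("CavityGrid",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 inside = "array", distanceLattice = "array",
                 cavityPoints = "matrix"),
  validity = function(object) {
    if (sum(object@inside) == 0L) return("cavity is empty")
    if (any(object@distanceLattice[object@inside] != 0))
      return("distance lattice must be 0 on cavity points")
    if (nrow(object@cavityPoints) != sum(object@inside))
      return("cavityPoints inconsistent with inside lattice")
    TRUE
  })

#' Scoring-function configuration
#'
#' Two presets mirror the two shipped scoring functions: the default
#' ("SF3") uses the repulsive polar term and no desolvation, the solvation
#' variant ("SF5") the opposite. The stage schedule of the docking protocol is
#' the only code that varies \code{vdwForm}, \code{toleranceScale} and
#' \code{dihedralWeightScale} between search stages.
#'
#' @slot weights named numeric: inter, intra, site, restraint (component
#'   weights) and vdw, polar, desolv, dihedral (sub-term weights).
#' @slot vdwForm "6-12" or "4-8".
#' @slot polarMode "attractive+repulsive" or "attractive-only".
#' @slot useDesolvation logical scalar.
#' @slot polarDistWindow numeric(2), ideal donor-heavy to acceptor distance
#'   window, Angstroms.
#' @slot polarDistTol base distance tolerance (ramp width), Angstroms.
#' @slot polarAngleTol base angular tolerance, degrees.
#' @slot toleranceScale stage relaxation multiplier (>= 1) applied to both
#'   polar tolerances.
#' @slot dihedralWeightScale stage scale in [0, 1] of the ligand dihedral term.
#' @slot vdwCap short-range cap on a single pair energy, score units.
#' @slot scale14 scale factor for 1-4 intramolecular vdW pairs.
#' @slot chargedScale multiplier on polar pairs where both partners are
#'   formally charged.
#' @export
setClass("ScoringConfig",
  representation(weights = "numeric", vdwForm = "character",
                 polarMode = "character", useDesolvation = "logical",
                 polarDistWindow = "numeric", polarDistTol = "numeric",
                 polarAngleTol = "numeric", toleranceScale = "numeric",
                 dihedralWeightScale = "numeric", vdwCap = "numeric",
                 scale14 = "numeric", chargedScale = "numeric"),
  validity = function(object) {
    need <- c("inter", "intra", "site", "restraint",
              "vdw", "polar", "desolv", "dihedral")
    if (!all(need %in% names(object@weights)))
      return(paste("weights must name:", paste(need, collapse = ", ")))
    if (!all(is.finite(object@weights))) return("weights must be finite")
    if (!object@vdwForm %in% c("6-12", "4-8")) return("bad vdwForm")
    if (!object@polarMode %in% c("attractive+repulsive", "attractive-only"))
      return("bad polarMode")
    if (object@toleranceScale < 1) return("toleranceScale must be >= 1")
    if (object@dihedralWeightScale < 0 || object@dihedralWeightScale > 1)
      return("dihedralWeightScale must lie in [0, 1]")
    TRUE
  })

#' Score decomposition of a pose
#'
#' @slot total weighted sum of the four components.
#' @slot inter,intra,site,restraint the four (unweighted) components.
#' @slot terms named numeric of sub-terms (inter.vdw, inter.polar, ...).
#' @slot weights the four component weights used to form the total.
#' @export
setClass("ScoreBreakdown",
  representation(total = "numeric", inter = "numeric", intra = "numeric",
                 site = "numeric", restraint = "numeric", terms = "numeric",
                 weights = "numeric"),
  validity = function(object) {
    w <- object@weights
    tot <- w[["inter"]] * object@inter + w[["intra"]] * object@intra +
      w[["site"]] * object@site + w[["restraint"]] * object@restraint
    if (abs(tot - object@total) > 1e-9)
      return("total must equal the weighted sum of components")
    TRUE
  })

#' Precalculated receptor vdW field, one lattice per ligand atom class
#'
#' @slot origin,spacing,dims lattice geometry (see [CavityGrid-class]).
#' @slot grids named list of numeric arrays, keyed by ligand vdW class
#'   (element symbol).
#' @export
setClass("VdwGridSet",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 grids = "list"),
  validity = function(object) {
    if (!all(vapply(object@grids, function(g) all(is.finite(g)), logical(1))))
      return("grid values must be finite (capped)")
    TRUE
  })

#' Pharmacophore tolerance-sphere restraint
#'
#' @slot featureType one of "hba", "hbd", "hydrophobic", "aliphatic",
#'   "aromatic", "negative", "positive", "any".
#' @slot center numeric(3), Angstroms.
#' @slot radius sphere radius, Angstroms.
#' @slot mandatory logical scalar.
#' @slot weight penalty proportionality constant (score units per A^2).
#' @export
setClass("PharmacophoreRestraint",
  representation(featureType = "character", center = "numeric",
                 radius = "numeric", mandatory = "logical",
                 weight = "numeric"),
  validity = function(object) {
    if (!object@featureType %in% ph4FeatureTypes())
      return(paste("featureType must be one of:",
                   paste(ph4FeatureTypes(), collapse = ", ")))
    if (object@radius <= 0) return("radius must be > 0")
    TRUE
  })

#' The eight recognised pharmacophore feature types
#' @return character vector of feature type keys.
#' @export
ph4FeatureTypes <- function() {
  c("hba", "hbd", "hydrophobic", "aliphatic", "aromatic",
    "negative", "positive", "any")
}

#' Tethered-template specification
#'
#' @slot smarts substructure query string (SMARTS subset).
#' @slot referenceCoords k x 3 matrix of reference coordinates for the matched
#'   substructure heavy atoms, in query-atom order.
#' @slot transTol maximum substructure centre-of-mass deviation, Angstroms.
#' @slot rotTol maximum substructure rotation, degrees.
#' @export
setClass("TetherSpec",
  representation(smarts = "character", referenceCoords = "matrix",
                 transTol = "numeric", rotTol = "numeric"),
  prototype(transTol = 0.1, rotTol = 1.0),
  validity = function(object) {
    if (object@transTol < 0 || object@rotTol < 0)
      return("tolerances must be >= 0")
    TRUE
  })

#' Minimum/maximum distance restraint between atom groups
#'
#' @slot ligandSelector integer vector of ligand atom indices.
#' @slot receptorSelector integer vector of receptor atom indices.
#' @slot bound distance bound, Angstroms (> 0).
#' @slot weight penalty weight.
#' @slot semantics "upper" (NOE-style: penalise min-pair distance above the
#'   bound) or "lower" (penalise min-pair distance below the bound).
#' @export
setClass("DistanceRestraint",
  representation(ligandSelector = "integer", receptorSelector = "integer",
                 bound = "numeric", weight = "numeric",
                 semantics = "character"),
  prototype(weight = 1.0, semantics = "upper"),
  validity = function(object) {
    if (object@bound <= 0) return("bound must be > 0")
    if (!object@semantics %in% c("upper", "lower"))
      return("semantics must be 'upper' or 'lower'")
    TRUE
  })

#' Collection of bias terms attached to a docking run
#'
#' @slot pharmacophores list of [PharmacophoreRestraint-class].
#' @slot nOpt number of optional pharmacophore restraints that must be met.
#' @slot tether a [TetherSpec-class] or NULL.
#' @slot distanceRestraints list of [DistanceRestraint-class].
#' @slot cavityWeight weight of the cavity containment penalty.
#' @export
setClass("RestraintSet",
  representation(pharmacophores = "list", nOpt = "integer",
                 tether = "ANY", distanceRestraints = "list",
                 cavityWeight = "numeric"),
  prototype(pharmacophores = list(), nOpt = 0L, tether = NULL,
            distanceRestraints = list(), cavityWeight = 1.0),
  validity = function(object) {
    nopt <- sum(!vapply(object@pharmacophores, slot, logical(1), "mandatory"))
    if (object@nOpt < 0L || object@nOpt > nopt)
      return("nOpt must lie in [0, number of optional restraints]")
    TRUE
  })

#' Result of one docking run
#'
#' @slot pose the docked [Ligand-class] (final coordinates).
#' @slot receptorDihedrals numeric, final receptor torsion angles (degrees).
#' @slot chromosome numeric, the encoded final search state.
#' @slot breakdown final-stage [ScoreBreakdown-class].
#' @slot runIndex which independent run produced this result.
#' @slot convergedGeneration generations used by the last GA stage.
#' @export
setClass("DockResult",
  representation(pose = "Ligand", receptorDihedrals = "numeric",
                 chromosome = "numeric", breakdown = "ScoreBreakdown",
                 runIndex = "integer", convergedGeneration = "integer"))

#' Virtual-screening enrichment metrics
#'
#' @slot auc area under the ROC curve.
#' @slot logAuc area under TPR vs log10(FPR) on [1e-3, 1], normalised so a
#'   random ranking gives (1 - 1e-3) / (3 ln 10) ~ 0.1446.
#' @slot ef named numeric, enrichment factor at each requested fraction.
#' @slot efMax maximum enrichment factor over all top-k prefixes.
#' @slot rocPoints matrix with columns fpr, tpr.
#' @export
setClass("VSMetrics",
  representation(auc = "numeric", logAuc = "numeric", ef = "numeric",
                 efMax = "numeric", rocPoints = "matrix"),
  validity = function(object) {
    if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
    if (any(object@ef < 0)) return("enrichment factors must be >= 0")
    TRUE
  })

#' Synthetic receptor-ligand complex with a constructed optimum
#'
#' @slot receptor toy cage [Receptor-class].
#' @slot ligand toy [Ligand-class] (input conformation).
#' @slot cavity mapped [CavityGrid-class] of the cage.
#' @slot optimalPose n x 3 matrix, ligand coordinates of the constructed
#'   optimum.
#' @slot optimalScore total score of the optimal pose under the default
#'   scoring configuration.
#' @slot metadata list of generator parameters (including the seed).
#' @export
setClass("ToyComplex",
  representation(receptor = "Receptor", ligand = "Ligand",
                 cavity = "CavityGrid", optimalPose = "matrix",
                 optimalScore = "numeric", metadata = "list"))
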