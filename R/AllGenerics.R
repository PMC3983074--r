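## Accessor generics. Slot access outside the package goes through these.

#' @rdname moleculeAccessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname moleculeAccessors
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname moleculeAccessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname moleculeAccessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))
#' @rdname moleculeAccessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname moleculeAccessors
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))
#' @rdname moleculeAccessors
#' @export
setGeneric("ringList", function(x) standardGeneric("ringList"))
#' @rdname moleculeAccessors
#' @export
setGeneric("sdFields", function(x) standardGeneric("sdFields"))
#' @rdname moleculeAccessors
#' @export
setGeneric("sdFields<-", function(x, value) standardGeneric("sdFields<-"))
#' @rdname moleculeAccessors
#' @export
setGeneric("molecule", function(x) standardGeneric("molecule"))
#' @rdname moleculeAccessors
#' @export
setGeneric("rotatableDihedrals", function(x) standardGeneric("rotatableDihedrals"))
#' @rdname moleculeAccessors
#' @export
setGeneric("flexibleDihedrals", function(x) standardGeneric("flexibleDihedrals"))
#' @rdname moleculeAccessors
#' @export
setGeneric("isHeavy", function(x) standardGeneric("isHeavy"))

#' Accessors for molecular containers
#'
#' `atomTable`/`bondTable` return the underlying data.frames; `coords` the
#' n x 3 coordinate matrix (replaceable); `nAtoms` the atom count; `ringList`
#' the perceived SSSR; `sdFields` the named character vector of SD data items;
#' `molecule` the [Molecule-class] inside a [Receptor-class] or
#' [Ligand-class]; `rotatableDihedrals`/`flexibleDihedrals` the torsion lists;
#' `isHeavy` the logical heavy-atom mask (element != H).
#'
#' @param x a [Molecule-class], [Receptor-class] or [Ligand-class].
#' @param value replacement value.
#' @return see description; accessors on Receptor/Ligand delegate to the
#'   contained Molecule.
#' @name moleculeAccessors
NULL

#' @rdname moleculeAccessors
setMethod("atomTable", "Molecule", function(x) x@atoms)
#' @rdname moleculeAccessors
setMethod("bondTable", "Molecule", function(x) x@bonds)
#' @rdname moleculeAccessors
setMethod("coords", "Molecule", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))
#' @rdname moleculeAccessors
setMethod("coords<-", "Molecule", function(x, value) {
  value <- as.matrix(value)
  stopifnot(nrow(value) == nrow(x@atoms), ncol(value) == 3)
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  x
})
#' @rdname moleculeAccessors
setMethod("nAtoms", "Molecule", function(x) nrow(x@atoms))
#' @rdname moleculeAccessors
setMethod("molName", "Molecule", function(x) x@name)
#' @rdname moleculeAccessors
setMethod("ringList", "Molecule", function(x) x@rings)
#' @rdname moleculeAccessors
setMethod("sdFields", "Molecule", function(x) x@sdFields)
#' @rdname moleculeAccessors
setMethod("sdFields<-", "Molecule", function(x, value) {
  x@sdFields <- value; x
})
#' @rdname moleculeAccessors
setMethod("isHeavy", "Molecule", function(x) x@atoms$element != "H")

for (cls in c("Receptor", "Ligand")) {
  setMethod("atomTable", cls, function(x) atomTable(x@molecule))
  setMethod("bondTable", cls, function(x) bondTable(x@molecule))
  setMethod("coords", cls, function(x) coords(x@molecule))
  setMethod("nAtoms", cls, function(x) nAtoms(x@molecule))
  setMethod("molName", cls, function(x) molName(x@molecule))
  setMethod("ringList", cls, function(x) ringList(x@molecule))
  setMethod("sdFields", cls, function(x) sdFields(x@molecule))
  setMethod("isHeavy", cls, function(x) isHeavy(x@molecule))
}
setMethod("coords<-", "Receptor", function(x, value) {
  coords(x@molecule) <- value; x
})
setMethod("coords<-", "Ligand", function(x, value) {
  coords(x@molecule) <- value; x
})
setMethod("sdFields<-", "Ligand", function(x, value) {
  sdFields(x@molecule) <- value; x
})
#' @rdname moleculeAccessors
setMethod("molecule", "Receptor", function(x) x@molecule)
#' @rdname moleculeAccessors
setMethod("molecule", "Ligand", function(x) x@molecule)
#' @rdname moleculeAccessors
setMethod("rotatableDihedrals", "Ligand", function(x) x@rotatableDihedrals)
#' @rdname moleculeAccessors
setMethod("flexibleDihedrals", "Receptor", function(x) x@flexibleDihedrals)

#' @rdname scoreAccessors
#' @export
setGeneric("scoreTotal", function(x) standardGeneric("scoreTotal"))
#' @rdname scoreAccessors
#' @export
setGeneric("scoreComponents", function(x) standardGeneric("scoreComponents"))
#' @rdname scoreAccessors
#' @export
setGeneric("scoreTerms", function(x) standardGeneric("scoreTerms"))

#' Accessors for score breakdowns and docking results
#'
#' @param x a [ScoreBreakdown-class] or [DockResult-class].
#' @return `scoreTotal`: the total score; `scoreComponents`: named numeric of
#'   the four components (inter, intra, site, restraint); `scoreTerms`: the
#'   named sub-term vector.
#' @name scoreAccessors
NULL
#' @rdname scoreAccessors
setMethod("scoreTotal", "ScoreBreakdown", function(x) x@total)
#' @rdname scoreAccessors
setMethod("scoreComponents", "ScoreBreakdown", function(x)
  c(inter = x@inter, intra = x@intra, site = x@site, restraint = x@restraint))
#' @rdname scoreAccessors
setMethod("scoreTerms", "ScoreBreakdown", function(x) x@terms)
#' @rdname scoreAccessors
setMethod("scoreTotal", "DockResult", function(x) x@breakdown@total)
#' @rdname scoreAccessors
setMethod("scoreComponents", "DockResult", function(x)
  scoreComponents(x@breakdown))
#' @rdname scoreAccessors
setMethod("scoreTerms", "DockResult", function(x) x@breakdown@terms)

#' @rdname cavityAccessors
#' @export
setGeneric("cavityPoints", function(x) standardGeneric("cavityPoints"))
#' @rdname cavityAccessors
#' @export
setGeneric("cavityVolume", function(x) standardGeneric("cavityVolume"))

#' Accessors for cavity grids
#'
#' @param x a [CavityGrid-class].
#' @return `cavityPoints`: n x 3 matrix of Cartesian cavity-point coordinates;
#'   `cavityVolume`: occupied volume estimate, point count times spacing^3
#'   (cubic Angstroms).
#' @name cavityAccessors
NULL
#' @rdname cavityAccessors
setMethod("cavityPoints", "CavityGrid", function(x) x@cavityPoints)
#' @rdname cavityAccessors
setMethod("cavityVolume", "CavityGrid", function(x)
  nrow(x@cavityPoints) * x@spacing^3)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms (%d heavy), %d bonds, %d rings\n",
              object@name, nrow(object@atoms),
              sum(object@atoms$element != "H"), nrow(object@bonds),
              length(object@rings)))
  if (length(object@sdFields))
    cat("  SD fields:", paste(names(object@sdFields), collapse = ", "), "\n")
})
setMethod("show", "Receptor", function(object) {
  cat(sprintf("Receptor '%s': %d atoms, %d flexible dihedrals\n",
              object@molecule@name, nrow(object@molecule@atoms),
              length(object@flexibleDihedrals)))
})
setMethod("show", "Ligand", function(object) {
  cat(sprintf("Ligand '%s': %d atoms (%d heavy), %d rotatable dihedrals\n",
              object@molecule@name, nrow(object@molecule@atoms),
              sum(object@molecule@atoms$element != "H"),
              length(object@rotatableDihedrals)))
})
setMethod("show", "CavityGrid", function(object) {
  cat(sprintf(
    "CavityGrid: %d cavity points, spacing %.2f A, volume %.1f A^3\n",
    nrow(object@cavityPoints), object@spacing, cavityVolume(object)))
})
setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf(
    "Score %.4f (inter %.4f, intra %.4f, site %.4f, restraint %.4f)\n",
    object@total, object@inter, object@intra, object@site, object@restraint))
})
setMethod("show", "DockResult", function(object) {
  cat(sprintf("DockResult run %d: score %.4f (converged after %d generations)\n",
              object@runIndex, object@breakdown@total,
              object@convergedGeneration))
})
setMethod("show", "VSMetrics", function(object) {
  cat(sprintf("VSMetrics: AUC %.3f, logAUC %.3f, EFmax %.1f\n",
              object@auc, object@logAuc, object@efMax))
  if (length(object@ef))
    cat("  EF:", paste(sprintf("%s%% = %.2f",
                               names(object@ef), object@ef), collapse = ", "),
        "\n")
})
setMethod("show", "ToyComplex", function(object) {
  cat(sprintf("ToyComplex: %d receptor atoms, ligand '%s', optimal score %.3f\n",
              nAtoms(object@receptor), molName(object@ligand),
              object@optimalScore))
})
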