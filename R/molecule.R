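## Molecule construction and graph perception (rings, components,
## aromaticity). Ring perception and interaction typing run at construction
## so every downstream module sees a fully annotated graph.

#' Build an annotated Molecule
#'
#' Assembles the atom/bond tables, perceives the smallest set of smallest
#' rings and assigns interaction classes. This is the single construction
#' path used by the file readers and the toy-system generators.
#'
#' @param elements character vector of element symbols.
#' @param xyz n x 3 coordinate matrix, Angstroms.
#' @param bonds data.frame with columns i, j and (optionally) order
#'   (defaults "1").
#' @param formalCharges integer vector (default all 0).
#' @param partialCharges numeric vector (default all 0; carried from input,
#'   not used by scoring).
#' @param name molecule name.
#' @param sdFields named character vector of SD data items.
#' @return a [Molecule-class] with rings perceived and interaction classes
#'   assigned.
#' @export
buildMolecule <- function(elements, xyz, bonds = data.frame(i = integer(),
                          j = integer(), order = character()),
                          formalCharges = NULL, partialCharges = NULL,
                          name = "", sdFields = character()) {
  n <- length(elements)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (is.null(formalCharges)) formalCharges <- integer(n)
  if (is.null(partialCharges)) partialCharges <- numeric(n)
  if (is.null(bonds$order)) bonds$order <- rep("1", nrow(bonds))
  atoms <- data.frame(
    element = as.character(elements),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    formalCharge = as.integer(formalCharges),
    partialCharge = as.numeric(partialCharges),
    iclass = rep("other", n), chargeFlag = rep("neutral", n),
    stringsAsFactors = FALSE)
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.character(bonds$order),
                      stringsAsFactors = FALSE)
  mol <- new("Molecule", name = name, atoms = atoms, bonds = bonds,
             rings = list(), sdFields = sdFields)
  mol@rings <- perceiveRings(mol)
  assignInteractionClasses(mol)
}

## Adjacency list: integer neighbour vectors per atom.
adjacencyList <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  bd <- mol@bonds
  for (k in seq_len(nrow(bd))) {
    adj[[bd$i[k]]] <- c(adj[[bd$i[k]]], bd$j[k])
    adj[[bd$j[k]]] <- c(adj[[bd$j[k]]], bd$i[k])
  }
  adj
}

moleculeGraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = mol@bonds[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol@atoms))))
}

#' Perceive the smallest set of smallest rings
#'
#' For each non-tree bond of a spanning tree, the smallest cycle through that
#' bond is recovered by shortest-path search with the bond removed; the
#' resulting cycle set is deduplicated. This reproduces the SSSR for the
#' simple and fused ring systems handled by the engine.
#'
#' @param mol a [Molecule-class].
#' @return list of integer vectors (ring atom indices, in ring order).
#' @export
perceiveRings <- function(mol) {
  if (nrow(mol@bonds) == 0) return(list())
  g <- moleculeGraph(mol)
  nRings <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::count_components(g)
  if (nRings <= 0) return(list())
  tree <- igraph::mst(g)
  treeKeys <- apply(igraph::as_edgelist(tree), 1,
                    function(e) paste(sort(as.integer(e)), collapse = "-"))
  rings <- list()
  bd <- mol@bonds
  for (k in seq_len(nrow(bd))) {
    key <- paste(sort(c(bd$i[k], bd$j[k])), collapse = "-")
    if (key %in% treeKeys) next
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, c(bd$i[k], bd$j[k])))
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(bd$i[k]), to = as.character(bd$j[k])))
    path <- as.integer(names(sp$vpath[[1]]))
    if (length(path) >= 3) rings[[length(rings) + 1L]] <- path
  }
  ## deduplicate by atom set
  if (length(rings) > 1) {
    keys <- vapply(rings, function(r) paste(sort(r), collapse = ","), "")
    rings <- rings[!duplicated(keys)]
  }
  rings
}

## Logical mask of atoms in aromatic rings. A ring is aromatic when all its
## bonds are typed "ar", or when it is a six-membered carbon/nitrogen ring
## with alternating single/double bonds (Kekule notation).
aromaticAtomMask <- function(mol) {
  n <- nrow(mol@atoms)
  out <- logical(n)
  if (!length(mol@rings)) return(out)
  bd <- mol@bonds
  bondKey <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j), sep = "-")
  for (r in mol@rings) {
    m <- length(r)
    orders <- character(m)
    for (k in seq_len(m)) {
      a <- r[k]; b <- r[if (k == m) 1L else k + 1L]
      hit <- match(paste(min(a, b), max(a, b), sep = "-"), bondKey)
      orders[k] <- if (is.na(hit)) "" else bd$order[hit]
    }
    arom <- all(orders == "ar")
    if (!arom && m == 6 &&
        all(mol@atoms$element[r] %in% c("C", "N")) &&
        all(orders %in% c("1", "2"))) {
      alt <- sum(orders == "2") == 3 &&
        all(abs(diff(as.integer(orders == "2"))) == 1)
      arom <- alt
    }
    if (arom) out[r] <- TRUE
  }
  out
}

## Atoms reachable from `from` after deleting the bond a-b (used to define
## the rotated set of a dihedral). Returns sorted integer indices.
componentAfterBondDeletion <- function(mol, a, b, from) {
  adj <- adjacencyList(mol)
  seen <- logical(nrow(mol@atoms))
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if ((v == a && w == b) || (v == b && w == a)) next
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  which(seen)
}

#' Count heavy atoms of a molecule or ligand
#' @param x a [Molecule-class], [Ligand-class] or [Receptor-class].
#' @return integer heavy-atom count.
#' @export
nHeavyAtoms <- function(x) sum(isHeavy(x))
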