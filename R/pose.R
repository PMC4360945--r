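#' Construct a molecular graph
#'
#' Heavy-atom connectivity of one compound: element symbols plus a simple
#' undirected bond list. This is the carrier of atom correspondence between
#' two docking programs' poses of the same molecule — the programs agree on
#' the molecular graph but not on atom numbering.
#'
#' @param elements Character vector of element symbols, one per atom
#'   (1-based contiguous indices).
#' @param bonds Integer matrix with columns `i`, `j`, `order` (one row per
#'   bond), or a 3-column matrix/data.frame coercible to that. May have
#'   zero rows (single atom).
#' @return A `molecular_graph` object.
#' @examples
#' ethanol <- molecular_graph(c("C", "C", "O"),
#'                            rbind(c(1, 2, 1), c(2, 3, 1)))
#' @export
molecular_graph <- function(elements, bonds = matrix(integer(0), 0, 3)) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n == 0L) vsf_stop("molecular graph must have at least one atom")
  bonds <- as.matrix(bonds)
  if (length(bonds) == 0L) bonds <- matrix(integer(0), 0L, 3L)
  if (ncol(bonds) == 2L) bonds <- cbind(bonds, 1L)
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("i", "j", "order")
  if (nrow(bonds)) {
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n)) {
      vsf_stop("bond references an atom index outside 1..n")
    }
    if (any(bonds[, "i"] == bonds[, "j"])) vsf_stop("self-bond not allowed")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) vsf_stop("duplicate bond in bond list")
  }
  structure(list(elements = elements, bonds = bonds),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  tab <- table(x$elements)
  cat(sprintf("<molecular_graph> %d atoms (%s), %d bonds\n",
              length(x$elements),
              paste0(names(tab), tab, collapse = ""), nrow(x$bonds)))
  invisible(x)
}

#' Construct a pose
#'
#' One compound's 3-D heavy-atom coordinates in the (shared) receptor
#' frame, paired with its molecular graph.
#'
#' @param graph A [molecular_graph()].
#' @param coords Numeric matrix, one row of `(x, y, z)` in Angstrom per
#'   atom; all coordinates finite.
#' @return A `pose` object.
#' @export
pose <- function(graph, coords) {
  stopifnot(inherits(graph, "molecular_graph"))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(graph$elements) || ncol(coords) != 3L) {
    vsf_stop("coords must be an n_atoms x 3 matrix")
  }
  if (!all(is.finite(coords))) vsf_stop("non-finite coordinate")
  colnames(coords) <- c("x", "y", "z")
  structure(list(graph = graph, coords = coords), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> %d heavy atoms\n", length(x$graph$elements)))
  invisible(x)
}

# Convert to an igraph object with integer vertex colours encoding the
# element symbol and edge colours encoding bond order. `palette` fixes the
# symbol -> integer map so two graphs are coloured consistently.
as_igraph_coloured <- function(g, palette) {
  n <- length(g$elements)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(g$bonds)) {
    ig <- igraph::add_edges(ig, as.vector(t(g$bonds[, 1:2, drop = FALSE])))
  }
  list(graph = ig,
       vcol = match(g$elements, palette),
       ecol = as.integer(g$bonds[, "order"]))
}

# Sorted element-count signature, for the formula pre-check.
formula_signature <- function(g) {
  tab <- table(g$elements)
  paste0(names(tab), as.integer(tab), collapse = "")
}

# All element-preserving isomorphisms a -> b as a list of integer
# permutations (sigma[i] = atom of b matched to atom i of a). Bond orders
# participate as edge colours only when match_bond_order is TRUE.
all_isomorphisms <- function(a, b, match_bond_order = FALSE) {
  palette <- sort(unique(c(a$elements, b$elements)))
  ga <- as_igraph_coloured(a, palette)
  gb <- as_igraph_coloured(b, palette)
  args <- list(graph1 = ga$graph, graph2 = gb$graph,
               vertex.color1 = ga$vcol, vertex.color2 = gb$vcol)
  if (match_bond_order) {
    args$edge.color1 <- ga$ecol
    args$edge.color2 <- gb$ecol
  }
  maps <- do.call(igraph::graph.get.isomorphisms.vf2, args)
  # igraph returns the graph2 -> graph1 direction (m[k] = atom of `a`
  # matched to atom k of `b`); invert to the a -> b convention used here
  lapply(maps, function(m) order(as.integer(m)))
}

#' Find an atom correspondence between two molecular graphs
#'
#' Returns one element- and adjacency-preserving bijection from the atoms
#' of `a` to the atoms of `b` (an isomorphism), as an integer permutation
#' `sigma` with `sigma[i]` the atom of `b` matched to atom `i` of `a`.
#' Needed because docking programs emit the same molecule with different
#' atom numbering.
#'
#' @param a,b [molecular_graph()] objects.
#' @param match_bond_order If `FALSE` (default) bond orders are ignored and
#'   only element + connectivity must agree — docking exports frequently
#'   disagree on aromatic bond encoding. If `TRUE`, bond orders must match
#'   too.
#' @return Integer permutation vector.
#' @seealso [enumerate_automorphisms()], [symmetry_min_rmsd()]
#' @export
find_correspondence <- function(a, b, match_bond_order = FALSE) {
  stopifnot(inherits(a, "molecular_graph"), inherits(b, "molecular_graph"))
  if (formula_signature(a) != formula_signature(b)) {
    vsf_stop(sprintf("formula mismatch: %s vs %s",
                     formula_signature(a), formula_signature(b)),
             class = "vsf_formula_mismatch")
  }
  maps <- all_isomorphisms(a, b, match_bond_order)
  if (length(maps) == 0L) {
    vsf_stop("connectivity mismatch: same formula but graphs are not isomorphic",
             class = "vsf_connectivity_mismatch")
  }
  maps[[1L]]
}

#' Enumerate element-preserving graph automorphisms
#'
#' All relabellings of a molecule's atoms that preserve elements and bonds
#' (e.g. the 12 symmetries of a benzene-like C6 ring). These are what make
#' naive atom-order RMSD ill-defined and must be minimised over.
#'
#' @param g A [molecular_graph()].
#' @param cap Hard limit on the number of automorphisms; exceeding it is an
#'   error (pathologically symmetric graphs would otherwise dominate
#'   runtime). Default 10000.
#' @param match_bond_order Match bond orders as well (default `FALSE`).
#' @return List of integer permutation vectors, always including the
#'   identity.
#' @export
enumerate_automorphisms <- function(g, cap = 10000L, match_bond_order = FALSE) {
  stopifnot(inherits(g, "molecular_graph"))
  cap <- as.integer(cap)
  if (is.na(cap) || cap < 1L) vsf_stop("cap must be a positive integer")
  auts <- all_isomorphisms(g, g, match_bond_order)
  if (length(auts) > cap) {
    vsf_stop(sprintf("automorphism count %d exceeds cap %d; raise the cap",
                     length(auts), cap), class = "vsf_automorphism_cap")
  }
  auts
}
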