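#' In-place RMSD between two poses under a fixed atom mapping
#'
#' Root mean square deviation over the n heavy atoms,
#' `sqrt( (1/n) * sum_i ||x_i - y_sigma(i)||^2 )`, computed in the common
#' receptor frame with NO superposition: both docking programs placed the
#' ligand in the same prepared receptor, so the displacement between the
#' two poses is itself the signal of (in)consistent binding modes.
#'
#' @param a,b [pose()] objects of the same molecule.
#' @param mapping Integer permutation from [find_correspondence()] (atom
#'   `i` of `a` corresponds to atom `mapping[i]` of `b`). Defaults to the
#'   identity.
#' @return RMSD in Angstrom.
#' @export
in_place_rmsd <- function(a, b, mapping = seq_len(nrow(a$coords))) {
  stopifnot(inherits(a, "pose"), inherits(b, "pose"))
  n <- nrow(a$coords)
  if (nrow(b$coords) != n) vsf_stop("coordinate count mismatch between poses")
  mapping <- as.integer(mapping)
  if (length(mapping) != n || anyDuplicated(mapping) ||
      any(mapping < 1L | mapping > n)) {
    vsf_stop("mapping is not a permutation of 1..n_atoms")
  }
  d <- a$coords - b$coords[mapping, , drop = FALSE]
  sqrt(sum(d * d) / n)
}

#' Kabsch-superposed RMSD (diagnostic variant)
#'
#' Minimum RMSD after optimal rigid superposition of `b` onto `a`
#' (Kabsch). Not used by the screening funnel — superposition would erase
#' exactly the binding-mode displacement the consistency filter measures —
#' but useful to separate "same conformer, different placement" from
#' "different conformer".
#'
#' @inheritParams in_place_rmsd
#' @return RMSD in Angstrom after superposition.
#' @export
superposed_rmsd <- function(a, b, mapping = seq_len(nrow(a$coords))) {
  stopifnot(inherits(a, "pose"), inherits(b, "pose"))
  n <- nrow(a$coords)
  if (nrow(b$coords) != n) vsf_stop("coordinate count mismatch between poses")
  x <- a$coords
  y <- b$coords[as.integer(mapping), , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(y, x))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  dd <- x - y %*% rot
  sqrt(sum(dd * dd) / n)
}

#' Symmetry-corrected minimum RMSD between two poses
#'
#' Minimum of [in_place_rmsd()] over every element- and bond-preserving
#' atom correspondence between the two graphs (equivalently: one found
#' correspondence composed with every automorphism). This prevents
#' topologically equivalent atoms — ring symmetries, equivalent methyls —
#' from inflating the RMSD of two identical binding modes.
#'
#' @param a,b [pose()] objects with isomorphic graphs.
#' @param cap Automorphism-enumeration cap (see
#'   [enumerate_automorphisms()]).
#' @param match_bond_order Passed to the isomorphism search.
#' @param superpose If `TRUE`, minimise [superposed_rmsd()] instead of the
#'   in-place value. The screening funnel always uses `FALSE`.
#' @return Minimum RMSD in Angstrom, with the minimising mapping attached
#'   as attribute `"mapping"`.
#' @export
symmetry_min_rmsd <- function(a, b, cap = 10000L, match_bond_order = FALSE,
                              superpose = FALSE) {
  stopifnot(inherits(a, "pose"), inherits(b, "pose"))
  if (formula_signature(a$graph) != formula_signature(b$graph)) {
    vsf_stop("formula mismatch between poses", class = "vsf_formula_mismatch")
  }
  maps <- all_isomorphisms(a$graph, b$graph, match_bond_order)
  if (length(maps) == 0L) {
    vsf_stop("connectivity mismatch between poses",
             class = "vsf_connectivity_mismatch")
  }
  if (length(maps) > cap) {
    vsf_stop(sprintf("isomorphism count %d exceeds cap %d",
                     length(maps), cap), class = "vsf_automorphism_cap")
  }
  fun <- if (superpose) superposed_rmsd else in_place_rmsd
  vals <- vapply(maps, function(m) fun(a, b, m), numeric(1))
  best <- which.min(vals)
  structure(vals[best], mapping = maps[[best]])
}

#' Pose-consistency test between two docking programs' poses
#'
#' A compound whose Glide-style and eHiTS-style poses agree to better than
#' `cutoff` (strictly) is considered consistently docked; boundary
#' equality fails. Non-isomorphic pose pairs (tautomer or protonation
#' divergence between programs) are reported as not comparable, never
#' silently passed.
#'
#' @param a,b [pose()] objects.
#' @param cutoff Positive RMSD cutoff in Angstrom; the screening default
#'   is 2.0.
#' @param ... Passed to [symmetry_min_rmsd()].
#' @return A list with elements `pass` (logical), `rmsd` (Angstrom, `NA`
#'   if not comparable), `comparable` (logical) and `reason` (character).
#' @export
pose_consistency <- function(a, b, cutoff = 2.0, ...) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    vsf_stop("cutoff must be a positive length")
  }
  r <- tryCatch(as.numeric(symmetry_min_rmsd(a, b, ...)),
                vsf_formula_mismatch = function(e) e,
                vsf_connectivity_mismatch = function(e) e)
  if (inherits(r, "condition")) {
    return(list(pass = FALSE, rmsd = NA_real_, comparable = FALSE,
                reason = conditionMessage(r)))
  }
  list(pass = r < cutoff, rmsd = r, comparable = TRUE,
       reason = if (r < cutoff) "pass" else "rmsd_at_or_above_cutoff")
}
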