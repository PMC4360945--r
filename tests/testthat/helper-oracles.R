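# Independent brute-force oracles. These deliberately avoid the package's
# igraph/rank machinery: isomorphisms by full factorial permutation search,
# ranks by pairwise counting.

# all permutations of 1..n as a list (n <= 8 in tests)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

adj_matrix <- function(g) {
  n <- length(g$elements)
  m <- matrix(FALSE, n, n)
  if (nrow(g$bonds)) {
    m[g$bonds[, 1:2, drop = FALSE]] <- TRUE
    m[g$bonds[, c(2, 1), drop = FALSE]] <- TRUE
  }
  m
}

# every element- and adjacency-preserving bijection a -> b (bond orders
# ignored), by checking all n! candidates
bf_isomorphisms <- function(a, b) {
  n <- length(a$elements)
  if (length(b$elements) != n) return(list())
  ma <- adj_matrix(a); mb <- adj_matrix(b)
  keep <- list()
  for (p in perms(n)) {
    p <- as.integer(p)
    if (any(a$elements != b$elements[p])) next
    if (all(ma == mb[p, p, drop = FALSE])) keep[[length(keep) + 1L]] <- p
  }
  keep
}

bf_rmsd <- function(xa, xb, p) sqrt(mean(rowSums((xa - xb[p, , drop = FALSE])^2)))

bf_symmetry_min_rmsd <- function(pa, pb) {
  maps <- bf_isomorphisms(pa$graph, pb$graph)
  if (length(maps) == 0L) return(NA_real_)
  min(vapply(maps, function(p) bf_rmsd(pa$coords, pb$coords, p), numeric(1)))
}

# per-compound recomputation of votes by pairwise counting (competition
# rank = 1 + number strictly better; membership threshold = m-th smallest
# rank with m = max(1, floor(f * N)))
bf_votes <- function(values, directions, f) {
  n <- nrow(values)
  memb <- matrix(FALSE, n, ncol(values))
  for (k in seq_len(ncol(values))) {
    v <- values[, k]
    if (directions[k] == "higher_better") v <- -v
    r <- vapply(seq_len(n), function(i) 1L + sum(v < v[i]), integer(1))
    m <- max(1L, floor(f * n))
    rstar <- sort(r)[m]
    memb[, k] <- r <= rstar
  }
  stats::setNames(rowSums(memb), rownames(values))
}

# small deterministic pose factory
make_pose <- function(elements, bonds, coords) {
  pose(molecular_graph(elements, bonds), coords)
}

# random connected molecule-like graph with n atoms (tree plus optional
# extra edge), random elements, random coordinates; for oracle sweeps
random_molecule <- function(n, elements = c("C", "C", "C", "N", "O")) {
  parent <- if (n > 1L) vapply(2:n, function(i) sample.int(i - 1L, 1L),
                               integer(1)) else integer(0)
  bonds <- if (n > 1L) cbind(parent, 2:n, 1L) else matrix(integer(0), 0, 3)
  if (n >= 4L && stats::runif(1) < 0.5) {
    repeat {
      extra <- sort(sample.int(n, 2L))
      key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
      if (!paste(extra[1], extra[2]) %in% key) break
    }
    bonds <- rbind(bonds, c(extra, 1L))
  }
  make_pose(sample(elements, n, replace = TRUE), bonds,
            matrix(stats::rnorm(n * 3, sd = 2), n, 3))
}

# relabel a pose by an arbitrary permutation (atom k of the new pose is
# atom perm[k] of the old one)
relabel_pose <- function(p, perm) {
  inv <- order(perm)
  bonds <- p$graph$bonds
  if (nrow(bonds)) {
    bonds[, 1] <- inv[bonds[, 1]]
    bonds[, 2] <- inv[bonds[, 2]]
  }
  make_pose(p$graph$elements[perm], bonds, p$coords[perm, , drop = FALSE])
}
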