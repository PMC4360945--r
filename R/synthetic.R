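#' Configure a synthetic screening library
#'
#' The generator emulates what the pipeline consumes — not real docking:
#' (a) K correlated criterion scores per compound, with a planted
#' sub-population of true binders shifted toward favourable values, and
#' (b) pose pairs of the same molecular graph in a common frame,
#' perturbed by per-atom noise, automorphism relabelling and occasional
#' gross displacement (inconsistent docking).
#'
#' Scores follow a one-factor model: latent affinity
#' `a_i ~ Normal(0, 1)`, shifted by `-delta` for binders (lower raw score
#' = more favourable), and criterion score
#' `s_ik = sqrt(rho) * a_i + sqrt(1 - rho) * eps_ik` with independent
#' standard-normal noise. A single shared factor is the simplest
#' structure that induces the inter-criterion correlation real consensus
#' criteria show (all are computed from the same poses) while leaving
#' `rho` sweepable. Higher-better criteria (predicted pKi) are emulated
#' by negating the internal lower-better score, keeping one code path.
#'
#' @param n Library size (>= 1).
#' @param criteria List of [criterion_spec()]s for the score criteria;
#'   default the four screening scores: `glide`, `ehits`, `ligx`
#'   (lower_better) and `pki` (higher_better). (Pose RMSD is not
#'   generated here; it comes from the pose pairs via the funnel.)
#' @param rho Inter-criterion correlation in `[0, 1)`; default 0.5.
#' @param prevalence Binder prevalence `pi` in `[0, 1]`; default 0.02.
#' @param delta Binder effect size (standardised shift of the latent
#'   affinity); default 1.
#' @param sigma_pose Per-atom coordinate noise (Angstrom, >= 0);
#'   default 0.15.
#' @param p_inconsistent Probability a compound's second pose is grossly
#'   displaced; default 0.1.
#' @param gross_shift Magnitude of the gross displacement (Angstrom);
#'   must exceed the 2.0 Angstrom consistency cutoff whenever
#'   `p_inconsistent > 0`; default 5.
#' @param seed Integer seed; the whole library is a deterministic
#'   function of the config.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n = 10000L, criteria = default_criteria(),
                             rho = 0.5, prevalence = 0.02, delta = 1,
                             sigma_pose = 0.15, p_inconsistent = 0.1,
                             gross_shift = 5, seed = 1L) {
  criteria <- as_criteria(criteria)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) vsf_stop("n must be >= 1")
  if (!is.numeric(rho) || rho < 0 || rho >= 1) vsf_stop("rho must lie in [0, 1)")
  if (prevalence < 0 || prevalence > 1) vsf_stop("prevalence must lie in [0, 1]")
  if (p_inconsistent < 0 || p_inconsistent > 1) {
    vsf_stop("p_inconsistent must lie in [0, 1]")
  }
  if (sigma_pose < 0) vsf_stop("sigma_pose must be >= 0")
  if (p_inconsistent > 0 && gross_shift <= 2.0) {
    vsf_stop("gross_shift must exceed the 2.0 Angstrom pose cutoff when p_inconsistent > 0")
  }
  structure(list(n = n, criteria = criteria, rho = rho,
                 prevalence = prevalence, delta = delta,
                 sigma_pose = sigma_pose, p_inconsistent = p_inconsistent,
                 gross_shift = gross_shift, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' The default screening criteria
#'
#' Two docking scores, a rigorous rescoring value and a predicted pKi —
#' the four tabulated criteria of the canonical five-criterion vote (the
#' fifth, pose RMSD, is computed by the funnel's consistency stage).
#'
#' @return List of [criterion_spec()]s.
#' @export
default_criteria <- function() {
  list(criterion_spec("glide", "lower_better"),
       criterion_spec("ehits", "lower_better"),
       criterion_spec("ligx", "lower_better"),
       criterion_spec("pki", "higher_better"))
}

#' Generate correlated criterion scores with planted binders
#'
#' See [synthetic_config()] for the model. All randomness flows from
#' `cfg$seed`; the same config is bit-identical on regeneration.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `table` (a [score_table()]), `labels` (named 0/1
#'   integer, 1 = planted binder) and `config`.
#' @export
generate_scores <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n
    K <- length(cfg$criteria)
    ids <- sprintf("CMPD%06d", seq_len(n))
    labels <- stats::rbinom(n, 1L, cfg$prevalence)
    a <- stats::rnorm(n) - cfg$delta * labels
    eps <- matrix(stats::rnorm(n * K), n, K)
    s <- sqrt(cfg$rho) * a + sqrt(1 - cfg$rho) * eps
    dir <- vapply(cfg$criteria, `[[`, character(1), "direction")
    s[, dir == "higher_better"] <- -s[, dir == "higher_better"]
    colnames(s) <- names(cfg$criteria)
    list(table = score_table(ids, cfg$criteria, s),
         labels = stats::setNames(as.integer(labels), ids),
         config = cfg)
  })
}

# ---- pose templates -------------------------------------------------------

# Hard-coded molecular templates with fixed reference coordinates, so the
# generator needs no chemistry toolkit. Geometry is idealised (bond
# lengths ~1.4-1.55 Angstrom); what matters downstream is connectivity,
# element symmetry and the common frame.
pose_template_registry <- function() {
  list(
    chain_c4 = pose(
      molecular_graph(rep("C", 4), rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
      # dyadic coordinates (exact doubles) so closed-form displacement
      # arithmetic at the 2.0 Angstrom boundary is exact
      rbind(c(0, 0, 0), c(1.25, 0.875, 0), c(2.5, 0, 0), c(3.75, 0.875, 0))),
    ring_c6 = pose(
      molecular_graph(rep("C", 6),
                      cbind(1:6, c(2:6, 1), 1L)),
      cbind(1.4 * cospi((0:5) / 3), 1.4 * sinpi((0:5) / 3), 0)),
    branched_c5 = pose(
      molecular_graph(rep("C", 5), cbind(1L, 2:5, 1L)),
      rbind(c(0, 0, 0), c(0.89, 0.89, 0.89), c(0.89, -0.89, -0.89),
            c(-0.89, 0.89, -0.89), c(-0.89, -0.89, 0.89))),
    hetero_oc2 = pose(
      molecular_graph(c("O", "C", "C"), rbind(c(1, 2, 1), c(2, 3, 1))),
      rbind(c(0, 0, 0), c(1.43, 0, 0), c(2.3, 1.2, 0)))
  )
}

#' Built-in pose template
#'
#' @param name One of `"chain_c4"` (linear butane-like chain),
#'   `"ring_c6"` (benzene-like regular hexagon, 12 automorphisms),
#'   `"branched_c5"` (neopentane-like, 24 automorphisms) or
#'   `"hetero_oc2"` (O-C-C chain, asymmetric).
#' @return A [pose()] with fixed reference coordinates.
#' @export
pose_template <- function(name) {
  reg <- pose_template_registry()
  if (!name %in% names(reg)) {
    vsf_stop(paste0("unknown template '", name, "'; available: ",
                    paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}

# per-session cache of template automorphisms (templates are fixed, the
# enumeration is pure; avoids one VF2 run per generated compound)
.vsf_template_cache <- new.env(parent = emptyenv())
template_automorphisms <- function(name) {
  if (is.null(.vsf_template_cache[[name]])) {
    .vsf_template_cache[[name]] <-
      enumerate_automorphisms(pose_template(name)$graph, cap = 10000L)
  }
  .vsf_template_cache[[name]]
}

# uniform random unit vector in R^3
runif_direction <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v * v))
}

#' Generate one perturbed pose pair
#'
#' Pose A is the template reference. Pose B is the reference with
#' per-atom Gaussian noise (`sigma_pose`), its atom order scrambled by a
#' random automorphism of the template (so a naive ordered RMSD is
#' inflated but the symmetry-corrected value is not), and — if
#' `inconsistent` — rigidly translated by `gross_shift` Angstrom in a
#' random direction, emulating a disagreeing binding mode.
#'
#' Uses the current RNG stream; callers seed via [generate_library()] or
#' [with_seed()]-style wrappers.
#'
#' @param template Template name (see [pose_template()]).
#' @param cfg A [synthetic_config()].
#' @param inconsistent Force the gross displacement on (`TRUE`) / off
#'   (`FALSE`); default draws Bernoulli(`cfg$p_inconsistent`).
#' @return List with `a`, `b` (poses) and `inconsistent` (logical).
#' @export
generate_pose_pair <- function(template, cfg,
                               inconsistent = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ref <- pose_template(template)
  n <- nrow(ref$coords)
  auts <- template_automorphisms(template)
  perm <- auts[[sample.int(length(auts), 1L)]]
  # B's atom k is template atom perm[k]; relabel graph + coords together
  inv <- order(perm)
  g <- ref$graph
  bonds <- g$bonds
  if (nrow(bonds)) {
    bonds[, 1] <- inv[bonds[, 1]]
    bonds[, 2] <- inv[bonds[, 2]]
  }
  gb <- molecular_graph(g$elements[perm], bonds)
  coords_b <- ref$coords[perm, , drop = FALSE] +
    matrix(stats::rnorm(3L * n, sd = cfg$sigma_pose), n, 3L)
  if (is.null(inconsistent)) {
    inconsistent <- stats::runif(1) < cfg$p_inconsistent
  }
  if (inconsistent) {
    coords_b <- coords_b +
      matrix(cfg$gross_shift * runif_direction(), n, 3L, byrow = TRUE)
  }
  list(a = ref, b = pose(gb, coords_b), inconsistent = inconsistent)
}

#' Generate a full synthetic screening library
#'
#' Scores, labels and pose pairs for every compound, all from one seed.
#' Regeneration from the same config is bit-identical.
#'
#' @param cfg A [synthetic_config()].
#' @return A `synthetic_library`: list with `table`, `labels`, `poses_a`,
#'   `poses_b` (lists of `pose_record`s keyed like SDF reads),
#'   `inconsistent` (named logical) and `config`.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sc <- generate_scores(cfg)
  templates <- names(pose_template_registry())
  with_seed(cfg$seed + 1L, {
    ids <- sc$table$ids
    tmpl <- sample(templates, cfg$n, replace = TRUE)
    poses_a <- vector("list", cfg$n)
    poses_b <- vector("list", cfg$n)
    inco <- logical(cfg$n)
    for (i in seq_len(cfg$n)) {
      pp <- generate_pose_pair(tmpl[i], cfg)
      pa <- pp$a; pa$id <- ids[i]; class(pa) <- c("pose_record", "pose")
      pb <- pp$b; pb$id <- ids[i]; class(pb) <- c("pose_record", "pose")
      poses_a[[i]] <- pa
      poses_b[[i]] <- pb
      inco[i] <- pp$inconsistent
    }
    structure(list(table = sc$table, labels = sc$labels,
                   poses_a = poses_a, poses_b = poses_b,
                   inconsistent = stats::setNames(inco, ids),
                   config = cfg),
              class = "synthetic_library")
  })
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf(
    "<synthetic_library> n=%d, K=%d, rho=%.2f, prevalence=%.3f, delta=%.2f (%d binders)\n",
    x$config$n, length(x$config$criteria), x$config$rho,
    x$config$prevalence, x$config$delta, sum(x$labels)))
  invisible(x)
}

#' Null distribution of the cumulative vote
#'
#' With K independent continuous criteria and no boundary ties, each
#' compound's membership events are independent Bernoulli(f), so the
#' cumulative vote is Binomial(K, f). Serves as the analytic oracle for
#' the voting machinery (e.g. `P(vote = 0) = 0.9^5 = 0.59049` at the
#' default K = 5, f = 0.1).
#'
#' @param K Number of criteria (>= 1).
#' @param f Top fraction in (0, 1).
#' @return Named probability vector over votes `0..K`.
#' @export
expected_vote_distribution <- function(K, f) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) vsf_stop("K must be >= 1")
  if (!is.numeric(f) || f <= 0 || f >= 1) vsf_stop("f must lie in (0, 1)")
  stats::setNames(stats::dbinom(0:K, K, f), 0:K)
}

#' Write a synthetic library to a directory
#'
#' Emits `scores.csv`, `poses_a.sdf`, `poses_b.sdf`, `labels.csv` and
#' `log.json` (config + seed, sufficient for bit-identical
#' regeneration).
#'
#' @param lib A `synthetic_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "synthetic_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_score_csv(lib$table, file.path(dir, "scores.csv"))
  write_sdf_poses(lib$poses_a, file.path(dir, "poses_a.sdf"))
  write_sdf_poses(lib$poses_b, file.path(dir, "poses_b.sdf"))
  utils::write.csv(data.frame(id = names(lib$labels),
                              binder = as.integer(lib$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- lib$config
  cfg$criteria <- lapply(cfg$criteria, function(cs) {
    list(name = cs$name, direction = cs$direction, source = cs$source)
  })
  jsonlite::write_json(unclass(cfg), file.path(dir, "log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
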