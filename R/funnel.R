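#' Funnel stage constructors
#'
#' A screening funnel is an ordered list of stages, each one of:
#' a score-threshold filter (`stage_score_threshold()`), the
#' cross-program pose-consistency filter (`stage_rmsd_consistency()`),
#' or the consensus-vote shortlist (`stage_consensus_vote()`).
#'
#' The canonical configuration mirrors the published protocol:
#' Glide-score stage with threshold 5.0 (strict `<`), eHiTS-score stage
#' with threshold 3.0, pose RMSD cutoff 2.0 Angstrom (strict `<`), then a
#' top-10% vote over five criteria selecting 5000 compounds. Note the
#' threshold comparator follows the Methods-style strict `<`; it is
#' configurable per stage because the source protocol is ambiguous
#' (`<5.0` vs `<=5.0`). Thresholds apply to raw stored score values — no
#' sign convention is imposed.
#'
#' @param criterion Criterion name the threshold applies to.
#' @param threshold Finite threshold value.
#' @param comparator `"lt"` (strict, default) or `"le"`.
#' @param cutoff RMSD cutoff in Angstrom (> 0), strict `<`.
#' @param cap Automorphism cap for the RMSD stage.
#' @param rmsd_criterion Name under which the stage's RMSD values are
#'   appended to the score table (so the vote can use pose consistency as
#'   a criterion); `NULL` to not record them.
#' @param criteria,f,shortlist Vote-stage parameters (see
#'   [consensus_vote()]); `criteria = NULL` votes over every criterion
#'   present when the stage runs, including a recorded RMSD column.
#' @return A `funnel_stage` object.
#' @name funnel_stages
NULL

#' @rdname funnel_stages
#' @export
stage_score_threshold <- function(criterion, threshold,
                                  comparator = c("lt", "le")) {
  comparator <- match.arg(comparator)
  if (!is.finite(threshold)) vsf_stop("threshold must be finite")
  structure(list(type = "score_threshold", criterion = criterion,
                 threshold = threshold, comparator = comparator),
            class = "funnel_stage")
}

#' @rdname funnel_stages
#' @export
stage_rmsd_consistency <- function(cutoff = 2.0, cap = 10000L,
                                   rmsd_criterion = "rmsd") {
  if (!is.numeric(cutoff) || cutoff <= 0) vsf_stop("cutoff must be > 0")
  structure(list(type = "rmsd_consistency", cutoff = cutoff, cap = cap,
                 rmsd_criterion = rmsd_criterion),
            class = "funnel_stage")
}

#' @rdname funnel_stages
#' @export
stage_consensus_vote <- function(criteria = NULL, f = 0.10,
                                 shortlist = 5000L) {
  if (!is.numeric(f) || f <= 0 || f > 1) vsf_stop("f must lie in (0, 1]")
  if (!is.numeric(shortlist) || shortlist < 1) {
    vsf_stop("shortlist must be >= 1")
  }
  structure(list(type = "consensus_vote", criteria = criteria, f = f,
                 shortlist = as.integer(shortlist)),
            class = "funnel_stage")
}

#' Assemble a funnel configuration
#'
#' @param stages List of `funnel_stage` objects, applied in order.
#' @param seed Integer seed recorded for provenance (the funnel itself is
#'   deterministic; the seed governs any stochastic diagnostics).
#' @param verbose Emit one-line per-stage summaries to stderr.
#' @return A `funnel_config`.
#' @seealso [default_funnel_config()]
#' @export
funnel_config <- function(stages, seed = 1L, verbose = FALSE) {
  if (inherits(stages, "funnel_stage")) stages <- list(stages)
  if (!length(stages) ||
      !all(vapply(stages, inherits, logical(1), "funnel_stage"))) {
    vsf_stop("stages must be a non-empty list of funnel_stage objects")
  }
  structure(list(stages = stages, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "funnel_config")
}

#' The paper-faithful default funnel
#'
#' Glide `< 5.0`, eHiTS `< 3.0`, pose RMSD `< 2.0` Angstrom, top-10%
#' five-criterion vote, shortlist 5000.
#'
#' @param glide_criterion,ehits_criterion Criterion names of the two
#'   docking-score stages.
#' @param shortlist Final shortlist size.
#' @param f Top fraction for the vote.
#' @param include_rmsd If `TRUE` (default) the pose RMSD recorded by the
#'   consistency stage also serves as a (lower-better) voting criterion,
#'   giving the vote its maximum of 5; if `FALSE` only the four score
#'   criteria vote.
#' @inheritParams funnel_config
#' @return A `funnel_config`.
#' @export
default_funnel_config <- function(glide_criterion = "glide",
                                  ehits_criterion = "ehits",
                                  shortlist = 5000L, f = 0.10,
                                  include_rmsd = TRUE, seed = 1L,
                                  verbose = FALSE) {
  funnel_config(list(
    stage_score_threshold(glide_criterion, 5.0, "lt"),
    stage_score_threshold(ehits_criterion, 3.0, "lt"),
    stage_rmsd_consistency(cutoff = 2.0,
                           rmsd_criterion = if (include_rmsd) "rmsd" else NULL),
    stage_consensus_vote(criteria = NULL, f = f, shortlist = shortlist)
  ), seed = seed, verbose = verbose)
}

#' Apply one score-threshold stage
#'
#' Keeps exactly the compounds whose stored value satisfies the
#' comparator against the threshold. Compounds with a missing value for
#' the criterion cannot demonstrate that they pass and are dropped,
#' counted separately.
#'
#' @param table A [score_table()].
#' @param criterion Criterion name.
#' @param threshold Threshold value.
#' @param comparator `"lt"` (strict) or `"le"`.
#' @return Surviving [score_table()] with attribute `"stage_drops"`, a
#'   list with `missing` and `threshold` id vectors.
#' @export
apply_score_stage <- function(table, criterion, threshold,
                              comparator = c("lt", "le")) {
  stopifnot(inherits(table, "score_table"))
  comparator <- match.arg(comparator)
  if (!criterion %in% names(table$criteria)) {
    vsf_stop(paste0("unknown criterion: ", criterion))
  }
  v <- table$values[, criterion]
  pass <- if (comparator == "lt") v < threshold else v <= threshold
  missing_ids <- table$ids[is.na(v)]
  pass[is.na(pass)] <- FALSE
  out <- subset_score_table(table, table$ids[pass])
  attr(out, "stage_drops") <- list(
    missing = missing_ids,
    threshold = setdiff(table$ids[!pass], missing_ids))
  out
}

#' Apply the pose-consistency stage
#'
#' Survivors are the compounds present in both pose sets, with isomorphic
#' heavy-atom graphs, whose symmetry-corrected in-place RMSD is strictly
#' below the cutoff. Everything else is dropped and tallied by reason
#' (`unpaired_a` / `unpaired_b` / `duplicate` / `not_comparable` /
#' `cutoff`). If a pose set carries several records for one id, the first
#' is used and the rest counted as `duplicate`.
#'
#' @param poses_a,poses_b Lists of `pose_record`s (see
#'   [read_sdf_poses()]).
#' @param cutoff RMSD cutoff in Angstrom (strict `<`; default 2.0).
#' @param cap Automorphism cap.
#' @param ids Optional id subset to restrict the comparison to.
#' @return List with `survivors` (ids), `rmsd` (named numeric over every
#'   comparable pair) and `drops` (named list of id vectors).
#' @export
apply_rmsd_stage <- function(poses_a, poses_b, cutoff = 2.0, cap = 10000L,
                             ids = NULL) {
  key <- function(poses) {
    pid <- vapply(poses, function(p) p$id, character(1))
    dup <- pid[duplicated(pid)]
    list(map = poses[!duplicated(pid)], ids = unique(pid), dup = unique(dup))
  }
  ka <- key(poses_a); kb <- key(poses_b)
  names(ka$map) <- ka$ids; names(kb$map) <- kb$ids
  universe <- if (is.null(ids)) union(ka$ids, kb$ids) else ids
  paired <- intersect(intersect(universe, ka$ids), kb$ids)
  drops <- list(
    unpaired_a = setdiff(intersect(universe, ka$ids), kb$ids),
    unpaired_b = setdiff(intersect(universe, kb$ids), ka$ids),
    duplicate = intersect(universe, union(ka$dup, kb$dup)),
    not_comparable = character(0), cutoff = character(0))
  rmsd <- stats::setNames(rep(NA_real_, length(paired)), paired)
  survivors <- character(0)
  for (id in paired) {
    res <- pose_consistency(ka$map[[id]], kb$map[[id]], cutoff = cutoff,
                            cap = cap)
    if (!res$comparable) {
      drops$not_comparable <- c(drops$not_comparable, id)
    } else {
      rmsd[id] <- res$rmsd
      if (res$pass) survivors <- c(survivors, id)
      else drops$cutoff <- c(drops$cutoff, id)
    }
  }
  list(survivors = survivors, rmsd = rmsd[!is.na(rmsd)], drops = drops)
}

#' Run the full screening funnel
#'
#' Applies the configured stages in order, maintaining a monotone chain
#' of survivor counts, and returns the final hit list together with a
#' per-stage report (input count, surviving count, parameters, drop
#' reasons). The run is fully deterministic given inputs and
#' configuration; a stage that eliminates every compound yields an empty
#' hit list and a warning, not an error.
#'
#' @param config A [funnel_config()].
#' @param table A [score_table()] of the full input library.
#' @param poses_a,poses_b Pose sets for the two docking programs
#'   (required iff the config contains an RMSD stage).
#' @return List with `hits` (`hit_list`) and `report` (`stage_report`).
#' @export
run_funnel <- function(config, table, poses_a = NULL, poses_b = NULL) {
  stopifnot(inherits(config, "funnel_config"), inherits(table, "score_table"))
  report <- list()
  hits <- NULL
  say <- function(...) if (config$verbose) message(sprintf(...))
  for (k in seq_along(config$stages)) {
    st <- config$stages[[k]]
    n_in <- n_compounds(table)
    drops <- list()
    if (st$type == "score_threshold") {
      table <- apply_score_stage(table, st$criterion, st$threshold,
                                 st$comparator)
      drops <- attr(table, "stage_drops")
      params <- list(criterion = st$criterion, threshold = st$threshold,
                     comparator = st$comparator)
      name <- paste0("score_threshold:", st$criterion)
    } else if (st$type == "rmsd_consistency") {
      if (is.null(poses_a) || is.null(poses_b)) {
        vsf_stop("config has an RMSD stage but pose sets were not supplied")
      }
      rs <- apply_rmsd_stage(poses_a, poses_b, cutoff = st$cutoff,
                             cap = st$cap, ids = table$ids)
      drops <- rs$drops
      table <- subset_score_table(table, rs$survivors)
      if (!is.null(st$rmsd_criterion) && n_compounds(table) > 0L) {
        table <- add_criterion(
          table, criterion_spec(st$rmsd_criterion, "lower_better"),
          rs$rmsd)
      }
      params <- list(cutoff = st$cutoff, cap = st$cap)
      name <- "rmsd_consistency"
    } else if (st$type == "consensus_vote") {
      if (n_compounds(table) > 0L) {
        cv <- consensus_vote(table, criteria = st$criteria, f = st$f,
                             shortlist = st$shortlist)
        hits <- cv$hits
      } else {
        hits <- empty_hitlist(if (is.null(st$criteria))
          names(table$criteria) else st$criteria)
      }
      table <- subset_score_table(table, hits$id)
      params <- list(f = st$f, shortlist = st$shortlist)
      name <- "consensus_vote"
    } else {
      vsf_stop(paste0("unknown stage type: ", st$type))
    }
    n_out <- n_compounds(table)
    say("[stage %d] %-28s %d -> %d", k, name, n_in, n_out)
    report[[k]] <- list(name = name, type = st$type, n_in = n_in,
                        n_out = n_out, params = params, drops = drops)
    if (n_out == 0L && k < length(config$stages)) {
      warning("stage '", name, "' eliminated all compounds", call. = FALSE)
    }
  }
  if (is.null(hits)) {
    warning("config has no consensus_vote stage; returning survivors unranked",
            call. = FALSE)
    votes <- stats::setNames(rep(0L, n_compounds(table)), table$ids)
    ranks <- matrix(NA_integer_, n_compounds(table), 0,
                    dimnames = list(table$ids, NULL))
    hits <- if (length(votes)) select_top_voted(votes, ranks, length(votes))
            else empty_hitlist(character(0))
  }
  structure(list(hits = hits,
                 report = structure(list(stages = report, seed = config$seed),
                                    class = "stage_report")),
            class = "funnel_result")
}

#' @export
print.stage_report <- function(x, ...) {
  cat("<stage_report>\n")
  for (s in x$stages) {
    cat(sprintf("  %-28s %8d -> %8d\n", s$name, s$n_in, s$n_out))
  }
  invisible(x)
}

#' @export
print.funnel_result <- function(x, ...) {
  print(x$report)
  print(x$hits)
  invisible(x)
}

#' Summarise a stage report as a data frame
#' @param object A `stage_report`.
#' @param ... Unused.
#' @return Data frame with columns `stage`, `type`, `n_in`, `n_out`.
#' @export
summary.stage_report <- function(object, ...) {
  data.frame(stage = vapply(object$stages, `[[`, character(1), "name"),
             type = vapply(object$stages, `[[`, character(1), "type"),
             n_in = vapply(object$stages, `[[`, integer(1), "n_in"),
             n_out = vapply(object$stages, `[[`, integer(1), "n_out"),
             stringsAsFactors = FALSE)
}

#' Serialise a stage report to JSON
#' @param report A `stage_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "stage_report"))
  out <- list(seed = report$seed,
              stages = lapply(report$stages, function(s) {
                list(name = s$name, type = s$type, n_in = s$n_in,
                     n_out = s$n_out, params = s$params,
                     drops = lapply(s$drops, length))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
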