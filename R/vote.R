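#' Rank compounds under one criterion
#'
#' Competition ("min") ranking: rank 1 is the most favourable value under
#' the criterion's direction, ties share the minimum rank, and compounds
#' with missing values receive no rank (`NA`).
#'
#' @param table A [score_table()].
#' @param criterion Criterion name or [criterion_spec()]; must belong to
#'   the table.
#' @return Named integer vector of ranks over `table$ids` (`NA` where the
#'   value is missing).
#' @examples
#' tab <- score_table(c("A", "B", "C"),
#'                    list(criterion_spec("glide", "lower_better")),
#'                    matrix(c(-9.1, -7.2, -8.5), ncol = 1))
#' rank_by_criterion(tab, "glide")  # A=1, C=2, B=3
#' @export
rank_by_criterion <- function(table, criterion) {
  stopifnot(inherits(table, "score_table"))
  nm <- if (inherits(criterion, "criterion_spec")) criterion$name else criterion
  if (!nm %in% names(table$criteria)) {
    vsf_stop(paste0("unknown criterion: ", nm))
  }
  spec <- table$criteria[[nm]]
  v <- table$values[, nm]
  if (all(is.na(v))) {
    vsf_stop(paste0("no compound has a value for criterion '", nm, "'"))
  }
  key <- if (spec$direction == "lower_better") v else -v
  r <- rank(key, ties.method = "min", na.last = "keep")
  stats::setNames(as.integer(r), table$ids)
}

#' Top-fraction membership from ranks
#'
#' The "top 10% appearance" rule: with `N` ranked compounds, the nominal
#' membership size is `m = max(1, floor(f * N))`; every compound whose
#' competition rank is at or better than the m-th best rank is a member,
#' so boundary ties are ALL included (membership can exceed `m` only under
#' ties). Unranked (missing-value) compounds are never members.
#'
#' @param ranks Named integer ranks from [rank_by_criterion()].
#' @param f Fraction in (0, 1]; the screening default is 0.10.
#' @return Named logical membership vector.
#' @export
top_fraction_members <- function(ranks, f = 0.10) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1) {
    vsf_stop("f must lie in (0, 1]")
  }
  ranked <- !is.na(ranks)
  n <- sum(ranked)
  if (n < 1L) vsf_stop("no ranked compounds")
  m <- max(1L, floor(f * n))
  rstar <- sort(ranks[ranked])[m]
  member <- ranked & !is.na(ranks) & ranks <= rstar
  member[is.na(member)] <- FALSE
  member
}

#' Cumulative consensus votes
#'
#' Each compound receives one binary vote per criterion on which it is a
#' top-fraction member; the cumulative vote is the integer sum, at most
#' the number of criteria (5 in the default configuration). Compounds not
#' evaluated on every criterion are excluded with a warning rather than
#' scored as non-members: in the intended funnel every voted compound has
#' passed all upstream scoring stages and therefore carries all values.
#'
#' @param memberships Logical matrix, one row per compound (rownames =
#'   ids), one column per criterion; `NA` marks "not evaluated".
#' @return Named integer votes for the fully-evaluated compounds.
#' @export
cumulative_votes <- function(memberships) {
  memberships <- as.matrix(memberships)
  if (is.null(rownames(memberships))) vsf_stop("memberships must have rownames")
  complete <- stats::complete.cases(memberships)
  if (any(!complete)) {
    warning(sum(!complete), " compound(s) missing a criterion evaluation; ",
            "excluded from voting", call. = FALSE)
  }
  m <- memberships[complete, , drop = FALSE]
  stats::setNames(as.integer(rowSums(m)), rownames(m))
}

#' Select the top-voted shortlist
#'
#' Orders compounds by cumulative vote (descending), breaking ties by
#' ascending mean normalised rank (mean over available criteria of
#' `rank / N_criterion`), then by compound id (C-locale lexicographic),
#' and returns the first `min(m, N)` entries. The tie-break chain replaces
#' the human visual-inspection step with a deterministic, auditable
#' ordering.
#'
#' @param votes Named integer votes from [cumulative_votes()].
#' @param ranks Integer matrix of per-criterion ranks (rownames = ids,
#'   colnames = criterion names; `NA` allowed).
#' @param m Shortlist size (>= 1); the screening default is 5000.
#' @return A `hit_list`: data frame with columns `id`, `cumulative_vote`,
#'   `rank_<criterion>`..., `tie_break_key`, in final order.
#' @export
select_top_voted <- function(votes, ranks, m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    vsf_stop("shortlist size m must be >= 1")
  }
  ranks <- as.matrix(ranks)
  ids <- names(votes)
  if (is.null(ids)) vsf_stop("votes must be named by compound id")
  rk <- ranks[ids, , drop = FALSE]
  n_per_crit <- colSums(!is.na(ranks))
  norm <- sweep(rk, 2, n_per_crit, `/`)
  key <- rowMeans(norm, na.rm = TRUE)
  key[is.nan(key)] <- Inf  # no rank anywhere: worst tie-break
  ord <- order(-votes, key, ids, method = "radix")
  take <- ord[seq_len(min(as.integer(m), length(votes)))]
  df <- data.frame(id = ids[take],
                   cumulative_vote = as.integer(votes[take]),
                   stringsAsFactors = FALSE)
  for (nm in colnames(rk)) df[[paste0("rank_", nm)]] <- rk[take, nm]
  df$tie_break_key <- unname(key[take])
  rownames(df) <- NULL
  class(df) <- c("hit_list", "data.frame")
  df
}

#' @export
print.hit_list <- function(x, ...) {
  cat(sprintf("<hit_list> %d compounds (votes %s..%s)\n", nrow(x),
              if (nrow(x)) min(x$cumulative_vote) else "-",
              if (nrow(x)) max(x$cumulative_vote) else "-"))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' One-call consensus vote over a score table
#'
#' Convenience wrapper chaining [rank_by_criterion()],
#' [top_fraction_members()], [cumulative_votes()] and (optionally)
#' [select_top_voted()] across all (or the given) criteria.
#'
#' @param table A [score_table()].
#' @param criteria Criterion names to vote on; default all in the table.
#' @param f Top fraction (default 0.10).
#' @param shortlist Shortlist size, or `NULL` to return every voted
#'   compound fully ordered.
#' @return List with `ranks` (matrix), `memberships` (logical matrix,
#'   `NA` = not evaluated), `votes` (named integer) and `hits`
#'   (`hit_list`).
#' @export
consensus_vote <- function(table, criteria = NULL, f = 0.10,
                           shortlist = NULL) {
  stopifnot(inherits(table, "score_table"))
  if (is.null(criteria)) criteria <- names(table$criteria)
  ranks <- sapply(criteria, function(nm) rank_by_criterion(table, nm))
  ranks <- matrix(as.integer(ranks), nrow = length(table$ids),
                  dimnames = list(table$ids, criteria))
  memb <- ranks
  mode(memb) <- "logical"
  for (nm in criteria) {
    r <- stats::setNames(ranks[, nm], table$ids)
    flags <- top_fraction_members(r, f)
    memb[, nm] <- ifelse(is.na(r), NA, flags)
  }
  votes <- cumulative_votes(memb)
  m <- if (is.null(shortlist)) length(votes) else shortlist
  hits <- if (length(votes)) select_top_voted(votes, ranks, m) else
    empty_hitlist(criteria)
  list(ranks = ranks, memberships = memb, votes = votes, hits = hits)
}

empty_hitlist <- function(criteria) {
  df <- data.frame(id = character(0), cumulative_vote = integer(0),
                   stringsAsFactors = FALSE)
  for (nm in criteria) df[[paste0("rank_", nm)]] <- integer(0)
  df$tie_break_key <- numeric(0)
  class(df) <- c("hit_list", "data.frame")
  df
}
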