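#' Define a scoring criterion
#'
#' A criterion is one column of a screening score table: a docking score,
#' a rescoring value, a predicted pKi, or a pose-consistency RMSD. Every
#' criterion must declare its favourable direction explicitly; there is no
#' default, because docking scores and pKi point opposite ways and a silent
#' default would corrupt every downstream rank.
#'
#' @param name Identifier, unique within a configuration.
#' @param direction `"lower_better"` (docking scores, RMSD) or
#'   `"higher_better"` (pKi).
#' @param source Optional CSV column name or SD tag the values come from;
#'   defaults to `name`.
#' @return A `criterion_spec` object.
#' @examples
#' criterion_spec("glide", "lower_better")
#' criterion_spec("pki", "higher_better", source = "MOE_pKi")
#' @export
criterion_spec <- function(name, direction = c("lower_better", "higher_better"),
                           source = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (missing(direction)) {
    stop("criterion '", name, "': direction must be set explicitly ",
         "('lower_better' or 'higher_better')", call. = FALSE)
  }
  direction <- match.arg(direction)
  structure(list(name = name, direction = direction, source = source),
            class = "criterion_spec")
}

#' @export
print.criterion_spec <- function(x, ...) {
  cat(sprintf("<criterion> %s [%s] <- %s\n", x$name, x$direction, x$source))
  invisible(x)
}

# Normalise a list of criterion_spec, enforcing unique names.
as_criteria <- function(criteria) {
  if (inherits(criteria, "criterion_spec")) criteria <- list(criteria)
  if (!is.list(criteria) || length(criteria) == 0L ||
      !all(vapply(criteria, inherits, logical(1), "criterion_spec"))) {
    stop("'criteria' must be a non-empty list of criterion_spec objects",
         call. = FALSE)
  }
  nm <- vapply(criteria, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate criterion name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(criteria) <- nm
  criteria
}

#' Construct a score table
#'
#' The central tabular container of the pipeline: one row per compound,
#' one column per scoring criterion. Missing values are kept as `NA`,
#' never imputed; what a missing score means is decided by the stage that
#' consumes the table (threshold stages drop, the vote excludes).
#'
#' @param ids Character vector of unique compound identifiers.
#' @param criteria List of [criterion_spec()] objects.
#' @param values Numeric matrix, `length(ids)` rows and one column per
#'   criterion (matched by criterion name via `colnames`, or positionally
#'   if unnamed). Present values must be finite.
#' @return A `score_table` object.
#' @export
score_table <- function(ids, criteria, values) {
  criteria <- as_criteria(criteria)
  ids <- trimws(as.character(ids))
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(ids) || ncol(values) != length(criteria)) {
    stop("values must be a ", length(ids), " x ", length(criteria),
         " matrix", call. = FALSE)
  }
  if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), names(criteria))) {
      stop("values column names do not match criterion names", call. = FALSE)
    }
    values <- values[, names(criteria), drop = FALSE]
  } else {
    colnames(values) <- names(criteria)
  }
  bad <- is.infinite(values) | is.nan(values)
  if (any(bad)) stop("non-finite score value(s) present", call. = FALSE)
  rownames(values) <- ids
  structure(list(ids = ids, criteria = criteria, values = values),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d compounds x %d criteria (%s)\n",
              length(x$ids), length(x$criteria),
              paste(names(x$criteria), collapse = ", ")))
  invisible(x)
}

#' Number of compounds in a score table
#' @param table A `score_table`.
#' @return Integer count.
#' @export
n_compounds <- function(table) {
  stopifnot(inherits(table, "score_table"))
  length(table$ids)
}

# Subset a score table to a set of compound ids, preserving stored order.
subset_score_table <- function(table, ids) {
  keep <- table$ids %in% ids
  structure(list(ids = table$ids[keep], criteria = table$criteria,
                 values = table$values[keep, , drop = FALSE]),
            class = "score_table")
}

# Append (or replace) one criterion column, value vector named by id.
add_criterion <- function(table, spec, values_by_id) {
  stopifnot(inherits(table, "score_table"), inherits(spec, "criterion_spec"))
  col <- unname(values_by_id[table$ids])
  criteria <- table$criteria
  criteria[[spec$name]] <- spec
  vals <- cbind(table$values[, setdiff(colnames(table$values), spec$name),
                             drop = FALSE],
                col)
  colnames(vals)[ncol(vals)] <- spec$name
  score_table(table$ids, criteria, vals[, names(criteria), drop = FALSE])
}
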