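#' Read a score table from CSV
#'
#' The CSV must carry an `id` column (compound identifiers, stripped of
#' surrounding whitespace, case-sensitive) and one column per criterion's
#' source name. Empty cells become missing values — never zero, never
#' imputed.
#'
#' @param path CSV file path.
#' @param criteria List of [criterion_spec()] objects; each spec's
#'   `source` names the CSV column to read.
#' @param id_column Name of the identifier column (default `"id"`).
#' @return A [score_table()].
#' @export
read_score_csv <- function(path, criteria, id_column = "id") {
  if (!file.exists(path)) vsf_stop(paste0("file not found: ", path))
  criteria <- as_criteria(criteria)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!id_column %in% names(raw)) {
    vsf_stop(paste0("missing id column '", id_column, "'"))
  }
  ids <- trimws(raw[[id_column]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    vsf_stop(paste0("duplicate compound id(s): ", paste(dup, collapse = ", ")))
  }
  vals <- matrix(NA_real_, nrow(raw), length(criteria),
                 dimnames = list(ids, names(criteria)))
  for (cs in criteria) {
    if (!cs$source %in% names(raw)) {
      vsf_stop(paste0("criterion column '", cs$source, "' not found in ", path))
    }
    cell <- raw[[cs$source]]
    present <- !is.na(cell) & nzchar(cell)
    num <- suppressWarnings(as.numeric(cell[present]))
    if (anyNA(num)) {
      bad_line <- which(present)[which(is.na(num))[1L]] + 1L  # +1 = header
      vsf_stop(sprintf("non-numeric value '%s' for criterion '%s' at line %d",
                       cell[present][which(is.na(num))[1L]], cs$name, bad_line))
    }
    vals[present, cs$name] <- num
  }
  score_table(ids, criteria, vals)
}

#' Write a score table to CSV
#'
#' Inverse of [read_score_csv()]: round-tripping preserves compounds,
#' criteria and every present value. Missing values are written as empty
#' cells.
#'
#' @param table A [score_table()].
#' @param path Output CSV path.
#' @export
write_score_csv <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  df <- data.frame(id = table$ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (nm in names(table$criteria)) df[[nm]] <- table$values[, nm]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) vsf_stop(paste0("cannot write: ", path))
  invisible(path)
}

# ---- SDF V2000 ------------------------------------------------------------

#' Read docking poses from a multi-record SDF V2000 file
#'
#' One pose record per SDF record; the compound id is the molecule title
#' line, whitespace-stripped. Hydrogens are dropped at read time (docking
#' programs may protonate differently); everything else is kept. Requested
#' SD tags are parsed as numeric scores when present. Multiple records may
#' share a title (multiple poses per compound); they are surfaced as
#' separate records for the caller to resolve.
#'
#' @param path SDF file path (V2000 only; V3000 records are rejected).
#' @param score_tags Character vector of SD tag names to parse as scores.
#' @return List of `pose_record` objects, each a [pose()] with fields
#'   `id`, `scores` (named numeric) and `record` (1-based record index).
#' @export
read_sdf_poses <- function(path, score_tags = character(0)) {
  if (!file.exists(path)) vsf_stop(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  # strip a trailing blank tail, then split on "$$$$" delimiters
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) vsf_stop("no SDF record delimiter ($$$$) found")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    rec <- lines[starts[k]:(ends[k] - 1L)]
    out[[k]] <- parse_sdf_record(rec, k, score_tags)
  }
  out
}

parse_sdf_record <- function(rec, idx, score_tags) {
  fail <- function(what) {
    vsf_stop(sprintf("SDF record %d: %s", idx, what), class = "vsf_sdf_parse")
  }
  if (length(rec) < 4L) fail("truncated record (missing header/counts line)")
  id <- trimws(rec[1L])
  counts <- rec[4L]
  if (grepl("V3000", counts, fixed = TRUE)) fail("V3000 records not supported")
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L || nbonds < 0L) {
    fail("malformed counts line")
  }
  if (length(rec) < 4L + natoms + nbonds) fail("truncated atom/bond block")
  atom_lines <- rec[5L:(4L + natoms)]
  xyz <- matrix(suppressWarnings(as.numeric(c(
    substr(atom_lines, 1L, 10L),
    substr(atom_lines, 11L, 20L),
    substr(atom_lines, 21L, 30L)))), ncol = 3L)
  el <- trimws(substr(atom_lines, 32L, 34L))
  if (anyNA(xyz) || any(!nzchar(el))) fail("malformed atom block")
  if (nbonds > 0L) {
    bond_lines <- rec[(5L + natoms):(4L + natoms + nbonds)]
    bij <- matrix(suppressWarnings(as.integer(c(
      substr(bond_lines, 1L, 3L),
      substr(bond_lines, 4L, 6L),
      substr(bond_lines, 7L, 9L)))), ncol = 3L)
    if (anyNA(bij)) fail("malformed bond block")
    if (any(bij[, 1:2] < 1L) || any(bij[, 1:2] > natoms)) {
      fail("bond block references an atom index outside 1..natoms (V2000 is 1-based)")
    }
  } else {
    bij <- matrix(integer(0), 0L, 3L)
  }
  # drop hydrogens and remap indices
  heavy <- which(el != "H")
  if (length(heavy) == 0L) fail("zero heavy atoms")
  remap <- integer(natoms)
  remap[heavy] <- seq_along(heavy)
  keep_bond <- bij[, 1] %in% heavy & bij[, 2] %in% heavy
  bonds <- bij[keep_bond, , drop = FALSE]
  if (nrow(bonds)) {
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
  }
  g <- molecular_graph(el[heavy], bonds)
  p <- pose(g, xyz[heavy, , drop = FALSE])
  scores <- parse_sd_tags(rec, score_tags, fail)
  p$id <- id
  p$scores <- scores
  p$record <- idx
  class(p) <- c("pose_record", "pose")
  p
}

# SD tags: "> <TagName>" (possibly with trailing register info), one or
# more data lines, terminated by a blank line.
parse_sd_tags <- function(rec, score_tags, fail) {
  scores <- stats::setNames(numeric(0), character(0))
  if (length(score_tags) == 0L) return(scores)
  tag_at <- grep("^>", rec)
  for (i in tag_at) {
    m <- regmatches(rec[i], regexpr("<[^>]+>", rec[i]))
    if (length(m) == 0L) next
    tag <- substr(m, 2L, nchar(m) - 1L)
    if (!tag %in% score_tags) next
    if (i + 1L > length(rec)) next
    val <- suppressWarnings(as.numeric(trimws(rec[i + 1L])))
    if (is.na(val)) fail(sprintf("non-numeric value for SD tag <%s>", tag))
    scores[tag] <- val
  }
  scores
}

#' Write poses to a multi-record SDF V2000 file
#'
#' Inverse of [read_sdf_poses()] for heavy-atom-only records; each pose's
#' `scores` (if any) are written as SD tags.
#'
#' @param poses List of `pose_record` objects (or [pose()]s carrying `id`).
#' @param path Output path.
#' @export
write_sdf_poses <- function(poses, path) {
  fmt_counts <- function(na, nb) {
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    vsf_stop(paste0("cannot write: ", path))
  })
  on.exit(close(con))
  for (p in poses) {
    g <- p$graph
    n <- length(g$elements)
    writeLines(c(if (is.null(p$id)) "" else p$id, "  vsfunnel", "",
                 fmt_counts(n, nrow(g$bonds))), con)
    for (i in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         p$coords[i, 1], p$coords[i, 2], p$coords[i, 3],
                         g$elements[i]), con)
    }
    if (nrow(g$bonds)) {
      for (j in seq_len(nrow(g$bonds))) {
        writeLines(sprintf("%3d%3d%3d  0", g$bonds[j, 1], g$bonds[j, 2],
                           g$bonds[j, 3]), con)
      }
    }
    writeLines("M  END", con)
    if (!is.null(p$scores) && length(p$scores)) {
      for (tag in names(p$scores)) {
        writeLines(c(sprintf("> <%s>", tag),
                     format(p$scores[[tag]], digits = 15), ""), con)
      }
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

# ---- hit lists ------------------------------------------------------------

#' Write a ranked hit list to CSV
#'
#' Columns: `id`, `cumulative_vote`, one `rank_<criterion>` column per
#' criterion, `tie_break_key`. Row order is the final ranking; a
#' round-trip read reproduces it exactly.
#'
#' @param hits A `hit_list` (from [select_top_voted()] or [run_funnel()]).
#' @param path Output CSV path.
#' @export
write_hitlist <- function(hits, path) {
  stopifnot(inherits(hits, "hit_list"))
  ok <- tryCatch({
    utils::write.csv(as.data.frame(hits), path, row.names = FALSE,
                     quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) vsf_stop(paste0("cannot write: ", path))
  invisible(path)
}

#' Read a hit list written by [write_hitlist()]
#' @param path CSV path.
#' @return A `hit_list` data frame in stored order.
#' @export
read_hitlist <- function(path) {
  if (!file.exists(path)) vsf_stop(paste0("file not found: ", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  df$cumulative_vote <- as.integer(df$cumulative_vote)
  for (nm in grep("^rank_", names(df), value = TRUE)) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  df$tie_break_key <- as.numeric(df$tie_break_key)
  class(df) <- c("hit_list", "data.frame")
  df
}
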