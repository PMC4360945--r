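# in-code SDF fixture builder (V2000); atoms = list of c(x, y, z, el)
sdf_record <- function(title, atoms, bonds, tags = list(),
                       counts_line = NULL) {
  n <- length(atoms)
  lines <- c(title, "  test", "",
             if (is.null(counts_line))
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       n, nrow(bonds))
             else counts_line)
  for (a in atoms) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0",
                              as.numeric(a[1]), as.numeric(a[2]),
                              as.numeric(a[3]), a[4]))
  }
  if (nrow(bonds)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2],
                              bonds[, 3]))
  }
  lines <- c(lines, "M  END")
  for (tag in names(tags)) {
    lines <- c(lines, sprintf("> <%s>", tag), as.character(tags[[tag]]), "")
  }
  c(lines, "$$$$")
}

ethanol_rec <- function(title = "ethanol", tags = list(GlideScore = -7.2)) {
  sdf_record(title,
             list(c(0, 0, 0, "C"), c(1.54, 0, 0, "C"), c(2.2, 1.2, 0, "O"),
                  c(2.9, 1.5, 0.4, "H")),
             rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L)),
             tags = tags)
}

test_that("read_score_csv parses, preserves missingness, rejects bad input", {
  crits <- list(criterion_spec("glide", "lower_better"))
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines("id,glide\nA,-9.1\nB,-7.2", path)
  tab <- read_score_csv(path, crits)
  expect_s3_class(tab, "score_table")
  expect_equal(tab$ids, c("A", "B"))
  expect_equal(unname(tab$values[, "glide"]), c(-9.1, -7.2))

  # absent cell -> missing, table still loads
  writeLines("id,glide\nA,\nB,-7.2", path)
  tab <- read_score_csv(path, crits)
  expect_true(is.na(tab$values["A", "glide"]))
  expect_equal(tab$values["B", "glide"], -7.2, ignore_attr = TRUE)

  writeLines("id,glide\nA,-9.1\nA,-7.2", path)
  expect_error(read_score_csv(path, crits), "duplicate compound id.*A")

  writeLines("id,glide\nA,-9.1", path)
  expect_error(read_score_csv(path, list(criterion_spec("ehits", "lower_better"))),
               "column 'ehits' not found")

  writeLines("id,glide\nA,-9.1\nB,oops", path)
  expect_error(read_score_csv(path, crits), "non-numeric.*line 3")
})

test_that("score CSV round-trip is the identity on ids, criteria, values", {
  crits <- list(criterion_spec("glide", "lower_better"),
                criterion_spec("pki", "higher_better"))
  vals <- matrix(c(-9.1, NA, -8.5, 6.2, 5.5, NA), ncol = 2,
                 dimnames = list(NULL, c("glide", "pki")))
  tab <- score_table(c("A", "B", "C"), crits, vals)
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_csv(tab, path)
  back <- read_score_csv(path, crits)
  expect_equal(back$ids, tab$ids)
  expect_equal(names(back$criteria), names(tab$criteria))
  expect_equal(back$values, tab$values)
})

test_that("read_sdf_poses parses V2000, drops hydrogens, reads tags", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(ethanol_rec(), path)
  poses <- read_sdf_poses(path, score_tags = "GlideScore")
  expect_length(poses, 1)
  p <- poses[[1]]
  expect_equal(p$id, "ethanol")
  expect_equal(p$graph$elements, c("C", "C", "O"))   # H dropped
  expect_equal(nrow(p$coords), 3)
  expect_equal(nrow(p$graph$bonds), 2)               # bond to H dropped
  expect_equal(unname(p$scores["GlideScore"]), -7.2)

  # two records sharing one title -> two pose_records, same id
  writeLines(c(ethanol_rec("dup"), ethanol_rec("dup")), path)
  poses <- read_sdf_poses(path)
  expect_length(poses, 2)
  expect_equal(vapply(poses, `[[`, character(1), "id"), c("dup", "dup"))
  expect_equal(vapply(poses, `[[`, integer(1), "record"), 1:2)
})

test_that("read_sdf_poses hard-errors on malformed records", {
  path <- withr::local_tempfile(fileext = ".sdf")

  # bond block referencing atom 0 (V2000 is 1-based)
  rec <- sdf_record("bad", list(c(0, 0, 0, "C"), c(1.5, 0, 0, "C")),
                    rbind(c(0L, 2L, 1L)))
  writeLines(rec, path)
  expect_error(read_sdf_poses(path), "record 1.*1-based")

  # V3000 rejected
  rec <- sdf_record("v3", list(c(0, 0, 0, "C")), matrix(integer(0), 0, 3),
                    counts_line = "  0  0  0     0  0            999 V3000")
  writeLines(rec, path)
  expect_error(read_sdf_poses(path), "V3000")

  # truncated record
  writeLines(c("t", "", "", "  5  0  0  0  0  0  0  0  0  0999 V2000",
               "$$$$"), path)
  expect_error(read_sdf_poses(path), "truncated")

  # all-hydrogen record
  rec <- sdf_record("allH", list(c(0, 0, 0, "H"), c(1, 0, 0, "H")),
                    rbind(c(1L, 2L, 1L)))
  writeLines(rec, path)
  expect_error(read_sdf_poses(path), "zero heavy atoms")
})

test_that("SDF write/read round-trip preserves graphs, coords, scores", {
  set.seed(42)
  poses <- lapply(1:5, function(i) {
    p <- random_molecule(sample(2:6, 1))
    p$id <- paste0("M", i)
    p$scores <- c(GlideScore = round(stats::rnorm(1), 4))
    class(p) <- c("pose_record", "pose")
    p
  })
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_poses(poses, path)
  back <- read_sdf_poses(path, score_tags = "GlideScore")
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$id, poses[[i]]$id)
    expect_equal(back[[i]]$graph$elements, poses[[i]]$graph$elements)
    expect_equal(back[[i]]$graph$bonds, poses[[i]]$graph$bonds)
    expect_equal(back[[i]]$coords, poses[[i]]$coords, tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$scores, poses[[i]]$scores)
  }
})

test_that("hit-list CSV round-trips in exact order, including empty", {
  votes <- stats::setNames(c(5L, 3L, 3L, 1L), c("D", "B", "A", "C"))
  ranks <- matrix(c(1L, 5L, 4L, 9L, 2L, 6L, 3L, 8L), ncol = 2,
                  dimnames = list(c("D", "B", "A", "C"), c("g", "e")))
  hits <- select_top_voted(votes, ranks, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hitlist(hits, path)
  expect_length(readLines(path), 5)  # header + 4
  back <- read_hitlist(path)
  expect_equal(back$id, hits$id)
  expect_equal(back$cumulative_vote, hits$cumulative_vote)
  expect_equal(back$rank_g, hits$rank_g)

  empty <- select_top_voted(stats::setNames(integer(0), character(0))[0],
                            ranks[0, , drop = FALSE], 1)
  expect_s3_class(empty, "hit_list")
  write_hitlist(empty, path)
  expect_length(readLines(path), 1)  # header only
  expect_equal(nrow(read_hitlist(path)), 0)
})
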