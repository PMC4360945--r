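two_crit_table <- function(ids, glide, ehits) {
  score_table(ids, list(criterion_spec("glide", "lower_better"),
                        criterion_spec("ehits", "lower_better")),
              cbind(glide = glide, ehits = ehits))
}

test_that("apply_score_stage enforces the comparator and tallies drops", {
  tab <- two_crit_table(c("A", "B", "C", "D"),
                        glide = c(4.9, 5.0, 5.1, -6.0),
                        ehits = c(1, 2, 3, 4))
  out <- apply_score_stage(tab, "glide", 5.0, "lt")
  expect_setequal(out$ids, c("A", "D"))  # B excluded by strictness
  expect_setequal(attr(out, "stage_drops")$threshold, c("B", "C"))

  out <- apply_score_stage(tab, "glide", 5.0, "le")
  expect_setequal(out$ids, c("A", "B", "D"))

  # all values pass -> unchanged
  out <- apply_score_stage(tab, "ehits", 100, "lt")
  expect_equal(out$ids, tab$ids)

  # missing values are dropped and counted separately
  tab2 <- two_crit_table(c("A", "B"), glide = c(NA, 1), ehits = c(1, 1))
  out <- apply_score_stage(tab2, "glide", 5.0, "lt")
  expect_equal(out$ids, "B")
  expect_equal(attr(out, "stage_drops")$missing, "A")
  expect_length(attr(out, "stage_drops")$threshold, 0)

  # empty input -> empty output
  empty <- subset_tab <- apply_score_stage(tab, "glide", -100, "lt")
  expect_equal(n_compounds(apply_score_stage(empty, "glide", 5, "lt")), 0)

  expect_error(apply_score_stage(tab, "nope", 1, "lt"), "unknown criterion")
})

as_record <- function(p, id) {
  p$id <- id
  class(p) <- c("pose_record", "pose")
  p
}

test_that("apply_rmsd_stage: strict cutoff, pairing and drop reasons", {
  tmpl <- pose_template("chain_c4")
  ok <- as_record(tmpl, "ok")
  atcut <- as_record(pose(tmpl$graph,
                          tmpl$coords + matrix(c(2, 0, 0), 4, 3, byrow = TRUE)),
                     "atcut")
  lone <- as_record(tmpl, "lone")
  odd <- as_record(pose_template("hetero_oc2"), "odd")

  pa <- list(as_record(tmpl, "ok"), as_record(tmpl, "atcut"),
             as_record(tmpl, "odd"), lone)
  pb <- list(ok, atcut, odd)
  pb[[3]] <- as_record(pose_template("hetero_oc2"), "odd")
  pb[[3]]$graph <- pose_template("ring_c6")$graph        # not isomorphic
  pb[[3]]$coords <- pose_template("ring_c6")$coords

  rs <- apply_rmsd_stage(pa, pb, cutoff = 2.0)
  expect_equal(rs$survivors, "ok")
  expect_equal(rs$drops$cutoff, "atcut")                 # exactly 2.0: strict
  expect_equal(rs$drops$not_comparable, "odd")
  expect_equal(rs$drops$unpaired_a, "lone")
  expect_equal(unname(rs$rmsd["atcut"]), 2.0)
  expect_equal(unname(rs$rmsd["ok"]), 0)
})

small_library <- function(n = 300, delta = 1, seed = 5, ...) {
  generate_library(synthetic_config(n = n, delta = delta, seed = seed, ...))
}

test_funnel_config <- function(shortlist = 25, verbose = FALSE) {
  funnel_config(list(
    stage_score_threshold("glide", 0.5, "lt"),
    stage_score_threshold("ehits", 0.5, "lt"),
    stage_rmsd_consistency(cutoff = 2.0),
    stage_consensus_vote(f = 0.1, shortlist = shortlist)
  ), verbose = verbose)
}

test_that("run_funnel: monotone chain, subsets, determinism", {
  lib <- small_library()
  res <- run_funnel(test_funnel_config(), lib$table, lib$poses_a, lib$poses_b)
  s <- summary(res$report)
  expect_true(all(diff(s$n_in) <= 0))
  expect_equal(s$n_in[-1], s$n_out[-nrow(s)])  # chained counts
  expect_true(all(s$n_out <= s$n_in))
  expect_true(all(res$hits$id %in% lib$table$ids))
  expect_lte(nrow(res$hits), 25)
  # rmsd criterion recorded for the vote: five rank columns
  expect_setequal(setdiff(names(res$hits), c("id", "cumulative_vote", "tie_break_key")),
                  paste0("rank_", c("glide", "ehits", "ligx", "pki", "rmsd")))

  # rerun is byte-identical at the file level
  res2 <- run_funnel(test_funnel_config(), lib$table, lib$poses_a, lib$poses_b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_hitlist(res$hits, f1)
  write_hitlist(res2$hits, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a single voting stage is equivalent to consensus_vote alone", {
  lib <- small_library(n = 150)
  res <- run_funnel(funnel_config(list(stage_consensus_vote(f = 0.1, shortlist = 40))),
                    lib$table)
  cv <- consensus_vote(lib$table, f = 0.1, shortlist = 40)
  expect_equal(res$hits, cv$hits)
})

test_that("threshold stages on different criteria commute", {
  lib <- small_library(n = 200)
  t1 <- apply_score_stage(apply_score_stage(lib$table, "glide", 0.3, "lt"),
                          "ehits", 0.6, "lt")
  t2 <- apply_score_stage(apply_score_stage(lib$table, "ehits", 0.6, "lt"),
                          "glide", 0.3, "lt")
  expect_equal(t1$ids, t2$ids)
  expect_equal(t1$values, t2$values)
})

test_that("a stage eliminating everything warns and yields an empty hit list", {
  lib <- small_library(n = 50)
  fc <- funnel_config(list(
    stage_score_threshold("glide", -100, "lt"),   # kills everything
    stage_consensus_vote(f = 0.1, shortlist = 10)))
  expect_warning(res <- run_funnel(fc, lib$table, lib$poses_a, lib$poses_b),
                 "eliminated all")
  expect_s3_class(res$hits, "hit_list")
  expect_equal(nrow(res$hits), 0)
})

test_that("rmsd stage in a funnel requires pose sets", {
  lib <- small_library(n = 20)
  expect_error(run_funnel(test_funnel_config(), lib$table),
               "pose sets were not supplied")
})

test_that("enrichment of planted binders is monotone in effect size", {
  fracs <- vapply(c(0, 0.5, 1, 2), function(delta) {
    lib <- generate_library(synthetic_config(
      n = 3000, prevalence = 0.05, delta = delta, seed = 19))
    res <- run_funnel(test_funnel_config(shortlist = 150),
                      lib$table, lib$poses_a, lib$poses_b)
    mean(lib$labels[res$hits$id])
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_true(all(fracs[-1] > 0.05))  # enriched above prevalence for delta > 0
})

test_that("stage report serialises to JSON with counts and drop tallies", {
  lib <- small_library(n = 100)
  res <- run_funnel(test_funnel_config(shortlist = 10),
                    lib$table, lib$poses_a, lib$poses_b)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(res$report, path)
  j <- jsonlite::read_json(path)
  expect_length(j$stages, 4)
  expect_equal(j$stages[[1]]$n_in, 100)
  expect_equal(j$stages[[2]]$n_in, j$stages[[1]]$n_out)
})
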