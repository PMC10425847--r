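test_that("dye-fill means bin to the printed 0-4 scores", {
  expect_equal(score_dyefill(12, 4), list(amphid_score = 0L, phasmid_score = 0L,
                                          overall = 0L))
  # strong mutant: 4.3 amphid / 0.3 phasmid neurons
  expect_equal(score_dyefill(4.3, 0.3)$overall, 4L)
  expect_equal(score_dyefill(4.3, 0.3)$amphid_score, 4L)
  expect_equal(score_dyefill(4.3, 0.3)$phasmid_score, 3L)
  # reference mutant: 6.9 / 0.4
  expect_equal(unlist(score_dyefill(6.9, 0.4)), c(amphid_score = 3L,
                                                  phasmid_score = 3L,
                                                  overall = 3L))
  # bin edges, including the values falling in the printed one-decimal gaps
  expect_equal(score_dyefill(11.5, 4)$amphid_score, 0L)
  expect_equal(score_dyefill(11.49, 4)$amphid_score, 1L)
  expect_equal(score_dyefill(10.95, 4)$amphid_score, 2L)  # printed gap 10.9-11
  expect_equal(score_dyefill(6, 4)$amphid_score, 3L)
  expect_equal(score_dyefill(5.9, 4)$amphid_score, 4L)
  expect_equal(score_dyefill(12, 0.25)$phasmid_score, 3L)
  expect_equal(score_dyefill(12, 0.24)$phasmid_score, 4L)
  expect_equal(score_dyefill(12, 3.745)$phasmid_score, 2L) # gap 3.74-3.75

  expect_error(score_dyefill(12.5, 4), "out of range")
  expect_error(score_dyefill(12, 4.5), "out of range")
})

test_that("dye-fill and fertility scores are monotone in the raw phenotype", {
  a <- sapply(seq(0, 12, by = 0.1), function(x) score_dyefill(x, 4)$amphid_score)
  expect_true(all(diff(a) <= 0))
  f <- sapply(seq(0, 150, by = 1), score_fertility)
  expect_true(all(diff(f) <= 0))
})

test_that("fertility pupae counts bin as printed", {
  expect_equal(score_fertility(120), 0L)   # control-level
  expect_equal(score_fertility(90), 0L)
  expect_equal(score_fertility(89), 1L)
  expect_equal(score_fertility(60), 1L)
  expect_equal(score_fertility(59), 2L)
  expect_equal(score_fertility(30), 2L)
  expect_equal(score_fertility(29), 3L)
  expect_equal(score_fertility(10), 3L)
  expect_equal(score_fertility(9), 4L)
  expect_equal(score_fertility(0), 4L)
  expect_error(score_fertility(-1), "nonnegative")
})

test_that("registered rubrics apply their printed bins", {
  # scolopidia: strictly more than 20% defective is abnormal
  expect_equal(score_rubric(0.25, "scolopidia"), 1L)
  expect_equal(score_rubric(0.20, "scolopidia"), 0L)

  # flight: strictly more than half unable to fly scores 2
  expect_equal(score_rubric(0.55, "flight", n_affected = 11), 2L)
  expect_equal(score_rubric(0.5, "flight", n_affected = 10), 1L)
  expect_equal(score_rubric(0.1, "flight", n_affected = 2), 0L)

  # uncoordination: strong categories, weak delegates to flight
  expect_equal(score_rubric("stuck_to_food", "uncoordination"), 4L)
  expect_equal(score_rubric("bottom_no_climb", "uncoordination"), 3L)
  expect_equal(score_rubric(0.6, "uncoordination", n_affected = 12), 2L)

  # viability
  expect_equal(score_rubric(1, "viability"), 4L)
  expect_equal(score_rubric(0.95, "viability"), 3L)
  expect_equal(score_rubric(0.5, "viability"), 2L)
  expect_equal(score_rubric(0.2, "viability", n_affected = 5), 1L)
  expect_equal(score_rubric(0.01, "viability", n_affected = 2), 0L)

  # wing posture
  expect_equal(score_rubric(1, "wing"), 4L)
  expect_equal(score_rubric(0.7, "wing"), 3L)
  expect_equal(score_rubric(0.5, "wing"), 2L)
  expect_equal(score_rubric(0.2, "wing", n_affected = 4), 1L)

  # spermiogenesis passes through validated stage scores
  expect_equal(score_rubric(4, "spermiogenesis"), 4L)
  expect_error(score_rubric(5, "spermiogenesis"), "0-4")

  expect_error(score_rubric(0.5, "telepathy"), "unknown rubric")
})

test_that("significance aggregation uses a strict score > 1 and skips NAs", {
  rec <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    novelty = c("known", "known", "known", "novel", "novel", "novel"),
    neurons = c(3L, 1L, NA, 0L, 2L, 1L),
    sperm   = c(0L, 1L, 4L, 1L, NA, NA),
    stringsAsFactors = FALSE
  )
  out <- aggregate_significance(rec)
  known <- out[out$novelty == "known", ]
  novel <- out[out$novelty == "novel", ]
  # g1 (3), g3 (4) significant; g2 maxes at 1 -> not significant
  expect_equal(known$n_significant, 2L)
  expect_equal(known$percent_significant, 67L)
  # g5 (2) significant; g4 max 1, g6 only NA+1
  expect_equal(novel$n_significant, 1L)
  expect_equal(novel$percent_significant, 33L)

  expect_error(aggregate_significance(rec[, -2]), "novelty")
  bad <- rec; bad$novelty[1] <- NA
  expect_error(aggregate_significance(bad), "novelty")
})
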