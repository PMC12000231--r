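test_that("cell aggregation handles means, medians and empty cells", {
  expect_equal(aggregate_cell(c(500, 600), "mean"), 550)
  expect_equal(aggregate_cell(c(1, 2, 3, 100), "median"), 2.5)
  expect_equal(aggregate_cell(7, "median"), 7)
  expect_true(is.na(aggregate_cell(numeric(0), "mean")))
})

make_cells <- function(avoid_t, appr_t, avoid_c, appr_c, reps = 2) {
  d <- expand.grid(rep = seq_len(reps),
                   direction = c("avoid", "approach"),
                   category = c("target", "control"),
                   stringsAsFactors = FALSE)
  base <- c(avoid_t, appr_t, avoid_c, appr_c)
  d$rt <- rep(base, each = reps)
  d$s <- "p1"
  trial_table(d, participant = "s", rt = "rt", factor1 = "category",
              factor2 = "direction")
}

test_that("participant scores follow the declared contrast orientation", {
  # single difference: avoid 600 vs approach 500 -> +100 bias
  d <- data.frame(s = "p1", dir = rep(c("avoid", "approach"), each = 2),
                  rt = c(590, 610, 495, 505))
  tt <- trial_table(d, "s", "rt", factor2 = "dir")
  spec1 <- score_spec("mean", "factor2", c(factor2 = "avoid"))
  expect_equal(participant_score(tt, spec1), 100)

  # double difference, hand-evaluated: (620-520) - (560-540) = 80
  tt2 <- make_cells(620, 520, 560, 540)
  expect_equal(participant_score(tt2, dd_spec()), 80)
  # all four cell means equal -> 0
  expect_equal(participant_score(make_cells(550, 550, 550, 550),
                                 dd_spec()), 0)
})

test_that("score_vector flags incomplete participants and pools trials", {
  tt <- toy_table(n_participants = 3, seed = 8)
  spec <- dd_spec()
  sv <- score_vector(tt, spec)
  expect_equal(nrow(sv), 3L)
  expect_true(all(sv$defined))

  drop <- !(tt$participant == "p2" & tt$factor1 == "control" &
              tt$factor2 == "avoid")
  tt2 <- tt[drop, ]
  class(tt2) <- class(tt)
  sv2 <- score_vector(tt2, spec)
  expect_equal(sum(sv2$defined), 2L)
  expect_true(is.na(sv2$score[sv2$participant == "p2"]))

  # concatenating two tables scores the pooled trials, not an average
  # of per-part scores
  a <- toy_table(n_participants = 2, reps = 2, seed = 9)
  b <- toy_table(n_participants = 2, reps = 2, seed = 10)
  b$presentation <- b$presentation + 16L
  ab <- rbind(as.data.frame(a), as.data.frame(b))
  class(ab) <- class(a)
  pooled <- score_vector(ab, spec)
  oracle <- vapply(unique(ab$participant), function(p) {
    sub <- ab[ab$participant == p, ]
    m <- tapply(sub$rt, list(sub$factor1, sub$factor2), mean)
    (m["target", "avoid"] - m["target", "approach"]) -
      (m["control", "avoid"] - m["control", "approach"])
  }, numeric(1))
  expect_equal(pooled$score, unname(oracle[pooled$participant]))
})

test_that("scores respect location, orientation and scale invariances", {
  tt <- toy_table(n_participants = 4, seed = 11)
  spec <- dd_spec()
  shifted <- tt
  shifted$rt <- shifted$rt + 250
  class(shifted) <- class(tt)
  expect_equal(score_vector(shifted, spec)$score,
               score_vector(tt, spec)$score)

  spec0 <- score_spec("mean")
  expect_equal(score_vector(shifted, spec0)$score,
               score_vector(tt, spec0)$score + 250)

  flipped <- score_spec("mean", c("factor1", "factor2"),
                        c(factor1 = "target", factor2 = "approach"))
  expect_equal(score_vector(tt, flipped)$score,
               -score_vector(tt, spec)$score)

  dspec <- score_spec("dscore", c("factor1", "factor2"),
                      c(factor1 = "target", factor2 = "avoid"))
  scaled <- tt
  scaled$rt <- scaled$rt * 3.7
  class(scaled) <- class(tt)
  expect_equal(score_vector(scaled, dspec)$score,
               score_vector(tt, dspec)$score)
})
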