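count_by <- function(table, assignment, ...) {
  key <- interaction(lapply(list(...), function(v) table[[v]]),
                     drop = TRUE)
  n1 <- tapply(assignment$half == 1L, key, sum)
  n2 <- tapply(assignment$half == 2L, key, sum)
  cbind(n1, n2)
}

test_that("stratified pair-splitting balances every stratum to within one", {
  # single participant, strata of sizes 1..9 in one condition, many seeds
  for (m in 1:9) {
    d <- data.frame(s = "p1", stim = "x", rt = seq_len(m) + 400)
    tt <- trial_table(d, "s", "rt", stimulus = "stim")
    for (seed in 1:50) {
      set.seed(seed)
      a <- stratified_split(tt)
      n1 <- sum(a$half == 1L)
      expect_true(abs(n1 - (m - n1)) <= 1L)
      expect_true(all(a$half %in% 1:2))
    }
  }
})

test_that("even strata split exactly and leftovers pool upward", {
  d <- data.frame(s = "p1", stim = rep(c("a", "b"), each = 8),
                  rt = 400 + 1:16)
  tt <- trial_table(d, "s", "rt", stimulus = "stim")
  set.seed(1)
  a <- stratified_split(tt)
  cnt <- count_by(tt, a, "stimulus")
  expect_true(all(cnt == 4L))  # stratum of 8 -> 4 per half, forced

  # two stimuli of 3 trials: one pair each (1/1), the two leftovers
  # pool at the condition level into one more pair -> 3/3 overall
  d2 <- data.frame(s = "p1", stim = rep(c("a", "b"), each = 3),
                   rt = 500 + 1:6)
  tt2 <- trial_table(d2, "s", "rt", stimulus = "stim")
  for (seed in 1:40) {
    set.seed(seed)
    a2 <- stratified_split(tt2)
    cnt2 <- count_by(tt2, a2, "stimulus")
    expect_true(all(abs(cnt2[, 1] - cnt2[, 2]) <= 1L))
    expect_equal(sum(a2$half == 1L), 3L)  # halves exactly 3/3
  }
})

test_that("condition-balanced splits honour cell counts and seeds", {
  d <- expand.grid(rep = 1:64, dir = c("avoid", "approach"), s = "p1",
                   stringsAsFactors = FALSE)
  d$rt <- 500 + seq_len(nrow(d))
  tt <- trial_table(d, "s", "rt", factor2 = "dir")
  set.seed(3)
  a <- condition_balanced_split(tt)
  expect_true(all(count_by(tt, a, "factor2") == 32L))

  d2 <- data.frame(s = "p1", dir = rep("avoid", 7), rt = 1:7 + 400)
  tt2 <- trial_table(d2, "s", "rt", factor2 = "dir")
  set.seed(4)
  a2 <- condition_balanced_split(tt2)
  expect_true(sum(a2$half == 1L) %in% 3:4)

  set.seed(99); h1 <- condition_balanced_split(tt)$half
  set.seed(99); h2 <- condition_balanced_split(tt)$half
  expect_identical(h1, h2)
  set.seed(100); h3 <- condition_balanced_split(tt)$half
  expect_false(identical(h1, h3))
})

test_that("deterministic splits follow presentation order", {
  d <- data.frame(s = "p1", rt = c(410, 420, 430, 440),
                  o = c(1L, 2L, 5L, 8L))
  tt <- trial_table(d, "s", "rt", presentation = "o")
  a <- odd_even_split(tt)
  # parity of the original index survives exclusions
  expect_equal(a$half, c(1L, 2L, 1L, 2L))

  single <- trial_table(data.frame(s = "p1", rt = 500), "s", "rt")
  a1 <- odd_even_split(single)
  expect_true("p1" %in% a1$empty_half)

  d8 <- data.frame(s = "p1", rt = 400 + 1:8)
  t8 <- trial_table(d8, "s", "rt")
  fs <- first_second_split(t8)
  expect_equal(fs$half, rep(1:2, each = 4L))
  d5 <- data.frame(s = "p1", rt = 400 + 1:5)
  fs5 <- first_second_split(trial_table(d5, "s", "rt"))
  expect_equal(sum(fs5$half == 1L), 3L)

  # blocked conditions make first-second halves unbalanced
  di <- data.frame(s = "p1", dir = rep(c("avoid", "approach"), each = 8),
                   rt = 400 + 1:16)
  fi <- first_second_split(trial_table(di, "s", "rt", factor2 = "dir"))
  cnt <- count_by(trial_table(di, "s", "rt", factor2 = "dir"), fi,
                  "factor2")
  expect_equal(unname(abs(cnt[, 1] - cnt[, 2])), c(8L, 8L))
  expect_true(length(fi$imbalance) > 0)
})

test_that("Monte Carlo resampling preserves sizes and overlaps itself", {
  tt <- toy_table(n_participants = 3, reps = 2, seed = 12)
  set.seed(2)
  pair <- monte_carlo_resample(tt)
  for (h in pair) {
    expect_equal(unname(table(h$participant)),
                 unname(table(tt$participant)))
  }
  one <- trial_table(data.frame(s = "p1", rt = 512), "s", "rt")
  p1 <- monte_carlo_resample(one)
  expect_equal(p1[[1]]$rt, 512)
  expect_equal(p1[[2]]$rt, 512)

  # expected fraction of distinct trials in a resample of a cell of
  # m = 8 is 1 - (1 - 1/8)^8
  m <- 8
  d <- data.frame(s = "p1", rt = 400 + 1:m)
  t8 <- trial_table(d, "s", "rt")
  set.seed(5)
  frac <- mean(replicate(4000, {
    length(unique(monte_carlo_resample(t8)[[1]]$rt)) / m
  }))
  expect_equal(frac, 1 - (1 - 1 / m)^m, tolerance = 0.01)
})

test_that("single-stimulus stratified splitting matches condition balancing", {
  d <- data.frame(s = "p1", stim = "only", dir = rep(c("a", "b"), each = 5),
                  rt = 400 + 1:10)
  tt <- trial_table(d, "s", "rt", stimulus = "stim", factor2 = "dir")
  # distributional equivalence: per-trial half-1 frequency ~ 0.5 and
  # per-condition counts identical in law ({2,3} and {3,2})
  probs <- function(f) {
    set.seed(17)
    h <- replicate(600, f(tt)$half)
    list(p = rowMeans(h == 1L),
         c1 = mean(colSums(h[1:5, ] == 1L)))
  }
  ps <- probs(stratified_split)
  pc <- probs(condition_balanced_split)
  expect_true(all(abs(ps$p - 0.5) < 0.07))
  expect_true(all(abs(pc$p - 0.5) < 0.07))
  expect_equal(ps$c1, pc$c1, tolerance = 0.05)
})
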