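test_that("Cronbach's alpha matches its algebraic reductions", {
  m <- matrix(rnorm(20), 5, 4)
  m_parallel <- matrix(rep(rnorm(6), 4), 6, 4)
  expect_equal(cronbach_alpha(m_parallel), 1)

  # p = 2 with equal variances reduces to 2r/(1+r)
  set.seed(21)
  x <- rnorm(30)
  y <- 0.4 * x + rnorm(30)
  y <- y / sd(y) * sd(x)
  r <- cor(x, y)
  expect_equal(cronbach_alpha(cbind(x, y)), 2 * r / (1 + r),
               tolerance = 1e-12)

  m43 <- matrix(c(3, 5, 4, 7, 8, 6, 2, 4, 3, 9, 8, 10), 4, 3,
                byrow = TRUE)
  expect_equal(cronbach_alpha(m43), 0.956043956043956,
               tolerance = 1e-12)
  m[2, 2] <- NA
  expect_error(cronbach_alpha(m), "missing")
  expect_error(cronbach_alpha(m[, 1, drop = FALSE]), "2 items")
})

test_that("Lord's difference-score reliability is correct and guarded", {
  expect_equal(lord_difference_alpha(0.7, 0.7, 3, 3, 0), 0.7)
  # equal components: reduces to (r - r_ab)/(1 - r_ab), so reliability
  # *drops* as the components correlate -- difference scores of highly
  # correlated parts are unreliable
  r <- 0.7
  for (rab in c(0.3, 0.6, 0.9)) {
    expect_equal(lord_difference_alpha(r, r, 2, 2, rab),
                 (r - rab) / (1 - rab))
  }
  expect_equal(lord_difference_alpha(0.8, 0.6, 2, 1, 0.3),
               0.684210526315790, tolerance = 1e-12)
  expect_warning(out <- lord_difference_alpha(0.5, 0.5, 2, 2, 1),
                 "no variance")
  expect_true(is.na(out))
})

test_that("the alpha pipeline recovers preset internal consistency", {
  spec <- dd_spec()
  # noise-free parallel stimuli in both categories -> alpha 1
  set.seed(31)
  p0 <- sim_params(n_participants = 24, n_reps = 2, alpha_target = 1,
                   bias_variance = 6, trial_sd = 1e-6)
  expect_equal(alpha_reliability(generate_dataset(p0), spec)$point, 1,
               tolerance = 1e-4)

  # single-category spec reduces to a plain alpha of subscores
  set.seed(32)
  p1 <- sim_params(n_participants = 30, n_categories = 1, n_reps = 2,
                   alpha_target = 0.7, bias_variance = 6, trial_sd = 2)
  d1 <- generate_dataset(p1)
  spec1 <- score_spec("mean", "factor2", c(factor2 = "avoid"))
  est1 <- alpha_reliability(d1, spec1)$point
  sub <- tapply(d1$rt * ifelse(d1$factor2 == "avoid", 1, -1),
                list(d1$participant, d1$stimulus), mean) * 2
  expect_equal(est1, cronbach_alpha(sub), tolerance = 1e-10)

  # parameter recovery at small trial noise, averaged over replicates
  set.seed(33)
  rec <- replicate(40, {
    p <- sim_params(n_participants = 60, n_reps = 2, alpha_target = 0.8,
                    bias_variance = 6, trial_sd = 0.01)
    alpha_reliability(generate_dataset(p), spec)$point
  })
  expect_equal(mean(rec), 0.8, tolerance = 0.05)
})

test_that("single split-half scores, correlates and corrects", {
  # within-participant constant scores with between-participant
  # variance: every split correlates perfectly
  d <- expand.grid(rep = 1:4, dir = c("avoid", "approach"),
                   s = paste0("p", 1:6), stringsAsFactors = FALSE)
  d$rt <- 500 + match(d$s, unique(d$s)) * ifelse(d$dir == "avoid", 10, -10)
  tt <- trial_table(d, "s", "rt", factor2 = "dir")
  spec <- score_spec("mean", "factor2", c(factor2 = "avoid"))
  set.seed(41)
  est <- single_splithalf(tt, spec, condition_balanced_split(tt))
  expect_equal(est$point, 1)

  # odd-even on a random table matches an independent hand pipeline
  tt2 <- toy_table(n_participants = 8, seed = 42)
  spec2 <- dd_spec()
  est2 <- single_splithalf(tt2, spec2, odd_even_split(tt2))
  odd <- as.data.frame(tt2)[tt2$presentation %% 2 == 1, ]
  even <- as.data.frame(tt2)[tt2$presentation %% 2 == 0, ]
  hand_score <- function(dd) {
    vapply(split(dd, dd$participant), function(sub) {
      m <- tapply(sub$rt, list(sub$factor1, sub$factor2), mean)
      (m["target", "avoid"] - m["target", "approach"]) -
        (m["control", "avoid"] - m["control", "approach"])
    }, numeric(1))
  }
  r <- cor(hand_score(odd), hand_score(even))
  expect_equal(est2$point, 2 * r / (1 + abs(r)), tolerance = 1e-12)

  # anti-correlated halves stay negative under the mirrored policy
  danti <- data.frame(s = rep(paste0("p", 1:6), each = 2),
                      o = rep(1:2, 6),
                      rt = 500 + c(rbind(1:6 * 10 + c(1, -2, 3, -1, 2, -3),
                                         6:1 * 10)))
  tanti <- trial_table(danti, "s", "rt", presentation = "o")
  esta <- single_splithalf(tanti, score_spec("mean"),
                           odd_even_split(tanti))
  expect_true(esta$point < 0 && esta$point > -1)
})

test_that("permutation split-half agrees across engines and reductions", {
  tt <- toy_table(n_participants = 12, seed = 43)
  spec <- dd_spec()

  # n_splits = 1 on a fixed assignment reduces to single_splithalf
  set.seed(44)
  a <- stratified_split(tt)
  est1 <- permutation_splithalf(tt, spec, assignments = list(a),
                                aggregator = "mean", ci = FALSE)
  est2 <- single_splithalf(tt, spec, a)
  expect_equal(est1$point, est2$point, tolerance = 1e-12)

  # compiled kernel and R reference engine agree distributionally
  set.seed(45)
  ec <- permutation_splithalf(tt, spec, 400, engine = "cpp")
  set.seed(46)
  er <- permutation_splithalf(tt, spec, 400, engine = "r")
  se <- sd(ec$correlations) / sqrt(400)
  expect_lt(abs(mean(ec$correlations) - mean(er$correlations)), 5 * se)
  expect_lt(abs(sd(ec$correlations) - sd(er$correlations)),
            0.25 * sd(ec$correlations))
  expect_lt(abs(ec$point - er$point), 12 * se)
})

test_that("noise-only data yields a near-zero permutation estimate", {
  # a single dataset's estimate carries dataset-frozen split-structure
  # noise (SD ~ 0.12 at this size), so the near-zero property is about
  # the estimator's mean across datasets
  set.seed(47)
  params <- sim_params(n_participants = 100, n_categories = 1,
                       n_stimuli = 8, n_reps = 8, directions = FALSE,
                       bias_variance = 0, trial_sd = 6)
  pts <- replicate(30, {
    d <- generate_dataset(params)
    permutation_splithalf(d, score_spec("mean"), 1500, ci = FALSE)$point
  })
  expect_lt(abs(mean(pts)), 0.05)
})

test_that("Monte Carlo split-half overestimates where permutation does not", {
  # noise-free data -> 1
  d <- expand.grid(rep = 1:4, s = paste0("p", 1:8),
                   stringsAsFactors = FALSE)
  d$rt <- 400 + match(d$s, unique(d$s)) * 7
  tt <- trial_table(d, "s", "rt")
  set.seed(51)
  expect_equal(monte_carlo_splithalf(tt, score_spec("mean"), 50)$point, 1)

  # noise-only data: MC substantially positive, permutation near zero
  set.seed(52)
  params <- sim_params(n_participants = 60, n_categories = 1,
                       n_stimuli = 8, n_reps = 8, directions = FALSE,
                       bias_variance = 0, trial_sd = 6)
  both <- replicate(6, {
    dd <- generate_dataset(params)
    c(mc = monte_carlo_splithalf(dd, score_spec("mean"), 800,
                                 ci = FALSE)$point,
      pm = permutation_splithalf(dd, score_spec("mean"), 800,
                                 ci = FALSE)$point)
  })
  expect_gt(mean(both["mc", ]), 0.2)
  expect_gt(mean(both["mc", ]), mean(both["pm", ]) + 0.15)
  dn <- generate_dataset(params)

  # a single draw with the simple-mean aggregator is the raw resample
  # correlation
  set.seed(53)
  one <- monte_carlo_splithalf(dn, score_spec("mean"), 1,
                               aggregator = "mean", ci = FALSE)
  expect_equal(one$point, unname(one$correlations[1]))
})

test_that("alpha ignores trial-level noise that lowers split-half", {
  set.seed(54)
  params <- sim_params(n_participants = 40, n_reps = 8,
                       alpha_target = 0.8, bias_variance = 6,
                       trial_sd = 2)
  d <- generate_dataset(params)
  spec <- dd_spec()
  # inflate trial noise while preserving every cell mean: +delta/-delta
  # pairs within each (even-sized) participant x stimulus x direction
  # cell, so all stimulus subscores stay bit-identical
  d2 <- as.data.frame(d)
  cellkey <- interaction(d2$participant, d2$stimulus, d2$factor2)
  d2$rt <- d2$rt + ave(rep(0, nrow(d2)), cellkey,
                       FUN = function(v) rep_len(c(60, -60), length(v)))
  tt2 <- trial_table(d2, "participant", "rt", stimulus = "stimulus",
                     factor1 = "factor1", factor2 = "factor2",
                     presentation = "presentation")
  expect_equal(alpha_reliability(tt2, spec)$point,
               alpha_reliability(d, spec)$point, tolerance = 1e-10)
  set.seed(55)
  p_orig <- permutation_splithalf(d, spec, 600)$point
  set.seed(55)
  p_infl <- permutation_splithalf(tt2, spec, 600)$point
  expect_lt(p_infl, p_orig - 0.1)
})
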