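test_that("limit cases of the latent decomposition hold exactly", {
  p1 <- sim_params(alpha_target = 1)
  set.seed(61)
  tr1 <- permsplit:::draw_truth(p1)
  expect_true(all(tr1$d == 0))  # alpha 1: no stimulus-specific part
  p0 <- sim_params(alpha_target = 0)
  set.seed(62)
  tr0 <- permsplit:::draw_truth(p0)
  expect_true(all(tr0$b == 0))  # alpha 0: purely stimulus-specific
  expect_error(sim_params(alpha_target = 1.2))
  expect_error(sim_params(trial_sd = 0))
})

test_that("generated data matches its preset marginal structure", {
  set.seed(63)
  p <- sim_params(n_participants = 3000, alpha_target = 0.6,
                  bias_variance = 6, intercategory_rho = 0.5)
  tr <- permsplit:::draw_truth(p)
  sub1 <- tr$b[, 1] + tr$d[, 1, ]
  expect_equal(mean(apply(sub1, 2, var)), p$subscore_variance,
               tolerance = 0.05 * p$subscore_variance)
  expect_equal(cronbach_alpha(sub1), 0.6, tolerance = 0.04)
  expect_equal(var(rowMeans(sub1)), 6, tolerance = 0.4)
  score2 <- rowMeans(tr$b[, 2] + tr$d[, 2, ])
  expect_equal(cor(rowMeans(sub1), score2), 0.5 * p$w *
                 p$subscore_variance / p$bias_variance,
               tolerance = 0.05)

  # trial noise SD and direction coding: avoid - approach recovers bias
  set.seed(64)
  ps <- sim_params(n_participants = 200, n_reps = 8, trial_sd = 6)
  d <- generate_dataset(ps)
  res <- tapply(d$rt, list(d$participant, d$stimulus, d$factor2), var)
  expect_equal(sqrt(mean(res)), 6, tolerance = 0.1)
})

test_that("same seed reproduces a dataset; pairs share only the truth", {
  p <- sim_params(n_participants = 10, n_reps = 2)
  set.seed(65); d1 <- generate_dataset(p)
  set.seed(65); d2 <- generate_dataset(p)
  expect_identical(as.data.frame(d1), as.data.frame(d2))

  set.seed(66)
  pair <- generate_pair(p)
  expect_identical(attr(pair[[1]], "truth"), attr(pair[[2]], "truth"))
  expect_false(identical(pair[[1]]$rt, pair[[2]]$rt))
})

test_that("closed-form true reliability matches a simulation oracle", {
  spec <- score_spec("mean")
  expect_error(true_reliability(sim_params(), score_spec("median")),
               "closed form")
  expect_equal(true_reliability(sim_params(bias_variance = 0), spec), 0)
  p_clean <- sim_params(trial_sd = 1e-9)
  expect_equal(true_reliability(p_clean, spec), 1, tolerance = 1e-12)

  # nontrivial cell: squared correlation between true and observed
  # scores over many participants
  set.seed(67)
  p <- sim_params(n_participants = 5000, n_reps = 2, alpha_target = 0.4,
                  bias_variance = 3, trial_sd = 5,
                  intercategory_rho = -0.5)
  d <- generate_dataset(p)
  spec_d <- score_spec("mean", c("factor1", "factor2"),
                       c(factor1 = "target", factor2 = "avoid"))
  obs <- score_vector(d, spec_d)
  obs <- obs[order(obs$participant), ]
  r2 <- cor(true_scores(d), obs$score)^2
  expect_equal(r2, true_reliability(p, spec_d), tolerance = 0.025)
})

test_that("trial-SD calibration inverts the reliability map", {
  base <- sim_params(n_participants = 50)
  cal <- calibrate_trial_sd(base, 0.5)
  expect_equal(true_reliability(cal), 0.5, tolerance = 1e-6)
  cal0 <- calibrate_trial_sd(base, 0)
  expect_equal(cal0$bias_variance, 0)
  # derived latent variances must follow: reliability-0 data is noise
  expect_equal(cal0$subscore_variance, 0)
  set.seed(70)
  tr0 <- permsplit:::draw_truth(cal0)
  expect_true(all(tr0$b == 0) && all(tr0$d == 0))
  cal99 <- calibrate_trial_sd(base, 0.999)
  expect_lt(cal99$trial_sd, 0.5)
  expect_error(calibrate_trial_sd(sim_params(bias_variance = 0), 0.5),
               "unattainable")
})

test_that("stratified permutation CIs cover the closed-form reliability", {
  set.seed(68)
  p <- sim_params(n_participants = 40)
  truth <- true_reliability(p)
  spec <- dd_spec()
  hits <- replicate(100, {
    est <- permutation_splithalf(generate_dataset(p), spec, 400)
    est$ci_low <= truth && truth <= est$ci_high
  })
  expect_gte(mean(hits), 0.9)
})
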