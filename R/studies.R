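#' @name studies
#' @title Simulation harnesses
#' @description
#' Three configurable simulation studies evaluate the estimators:
#' [run_study1()] compares five reliability coefficients by how well
#' they forecast a simulated test-retest correlation; [run_study2()]
#' finds the number of random splits needed for a stable
#' permutation-based estimate; [run_study3()] checks the calibration of
#' the permutation-based 95% confidence intervals. Each harness is
#' deterministic given a seed, ships with scaled-down defaults that run
#' on one CPU in minutes, and accepts the full-scale settings (marked
#' long-running in the documentation of each argument).
NULL

# Design matching a score type at a given trial count: double
# differences need 2 categories x directions, single differences one
# category x directions, averages one category without directions.
design_params <- function(score_type = c("double", "single", "average"),
                          n_participants, trials = 256,
                          alpha_target = 0.6, bias_variance = 4,
                          trial_sd = 6, intercategory_rho = 0,
                          n_stimuli = 8) {
  score_type <- match.arg(score_type)
  C <- if (score_type == "double") 2L else 1L
  dirs <- score_type != "average"
  denom <- C * n_stimuli * (if (dirs) 2L else 1L)
  if (trials %% denom != 0L) {
    stop("trials must be a multiple of ", denom, " for this design",
         call. = FALSE)
  }
  sim_params(n_participants = n_participants, n_categories = C,
             n_stimuli = n_stimuli, n_reps = trials %/% denom,
             directions = dirs, alpha_target = alpha_target,
             bias_variance = bias_variance, trial_sd = trial_sd,
             intercategory_rho = intercategory_rho)
}

# Score spec matching a design.
design_spec <- function(params, aggregator = "mean") {
  contrast <- c(if (params$n_categories == 2L) "factor1",
                if (params$directions) "factor2")
  orientation <- c(factor1 = "target", factor2 = "avoid")[contrast]
  score_spec(aggregator, contrast = contrast, orientation = orientation)
}

# Re-rank presentation indices within participant (used when a half
# dataset becomes a session of its own).
rerank_presentation <- function(table) {
  table$presentation <- stats::ave(table$presentation, table$participant,
                                   FUN = rank)
  table
}

#' Study harness: accuracy of five reliability coefficients
#'
#' Generates datasets over a grid of latent subscore alpha, bias
#' variance, trial noise SD and (for double differences) intercategory
#' correlation; splits each dataset into a test and a retest half with
#' the same participants, stimuli and conditions; computes the selected
#' reliability coefficients on both halves; and predicts the observed
#' between-half correlation from each coefficient pair. The full
#' double-difference grid is 2 replicates x 6 alphas x 5 variances x
#' 5 trial SDs x 3 correlations = 900 datasets of 40 participants and
#' 256 trials.
#'
#' @param score_type `"double"`, `"single"` or `"average"`.
#' @param n_splits random splits per permutation estimate (and Monte
#'   Carlo draws); 1000 by default, 10000 for a full-scale run
#'   (long-running).
#' @param methods subset of `c("alpha", "odd_even", "permutation",
#'   "stratified", "monte_carlo")`.
#' @param replicates datasets per grid cell (2 for double differences,
#'   6 otherwise, matching the study design).
#' @param alphas,variances,trial_sds,rhos grid values.
#' @param aggregator score aggregator (the study pattern is identical
#'   for means and medians; means by default).
#' @return data.frame, one row per dataset x method, with the generator
#'   parameters, the two half reliabilities `r1`, `r2`, the `predicted`
#'   and `observed` test-retest correlation. Accuracy and sensitivity
#'   summaries: [study1_accuracy()], [study1_sensitivity()].
#' @export
run_study1 <- function(score_type = c("double", "single", "average"),
                       n_splits = 1000,
                       methods = c("alpha", "odd_even", "permutation",
                                   "stratified", "monte_carlo"),
                       replicates = NULL,
                       alphas = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                       variances = c(2, 4, 6, 8, 10),
                       trial_sds = c(2, 4, 6, 8, 10),
                       rhos = c(-0.5, 0, 0.5),
                       aggregator = "mean") {
  score_type <- match.arg(score_type)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(replicates)) {
    replicates <- if (score_type == "double") 2L else 6L
  }
  if (score_type != "double") rhos <- 0
  trials <- switch(score_type, double = 256L, single = 128L,
                   average = 64L)
  grid <- expand.grid(replicate = seq_len(replicates),
                      alpha_target = alphas, bias_variance = variances,
                      trial_sd = trial_sds, rho = rhos,
                      KEEP.OUT.ATTRS = FALSE)
  policy <- sb_policy()

  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- design_params(score_type, 40L, trials,
                            alpha_target = grid$alpha_target[g],
                            bias_variance = grid$bias_variance[g],
                            trial_sd = grid$trial_sd[g],
                            intercategory_rho = grid$rho[g])
    spec <- design_spec(params, aggregator)
    table <- generate_dataset(params)
    halves <- lapply(split_halves(table, stratified_split(table)),
                     rerank_presentation)
    observed <- as.numeric(pearson(score_vector(halves[[1]], spec),
                                   score_vector(halves[[2]], spec)))
    ests <- lapply(methods, function(m) {
      vapply(halves, function(h) {
        switch(m,
               alpha = alpha_reliability(h, spec)$point,
               odd_even = single_splithalf(h, spec, odd_even_split(h),
                                           policy)$point,
               permutation = permutation_splithalf(h, spec, n_splits,
                                                   stratify = FALSE,
                                                   policy = policy,
                                                   ci = FALSE)$point,
               stratified = permutation_splithalf(h, spec, n_splits,
                                                  stratify = TRUE,
                                                  policy = policy,
                                                  ci = FALSE)$point,
               monte_carlo = monte_carlo_splithalf(h, spec, n_splits,
                                                   ci = FALSE)$point)
      }, numeric(1))
    })
    rows[[g]] <- data.frame(grid[g, , drop = FALSE],
                            method = methods,
                            r1 = vapply(ests, `[`, 0, 1),
                            r2 = vapply(ests, `[`, 0, 2),
                            observed = observed,
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out$predicted <- predicted_retest(out$r1, out$r2)
  out
}

#' Accuracy summary of a study-1 run
#'
#' @param results output of [run_study1()].
#' @return data.frame per method: RMSE, mean (systematic) deviation,
#'   records used and undefined predictions excluded.
#' @export
study1_accuracy <- function(results) {
  do.call(rbind, lapply(split(results, results$method), function(d) {
    m <- accuracy_metrics(d$predicted, d$observed)
    data.frame(method = d$method[1], rmse = m$rmse,
               mean_deviation = m$mean_deviation, n = m$n,
               n_undefined = m$n_undefined, row.names = NULL)
  }))
}

#' Sensitivity of estimates to the generator parameters
#'
#' Pearson correlations, across datasets, between each generator
#' parameter and (a) the observed test-retest correlation, (b) each
#' method's predicted test-retest correlation (undefined predictions
#' excluded pairwise).
#'
#' @param results output of [run_study1()].
#' @return data.frame: method (or `"observed"`), parameter, correlation.
#' @export
study1_sensitivity <- function(results) {
  pars <- c("alpha_target", "bias_variance", "trial_sd", "rho")
  pars <- pars[vapply(pars, function(p) {
    length(unique(results[[p]])) > 1L
  }, logical(1))]
  one_obs <- results[!duplicated(results[, c("replicate", "alpha_target",
                                             "bias_variance", "trial_sd",
                                             "rho")]), ]
  rows <- lapply(pars, function(p) {
    data.frame(method = "observed", parameter = p,
               correlation = stats::cor(one_obs[[p]], one_obs$observed,
                                        use = "complete.obs"))
  })
  for (m in unique(results$method)) {
    d <- results[results$method == m, ]
    rows <- c(rows, lapply(pars, function(p) {
      data.frame(method = m, parameter = p,
                 correlation = stats::cor(d[[p]], d$predicted,
                                          use = "complete.obs"))
    }))
  }
  do.call(rbind, rows)
}

#' Study harness: splits required for a stable estimate
#'
#' For each condition cell, generates replicate datasets, computes a
#' large pool of stratified split-half correlations per dataset, and
#' determines how many randomly drawn correlations must be averaged for
#' the resulting reliability estimate to be stable. Stability is
#' assessed on the estimate as reported -- the Olkin-Pratt aggregate of
#' the drawn correlations passed through the mirrored Spearman-Brown
#' formula -- against the same transform of the grand pool: the
#' requirement is that 95% of drawn-subset estimates deviate less than
#' `criterion` from the pool estimate. Subsets are drawn from the
#' cell's correlations pooled across its replicate datasets, so the
#' dispersion they see is the full split-correlation variability
#' (about 1/sqrt(n-1) at true reliability 0), including the
#' dataset-level component of split variation and not merely the
#' within-one-dataset residual. Subset sizes grow in steps of `step`;
#' the reported figure is the first size above the largest failing
#' size.
#'
#' @param sample_sizes participant counts (full-scale grid:
#'   30, 45, 60, 120).
#' @param trial_counts trials per participant (64, 128, 256).
#' @param reliabilities true mean-score reliabilities to calibrate the
#'   generator to (0 is the hardest and the one used for
#'   recommendations; 0 is realized by zero bias variance).
#' @param score_types subset of `c("average", "single", "double")`.
#' @param aggregators subset of `c("mean", "median", "dscore")`; all
#'   three are computed from the same splits.
#' @param datasets_per_cell replicate datasets per cell (full scale:
#'   150; scaled default 20).
#' @param pool_size split correlations per dataset (full scale: 20000;
#'   scaled default 10000).
#' @param draws subset-average draws per size entering each
#'   proportion; more draws tighten the criterion crossing.
#' @param step,max_size subset-size grid.
#' @param stratify stratified splitting (the requirement barely differs
#'   without stratification).
#' @param criterion,coverage stability criterion: `coverage` of subset
#'   estimates within `criterion` of the pool estimate.
#' @return data.frame per cell x aggregator with `required_splits`.
#' @export
run_study2 <- function(sample_sizes = 30, trial_counts = 256,
                       reliabilities = 0,
                       score_types = "double",
                       aggregators = c("mean", "median", "dscore"),
                       datasets_per_cell = 30, pool_size = 10000,
                       draws = 1600, step = 100, max_size = 8000,
                       stratify = TRUE, criterion = 0.01,
                       coverage = 0.95) {
  stopifnot(max_size <= pool_size)
  sizes <- seq(step, max_size, by = step)
  grid <- expand.grid(n = sample_sizes, trials = trial_counts,
                      reliability = reliabilities,
                      score_type = score_types,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pooled <- vector("list", length(aggregators))
    names(pooled) <- aggregators
    for (d in seq_len(datasets_per_cell)) {
      params <- design_params(grid$score_type[g], grid$n[g],
                              grid$trials[g])
      params <- calibrate_trial_sd(params, grid$reliability[g])
      table <- generate_dataset(params)
      ki <- kernel_inputs(table, design_spec(params, "mean"))
      res <- split_pool_kernel(ki$rt, ki$part, ki$cell, ki$stim,
                               ki$n_parts, ki$n_cells, ki$weights,
                               as.integer(pool_size), stratify,
                               "mean" %in% aggregators,
                               "median" %in% aggregators,
                               "dscore" %in% aggregators)
      for (a in aggregators) {
        r <- res$cor[, a]
        n <- res$n[, a]
        keep <- !is.na(r)
        pooled[[a]] <- c(pooled[[a]],
                         r[keep] * op5_factor(r[keep], n[keep]))
      }
    }
    req <- vapply(aggregators, function(a) {
      cvals <- pooled[[a]]
      pool_est <- spearman_brown(min(1, max(-1, mean(cvals))))
      within <- integer(length(sizes))
      for (j in seq_len(draws)) {
        cs <- cumsum(sample(cvals, max_size, replace = TRUE))
        est <- spearman_brown(pmin(1, pmax(-1, cs[sizes] / sizes)))
        within <- within + (abs(est - pool_est) < criterion)
      }
      fail <- within / draws < coverage
      if (any(fail)) sizes[max(which(fail))] + step else step
    }, numeric(1))
    out[[g]] <- data.frame(grid[g, , drop = FALSE],
                           aggregator = aggregators,
                           required_splits = req, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Study harness: calibration of permutation-based confidence intervals
#'
#' Generates pairs of datasets sharing the same participants and latent
#' structure (a simulated exact replication), computes the stratified
#' permutation-based split-half reliability with its quantile-based 95%
#' CI on both, predicts the test-retest correlation with the averaged
#' CI, and compares against the observed cross-dataset correlation.
#'
#' @param pairs_per_cell dataset pairs per condition (full scale: 200;
#'   scaled default 24).
#' @param n_splits splits per reliability estimate (full scale: 10000).
#' @param sample_sizes participant counts.
#' @param score_types subset of `c("average", "single", "double")`.
#' @param variabilities named latent bias variances; the defaults map
#'   none/medium/large to v = 0, 4, 10 at trial SD 6.
#' @param trials trials per participant.
#' @return list: `records` (one row per pair), `outside` (fraction of
#'   observed correlations strictly outside the averaged CI),
#'   `n_undefined` predictions excluded, and `error_table` (mean
#'   absolute prediction error by sample size x predicted-correlation
#'   quartile bin).
#' @export
run_study3 <- function(pairs_per_cell = 24, n_splits = 1000,
                       sample_sizes = c(30, 60, 120, 240),
                       score_types = c("average", "single", "double"),
                       variabilities = c(none = 0, medium = 4,
                                         large = 10),
                       trials = 256) {
  grid <- expand.grid(n = sample_sizes, score_type = score_types,
                      variability = names(variabilities),
                      pair = seq_len(pairs_per_cell),
                      stringsAsFactors = FALSE)
  policy <- sb_policy()
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- design_params(grid$score_type[g], grid$n[g], trials,
                            bias_variance =
                              variabilities[[grid$variability[g]]])
    spec <- design_spec(params, "mean")
    pair <- generate_pair(params)
    ests <- lapply(pair, function(tab) {
      permutation_splithalf(tab, spec, n_splits, stratify = TRUE,
                            policy = policy)
    })
    observed <- as.numeric(pearson(score_vector(pair[[1]], spec),
                                   score_vector(pair[[2]], spec)))
    pred <- predicted_retest(ests[[1]]$point, ests[[2]]$point)
    ci <- prediction_ci(c(ests[[1]]$ci_low, ests[[1]]$ci_high),
                        c(ests[[2]]$ci_low, ests[[2]]$ci_high))
    rows[[g]] <- data.frame(grid[g, , drop = FALSE],
                            r1 = ests[[1]]$point, r2 = ests[[2]]$point,
                            predicted = pred, observed = observed,
                            ci_low = ci[1], ci_high = ci[2],
                            row.names = NULL)
  }
  records <- do.call(rbind, rows)
  defined <- !is.na(records$predicted)
  cov <- ci_coverage(records$observed[defined],
                     records$ci_low[defined], records$ci_high[defined])
  bins <- c(0, 0.25, 0.5, 0.75, 1)
  bin_lab <- paste(utils::head(bins, -1), bins[-1], sep = "-")
  err_tab <- matrix(NA_real_, length(sample_sizes), length(bin_lab),
                    dimnames = list(sample_sizes, bin_lab))
  inbin <- defined & records$predicted >= 0
  bin_idx <- pmin(findInterval(records$predicted[inbin], bins,
                               rightmost.closed = TRUE), 4L)
  abs_err <- abs(records$predicted[inbin] - records$observed[inbin])
  for (i in seq_along(sample_sizes)) {
    for (b in seq_along(bin_lab)) {
      sel <- records$n[inbin] == sample_sizes[i] & bin_idx == b
      if (any(sel)) err_tab[i, b] <- mean(abs_err[sel])
    }
  }
  list(records = records, outside = cov$outside, n_ci = cov$n,
       n_undefined = sum(!defined), error_table = err_tab)
}
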