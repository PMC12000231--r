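#' @name coefficients
#' @title Reliability estimators
#' @description
#' The estimators compared in this package: Cronbach's alpha on
#' stimulus-specific subscores (combined across stimulus categories with
#' Lord's difference-score formula where needed), single split-half
#' estimators on a fixed assignment (odd-even, first-second, or any
#' random split), the permutation-based split-half (the recommended
#' method, especially with stimulus stratification), and the Monte Carlo
#' split-half (included to demonstrate its overestimation).
NULL

new_reliability_estimate <- function(method, point, ci = NULL,
                                     correlations = NULL, ns = NULL,
                                     policy = NULL, aggregator = NA_character_,
                                     n_dropped = 0L) {
  structure(list(method = method, point = point,
                 ci_low = if (is.null(ci)) NA_real_ else ci[1],
                 ci_high = if (is.null(ci)) NA_real_ else ci[2],
                 correlations = correlations, ns = ns,
                 n_splits = length(correlations),
                 policy = policy, aggregator = aggregator,
                 n_dropped = n_dropped),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat("Reliability estimate (", x$method, ")\n", sep = "")
  cat(sprintf("  point estimate: %.4f\n", x$point))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% CI: [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  }
  if (x$n_splits > 0) {
    cat(sprintf("  splits: %d (aggregated with %s)\n",
                x$n_splits, x$aggregator))
  }
  if (!is.null(x$policy)) {
    cat(sprintf("  Spearman-Brown: %s formula, negatives %s, %s, k = %g\n",
                x$policy$formula, x$policy$negatives, x$policy$order,
                x$policy$k))
  }
  if (x$n_dropped > 0) {
    cat(sprintf("  undefined split correlations dropped: %d\n", x$n_dropped))
  }
  invisible(x)
}

#' Scatterplot data of a permutation estimate
#'
#' @param x a `reliability_estimate` holding split correlations.
#' @param ... passed to [graphics::hist()].
#' @export
plot.reliability_estimate <- function(x, ...) {
  if (is.null(x$correlations)) stop("no split correlations stored")
  graphics::hist(x$correlations, main = paste("Split correlations -",
                                              x$method),
                 xlab = "split-half correlation", ...)
  graphics::abline(v = x$point, col = 2, lwd = 2)
  invisible(x)
}

#' Cronbach's alpha of a subscore matrix
#'
#' Internal consistency of a complete participants x items matrix:
#' \eqn{\alpha = \frac{p}{p-1}\left(1 - \frac{\sum_i Var(X_i)}
#' {\sum_i\sum_j Cov(X_i, X_j)}\right)} with p items (columns).
#' Sample (n - 1) variances and covariances are used throughout; the
#' ratio is invariant to that common factor. The matrix must be
#' complete: alpha has no mechanism for missing entries, which is
#' precisely what makes it awkward for RT tasks with trial exclusions.
#'
#' @param m numeric matrix, participants in rows, items/stimuli in
#'   columns (p >= 2).
#' @return alpha (can be negative; not clamped).
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  p <- ncol(m)
  if (p < 2L) stop("alpha requires at least 2 items", call. = FALSE)
  if (anyNA(m)) {
    stop("subscore matrix has missing entries; Cronbach's alpha is ",
         "undefined for incomplete data", call. = FALSE)
  }
  cv <- stats::cov(m)
  total <- sum(cv)
  if (total == 0) stop("zero total covariance", call. = FALSE)
  p / (p - 1) * (1 - sum(diag(cv)) / total)
}

#' Lord's reliability of a difference score
#'
#' Combines the reliabilities of two component scores into the
#' reliability of their difference:
#' \eqn{r_{a-b} = \frac{r_a s_a^2 + r_b s_b^2 - 2 r_{ab} s_a s_b}
#' {s_a^2 + s_b^2 - 2 r_{ab} s_a s_b}}.
#'
#' @param r_a,r_b component reliabilities.
#' @param s_a,s_b component score standard deviations (> 0).
#' @param r_ab correlation between the component scores.
#' @return the difference-score reliability; `NA` with a warning when
#'   the denominator vanishes (perfectly correlated equal-variance
#'   components leave no difference-score variance).
#' @export
lord_difference_alpha <- function(r_a, r_b, s_a, s_b, r_ab) {
  stopifnot(s_a > 0, s_b > 0)
  den <- s_a^2 + s_b^2 - 2 * r_ab * s_a * s_b
  if (den <= 0) {
    warning("difference score has no variance; reliability undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (r_a * s_a^2 + r_b * s_b^2 - 2 * r_ab * s_a * s_b) / den
}

# Which contrast factor separates stimulus sets (each stimulus occurs
# in exactly one of its levels)? Returns the factor name or NULL.
category_factor <- function(table, spec) {
  for (fc in spec$contrast) {
    tab <- table(table$stimulus, table[[fc]])
    if (all(rowSums(tab > 0) == 1L)) return(fc)
  }
  NULL
}

# participants x stimuli subscore matrix for one subset of trials:
# per stimulus the direction difference (if dir_factor given, oriented
# minuend - subtrahend) or the plain mean RT.
subscore_matrix <- function(table, dir_factor = NULL, minuend = NULL) {
  parts <- sort(unique(table$participant))
  stims <- sort(unique(table$stimulus))
  m <- matrix(NA_real_, length(parts), length(stims),
              dimnames = list(parts, stims))
  pick <- function(agg) {
    agg[cbind(rep(match(parts, rownames(agg)), length(stims)),
              rep(match(stims, colnames(agg)), each = length(parts)))]
  }
  if (is.null(dir_factor)) {
    agg <- tapply(table$rt, list(table$participant, table$stimulus), mean)
    m[] <- pick(agg)
  } else {
    plus <- table[[dir_factor]] == minuend
    a <- tapply(table$rt[plus], list(table$participant[plus],
                                     table$stimulus[plus]), mean)
    b <- tapply(table$rt[!plus], list(table$participant[!plus],
                                      table$stimulus[!plus]), mean)
    m[] <- pick(a) - pick(b)
  }
  if (anyNA(m)) {
    stop("empty participant x stimulus (x direction) cell; the alpha ",
         "pipeline requires complete designs", call. = FALSE)
  }
  m
}

#' Cronbach's-alpha-based reliability of a (difference) score
#'
#' The subscore workaround commonly used to bring alpha to RT tasks:
#' stimulus-specific (bias) subscores are computed per participant,
#' alpha is computed over stimuli within each stimulus category, and for
#' double-difference scores the two categories' alphas are combined with
#' [lord_difference_alpha()] using the category score SDs and their
#' intercorrelation. Because trials are averaged into subscores first,
#' the estimate is blind to trial-level RT variance, and with unequal
#' trial counts it weights trials unequally; both limitations are the
#' reason this estimator is kept only as a comparison.
#'
#' @param table a `trial_table` with stimulus identifiers.
#' @param spec a [score_spec()]; the aggregator must be mean-based
#'   (alpha has no median analogue here).
#' @return a `reliability_estimate` with method `"alpha"`.
#' @export
alpha_reliability <- function(table, spec) {
  if (anyNA(table$stimulus)) {
    stop("alpha pipeline requires a stimulus column", call. = FALSE)
  }
  cnt <- table(table$participant, table$stimulus)
  if (length(unique(as.vector(cnt[cnt > 0]))) > 1L) {
    warning("unequal trial counts per stimulus: alpha weights trials ",
            "unequally", call. = FALSE)
  }
  orientation <- if (length(spec$contrast)) resolve_orientation(table, spec)
  cat_fc <- category_factor(table, spec)
  dir_fc <- setdiff(spec$contrast, cat_fc)
  if (length(dir_fc) == 0L) dir_fc <- NULL
  if (length(dir_fc) > 1L) {
    stop("at most one within-stimulus contrast factor is supported",
         call. = FALSE)
  }
  if (is.null(cat_fc)) {
    m <- subscore_matrix(table, dir_fc, orientation[dir_fc])
    point <- cronbach_alpha(m)
  } else {
    lv_min <- orientation[[cat_fc]]
    lv_all <- sort(unique(table[[cat_fc]]))
    lv_sub <- setdiff(lv_all, lv_min)
    m_a <- subscore_matrix(table[table[[cat_fc]] == lv_min, ],
                           dir_fc, orientation[dir_fc])
    m_b <- subscore_matrix(table[table[[cat_fc]] == lv_sub, ],
                           dir_fc, orientation[dir_fc])
    if (!identical(rownames(m_a), rownames(m_b))) {
      stop("participants differ between categories", call. = FALSE)
    }
    a <- rowMeans(m_a)
    b <- rowMeans(m_b)
    point <- lord_difference_alpha(cronbach_alpha(m_a), cronbach_alpha(m_b),
                                   stats::sd(a), stats::sd(b),
                                   stats::cor(a, b))
  }
  new_reliability_estimate("alpha", point)
}

#' Single split-half reliability
#'
#' Scores both halves of one split assignment, correlates the
#' participants' half scores, and applies the policy's Spearman-Brown
#' step (k = 2 by default). Participants with an undefined score in
#' either half are dropped from the correlation.
#'
#' @param table a `trial_table`.
#' @param spec a [score_spec()].
#' @param assignment a `split_assignment`, e.g. from [odd_even_split()].
#' @param policy an [sb_policy()].
#' @return a `reliability_estimate`.
#' @export
single_splithalf <- function(table, spec, assignment,
                             policy = sb_policy()) {
  halves <- split_halves(table, assignment)
  r <- pearson(score_vector(halves[[1]], spec),
               score_vector(halves[[2]], spec))
  if (is.na(r)) {
    stop("undefined split correlation (fewer than 4 jointly defined ",
         "participants or zero variance)", call. = FALSE)
  }
  est <- policy_correct(as.numeric(r), policy)
  new_reliability_estimate(paste0("single_splithalf_", assignment$scheme),
                           est, correlations = as.numeric(r),
                           ns = attr(r, "n"), policy = policy)
}

# Kernel input preparation: trials sorted by (participant, cell,
# stimulus) with 0-based integer codes.
kernel_inputs <- function(table, spec) {
  orientation <- if (length(spec$contrast)) resolve_orientation(table, spec)
  cellv <- cell_index(table, spec, orientation)
  partf <- factor(table$participant)
  stimf <- if (anyNA(table$stimulus)) rep(1L, nrow(table)) else
    as.integer(factor(table$stimulus))
  ord <- order(as.integer(partf), cellv, stimf)
  list(rt = table$rt[ord],
       part = as.integer(partf)[ord] - 1L,
       cell = as.integer(cellv)[ord] - 1L,
       stim = stimf[ord] - 1L,
       n_parts = nlevels(partf),
       n_cells = required_cells(table, spec),
       weights = cell_weights(spec),
       participants = levels(partf),
       has_stimulus = !anyNA(table$stimulus))
}

#' Permutation-based split-half reliability
#'
#' The recommended estimator: computes the split-half correlation of
#' many random (stratified) splits, aggregates the raw correlations
#' (Olkin-Pratt by default), and applies the policy's Spearman-Brown
#' step -- by default the mirrored formula after aggregation. The 95%
#' CI is formed from the 2.5% and 97.5% empirical quantiles (linear
#' interpolation) of the raw split correlations, each passed through the
#' same Spearman-Brown step. Participants with an undefined score in
#' either half of a split are dropped from that split's correlation
#' only; splits whose correlation is undefined are dropped from
#' aggregation with a recorded count.
#'
#' Around 5,400 splits give a stable estimate even in the hardest case
#' examined by the bundled split-count study (median-based
#' double-difference scores, 30 participants); larger samples need
#' fewer. The default of 6,000 is a safe general-purpose choice.
#'
#' @param table a `trial_table`.
#' @param spec a [score_spec()].
#' @param n_splits number of random splits (default 6000).
#' @param stratify stratify splits by stimulus within condition within
#'   participant (`TRUE`, recommended) or balance conditions only.
#' @param policy an [sb_policy()].
#' @param aggregator `"op5"` (default), `"mean"` or `"fisher"`.
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (reference
#'   implementation via [stratified_split()] and [score_vector()]; slow,
#'   used for cross-validation).
#' @param assignments optional list of `split_assignment`s to use
#'   instead of fresh random splits (forces the R engine); with a single
#'   assignment the result matches [single_splithalf()].
#' @param ci compute the quantile CI (`TRUE`).
#' @return a `reliability_estimate` with the raw split correlations.
#' @export
permutation_splithalf <- function(table, spec, n_splits = 6000,
                                  stratify = TRUE, policy = sb_policy(),
                                  aggregator = c("op5", "mean", "fisher"),
                                  engine = c("cpp", "r"),
                                  assignments = NULL, ci = TRUE) {
  aggregator <- match.arg(aggregator)
  engine <- match.arg(engine)
  if (!is.null(assignments)) engine <- "r"
  if (n_splits < 1L) stop("n_splits must be >= 1", call. = FALSE)
  if (stratify && anyNA(table$stimulus)) {
    stop("stimulus column required for stratified splitting", call. = FALSE)
  }

  if (engine == "cpp") {
    ki <- kernel_inputs(table, spec)
    want <- c(mean = FALSE, median = FALSE, dscore = FALSE)
    want[spec$aggregator] <- TRUE
    res <- split_pool_kernel(ki$rt, ki$part, ki$cell, ki$stim,
                             ki$n_parts, ki$n_cells, ki$weights,
                             as.integer(n_splits), stratify,
                             want[["mean"]], want[["median"]],
                             want[["dscore"]])
    r <- res$cor[, spec$aggregator]
    n <- res$n[, spec$aggregator]
  } else {
    if (is.null(assignments)) {
      assignments <- replicate(n_splits, {
        if (stratify) stratified_split(table) else
          condition_balanced_split(table)
      }, simplify = FALSE)
    }
    rs <- lapply(assignments, function(a) {
      halves <- split_halves(table, a)
      pearson(score_vector(halves[[1]], spec),
              score_vector(halves[[2]], spec))
    })
    r <- vapply(rs, as.numeric, numeric(1))
    n <- vapply(rs, attr, 0L, "n")
  }

  if (all(is.na(r))) stop("all split correlations undefined", call. = FALSE)
  agg_fun <- cor_aggregator(aggregator)
  point <- apply_policy(r, n, policy, agg_fun)
  ci_out <- NULL
  if (ci) {
    q <- stats::quantile(r, c(0.025, 0.975), na.rm = TRUE, names = FALSE,
                         type = 7)
    ci_out <- policy_correct(q, policy)
  }
  method <- if (stratify) "stratified_permutation" else "permutation"
  new_reliability_estimate(method, point, ci_out, correlations = r,
                           ns = n, policy = policy,
                           aggregator = aggregator,
                           n_dropped = sum(is.na(r)))
}

#' Monte Carlo split-half reliability
#'
#' Correlates participant scores from two with-replacement resamples of
#' the data, repeated `n_draws` times, and aggregates the correlations
#' with no Spearman-Brown step (the resamples are full-sized). Because
#' the same trial can land in both resamples, the coefficient
#' substantially overestimates reliability; it is provided to
#' demonstrate that bias, not for use.
#'
#' @param table a `trial_table`.
#' @param spec a [score_spec()].
#' @param n_draws number of resample pairs.
#' @param aggregator `"op5"`, `"mean"` or `"fisher"`.
#' @param engine `"cpp"` or `"r"`.
#' @param ci compute the quantile CI of the raw correlations.
#' @return a `reliability_estimate`.
#' @export
monte_carlo_splithalf <- function(table, spec, n_draws = 6000,
                                  aggregator = c("op5", "mean", "fisher"),
                                  engine = c("cpp", "r"), ci = TRUE) {
  aggregator <- match.arg(aggregator)
  engine <- match.arg(engine)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  if (engine == "cpp") {
    ki <- kernel_inputs(table, spec)
    want <- c(mean = FALSE, median = FALSE, dscore = FALSE)
    want[spec$aggregator] <- TRUE
    res <- mc_pool_kernel(ki$rt, ki$part, ki$cell, ki$n_parts,
                          ki$n_cells, ki$weights, as.integer(n_draws),
                          want[["mean"]], want[["median"]],
                          want[["dscore"]])
    r <- res$cor[, spec$aggregator]
    n <- res$n[, spec$aggregator]
  } else {
    rs <- lapply(seq_len(n_draws), function(i) {
      pair <- monte_carlo_resample(table)
      pearson(score_vector(pair[[1]], spec),
              score_vector(pair[[2]], spec))
    })
    r <- vapply(rs, as.numeric, numeric(1))
    n <- vapply(rs, attr, 0L, "n")
  }
  if (all(is.na(r))) stop("all resample correlations undefined",
                          call. = FALSE)
  agg_fun <- cor_aggregator(aggregator)
  point <- as.numeric(agg_fun(r, n))
  ci_out <- if (ci) {
    stats::quantile(r, c(0.025, 0.975), na.rm = TRUE, names = FALSE,
                    type = 7)
  }
  new_reliability_estimate("monte_carlo", point, ci_out,
                           correlations = r, ns = n,
                           aggregator = aggregator,
                           n_dropped = sum(is.na(r)))
}
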