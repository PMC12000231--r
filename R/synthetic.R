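#' Parameters of a synthetic reaction-time task
#'
#' Describes a hierarchical-normal generative model for trial-level RT
#' data with a controllable internal structure:
#' * per participant i and stimulus category c, a latent shared bias
#'   \eqn{b_{ic} \sim N(0, u)}, with correlation `intercategory_rho`
#'   between the two categories' shared biases;
#' * per stimulus t within category, a stable participant-specific
#'   deviation \eqn{d_{ict} \sim N(0, q)};
#' * i.i.d. trial noise with SD `trial_sd`.
#'
#' `bias_variance` v fixes the variance of the latent *category-level*
#' bias score (the mean over the category's p stimuli of the
#' stimulus-specific bias subscores \eqn{b + d_t}), i.e.
#' \eqn{u + q/p = v}, and `alpha_target` controls how that variance
#' decomposes: with \eqn{w = \alpha / (p - (p-1)\alpha)} solving the
#' parallel-items identity \eqn{\alpha = p w / (1 + (p-1) w)}, the
#' subscore variance is \eqn{v_{sub} = v / (w + (1-w)/p)} and
#' \eqn{u = v_{sub} w}, \eqn{q = v_{sub} (1-w)}. The latent subscores
#' then have Cronbach's alpha equal to `alpha_target` (defined before
#' trial noise, which keeps alpha = 1 attainable with nonzero noise)
#' while the category score's true variance stays at v for every alpha
#' -- so the preset alpha moves internal consistency without moving
#' the score's actual reliability, the dissociation the accuracy
#' harness exploits.
#'
#' With `directions = TRUE` each trial is an approach or an avoid
#' response and the bias enters with opposite half-weights
#' (\eqn{\pm\tfrac12 (b + d)}), so that the avoid - approach contrast
#' recovers the bias; without directions the bias enters additively and
#' the participant's mean RT carries it.
#'
#' The defaults reproduce the double-difference design used throughout
#' the bundled simulation studies: 40 participants, two stimulus
#' categories of eight stimuli, eight approach and eight avoid trials
#' per stimulus (256 trials per participant).
#'
#' @param n_participants number of participants.
#' @param n_categories 1 or 2 stimulus categories.
#' @param n_stimuli stimuli per category.
#' @param n_reps trials per stimulus per direction (or per stimulus,
#'   without directions).
#' @param directions do trials carry an approach/avoid direction?
#' @param alpha_target target Cronbach's alpha of the latent
#'   within-category stimulus bias subscores, in [0, 1].
#' @param bias_variance variance v of the latent category-level bias
#'   score (>= 0).
#' @param trial_sd SD of i.i.d. trial noise (> 0), ms.
#' @param intercategory_rho correlation between the two categories'
#'   biases, in [-1, 1].
#' @param baseline constant baseline RT in ms. All estimators here are
#'   location-invariant; the default keeps generated RTs positive.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_participants = 40, n_categories = 2,
                       n_stimuli = 8, n_reps = 8, directions = TRUE,
                       alpha_target = 0.8, bias_variance = 4,
                       trial_sd = 6, intercategory_rho = 0,
                       baseline = 600) {
  stopifnot(n_participants >= 1, n_categories %in% 1:2, n_stimuli >= 1,
            n_reps >= 1, alpha_target >= 0, alpha_target <= 1,
            bias_variance >= 0, trial_sd > 0,
            abs(intercategory_rho) <= 1)
  p <- n_stimuli
  w <- alpha_target / (p - (p - 1) * alpha_target)
  if (is.nan(w) || w < 0 || w > 1) {
    stop("alpha_target infeasible for this stimulus count", call. = FALSE)
  }
  subscore_variance <- bias_variance / (w + (1 - w) / p)
  structure(list(n_participants = n_participants,
                 n_categories = n_categories, n_stimuli = n_stimuli,
                 n_reps = n_reps, directions = directions,
                 alpha_target = alpha_target,
                 bias_variance = bias_variance, trial_sd = trial_sd,
                 intercategory_rho = intercategory_rho,
                 baseline = baseline, w = w,
                 subscore_variance = subscore_variance),
            class = "sim_params")
}

# Draw the latent participant structure (biases b and stimulus
# deviations d) for one set of participants.
draw_truth <- function(params) {
  n <- params$n_participants
  C <- params$n_categories
  p <- params$n_stimuli
  u <- params$subscore_variance * params$w          # shared component
  q <- params$subscore_variance * (1 - params$w)    # stimulus-specific
  if (C == 2L) {
    rho <- params$intercategory_rho
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    b <- cbind(z1, z2) * sqrt(u)
  } else {
    b <- matrix(stats::rnorm(n, sd = sqrt(u)), n, 1)
  }
  d <- array(stats::rnorm(n * C * p, sd = sqrt(q)), dim = c(n, C, p))
  list(b = b, d = d)
}

# Materialize one trial table from a drawn truth, with fresh trial
# noise and a fresh random presentation order per participant.
materialize <- function(params, truth) {
  n <- params$n_participants
  C <- params$n_categories
  p <- params$n_stimuli
  reps <- params$n_reps
  dirs <- if (params$directions) 2L else 1L
  per_part <- C * p * dirs * reps
  total <- n * per_part

  part <- rep(seq_len(n), each = per_part)
  cat_i <- rep(rep(seq_len(C), each = p * dirs * reps), times = n)
  stim_i <- rep(rep(seq_len(p), each = dirs * reps, times = C), times = n)
  dir_i <- rep(rep(seq_len(dirs), each = reps, times = C * p), times = n)

  latent <- truth$b[cbind(part, cat_i)] + truth$d[cbind(part, cat_i, stim_i)]
  signal <- if (params$directions) {
    ifelse(dir_i == 1L, 0.5, -0.5) * latent   # dir 1 = avoid, 2 = approach
  } else {
    latent
  }
  rt <- params$baseline + signal + stats::rnorm(total, sd = params$trial_sd)

  cat_lab <- c("target", "control")[cat_i]
  out <- data.frame(
    participant = sprintf("p%03d", part),
    stimulus = paste0(substr(cat_lab, 1, 1), stim_i),
    factor1 = if (C == 2L) cat_lab else NA_character_,
    factor2 = if (params$directions) {
      c("avoid", "approach")[dir_i]
    } else NA_character_,
    rt = rt,
    stringsAsFactors = FALSE
  )
  pres <- integer(total)
  for (idx in split(seq_len(total), part)) {
    pres[idx] <- sample.int(length(idx))
  }
  out$presentation <- pres
  attr(out, "params") <- params
  attr(out, "truth") <- truth
  class(out) <- c("trial_table", "data.frame")
  out
}

# Rebuild a sim_params object with some fields replaced, keeping the
# derived quantities (w, subscore_variance) consistent. Fields of a
# sim_params must never be mutated directly.
update_params <- function(params, ...) {
  fields <- list(n_participants = params$n_participants,
                 n_categories = params$n_categories,
                 n_stimuli = params$n_stimuli, n_reps = params$n_reps,
                 directions = params$directions,
                 alpha_target = params$alpha_target,
                 bias_variance = params$bias_variance,
                 trial_sd = params$trial_sd,
                 intercategory_rho = params$intercategory_rho,
                 baseline = params$baseline)
  fields[names(list(...))] <- list(...)
  do.call(sim_params, fields)
}

#' Generate a synthetic trial-level dataset
#'
#' @param params a [sim_params()].
#' @return a `trial_table`; the drawn latent structure is attached as
#'   `attr(x, "truth")` and the parameters as `attr(x, "params")`.
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  materialize(params, draw_truth(params))
}

#' Generate a test-retest pair of datasets
#'
#' Two datasets sharing the same participants with the same latent
#' biases and stimulus deviations, differing only in trial noise and
#' presentation order -- a simulated exact replication of the session.
#'
#' @param params a [sim_params()].
#' @return list of two `trial_table`s.
#' @export
generate_pair <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  truth <- draw_truth(params)
  list(materialize(params, truth), materialize(params, truth))
}

#' Closed-form true reliability of a mean-based score
#'
#' Ratio of between-participant true-score variance to total score
#' variance implied by the variance components and trial counts, for
#' the score matching the dataset's design (double difference for two
#' categories with directions, single difference for one category with
#' directions, plain average without directions). True score here means
#' the participant's expected score under fresh trial noise with the
#' same stimuli, matching what [generate_pair()] holds fixed.
#'
#' With p stimuli per category, m = `n_reps` trials per stimulus per
#' direction, trial variance s^2, category score variance v and shared
#' component u (see [sim_params()]):
#' * double difference: \eqn{V_T = 2 (v - \rho u)},
#'   \eqn{V_E = 4 s^2 / (p m)}
#' * single difference: \eqn{V_T = v}, \eqn{V_E = 2 s^2 / (p m)}
#' * average: \eqn{V_T = v}, \eqn{V_E = s^2 / (p m)}
#'
#' @param params a [sim_params()].
#' @param spec a [score_spec()]; only mean aggregators have a closed
#'   form (median and D-score reliabilities must be simulated).
#' @return reliability in [0, 1].
#' @export
true_reliability <- function(params, spec = score_spec("mean")) {
  stopifnot(inherits(params, "sim_params"))
  if (spec$aggregator != "mean") {
    stop("closed form exists only for mean-based scores; simulate for ",
         "median or D scores", call. = FALSE)
  }
  v <- params$bias_variance
  u <- params$subscore_variance * params$w
  p <- params$n_stimuli
  m <- params$n_reps
  s2 <- params$trial_sd^2
  if (params$n_categories == 2L && params$directions) {
    vt <- 2 * (v - params$intercategory_rho * u)
    ve <- 4 * s2 / (p * m)
  } else if (params$directions) {
    vt <- v
    ve <- 2 * s2 / (p * m)
  } else {
    vt <- v
    ve <- s2 / (p * m)
  }
  if (vt == 0) return(0)
  vt / (vt + ve)
}

#' Calibrate the trial noise SD to a target reliability
#'
#' Inverts [true_reliability()] for the trial SD by monotone root
#' finding. A target of 0 is realized exactly by removing the latent
#' bias variance (v = 0) instead, since no finite noise level nulls a
#' nonzero true-score variance.
#'
#' @param params a [sim_params()]; its `trial_sd` is ignored.
#' @param target target reliability in [0, 1).
#' @param spec a mean-based [score_spec()].
#' @param tol bisection tolerance on the achieved reliability.
#' @return a `sim_params` whose true reliability equals `target`.
#' @export
calibrate_trial_sd <- function(params, target, spec = score_spec("mean"),
                               tol = 1e-9) {
  stopifnot(inherits(params, "sim_params"), target >= 0, target < 1)
  if (target == 0) {
    return(update_params(params, bias_variance = 0))
  }
  if (params$bias_variance <= 0) {
    stop("target > 0 unattainable with zero bias variance", call. = FALSE)
  }
  f <- function(s) {
    true_reliability(update_params(params, trial_sd = s), spec) - target
  }
  upper <- 1
  while (f(upper) > 0) upper <- upper * 2
  s <- stats::uniroot(f, c(1e-8, upper), tol = tol)$root
  update_params(params, trial_sd = s)
}

#' True participant scores of a generated dataset
#'
#' The expected score of each participant under the design's mean-based
#' score, computed from the latent truth attached by
#' [generate_dataset()]; useful as a simulation oracle.
#'
#' @param table a generated `trial_table`.
#' @return numeric vector ordered as `sort(unique(participant))`.
#' @export
true_scores <- function(table) {
  truth <- attr(table, "truth")
  params <- attr(table, "params")
  if (is.null(truth)) stop("table carries no latent truth", call. = FALSE)
  dbar <- apply(truth$d, 1:2, mean)
  sc <- if (params$n_categories == 2L) {
    (truth$b[, 1] + dbar[, 1]) - (truth$b[, 2] + dbar[, 2])
  } else {
    truth$b[, 1] + dbar[, 1]
  }
  sc[order(sprintf("p%03d", seq_along(sc)))]
}
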