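#' @name splitting
#' @title Trial-to-half splitting schemes
#'
#' @description
#' All split-half estimators in this package consume a *split
#' assignment*: a vector giving, for every trial, which of the two
#' halves it belongs to. Random schemes draw from R's RNG, so
#' `set.seed()` makes any assignment bit-reproducible.
#'
#' The random schemes balance trial counts hierarchically
#' (participant > condition > stimulus) by *pair splitting*: the trials
#' of each bottom stratum are randomly paired, each pair contributes one
#' trial to each half, and the single leftover trial (if the stratum is
#' odd-sized) is pooled with the leftovers of its sibling strata at the
#' parent level, where the pooled trials are pair-split in turn. A final
#' odd trial at the participant level is assigned to a half uniformly at
#' random. Within every stratum the two halves therefore differ by at
#' most one trial.
NULL

# Randomly pair the trial indices `idx` and assign each pair's members
# to opposite halves; returns the leftover index (length 0 or 1).
# Writes into `env$half`.
pair_split <- function(idx, env) {
  m <- length(idx)
  if (m == 0L) return(integer(0))
  if (m > 1L) idx <- sample(idx)
  npair <- m %/% 2L
  if (npair > 0L) {
    a <- idx[seq_len(npair) * 2L - 1L]
    b <- idx[seq_len(npair) * 2L]
    coin <- sample(c(1L, 2L), npair, replace = TRUE)
    env$half[a] <- coin
    env$half[b] <- 3L - coin
  }
  if (m %% 2L == 1L) idx[m] else integer(0)
}

new_split_assignment <- function(half, scheme, stratified = FALSE) {
  structure(list(half = half, scheme = scheme, stratified = stratified),
            class = "split_assignment")
}

condition_key <- function(table) {
  paste(table$factor1, table$factor2, sep = "\r")
}

balanced_split_impl <- function(table, stratify) {
  if (nrow(table) == 0L) stop("cannot split an empty table", call. = FALSE)
  if (stratify && anyNA(table$stimulus)) {
    stop("stimulus column required for stratified splitting",
         call. = FALSE)
  }
  env <- new.env()
  env$half <- integer(nrow(table))
  cond <- condition_key(table)
  by_part <- split(seq_len(nrow(table)), table$participant)
  for (pidx in by_part) {
    leftover_p <- integer(0)
    by_cond <- split(pidx, cond[pidx])
    for (cidx in by_cond) {
      if (stratify) {
        leftover_c <- integer(0)
        by_stim <- split(cidx, table$stimulus[cidx])
        for (sidx in by_stim) {
          leftover_c <- c(leftover_c, pair_split(sidx, env))
        }
        leftover_p <- c(leftover_p, pair_split(leftover_c, env))
      } else {
        leftover_p <- c(leftover_p, pair_split(cidx, env))
      }
    }
    odd <- pair_split(leftover_p, env)
    if (length(odd) == 1L) env$half[odd] <- sample(c(1L, 2L), 1L)
  }
  env$half
}

#' Stimulus-stratified random split
#'
#' Random pair split within each participant x condition x stimulus
#' stratum, pooling odd leftovers upward (condition, then participant).
#' Both halves end up with a near-equal number of trials for every
#' stimulus within every condition of every participant.
#'
#' @param table a `trial_table` with a stimulus column.
#' @return a `split_assignment` (`$half` is 1/2 per trial).
#' @export
stratified_split <- function(table) {
  new_split_assignment(balanced_split_impl(table, TRUE),
                       "stratified", TRUE)
}

#' Condition-balanced random split
#'
#' As [stratified_split()] but with the hierarchy participant >
#' condition only: each condition cell of each participant is split
#' near-evenly, without regard to stimulus identity.
#'
#' @param table a `trial_table`.
#' @return a `split_assignment`.
#' @export
condition_balanced_split <- function(table) {
  new_split_assignment(balanced_split_impl(table, FALSE),
                       "condition_balanced", FALSE)
}

#' Odd-even split
#'
#' Deterministic split by the parity of the presentation index within
#' participant: odd indices form half 1, even indices half 2. Parity is
#' taken from the original presentation index, so trials keep their
#' session alternation structure even after exclusions.
#'
#' @param table a `trial_table`.
#' @return a `split_assignment`; participants with an empty half (single
#'   trial) are listed in `$empty_half`.
#' @export
odd_even_split <- function(table) {
  half <- ifelse(table$presentation %% 2L == 1L, 1L, 2L)
  out <- new_split_assignment(half, "odd_even")
  tab <- table(table$participant, half)
  missing_lv <- setdiff(c("1", "2"), colnames(tab))
  empties <- rownames(tab)[rowSums(tab == 0) > 0]
  if (length(missing_lv) > 0) empties <- rownames(tab)
  out$empty_half <- empties
  out
}

#' First-second split
#'
#' Deterministic split at the middle of each participant's session: the
#' first ceiling(m/2) retained trials (by presentation index) form half
#' 1, the remainder half 2. With interleaved conditions the halves can
#' be condition-unbalanced; the per-condition imbalance is reported in
#' `$imbalance`.
#'
#' @param table a `trial_table`.
#' @return a `split_assignment`.
#' @export
first_second_split <- function(table) {
  half <- integer(nrow(table))
  by_part <- split(seq_len(nrow(table)), table$participant)
  for (pidx in by_part) {
    ord <- pidx[order(table$presentation[pidx])]
    m <- length(ord)
    n1 <- ceiling(m / 2)
    half[ord[seq_len(n1)]] <- 1L
    if (m > n1) half[ord[(n1 + 1L):m]] <- 2L
  }
  out <- new_split_assignment(half, "first_second")
  key <- paste(table$participant, condition_key(table))
  n1 <- tapply(half == 1L, key, sum)
  n2 <- tapply(half == 2L, key, sum)
  imb <- abs(n1 - n2)
  out$imbalance <- imb[imb > 1L]
  out
}

#' Split a trial table into its two halves
#'
#' @param table a `trial_table`.
#' @param assignment a `split_assignment` for that table.
#' @return list of two `trial_table`s.
#' @export
split_halves <- function(table, assignment) {
  stopifnot(inherits(assignment, "split_assignment"),
            length(assignment$half) == nrow(table))
  lapply(1:2, function(h) {
    out <- table[assignment$half == h, , drop = FALSE]
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' Monte Carlo resampling of a trial table
#'
#' Draws two datasets from the table *with replacement*, each matching
#' every participant's original trial count. Because the same trial can
#' enter both resamples, correlating scores from the two resamples
#' overstates reliability; the estimator built on this scheme
#' ([monte_carlo_splithalf()]) is included to demonstrate that bias.
#'
#' @param table a `trial_table`.
#' @return list of two resampled `trial_table`s.
#' @export
monte_carlo_resample <- function(table) {
  by_part <- split(seq_len(nrow(table)), table$participant)
  draw <- function() {
    idx <- unlist(lapply(by_part, function(p) {
      p[sample.int(length(p), length(p), replace = TRUE)]
    }), use.names = FALSE)
    out <- table[idx, , drop = FALSE]
    class(out) <- c("trial_table", "data.frame")
    out
  }
  list(draw(), draw())
}
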