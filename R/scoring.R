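#' Define how participant scores are formed
#'
#' A score specification states how a participant's trials are collapsed
#' into a single number: the within-cell aggregator, which condition
#' factors are contrasted (0 factors gives a plain aggregate, 1 a single
#' difference, 2 a double difference), and the subtraction orientation,
#' i.e. which level of each factor is the minuend. With the
#' approach-avoidance convention `avoid - approach`, a positive bias
#' means faster approach than avoidance.
#'
#' The `dscore` aggregator computes the mean-based score and divides it
#' by the participant's overall RT standard deviation (unbiased, n - 1
#' denominator) across all trials entering the score, making the score
#' unitless and invariant to a participant-specific rescaling of RTs.
#' With 0 contrast factors this reduces to mean/SD.
#'
#' @param aggregator one of `"mean"`, `"median"`, `"dscore"`.
#' @param contrast character vector (length 0-2) of canonical factor
#'   names to contrast, in order: subset of `c("factor1", "factor2")`.
#' @param orientation named character vector giving, for each contrast
#'   factor, the level used as minuend. Unnamed factors default to the
#'   alphabetically last observed level (deterministic; for
#'   "approach"/"avoid" this is "avoid", reproducing the usual sign
#'   convention). State it explicitly for anything that matters.
#' @return an object of class `score_spec`.
#' @examples
#' # double-difference of means: (avoid-approach)_target - (avoid-approach)_control
#' score_spec("mean", contrast = c("factor1", "factor2"),
#'            orientation = c(factor1 = "target", factor2 = "avoid"))
#' @export
score_spec <- function(aggregator = c("mean", "median", "dscore"),
                       contrast = character(0), orientation = NULL) {
  aggregator <- match.arg(aggregator)
  contrast <- as.character(contrast)
  if (length(contrast) > 2L ||
      !all(contrast %in% c("factor1", "factor2"))) {
    stop("contrast must name at most two of 'factor1', 'factor2'",
         call. = FALSE)
  }
  if (anyDuplicated(contrast)) stop("duplicated contrast factor")
  if (!is.null(orientation)) {
    if (is.null(names(orientation)) ||
        !all(names(orientation) %in% contrast)) {
      stop("orientation must be named by contrast factors", call. = FALSE)
    }
  }
  structure(list(aggregator = aggregator, contrast = contrast,
                 orientation = orientation),
            class = "score_spec")
}

# Resolve, per contrast factor, the minuend level against the data.
resolve_orientation <- function(table, spec) {
  out <- character(0)
  for (fc in spec$contrast) {
    lv <- sort(unique(table[[fc]]))
    if (length(lv) != 2L || anyNA(lv)) {
      stop("contrast factor ", fc, " must have exactly two levels",
           call. = FALSE)
    }
    minuend <- spec$orientation[[fc]]
    if (is.null(minuend)) minuend <- lv[2L]
    if (!minuend %in% lv) {
      stop("orientation level '", minuend, "' not a level of ", fc,
           call. = FALSE)
    }
    out[fc] <- minuend
  }
  out
}

# Number of condition cells a spec requires (2^number of contrasts).
required_cells <- function(table, spec) {
  2L^length(spec$contrast)
}

# 1-based condition-cell index per trial, plus the contrast weight of
# each cell. Cell 1 is the all-minuend cell; weights multiply to give
# score = sum_c w_c * aggregate(cell c).
cell_index <- function(table, spec, orientation = NULL) {
  if (length(spec$contrast) == 0L) return(rep(1L, nrow(table)))
  if (is.null(orientation)) orientation <- resolve_orientation(table, spec)
  idx <- rep(1L, nrow(table))
  for (i in seq_along(spec$contrast)) {
    fc <- spec$contrast[i]
    bit <- as.integer(table[[fc]] != orientation[[fc]])
    idx <- idx + bit * 2L^(i - 1L)
  }
  idx
}

cell_weights <- function(spec) {
  k <- length(spec$contrast)
  if (k == 0L) return(1)
  signs <- expand.grid(rep(list(c(1, -1)), k))
  apply(signs, 1L, prod)
}

#' Aggregate the RTs of one cell
#'
#' @param x numeric vector of RTs.
#' @param aggregator `"mean"` or `"median"` (the `dscore` normalization
#'   applies to the whole score, not a single cell). The median of an
#'   even count is the midpoint of the two central values.
#' @return the aggregate, or `NA_real_` for an empty cell (the
#'   undefined-cell signal; it propagates to an undefined score).
#' @export
aggregate_cell <- function(x, aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  if (length(x) == 0L) return(NA_real_)
  if (aggregator == "mean") mean(x) else stats::median(x)
}

#' Score a single participant's trials
#'
#' Computes the participant's score under a [score_spec()]: per-cell
#' aggregates combined with the contrast weights, then (for `dscore`)
#' divided by the participant's overall RT SD. Any empty required cell
#' makes the score undefined (`NA`).
#'
#' @param trials a `trial_table` (or data.frame with canonical columns)
#'   holding one participant's trials.
#' @param spec a [score_spec()].
#' @param orientation optional pre-resolved orientation (internal use,
#'   so that orientation does not silently change across data subsets).
#' @return scalar score, `NA` if undefined.
#' @export
participant_score <- function(trials, spec, orientation = NULL) {
  k <- required_cells(trials, spec)
  idx <- cell_index(trials, spec, orientation)
  w <- cell_weights(spec)
  base_agg <- if (spec$aggregator == "dscore") "mean" else spec$aggregator
  agg <- vapply(seq_len(k), function(c) {
    aggregate_cell(trials$rt[idx == c], base_agg)
  }, numeric(1))
  if (anyNA(agg)) return(NA_real_)
  score <- sum(w * agg)
  if (spec$aggregator == "dscore") {
    if (nrow(trials) < 2L) return(NA_real_)
    s <- stats::sd(trials$rt)
    if (s == 0) return(NA_real_)
    score <- score / s
  }
  score
}

#' Score every participant in a trial table
#'
#' @param table a `trial_table`.
#' @param spec a [score_spec()].
#' @return data.frame with columns `participant`, `score` (`NA` when a
#'   required cell is empty) and `defined`.
#' @export
score_vector <- function(table, spec) {
  orientation <- if (length(spec$contrast)) resolve_orientation(table, spec)
  parts <- unique(table$participant)
  rows <- split(seq_len(nrow(table)), table$participant)
  score <- vapply(parts, function(p) {
    participant_score(table[rows[[p]], , drop = FALSE], spec, orientation)
  }, numeric(1))
  data.frame(participant = parts, score = unname(score),
             defined = !is.na(score), row.names = NULL,
             stringsAsFactors = FALSE)
}
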