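#' Split-half reliability from a long-format data frame
#'
#' Convenience front end mirroring the call style of the reliability
#' packages this one follows: point at a long-format data frame, name
#' the subject, RT, stratification and difference-score columns, and
#' get the stratified permutation-based split-half reliability with its
#' 95% CI.
#'
#' @param data long-format data.frame, one row per trial.
#' @param subjvar name of the participant column.
#' @param aggvar name of the RT column.
#' @param stratvar optional name of the stimulus column; when given,
#'   splits are stratified by stimulus within condition within
#'   participant.
#' @param diffvars character vector (length 0-2) of condition columns
#'   to subtract over: one gives a single difference, two a double
#'   difference.
#' @param splits number of random splits (default 6000, a safe
#'   general-purpose count).
#' @param aggfunc `"mean"`, `"median"` or `"dscore"` within-cell
#'   aggregation.
#' @param orientation optional named character vector (names from
#'   `diffvars`) giving the minuend level of each difference; defaults
#'   to the alphabetically last level.
#' @param sb Spearman-Brown handling: `"mirrored"` (recommended),
#'   `"standard"`, or `"nullify"` (zero negative aggregate before the
#'   standard formula).
#' @param aggregator correlation aggregation: `"op5"` (default),
#'   `"mean"` or `"fisher"`.
#' @param seed optional integer seed set before splitting.
#' @return a `reliability_estimate`; `print()` shows the point estimate
#'   and CI, `plot()` the split-correlation distribution.
#' @examples
#' params <- sim_params(n_participants = 20, n_reps = 4)
#' d <- generate_dataset(params)
#' splithalf_reliability(d, "participant", "rt", stratvar = "stimulus",
#'                       diffvars = c("factor1", "factor2"),
#'                       splits = 200, seed = 1)
#' @export
splithalf_reliability <- function(data, subjvar, aggvar, stratvar = NULL,
                                  diffvars = NULL, splits = 6000,
                                  aggfunc = c("mean", "median", "dscore"),
                                  orientation = NULL,
                                  sb = c("mirrored", "standard",
                                         "nullify"),
                                  aggregator = c("op5", "mean", "fisher"),
                                  seed = NULL) {
  aggfunc <- match.arg(aggfunc)
  sb <- match.arg(sb)
  aggregator <- match.arg(aggregator)
  if (length(diffvars) > 2L) stop("at most two difference columns",
                                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  table <- trial_table(data, participant = subjvar, rt = aggvar,
                       stimulus = stratvar,
                       factor1 = if (length(diffvars) >= 1) diffvars[1],
                       factor2 = if (length(diffvars) >= 2) diffvars[2])
  contrast <- c("factor1", "factor2")[seq_along(diffvars)]
  ors <- NULL
  if (!is.null(orientation)) {
    ors <- stats::setNames(unname(orientation),
                           contrast[match(names(orientation), diffvars)])
  }
  spec <- score_spec(aggfunc, contrast = contrast, orientation = ors)
  policy <- switch(sb,
                   mirrored = sb_policy("mirrored", "none"),
                   standard = sb_policy("standard", "none"),
                   nullify = sb_policy("standard", "nullify"))
  permutation_splithalf(table, spec, n_splits = splits,
                        stratify = !is.null(stratvar), policy = policy,
                        aggregator = aggregator)
}
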