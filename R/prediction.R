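#' Predicted test-retest correlation from two reliabilities
#'
#' The attenuation-style prediction
#' \eqn{\sqrt{|r_1| |r_2|} \times \min(\mathrm{sgn}\, r_1,
#' \mathrm{sgn}\, r_2)}, defined only when the two reliabilities agree
#' in sign; with one positive and one negative estimate the sign of the
#' prediction is undefined and `NA` is returned (such records are
#' excluded from accuracy metrics and counted).
#'
#' @param r1,r2 session reliabilities (vectorized). Values outside
#'   [-1, 1] are accepted: covariance-based estimators such as the
#'   alpha pipeline can produce reliabilities far below -1, and their
#'   (equally out-of-range) predictions are part of what the accuracy
#'   harness measures.
#' @return predicted correlation(s), `NA` where undefined.
#' @examples
#' predicted_retest(0.9, 0.4)   # 0.6
#' predicted_retest(-0.2, 0.3)  # NA: signs disagree
#' @export
predicted_retest <- function(r1, r2) {
  out <- sqrt(abs(r1) * abs(r2)) * pmin(sign(r1), sign(r2))
  out[sign(r1) != sign(r2)] <- NA_real_
  out
}

#' Confidence interval of a predicted test-retest correlation
#'
#' Endpoint-wise arithmetic mean of the two sessions' reliability CIs.
#'
#' @param ci1,ci2 length-2 numeric vectors `c(low, high)`, or `NULL`.
#' @return length-2 numeric vector, or `NULL` if either CI is absent.
#' @export
prediction_ci <- function(ci1, ci2) {
  if (is.null(ci1) || is.null(ci2)) return(NULL)
  (ci1 + ci2) / 2
}

#' Prediction accuracy metrics
#'
#' Mean deviation (average signed error, negative meaning systematic
#' underestimation) and root mean square error of predicted versus
#' observed test-retest correlations. Undefined predictions are excluded
#' and counted.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return list with `mean_deviation`, `rmse`, `n`, `n_undefined`.
#' @export
accuracy_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  keep <- !is.na(predicted) & !is.na(observed)
  if (!any(keep)) stop("no defined predictions", call. = FALSE)
  err <- predicted[keep] - observed[keep]
  list(mean_deviation = mean(err),
       rmse = sqrt(mean(err^2)),
       n = sum(keep),
       n_undefined = sum(is.na(predicted)))
}

#' Fraction of observations outside their confidence intervals
#'
#' Proportion of records whose observed correlation lies strictly
#' outside [low, high]; boundary values count as inside (the
#' conservative convention). Records with an undefined prediction or CI
#' are excluded.
#'
#' @param observed observed test-retest correlations.
#' @param low,high CI endpoints (same length).
#' @return list with `outside` (the fraction), `n` records evaluated.
#' @export
ci_coverage <- function(observed, low, high) {
  keep <- !is.na(observed) & !is.na(low) & !is.na(high)
  out <- observed[keep] < low[keep] | observed[keep] > high[keep]
  list(outside = mean(out), n = sum(keep))
}
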