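#' Pearson correlation of two score vectors
#'
#' Correlates the participants' scores from one half with their scores
#' from the other half, over the participants whose score is defined in
#' both. Degenerate inputs (fewer than 4 joint participants, or zero
#' variance in either half) yield `NA_real_`, the undefined-correlation
#' signal; undefined correlations are recorded and dropped from
#' aggregation rather than propagated as errors.
#'
#' @param x,y either numeric vectors, or two data.frames as returned by
#'   [score_vector()] (matched by participant).
#' @return correlation, or `NA_real_` when undefined; the number of
#'   jointly defined participants is attached as `attr(, "n")`.
#' @export
pearson <- function(x, y) {
  if (is.data.frame(x)) {
    m <- merge(x, y, by = "participant")
    x <- m$score.x
    y <- m$score.y
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  r <- if (n < 4L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    NA_real_
  } else {
    stats::cor(x, y)
  }
  attr(r, "n") <- n
  r
}

# Five-term Olkin-Pratt correction factor: multiplies r so that the
# average over many correlations is approximately unbiased for the
# population correlation at sample size N. Gamma ratios are evaluated in
# log space so large N cannot overflow.
op5_factor <- function(r, n) {
  n <- rep_len(n, length(r))
  z <- 1 - r^2
  out <- rep(1, length(r))
  for (k in 1:5) {
    ratio <- exp(2 * (lgamma(k + 0.5) - lgamma(0.5)) +
                   lgamma((n - 2) / 2) - lgamma((n - 2) / 2 + k))
    out <- out + ratio * z^k / factorial(k)
  }
  out
}

#' Olkin-Pratt (OP5) mean of correlations
#'
#' Averages split-half correlations after multiplying each by the
#' five-term Olkin-Pratt debiasing factor
#' \deqn{r_i \left[1 + \sum_{k=1}^{5}
#'   \frac{\Gamma(\tfrac12+k)^2\,\Gamma(\tfrac{N-2}{2})}
#'        {\Gamma(\tfrac12)^2\,\Gamma(\tfrac{N-2}{2}+k)}
#'   \frac{(1-r_i^2)^k}{k!}\right]}
#' which counteracts the towards-zero bias of a simple mean of Pearson
#' correlations. The result is clamped to [-1, 1], since the truncated
#' five-term correction can marginally overshoot for extreme r at tiny
#' N.
#'
#' @param r numeric vector of correlations in [-1, 1]; `NA`s (undefined
#'   split correlations) are dropped with their count recorded in
#'   `attr(, "n_dropped")`.
#' @param n sample size(s) N behind each correlation (number of
#'   participant pairs); scalar or vector along `r`. All must be >= 5.
#' @return the aggregated correlation.
#' @export
op5_mean <- function(r, n) {
  if (length(r) == 0L) stop("empty correlation sample", call. = FALSE)
  n <- rep_len(n, length(r))
  keep <- !is.na(r)
  n_dropped <- sum(!keep)
  r <- r[keep]
  n <- n[keep]
  if (length(r) == 0L) stop("all correlations undefined", call. = FALSE)
  if (any(n < 5L)) stop("op5_mean requires N >= 5", call. = FALSE)
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]",
                            call. = FALSE)
  out <- mean(r * op5_factor(r, n))
  out <- min(1, max(-1, out))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Simple mean of correlations
#'
#' The arithmetic mean, which is biased towards zero; kept as a
#' comparison aggregator.
#'
#' @param r numeric vector of correlations; `NA`s dropped.
#' @param n ignored (kept for a common aggregator interface).
#' @export
simple_mean <- function(r, n = NULL) {
  if (length(r) == 0L) stop("empty correlation sample", call. = FALSE)
  mean(r, na.rm = TRUE)
}

#' Fisher-z mean of correlations
#'
#' tanh of the mean of atanh(r): counteracts the towards-zero bias of
#' the simple mean but overshoots away from zero.
#'
#' @param r numeric vector of correlations with |r| < 1; `NA`s dropped.
#' @param n ignored (common aggregator interface).
#' @export
fisher_z_mean <- function(r, n = NULL) {
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("empty correlation sample", call. = FALSE)
  if (any(abs(r) >= 1)) {
    stop("fisher_z_mean undefined for |r| = 1 (infinite z)", call. = FALSE)
  }
  tanh(mean(atanh(r)))
}

cor_aggregator <- function(method = c("op5", "mean", "fisher")) {
  switch(match.arg(method),
         op5 = op5_mean,
         mean = simple_mean,
         fisher = fisher_z_mean)
}
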