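# Independent oracles and small fixture builders shared across tests.

# Exact closed form of the five-term Olkin-Pratt correction, reduced to
# rational gamma identities: (Gamma(1/2+k)/Gamma(1/2))^2 =
# ((2k)!/(4^k k!))^2 and Gamma(x)/Gamma(x+k) = 1/prod_{j<k}(x+j).
# Shares no code with op5_mean() / op5_factor().
op5_oracle <- function(r, n) {
  n <- rep_len(n, length(r))
  vals <- vapply(seq_along(r), function(i) {
    corr <- 1
    for (k in 1:5) {
      g <- (factorial(2 * k) / (4^k * factorial(k)))^2
      den <- prod((n[i] - 2) / 2 + 0:(k - 1))
      corr <- corr + g / den * (1 - r[i]^2)^k / factorial(k)
    }
    r[i] * corr
  }, numeric(1))
  mean(vals)
}

# Small AAT-style fixture: full 2x2 design, `reps` trials per cell,
# deterministic RTs unless given.
toy_table <- function(n_participants = 6, reps = 4, rt = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- expand.grid(rep = seq_len(reps),
                   direction = c("avoid", "approach"),
                   stimulus = c("t1", "t2", "c1", "c2"),
                   participant = paste0("p", seq_len(n_participants)),
                   stringsAsFactors = FALSE)
  d$category <- ifelse(startsWith(d$stimulus, "t"), "target", "control")
  d$rt <- if (is.null(rt)) 500 + stats::rnorm(nrow(d), sd = 40) else rt
  trial_table(d, participant = "participant", rt = "rt",
              stimulus = "stimulus", factor1 = "category",
              factor2 = "direction")
}

dd_spec <- function(aggregator = "mean") {
  score_spec(aggregator, contrast = c("factor1", "factor2"),
             orientation = c(factor1 = "target", factor2 = "avoid"))
}
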