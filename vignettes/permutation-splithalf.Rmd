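---
title: "Estimating reaction-time task reliability with permutation-based split halves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating reaction-time task reliability with permutation-based split halves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permsplit)
```

## The problem

Scores from trial-level reaction-time (RT) paradigms -- the
approach-avoidance task, the implicit association task, dot-probe
tasks -- are usually contrasts of aggregated RTs: a participant's mean
avoid RT minus mean approach RT for one stimulus category, often
further differenced against a control category. Questionnaire-style
internal-consistency coefficients fit this structure badly: trials
cannot be matched one-to-one across participants, outlier and error
trials are removed so trial counts differ, and the score of interest is
a difference, not a sum. The common workaround -- averaging each
stimulus's trials into a subscore and feeding the subscores to
Cronbach's alpha -- discards the trial-level error entirely and weights
trials unequally whenever counts are unbalanced.

`permsplit` implements the family of single-session reliability
estimators appropriate to such data, centred on the **stratified
permutation-based split-half**: correlate participants' scores from two
random halves of the trials, repeat over thousands of random splits,
aggregate the correlations, and correct the aggregate for test length.
The alternatives (subscore alpha combined over categories with Lord's
difference-score formula, odd-even and first-second single splits, and
the with-replacement Monte Carlo split-half) are included so their
biases can be demonstrated rather than merely asserted.

## The estimator

For one random split, participants' scores are computed per half under
a *score specification*: a within-cell aggregator (mean, median, or a
D-score -- the mean-based score divided by the participant's overall RT
SD, unbiased $n-1$ denominator), up to two binary contrast factors, and
an orientation saying which level is the minuend. The two half scores
are Pearson-correlated over participants; participants with an empty
required cell in a half are dropped from that split only.

**Splitting.** Halves must be near-replications of each other, so
random splits are balanced hierarchically (participant > condition >
stimulus) by pair splitting: trials in each bottom stratum are randomly
paired, each pair contributes one trial to each half, odd leftovers are
pooled with sibling strata's leftovers at the parent level and
pair-split there, and a final odd trial per participant is assigned by
a coin flip. Every stratum therefore differs by at most one trial
between halves. Pair membership is re-randomized on every split;
freezing the pairs would artificially shrink the permutation variance.
The leftover rule (pair-splitting pooled leftovers rather than flipping
each independently) keeps the halves' total sizes near-equal by
construction.

**Aggregation.** Simple means of correlations are biased towards zero
and Fisher-z means away from it, so the default aggregator is the
five-term Olkin-Pratt estimator
$$\bar r_{OP5} = \frac1n \sum_i r_i\!\left[1 + \sum_{k=1}^{5}
\frac{\Gamma(\tfrac12+k)^2\,\Gamma(\tfrac{N-2}{2})}
     {\Gamma(\tfrac12)^2\,\Gamma(\tfrac{N-2}{2}+k)}
\frac{(1-r_i^2)^k}{k!}\right],$$
with the gamma ratios evaluated in log space (large $N$ would overflow
the gammas themselves) and the result clamped to $[-1, 1]$ because the
truncated correction can overshoot marginally for extreme $r$ at tiny
$N$. Undefined split correlations (zero-variance halves, fewer than
four joint participants) are dropped with a recorded count -- the only
sign-neutral treatment. Each $r_i$ is corrected with its own $N_i$, so
splits that lose participants are handled exactly.

**Length correction.** A split-half correlation reflects half-length
tests. The standard Spearman-Brown formula $kr/(1+(k-1)r)$ explodes for
negative $r$ (pole at $r = -1/(k-1)$); the *mirrored* variant
$kr/(1+(k-1)|r|)$ applies the same magnitude of change on both sides of
zero. The default policy applies the mirrored formula with $k = 2$
*after* aggregation and never nullifies; nullification (zeroing
negative correlations) and per-split correction remain available
because the accuracy harness compares all of them -- nullification
truncates the lower tail, which is exactly what ruins the CIs built
from the split-correlation quantiles.

**Confidence intervals.** The 95% CI is the 2.5% and 97.5% empirical
quantiles (linear interpolation; the convention is fixed only for
bit-reproducibility) of the raw split correlations, each passed through
the same Spearman-Brown step as the point estimate. These intervals
describe the dispersion of split correlations; the CI-calibration
harness (below) measures how well they bound actual test-retest error.

**Predicted test-retest correlation.** Two session reliabilities
$r_1, r_2$ predict a test-retest correlation
$\sqrt{|r_1||r_2|}\cdot\min(\operatorname{sgn} r_1,
\operatorname{sgn} r_2)$ when the signs agree; with discordant signs
the prediction's sign is undefined and the record is excluded (and
counted). Estimates outside $[-1,1]$ -- which the alpha pipeline
genuinely produces -- propagate, since their badness is part of what
the harness measures. The prediction's CI is the endpoint-wise mean of
the two sessions' CIs, with boundary observations counted as covered
(the conservative convention; neither choice is dictated by the
procedure itself).

## The synthetic-data generator

`sim_params()` / `generate_dataset()` produce trial tables from a
hierarchical Gaussian model: participant $i$, category $c$, stimulus
$t$ has a latent bias $b_{ic} + d_{ict}$ with $b_{ic} \sim N(0, u)$
(correlated $\rho$ across the two categories) and
$d_{ict} \sim N(0, q)$; each trial adds $\pm\tfrac12$ of the latent
bias by response direction (avoid $+$, approach $-$) plus $N(0, s^2)$
noise. Two knobs control the latent structure:

* `bias_variance` $v$ is the variance of the *category-level* bias
  score, $u + q/p = v$ for $p$ stimuli. Holding the category score's
  variance fixed -- rather than the per-stimulus subscore variance --
  is what lets the next knob move internal consistency without moving
  the score's actual reliability.
* `alpha_target` sets the Cronbach's alpha of the latent stimulus
  subscores through the parallel-items identity
  $\alpha = pw/(1+(p-1)w)$, $w = \alpha/(p-(p-1)\alpha)$, by splitting
  $v$ as $u = v_{sub}w$, $q = v_{sub}(1-w)$ with
  $v_{sub} = v/(w + (1-w)/p)$. Alpha is defined on the *latent*
  subscores so that $\alpha = 1$ remains attainable with nonzero trial
  noise.

The closed-form true reliability of the mean-based score follows from
the variance components (`true_reliability()`): e.g. for the double
difference $V_T = 2(v - \rho u)$ against error $4s^2/(pm)$ with $m$
trials per stimulus per direction. `calibrate_trial_sd()` inverts this
map by monotone root finding; a target of exactly 0 is realized by
$v = 0$, since no finite noise nulls a nonzero signal. Median and
D-score reliabilities have no closed form and are assessed by
simulation. The baseline RT is a constant 600 ms: every estimator here
is location-invariant, and the offset merely keeps generated RTs
positive. Presentation order is randomized per participant, so the
deterministic odd-even and first-second splits behave as they would in
a randomized session.

What the generator does *not* emulate: RT skew (no ex-Gaussian or
log-normal shape), autocorrelation and learning or fatigue trends,
error trials, and outliers. Passing tests therefore show that the
estimators behave correctly under an idealized exchangeable-trials
model; with autocorrelated real data all split-half coefficients may
be optimistic, and nothing here measures that.

A note on what "reliability 0" data look like: a single dataset's
permutation estimate at true reliability 0 is unbiased but not tightly
zero -- the empirical ratio of full-data score variance to split
deviation variance is frozen per dataset, leaving an estimate SD of
roughly 0.12 at 100 participants after length correction, however many
splits are averaged. Near-zero behaviour is therefore a property of
the mean across datasets, and the split-count study below treats
estimate dispersion accordingly.

## The three simulation harnesses

All harnesses are deterministic given a seed, and all default to
scaled-down problem sizes that finish on one CPU in minutes; the
full-scale settings from the accuracy literature are documented in
each argument and are long-running.

**Accuracy (`run_study1`).** Over a grid of preset subscore alpha
(0-1), bias-score variance (2-10), trial noise SD (2-10) and
intercategory correlation ($\mp$0.5, 0), datasets of 40 participants
and 256 trials are split into a test and a retest half sharing
participants, stimuli and conditions (presentation indices are
re-ranked within each half so it forms a session of its own); each
coefficient is computed on both halves and its predicted test-retest
correlation is compared with the observed between-half correlation.
The default scaled run uses 1,000 splits per estimate rather than
10,000. Two patterns matter: error ordering (stratified $\le$
unstratified $<$ odd-even $<$ alpha, with Monte Carlo positively
biased) and sensitivity (trial noise drives the real correlation and
the split-half estimates but barely moves alpha, while the preset
subscore alpha drives only the alpha estimate).

**Split count (`run_study2`).** How many random splits make the
reported coefficient stable? Per condition cell, replicate datasets
(default 30; full scale 150) each contribute a pool of split
correlations (default 10,000; full scale 20,000). Stability is
assessed on the estimate *as reported* -- the Olkin-Pratt aggregate of
a drawn subset passed through the mirrored Spearman-Brown formula --
against the same transform of the cell's pooled grand average, with
subsets drawn from the cell's pooled correlations so that they
experience the full split-correlation dispersion (about
$1/\sqrt{n-1}$ at true reliability 0), including the dataset-level
component. The reported figure is the first subset size (step 100)
above the largest size at which fewer than 95% of subset estimates
fall within 0.01 of the pool estimate. Assessing stability on the raw
correlation average instead would quarter the requirement (the
mirrored formula has slope 2 near zero), and conditioning subsets on a
single dataset would roughly halve it again; both alternatives
understate how far one lab's reported coefficient can sit from
another's. At true reliability 0 the requirement is maximal -- around
5,400 splits for median-based double-difference scores with 30
participants, falling to roughly 1,300 at 120 participants -- and it
declines with true reliability.

**CI calibration (`run_study3`).** Pairs of datasets sharing latent
structure (true replications, 256 trials each) are generated across
score types, true-score variability levels ($v = 0, 4, 10$ at trial SD
6 for none/medium/large) and sample sizes 30-240; each dataset gets a
stratified permutation estimate with CI (default 24 pairs per cell and
1,000 splits; full scale 200 and 10,000), and the observed
cross-dataset correlation is compared with the averaged CI. About 6.6%
of observed correlations fall outside the nominal 95% interval -- the
intervals are slightly anticonservative -- and the mean absolute
prediction error grows as samples shrink and reliability drops
(about 0.19 for 30 participants when the predicted correlation is
below 0.25).

For the three score types the harnesses use the design that makes each
score meaningful under this generator: two categories with directions
for double differences, one category with directions for single
differences, and one category without directions for plain averages
(a direction-balanced design would cancel a participant's average
bias, leaving an average score with no true variance by construction).

## Other design choices

* **Exclusions before splitting.** `exclude_trials()` runs on the full
  table; whether preprocessing should instead happen after splitting
  (to avoid leaking full-data statistics into both halves) is an open
  methodological question, so the package does the conventional thing
  and documents the caveat.
* **Odd-even parity uses the original presentation index**, not the
  post-exclusion rank, preserving the session's alternation structure
  after trial removal.
* **Alpha pipeline is deliberately rigid**: it errors on any empty
  participant-by-stimulus cell and warns on unbalanced trial counts,
  because silently accommodating either is precisely how the
  coefficient gets misused on RT data.
* **Variance denominators** are sample ($n-1$) throughout; alpha's
  ratio is invariant to the choice, which is fixed only for
  bit-reproducibility.
* **Reproducibility.** All randomness flows from R's RNG. The compiled
  split kernel seeds a local xoshiro256++ generator from R's RNG at
  entry, so `set.seed()` fixes every result while the hot loop stays
  cheap; the pure-R splitting functions are the reference
  implementation and the test suite checks the two paths agree
  distributionally.

## Limitations

Autocorrelated and drifting RTs violate the exchangeability the splits
rely on and are not modelled. The alpha pipeline supports at most one
within-stimulus contrast factor beyond the category factor. The
analytic (non-permutation) CI for the predicted test-retest
correlation is not implemented: no satisfactory closed form is
established, and the permutation quantiles outperform the analytic
intervals that have been tried. McDonald's omega and accuracy-based
(error-rate) scores are out of scope.
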