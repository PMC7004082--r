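---
title: "Methods: movement states, site fidelity and personality-dependent repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement states, site fidelity and personality-dependent repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldforage)
```

`boldforage` analyses whether a personality axis (boldness, scored at the
nest) predicts how spatially specialized a colonial central-place forager
is at sea. The pipeline has five statistical stages, each exposed as
plain functions: trip processing, a movement hidden Markov model (HMM),
a randomization-based site-fidelity index, boldness scoring with
repeatability estimation, and group-level repeatability comparison. A
synthetic-data generator with fully known ground truth backs every stage
with parameter-recovery tests.

## Trip processing

GPS fixes are segmented into foraging trips as maximal runs of
consecutive fixes farther than `buffer_m` (default 300 m) from the
colony whose first-to-last elapsed time exceeds `min_trip_hr` (default
1 hr). The duration rule is read as *first-to-last outside fix*, not
accumulated time outside the buffer; the two differ only for tracks that
re-enter the buffer mid-run, which segmentation treats as separate runs
anyway. Trips touching the start or end of a recording without returning
inside the buffer are flagged incomplete, the operational proxy for
logger failure. Incomplete trips are excluded from distance and duration
summaries; their maximum range is kept only when the final recorded fix
lies within 75% of the trip's maximum colony distance.

Tracks are linearly interpolated in time to a regular grid (10 min for
incubation, 2 min for chick rearing, matching the emulated duty cycles).
Distances are haversine on a sphere of radius 6,371 km; at the < 300 km
ranges involved, the spherical error is negligible relative to GPS
noise. Turning angles are signed changes in initial bearing,
counter-clockwise positive, wrapped to (-pi, pi].

## The movement HMM

Each interpolated step contributes a step length (gamma distributed,
parameterized by mean and standard deviation) and a turning angle (von
Mises with mean direction mu and concentration kappa), with hidden
states following a first-order Markov chain. The forward recursion uses
per-step scaling and is implemented in C++ for long pooled tracks;
trips are independent chains sharing parameters. Fitting maximizes the
pooled log likelihood by BFGS on a working scale (log for positive
parameters, multinomial logit for the initial distribution and
transition rows), with jittered multi-starts (default 5) and the best
solution retained. Exhaustive path enumeration at short series lengths
is used as the test oracle for both the forward likelihood and the
Viterbi decoder.

Numerical choices:

* Steps are floored at 0.1 m before gamma evaluation, which keeps the
  likelihood finite for stationary fixes without a zero-inflation
  component.
* The first turning angle of every trip is treated as missing and
  contributes step density only.
* Default starting values place the state step means at spread
  quantiles (15%-85%) of the observed step lengths with sd equal to the
  mean, weakly concentrated angles, and a sticky (0.9 diagonal)
  transition matrix. Data-driven starts were preferred over fixed
  metre-scale constants because the appropriate scale varies by an
  order of magnitude with the fix interval; explicit starting values
  can always be supplied.
* The state count is chosen by AIC (`select_n_states`), with
  `k = (n - 1) + n(n - 1) + 4n` free parameters.

After fitting, states are labelled automatically: *travelling* is the
state with the largest mean step; *foraging* (area-restricted search)
is, among the rest, the state whose angle distribution is least
concentrated at zero, preferring small steps; the remainder is
*resting*. Runs of consecutive foraging-state fixes become foraging
sites, summarized by the arithmetic mean of member coordinates (the
centre rule is a package choice; a medoid would differ only for very
elongated runs). Fix states come from the outgoing step, with the final
fix inheriting the last step's state. Trips whose decoded path contains
no foraging fix are dropped as showing no area-restricted search — an
operational replacement for visual screening.

## Site-fidelity index

With every foraging site in turn as the focal site, the randomization
pairs it with one uniformly drawn site of the same bird from a
different trip, and one uniformly drawn site from each other bird of
the same colony (single-trip birds act as donors only). Each
between-individual pair yields a Bernoulli outcome: 1 when the bird's
own paired site is strictly closer to the focal site than the other
bird's site (ties score 0; they have measure zero on real coordinates).
Pooled outcomes are modelled per iteration by a binomial GLM with bird
identity as a factor (no global intercept) plus the centred absolute
time difference in days between the focal and within-individual sites.
The time difference is attached to the within pair — the index's
definition leaves this open; the within pair is the one whose temporal
proximity modulates the fidelity signal. Each bird's fidelity is the
inverse logit of its coefficient, i.e. the estimate at the mean time
difference, with delta-method standard errors; this keeps estimates on
the proportion scale and comparable across birds. Complete separation
(all outcomes 0 or 1 for a bird) is clamped to `1/(2m)` from the
boundary and flagged rather than penalized, keeping the estimator
transparent. The default 1,000 iterations under one seeded RNG stream
make runs bit-reproducible.

Across iterations, the boldness model `fidelity ~ boldness + sex +
colony + date` is refitted per iteration; the two-way interactions with
boldness are screened on the iteration-mean estimates and dropped when
non-significant. Two intervals are reported for each coefficient: the
2.5%/97.5% quantiles across iterations, which quantify only the
randomization (pairing) uncertainty and are typically narrow, and a
confidence interval combining the mean estimate with the mean model
standard error, which carries the sampling uncertainty and is the one
to use for inference (the null-calibration tests use it).

## Boldness scoring and repeatability

The five behaviour-state proportions of the 60-s novel-object test are
collapsed by PCA on the covariance (unscaled) matrix of the centred
proportions. Because each row sums to one, the fifth component is the
simplex normal direction: zero variance and loadings of `1/sqrt(5)`
(0.447) in magnitude — a built-in analytic check — and four components
carry all variance. Covariance PCA (not correlation) is what makes this
structure exact, which is also the reason it was chosen. PC1 is
sign-oriented so sitting loads positively: high scores are bold
(stayed seated), low scores shy (left the ledge).

Adjusted repeatability of PC1 fits a linear mixed model with test date,
stage, observer and test number as fixed effects and a random intercept
per bird; `R = sigma2_bird / (sigma2_bird + sigma2_res)`. The p value
is a boundary-corrected likelihood-ratio test (50:50
chi-square(0)/chi-square(1) mixture). Confidence intervals come from a
seeded parametric bootstrap. The default interval is the *basic*
(reflected) bootstrap, clamped to [0, 1]: the variance-ratio estimator
is biased toward zero in small samples, and the percentile interval
inherits that bias twice while the basic interval cancels it. In a
20-seed calibration at 100 birds x 3 tests with true R = 0.7, basic
intervals covered the truth in 20/20 runs against 17/20 for percentile
and bias-corrected percentile. Percentile intervals remain available
via `ci_type = "perc"`.

One boldness value per bird comes from OLS with bird identity as a
factor (no intercept) plus centred covariates; birds tested once still
get estimates. The median split assigns birds strictly above the median
to *bold* and the rest — including any bird exactly at the median — to
*shy*, an explicit tie rule the split needs to be reproducible.

## Group repeatability and spatial models

Trip metrics (distance, duration, maximum range; log10 transformed) are
analysed per bold/shy group with the same variance-ratio estimator and
bootstrap, one row per trip. Groups are compared by the 84%
confidence-interval overlap rule: disjoint 84% intervals approximate a
z test at the 0.05 level, and `ci_overlap_calibration()` reproduces the
expected ~0.047 type-I rate by Monte-Carlo. A shared endpoint counts as
overlap.

Spatial partitioning is tested by linear mixed models of site latitude
(log2) and longitude (square root) with random intercepts for trip
nested within bird, REML estimates, and per-term likelihood-ratio tests
on full-ML refits. The square-root transform needs positive longitudes
(true east of Greenwich); negative values get an automatic +360 offset,
reported in the result. When each bird holds a single site the
hierarchy is degenerate and the model intentionally reduces to OLS.

## The synthetic-data generator

`sim_config()` realizes a multi-colony field season: per-bird latent
boldness (between-bird variance share set by `boldness_repeatability`,
default 0.678), per-bird site-fidelity level optionally coupled to
boldness on the logit scale, and a preferred foraging site per bird
drawn uniformly in a 5-60 km annulus — magnitudes matching published
kittiwake trip ranges. `simulate_tracks()` builds round trips on a
local tangent plane (east-west scaling at each point's own latitude,
near-isometric over the annulus): a travel out-leg steered at the trip
target with von Mises heading noise, a foraging/resting dwell whose
states follow the true HMM's restricted transition probabilities, and a
return leg; all step lengths are drawn from the true state
distributions. The trip target is the preferred site with probability
`fidelity_level`, else a fresh annulus draw. Steps whose length is
altered by a boundary (arrival truncation, colony-buffer push) or drawn
inside the arrival-censoring zone are flagged `NA` in the ground truth,
so emission-recovery tests use only unconditioned draws. The default
true HMM has step means 5,000 / 500 / 100 m per 10-min interval
(travel / forage / rest, about 30 / 3 / 0.6 km/h) with sticky
transitions.

`simulate_personality()` maps a latent bird value onto the five test
proportions through a fixed compositional gradient (sitting up,
off-ledge down); measurement noise spans only the directions orthogonal
to the simplex constraint and to that gradient, so the configured
repeatability carries onto PC1 undiluted and PC1 explains ~63% of the
variance. `simulate_sites()` skips movement entirely and plants
foraging sites directly — the fast surface for fidelity tests.

What the generator does *not* emulate: environmental covariates
(bathymetry, fronts, glacier edges), tides and wind, chick-age dynamics,
irregular fix loss, and spatial autocorrelation of site quality.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to every property of
field data.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, and two runs with the
same configuration are bit-identical. The test suite exercises the HMM
oracle at series length 8 (exhaustive enumeration over 3^8 paths),
parameter recovery at 20 tracks x 500 steps, the fidelity oracle on
toy colonies of up to 4 birds with 1,000 iterations, fidelity null and
sign recovery at 24 birds x 3 trips with 100 randomization iterations
over 20 seeded replicates, and group-repeatability contrasts at 30
birds x 4 trips per group with 150 bootstrap replicates — sizes chosen
to estimate each property with comfortable Monte-Carlo margin while
keeping a full run in a few minutes on one core. Field-study-scale
settings (1,000 iterations, 1,000 bootstrap replicates) are the package
defaults.

## Known limitations

* No zero-inflated step distribution and no covariates on transition
  probabilities; truly stationary loggers would need the former.
* The fidelity GLM treats outcomes within an iteration as independent,
  as the original index does; outcomes sharing a focal site are in fact
  correlated, which the across-iteration spread partially absorbs.
* Label assignment is rule-based; pathological fits (e.g. two states
  collapsing onto one mode) can mislabel, though multi-starts make this
  rare.
* The tangent-plane generator distorts diagonal distances by ~0.3% at
  the annulus edge; linear interpolation of latitude/longitude can
  exceed great-circle path length by sub-millimetre amounts.
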