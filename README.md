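# boldforage

Movement-ecology tooling for a question about animal personality and
foraging specialization: **are bolder individuals of a colonial
central-place forager more faithful to their foraging sites, and more
repeatable in their trips, than shy ones?** The package implements the
full analysis chain for GPS-tracked, personality-tested seabirds (the
motivating system is cliff-nesting kittiwakes commuting from Arctic
colonies), and a synthetic-data generator with known ground truth so
every stage can be validated by parameter recovery.

## What it computes

* **Trip processing** — foraging trips are maximal runs of fixes beyond
  a 300 m colony buffer lasting over 1 hr; tracks are linearly
  interpolated to a regular grid (10 min incubation, 2 min chick
  rearing); incomplete trips keep their maximum range only if the bird
  returned within 75% of its maximum colony distance.
* **Behavioural states** — a 3-state hidden Markov model on step
  lengths (gamma) and turning angles (von Mises),

  step_t | S_t = j  ~  Gamma(mean_j, sd_j),
  angle_t | S_t = j  ~  vonMises(mu_j, kappa_j),

  fitted by maximizing the scaled forward likelihood over pooled trips,
  decoded by Viterbi, states auto-labelled travelling / foraging
  (area-restricted search) / resting, and runs of foraging fixes
  aggregated into foraging sites.
* **Site fidelity** — the randomization similarity index: each focal
  site is paired with one same-bird site from another trip and one site
  from every other bird of the colony; the per-bird index is the
  (inverted) proportion of between-individual sites closer than the
  bird's own paired site, estimated per iteration by a binomial GLM with
  bird identity and the pair time difference, over 1,000 seeded
  iterations; fidelity is then modelled against boldness, sex, colony
  and date across iterations.
* **Boldness** — covariance PCA collapses the five novel-object
  behaviour proportions to PC1 (bold = kept sitting); adjusted
  repeatability R = s²_bird / (s²_bird + s²_res) from a mixed model with
  parametric-bootstrap CIs; per-bird scores from factor OLS; median
  split into bold/shy.
* **Repeatability comparison** — group-level repeatability of
  log10 trip distance, duration and maximum range, compared between
  bold and shy birds by the non-overlap of 84% confidence intervals
  (equivalent to a z test at the 0.05 level), plus linear mixed models
  of site latitude/longitude testing for spatial partitioning.

## Worked example

Simulate a two-colony study in which the true boldness-fidelity
coupling is positive (logit slope 2.5), the true boldness repeatability
is 0.678, and the true HMM has step means 5,000 / 500 / 100 m, then run
the full pipeline:

```r
library(boldforage)

cfg <- sim_config(n_colonies = 2, n_birds_per_colony = 12,
                  n_trips_per_bird = 3, boldness_fidelity_slope = 2.5,
                  rng_seed = 42)
fixes    <- simulate_tracks(cfg)
tests    <- simulate_personality(cfg, n_tests = 3)
colonies <- data.frame(colony_id = c("colony1", "colony2"),
                       lat = sapply(cfg$colony_coords, `[`, 1),
                       lon = sapply(cfg$colony_coords, `[`, 2))

report <- run_pipeline(fixes, colonies, tests,
                       bird_meta = cfg$birds[, c("bird_id", "sex")],
                       config = pipeline_config(fidelity_n_iter = 300,
                                                n_boot = 500, seed = 1))
```

Printed output (abridged):

```
$ counts: 4582 fixes, 24 birds, 72 trips kept, 229 foraging sites

       state step_mean_m step_sd_m kappa
1    resting          99        79  1.82
2   foraging         534       438  0.71
3 travelling        4722      2361  2.50

boldness PC1 repeatability: R = 0.712, 95% CI 0.593-0.945, p = 2.9e-09

              term    mean ci_lower ci_upper
2         boldness  1.1074    0.227    1.988
3             sexM -0.0315   -0.215    0.152
```

Reading it: the fitted HMM recovers the generating step means (5,000 /
500 / 100 m) within a few percent and labels the states correctly; the
boldness score's repeatability estimate (0.712) brackets the configured
0.678; and the boldness coefficient on site fidelity is positive with a
95% interval excluding zero — the planted positive coupling, recovered
end-to-end from raw synthetic GPS fixes.

`run_pipeline(..., output_dir = "out")` additionally writes
`trips.csv`, `states.csv`, `sites.csv`, `boldness.csv`, fidelity and
repeatability tables, and a machine-readable `report.json` with full
per-stage bookkeeping (trips dropped below the minimum duration, trips
dropped for showing no area-restricted search, and so on). A thin
command-line wrapper lives at `inst/cli/boldforage.R`
(`simulate` / `all` subcommands).

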