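---
title: "Methods: dyadic grooming rates under constrained randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic grooming rates under constrained randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxbond)
```

## The experimental design the package models

A colony of bats (or any individually recognisable animals) is assembled
from several distant capture sites, so that same-site pairs are familiar
and cross-site pairs are strangers. Observation runs through three
contiguous phases: a pre-treatment phase of free association, a short
forced-proximity phase in which the colony is partitioned into
site-complete triads (one bat per site, so every cage-mate pair is
previously unfamiliar) each housed in a small cage, and a post-treatment
phase of free association. Throughout, observers record directed
allogrooming bouts of at least 5 s with actor, receiver, date and
duration, plus the hours sampled per day.

The scientific question is causal: does the randomly assigned week of
proximity durably raise grooming in the treated (test) pairs relative to
the cross-site pairs that were not treated (controls)? Because the triad
assignment is the only randomised quantity, the natural null distribution
re-randomises exactly that assignment and nothing else.

## Rates and change scores

For a dyad in a phase, exposure `H` is the sum of sampled hours over the
sessions in which both members could interact: all sessions in the free
phases, and only the shared-cage sessions during forced proximity. With
directed totals `S_ab`, `S_ba` (seconds), the symmetric rate is
`x = (S_ab/H + S_ba/H)/2` and the *allogrooming log rate* is
`log(1 + x)`, which stabilises the strongly mean-dependent variance of
grooming durations. The per-dyad change score is
`delta = log rate(POST) - log rate(PRE)`.

Two conventions deserve note:

- "Seconds per hour averaged over hours" is computed as total seconds
  divided by total exposure hours (an exposure-weighted mean), not as the
  mean of per-hour values. The two coincide under equal sampling; the
  weighted form remains well defined for partial hours and unequal
  session lengths.
- A dyad with zero exposure in a phase has an *undefined* rate, reported
  as `NA`, never as 0. During forced proximity this is every non-cage
  pair; downstream statistics treat such rates as missing.

## Resampling inference

**Percentile bootstrap.** Class means of `delta` get percentile CIs from
resampling dyads with replacement (default 5000 resamples; empirical
quantiles via `stats::quantile`'s default interpolation). The resampling
unit matches what each mean averages over: dyads for class means, bats
for the per-bat partner-preference statistics. Dyads sharing an
individual are not independent; the bootstrap ignores this, which is a
known limitation of dyadic analyses of this kind and is flagged below.

**Constrained permutation test.** The statistic is
`mean(delta | TEST) - mean(delta | CONTROL)`. A null draw re-assigns
bats uniformly at random into new site-complete triads, relabels the
cross-site dyads accordingly (same-site dyads can never become
cage-mates, so familiar dyads never enter the statistic), and recomputes
the statistic on the *fixed* per-dyad changes. With `s` sites of `b`
bats the assignment space has `(b!)^(s-1)` elements (anchor one site,
permute the others) — 25,401,600 for the reference design — so the test
is Monte-Carlo by default with the add-one estimator
`p = (1 + #{null >= obs}) / (1 + n_perm)`, and switches automatically to
the exhaustive null when the space has at most `exhaustive_cap`
(default 100,000) elements, where `p = #{null >= obs} / N` including the
identity assignment. The test is one-sided (upper) by default because the
hypothesis is directional; `alternative` switches this. Comparisons use
a `1e-12` slack so that ties produced by exact arithmetic count as
exceedances rather than falling to floating-point noise.

**Partner-preference shift and trade-off.** Per bat and phase, the
proportion of its summed log rates that involves different-site partners;
the statistic is the mean over bats of the POST-minus-PRE change, with a
bat-level bootstrap CI. Summing *log-transformed* rates is the package's
primary definition; `use_log = FALSE` gives the raw-rate variant since
either reading is defensible. A bat with zero total rate in a phase has
an undefined proportion and is dropped with a warning. The trade-off
statistic is the Pearson correlation, across bats, of the mean change in
grooming to familiar vs to different-site partners (bootstrap CI over
bats, two-sided t-test p as a descriptive companion).

**Rank models on the test dyads.** OLS on midranks:
`rank(delta) ~ rank(forced rate)`, and
`rank(post) ~ rank(pre) + rank(forced)` with the forced coefficient of
interest. The permutation null shuffles the forced-phase values among
the dyads of each cage independently (each triad contributes three
within-cage dyads, so the exhaustive within-cage null has `6^c`
arrangements for `c` cages; 279,936 for 7 cages, above the default cap,
hence Monte-Carlo there too). Permuting values within cages leaves the
global midrank multiset unchanged, so the implementation permutes rank
entries directly and uses closed-form slope updates. One-sided upper
permutation p-values; the parametric OLS p is reported alongside as a
descriptive quantity. All-tied vectors raise errors rather than silently
returning `NaN`.

## The synthetic colony generator

`generate_colony()` emulates the design's statistical structure, not its
ethology. Per session and ordered co-observable pair the bout count is
Poisson with

```
log lambda = log(base_rate_lambda)
           + [same site]   * log(familiarity_multiplier)
           + u_pair                    # Normal(0, dyad_sd), shared by both directions
           + [test dyad, treated phase] * treatment_effect_delta
```

and bout durations are `5 + Exponential(bout_mean_s)` seconds. The
shared `u_pair` reflects that allogrooming is largely bidirectional; the
log-normal heterogeneity plus Poisson counting produces the overdispersed,
right-skewed dyadic rates such colonies show. The treatment shift applies
during the forced and post phases (`treatment_in_forced` switches the
former off; whether grooming is already elevated inside the cages is an
empirical question the analysis does not need to resolve).

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_sites`, `bats_per_site` | 3, 7 | the reference design: 21 bats, 7 triads, 21/126/63 test/control/familiar dyads |
| `phase_lengths_days` | 42, 7, 63 | six-week pre, one-week treatment, nine-week post |
| `hours_range` | 3–6 h/day, uniform integers | the design's daily sampling effort |
| `base_rate_lambda` | 0.15 bouts/h | with the duration mean this puts unfamiliar pairs near 15 s/h, where `log(1+x)` is effectively logarithmic, so an additive log-lambda shift is recovered on the log-rate scale nearly unbiasedly |
| `familiarity_multiplier` | 3 | familiar pairs groom several-fold more, giving clearly separated familiar/unfamiliar distributions |
| `dyad_sd` | 0.6 | log-rate spreads of roughly half a log-unit across dyads, a realistic heterogeneity for captive colonies |
| `bout_mean_s` | 95 s | mean bout 100 s; chosen jointly with `base_rate_lambda` so the rate regime above holds at a computable bout volume |
| `treatment_effect_delta` | 0.5 | a medium effect on the log scale; 0 gives the calibration null |

One master seed drives named substreams (design, hours, dyad effects,
counts, durations), each consumed in a fixed canonical order, so the same
configuration and seed reproduce a colony exactly, and
`generate_null_ensemble()` derives per-replicate seeds deterministically.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: no diurnal or seasonal rhythm, no social
drift in the controls (real colonies familiarise over months, so real
control dyads can show positive mean change), no reciprocity dynamics
within dyads, no individual-level gregariousness (heterogeneity is purely
dyadic), and no measurement error in identities. Calibration and
recovery results below are statements about the inference machinery under
this model, not about any particular field system.

## Numerical and testing choices

- Degenerate inputs: empty bout files are valid (all rates are exactly
  0); zero-exposure dyads are `NA`; constant vectors make correlations
  and rank fits error loudly.
- CSV output writes numerics with 17 significant digits, making
  write/read round trips bit-exact.
- The test suite checks the rate arithmetic against hand-tabulated toy
  colonies (4 bats, up to 3 sessions per phase) at `1e-12`; permutation
  machinery against brute-force enumeration on designs small enough to
  enumerate (4 triad assignments for 3 sites x 2 bats, 36 within-cage
  arrangements for 2 cages); and the whole pipeline by simulation:
  bootstrap coverage over 500 Normal replicates, type-I error of the
  permutation test over 200 null colonies at the full design with 500
  permutations each, and recovery of an injected 0.5 log-scale effect
  over 200 replicates — sizes chosen to give exact-binomial 99% decision
  bands that are informative while keeping the default suite quick on a
  single core.

## Known limitations

- Dyads sharing a bat are treated as exchangeable units by the
  bootstrap; the permutation test conditions only on site-completeness
  of the triads, matching the randomisation actually performed, but the
  bootstrap CIs inherit the usual dyadic non-independence caveat.
- The rank models have far less power than the group contrast: forced-
  phase rates rest on one week of exposure and only the test dyads enter.
- `log(1+x)` compresses genuinely multiplicative effects at low rates;
  recovery of an additive log-lambda shift is approximate unless rates
  sit well above 1 s/h (the default generator regime does).
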