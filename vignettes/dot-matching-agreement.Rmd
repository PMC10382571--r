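---
title: "Measuring spatial agreement in dot-matching correspondence experiments"
author: "dotmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial agreement in dot-matching correspondence experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotmatch)
```

## The problem

In a dot-matching experiment an observer is shown a probe location on a base
stimulus and places a dot at the location they perceive as *corresponding*
on a differently shaped test stimulus. Repeating this over a set of probe
locations, observers, repetitions, and presentation conditions (with or
without intermediate forms shown between the two stimuli) yields a table of
2-D dot placements inside a known shape outline. `dotmatch` quantifies three
things: how well observers agree with each other (inter-observer
consistency), whether that agreement beats chance, and whether groups —
conditions, naive cohorts, expert cohorts — put their dots in the same
places.

## The model and its statistics

All coordinates are continuous pixels in image convention (origin top-left,
y downward); distances are Euclidean and reported in the same unnamed pixel
"units".

**Consistency.** For probe $p$ with one aggregated response per observer,
the statistic is the mean pairwise distance over all unordered observer
pairs. It is translation- and rotation-invariant and scales linearly with
the image. Under isotropic Gaussian placement noise with per-axis SD
$\sigma$, its expectation is exactly $\sigma\sqrt{\pi}$ (the difference of
two such placements is Gaussian with per-axis variance $2\sigma^2$, and the
mean norm of a 2-D Gaussian is $\sqrt{v\,\pi/2}$ per-axis-variance $v$).
This identity is the backbone of the generator-recovery tests.

**Random baseline.** Chance agreement is the expected distance between two
independent uniform locations inside the test-shape contour. Because the
mean pairwise distance of $N$ i.i.d. uniform points has this same
expectation for every $N \ge 2$, the baseline is estimated from independent
point *pairs* (default $10^5$, seed recorded in the report) rather than by
mimicking cohort size — lower variance and no dependence on $N$. For the
unit square the exact constant is $(2+\sqrt2+5\,\mathrm{asinh}\,1)/15
\approx 0.5214$; for the unit disc $128/(45\pi) \approx 0.9054$. The
Monte-Carlo estimator reproduces both, which is the sampler's acceptance
check.

**Consistency vs. random.** The per-probe consistency vector is compared to
the constant baseline by a paired $t$-test over probes (equivalently a
one-sample $t$ on the differences), $df = k-1$ for $k$ probes. The baseline
is deliberately a *constant* within one analysis, not resampled per probe:
one number serves all probes.

**Neighbor test.** The conservative check asks whether responses for a
probe are closer to each other than to the median response of its nearest
other probe (nearest on the base stimulus; distance ties break towards the
lexicographically smaller probe id). Note an asymmetry built into this
construction: the within-probe term is a *pairwise* distance (expectation
$\sigma\sqrt\pi \approx 1.77\sigma$ under pure noise) while the
between-probe term is a distance to a fitted *median* (expectation
$\approx 1.35\sigma$ when probes are indistinguishable). When there is no
real neighbor structure the test therefore tends to come out *positive*,
i.e. it is biased against concluding that observers discriminate
neighboring probes — which is exactly why it is the conservative companion
to the random-baseline test. The calibration property we verify is
directional: under a one-cluster null, significant *negative* outcomes are
rare.

**Proximity comparisons.** For condition and cohort comparisons, each
probe's responses are measured against two reference maps (per-probe median
locations): mean distance to the "self" reference vs. to the "other"
reference, compared by a paired $t$ over probes. When the self reference is
estimated from the very responses being tested (the descriptive convention
used in the experimental literature, and by `run_analyze()`), the self
distances are biased small — the reference has been fit to the data. That
is fine for describing how far apart two conditions are, but it is
anticonservative as a null test. The package's type-I calibration therefore
uses reference maps estimated from cohorts *independent* of the analysed
responses; under a zero condition shift the self/other labels are then
exchangeable and the test rejects at the nominal 5% rate. The power
companion injects a shift of $10\sigma$ and uses the known true maps as
references.

**Observer-level tests.** Response times are averaged per observer across
probes and repetitions and compared between conditions by a paired $t$ over
observers; 6-point confidence and similarity ratings likewise. Identity
judgements allow multiple selections per observer, which breaks the
pairing, so each selected choice contributes one coded observation to a
classic pooled-variance two-sample $t$ ($df = n_a + n_b - 2$). The numeric
coding of the four identity choices is an explicit, mandatory configuration
entry (default ordinal: unrelated 0, same class 1, either "modified
version" 2) because no canonical coding exists.

## Conventions the experiment leaves open

Three conventions are not dictated by the paradigm and are therefore
explicit configuration, recorded in every report:

- **Repetition aggregation** (`aggregation`): the repeated placements of an
  observer on one probe are collapsed to their componentwise median by
  default (robust to a single slip); the mean is available. Response times
  aggregate by mean.
- **2-D median** (`median_type`): median maps use the componentwise
  (per-axis) median by default; the geometric (Weiszfeld) median is the
  alternative. For point-symmetric response clouds the two coincide.
- **Containment** is closed: dots digitised exactly on the contour count as
  inside. Responses *outside* the outline are retained with a warning
  rather than rejected — experts sometimes deliberately place dots off the
  organ, and that is data.

## The synthetic generator

`synthetic_config()` defaults describe one emulated study: 10 probe
locations, 10 naive observers completing both conditions with 3 repetitions
each, and a 6-expert cohort placing one careful, untimed dot per probe.
Responses are the condition's true location plus isotropic Gaussian noise,
redrawn until inside the contour (rejection clipping keeps the within-shape
distribution smooth; projecting to the boundary would pile mass on the
contour). True probe locations are spread by greedy farthest-point
selection among eligible interior candidates, because real probe sets mark
deliberately distinct anatomical locations, not uniform draws.

The default scale and noise levels are set from the analytic relations
above so the simulated statistics sit at published magnitudes for this kind
of experiment: a blob-shaped contour of base radius 260 px puts the uniform
baseline near 235 units; $\sigma_{\text{without}} = 36$ and
$\sigma_{\text{with}} = 84$ give expected aggregated consistencies
$0.67\sigma\sqrt{\pi}$ of roughly 43 and 100 units (the 0.67 factor is the
variance reduction of a median of three repetitions); the with-intermediates
truth is the without truth shifted 150 px towards the shape's "tip";
response times are lognormal with means near 5.7 s and 6.1 s; similarity
ratings are higher with intermediates. Expert noise (16 px) makes experts
about as consistent as the scale-adjusted published expert statistics.

What the generator does *not* emulate, and what green tests therefore do
not show about real data: anatomically meaningful probe layouts and
contours; observer idiosyncrasies (each synthetic dot is an independent
draw — no per-observer bias fields, no learning across repetitions or
blocks); heavy-tailed or oblique placement errors; the repetition-control
cohort; and any cognitive mechanism for *why* intermediates shift
judgements — the shift is simply injected.

```{r generator, eval = FALSE}
cfg <- synthetic_config(seed = 2026)
sim <- simulate_experiment(cfg)
agg <- aggregate_repetitions(sim$responses)
consistency_analysis(select_responses(agg, "naive", "without_intermediates"),
                     n_pairs = 1e5, seed = 7)
```

## Numerical choices and degenerate inputs

- Polygon validity is checked eagerly: at least three distinct vertices,
  strictly positive shoelace area, and no intersection between
  non-adjacent edges. GeoJSON polygons with interior rings are rejected —
  the resampling null is defined on a simply connected contour.
- Point-in-polygon uses crossing counts plus an explicit on-segment test at
  a tolerance of $10^{-9}$ of the shape extent, so the closed-containment
  convention is exact on edges and vertices.
- Uniform sampling is bounding-box rejection: exactly uniform for arbitrary
  simple polygons, no triangulation. Batch sizes adapt to the acceptance
  rate; a fixed seed gives identical output.
- The geometric median uses Weiszfeld iteration with a relative step
  tolerance of $10^{-10}$, stopping on data-point collisions.
- Zero-variance $t$ statistics are split into two cases: exactly identical
  inputs are a well-defined "no effect" ($t = 0$, $p = 1$), while a
  constant non-zero difference has an undefined $t$ and raises a typed
  `dotmatch_degenerate_test` error carrying the sign of the difference, so
  callers must handle the pathological case explicitly instead of receiving
  $\pm\infty$.
- Rejection clipping that fails $10^4$ redraws for a single response (noise
  SD far larger than the shape) raises a configuration error naming the
  parameter.

## Problem sizes used by the test-suite calibrations

The property checks run at sizes chosen to make their Monte-Carlo error
small relative to the asserted tolerances: $2\times10^5$ pairs for the
analytic constants (tolerance 0.005); $\sigma \in \{2, 5, 10\}$ with 20
observers, 10 probes and 20 seeds for $\sigma\sqrt{\pi}$ recovery, asserted
on the seed-averaged grand mean within 5% (a single seed's grand mean has
relative SD near 3.6%, so per-seed assertion at 5% would be noise-limited,
not informative); 500 null runs and 200 power runs for the proximity-test
calibration; 1000 random vectors at $10^{-10}$ relative tolerance against
independently coded $t$ oracles.

## Limitations

- The neighbor relation is fixed to the nearest probe on the base stimulus;
  anatomically defined neighbor structures are not modelled.
- No correction for multiple testing is applied, and no nonparametric
  alternatives are offered; probes are treated as exchangeable paired
  units, ignoring spatial autocorrelation between nearby probes.
- The deposit adapter maps external CSV layouts by column/level renaming
  only; reproducing a specific archived dataset may additionally require
  choosing the aggregation and median conventions above to match the
  original (unstated) ones.
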