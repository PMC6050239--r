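---
title: "Pond versus stream control of nitrogen removal: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pond versus stream control of nitrogen removal: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondnet)
```

## The question and the model

Lakes, reservoirs and other ponded waters sit directly on river networks
and can remove a disproportionate share of the nitrogen moving through
them. Whether a particular ponded water removes *more* nitrogen than the
stream that would occupy its place is a balance between hydrology (how long
water lingers) and biology (how fast the benthos takes nitrogen up).
`pondnet` makes that comparison operational: it routes annual
total-nitrogen loads through a directed tree of reaches twice — once
through the existing mixture of streams and ponds, once through a
counterfactual network in which every ponded water is replaced by a
hydraulically consistent stream — and quantifies the difference locally and
cumulatively.

Removal is first-order on benthic area, flow is steady, and annual means
are used throughout. A stream reach transmits nitrogen with efficiency

$$\frac{\mathrm{Load_{OUT}}}{\mathrm{Load_{IN}}}
  = \exp\!\left(-\nu_s \frac{\tau}{d}\right),
  \qquad \frac{\tau}{d} = \frac{L\,b}{Q_s},$$

where $\nu_s$ (m d$^{-1}$) is the stream uptake velocity, $\tau$ the travel
time (d) and $d$ the mean depth (m). During routing, load generated within
the reach's own catchment enters at the reach midpoint and experiences half
the travel time. A ponded water (or each segment of one) is completely
mixed, so inflowing and locally generated load decay together:

$$\frac{\mathrm{Load_{OUT}}}{\mathrm{Load_{IN}}}
  = \exp\!\left(-\nu_p \frac{A_p}{Q_p}\right),$$

with $A_p/Q_p$ the reciprocal hydraulic load (d m$^{-1}$), i.e. the time to
displace a unit water column. The dimensionless Damköhler numbers
$Da_p = (A_p/Q_p)\,\nu_p$ and $Da_s = (Lb/Q_s)\,\nu_s$ compare retention
and reaction timescales, and because the annual discharge through a pond
and its replacement is the same, their ratio factorizes into hydrology
times biology:

$$\frac{Da_p}{Da_s} = \underbrace{\frac{A_p}{L\,b}}_{\mathrm{HDI}}
 \cdot \frac{\nu_p}{\nu_s}.$$

The *hydrologic dominance index* (HDI) is the pond's surface area over its
replacement's wetted surface area. A pond removes exactly the proportion
its replacement would when $Da_p = Da_s$, i.e. at
$\mathrm{HDI} = \nu_s/\nu_p$; above that it dominates. The acceptance
script and the test suite locate this crossover by bisection and verify it
lands at a Damköhler ratio of one to $10^{-9}$.

## Local proportions and their load-freeness

Per pond we report $R_p = 1-\mathrm{Load_{OUT}}/\mathrm{Load_{IN}}$, the
analogous $R_s$ for the replacement, and $\Delta R = R_p - R_s$ (positive
means the pond dominates). For a single-segment pond these are the closed
forms $1-e^{-Da_p}$ and $1-e^{-Da_s}$ — the full-travel-time efficiency
ratios — so local efficiencies are independent of how sources are
distributed across the landscape; routing subtleties (the midpoint rule)
affect mass fluxes but not these local proportions. Only segmented ponds,
whose multiple segments receive separate external inflows, need a
routed-load aggregation: one value for the whole ponded water, one minus
the load exiting its terminal segments over the load entering it from
outside plus the load generated inside. This is why switching between
spatially uniform and spatially variable sources leaves every
single-segment $R_p$ and $R_s$ unchanged (a property the tests assert
exactly), while cumulative proportions $R_{\mathrm{accum}}$ do shift with
the source pattern.

Cumulatively, $R_{\mathrm{accum}} = 1 -
\mathrm{Load_{accumOUT}}/\mathrm{Load_{NODECAY}}$ compares routed outflow
to the decay-free accumulation of all upstream sources, and
$\Delta R_{\mathrm{accum}}$ is its difference between the two scenarios.

## Physical metrics

* **Circularity** $4\pi A_p/P^2$: one for a circle, small for elongated
  water bodies. Perimeter and area come from the pond polygon via the
  shoelace formula; for holed polygons the net area and exterior-ring
  perimeter are used.
* **Pond connectivity** $L_{\mathrm{centroid}}/L$: distance from the pond
  polygon's area centroid to the midpoint of the intersecting reach (taken
  at half the *arc* length, which matters on curved flowlines), scaled by
  reach length; the mean over segments gives one value per pond. Small
  values mean the pond is centred on the flow path and plausibly well
  mixed.
* **Pond density** at a reach: cumulative upstream pond surface area over
  cumulative upstream drainage area. Densities above one can only arise
  from inconsistent catchment data; they are flagged and excluded from
  threshold fits.
* **Cumulative HDI**: wetted surface area is extensive, so the existing
  (ponds as ponds) and replaced (ponds as streams) surface areas are
  accumulated independently and then divided. Reaches with no upstream pond
  have a cumulative HDI of exactly one; values above one mark
  pond-dominated hydrology.
* **Cumulative connectivity**: the mean connectivity over the unique
  ponds upstream. Each pond counts once regardless of segmentation; a
  segmented pond is located at its most downstream segment's reach, the
  point past which the whole pond has drained. The metric is undefined
  (reported `NA`) where no pond lies upstream.

## Hydraulic geometry of the replacement

The stream that replaces a pond inherits the reach's length and slope
(artificial lake flowlines trace the most direct path), carries the pond's
discharge ($Q_p = Q_s$ over the annual mean), takes depth from the power
law $d = 0.261\,Q^{0.3966}$ (Q in m$^3$ s$^{-1}$; a regression over 112 US
river sites), velocity from a pluggable estimator, and width from
continuity $b = Q/(v\,d)$, which closes $Q = v\,d\,b$ to machine precision.
Published travel-time methods (e.g. Jobson's regressions on drainage area,
discharge, length and slope) are regional fits, so the velocity model is a
configuration point with three shipped options: `from_input` (use the
recorded mean annual velocity; the default for data-driven networks),
`constant`, and `power_law` ($v = kQ^m$; the generator's default with
$k = 2.5\times10^4$ m d$^{-1}$, $m = 0.1$, about 0.3 m s$^{-1}$ at unit
discharge). Sinuosity multiplies travel time; its default of 1 reflects
near-straight artificial flowlines, and setting 2 reproduces the classic
sensitivity case in which travel time (and hence the stream Damköhler
number) at most doubles.

Discharge is carried in m$^3$ d$^{-1}$ (the hydrography convention) and
converted with the fixed factor 86 400 only inside the depth law, whose
coefficient is defined for m$^3$ s$^{-1}$.

## Uptake velocities

Streams get two uptake velocities split at a mean annual discharge of
2.83 m$^3$ s$^{-1}$ (small streams are the statistically influential
class). Calibrated regional values belong to the data they were fitted on;
the package defaults — $\nu_{s,\mathrm{small}} = 0.2$,
$\nu_{s,\mathrm{large}} = 0.05$, $\nu_p = 0.02$ m d$^{-1}$ — were chosen
once as round magnitudes consistent with the robust qualitative finding
that streams are roughly an order of magnitude (regionally up to 14–18
times) more biologically efficient per unit benthic area than ponded
waters. They set the default HDI dominance threshold at
$\nu_s/\nu_p = 10$.

## Threshold detection

Three threshold types are detected:

1. **Pond density, per stream order.** Densities are trimmed to their
   central 98% (symmetric 1% tails, damping extreme values), a LOWESS of
   $\Delta R_{\mathrm{accum}}$ on density is fitted (span 0.5, two
   robustifying iterations; both configurable since the result depends on
   them), and envelopes are formed by smoothing the positive and negative
   residuals separately and adding them to the fit. The smoothed residual
   curves are clamped to their sign so the envelope ordering
   lower $\le$ fit $\le$ upper cannot invert at sparse edges. The threshold
   is the smallest density on a log-spaced grid (200 points over the
   retained range) from which the lower envelope stays positive at every
   larger density — "consistently above zero" made computable and
   resolution-controlled. Orders with fewer than 20 points are flagged, not
   errored.
2. **HDI.** Analytic: $\nu_s/\nu_p$.
3. **Pond connectivity.** Connectivities are cut at their 99th percentile,
   then a continuous two-segment piecewise-linear regression of $\Delta R$
   on connectivity with one free breakpoint is fitted by the standard
   iterative breakpoint update (with a grid-search-plus-refinement fallback
   when the iteration wanders), the slope change is tested with a
   Davies-type bound over a candidate grid, and a normal-theory 95% CI
   comes from the breakpoint's delta-method standard error. `found` is
   FALSE when the slope change is not significant. Parameter-recovery tests
   plant a break at 0.36 (a value of the order reported for north-eastern
   networks) with noise sd 0.02 at n = 1000 and require 95% CI coverage in
   at least 85 of 100 replicates.

## Variance partition

The dominance model
$\ln R_p - \ln R_s = \beta_0 + \beta_1 \ln c + \beta_2 \ln s +
\beta_3 \ln \mathrm{DA} + \varepsilon$
is ordinary least squares on the log scale; records with non-positive
proportions or predictors are dropped and counted rather than offset by
pseudo-counts. Explained variance is attributed by sequential (Type I) sums
of squares. The entry order is a parameter; the default (drainage area,
then connectivity, then circularity) puts drainage area first because it
carries most of the explained variance — it is strongly negatively
rank-correlated with the HDI, since rivers grow downstream while ponds do
not keep pace. On generated networks the partition reproduces this
structure (drainage area dominating, connectivity second), as the worked
example in the README shows.

## The synthetic study system

The generator emulates the statistical structure of medium-resolution
hydrography attributes so every stage is testable without any download:

* topology: a random recursive tree (each reach attaches to a uniformly
  chosen existing reach), which yields realistic Strahler-order
  distributions at desk scale; a balanced binary cascade is available for
  controlled experiments;
* incremental catchment areas lognormal (median 2 km$^2$, sdlog 0.8) and
  reach lengths lognormal (median 1.5 km, sdlog 0.6), slopes uniform on
  $[10^{-4}, 0.05]$;
* discharge = 0.5 m yr$^{-1}$ of runoff times accumulated drainage area,
  so the outlet closes the water balance exactly;
* ponds on 15% of reaches (the share of reaches covered by ponded waters
  in the motivating regional datasets), with lognormal areas (median
  5 ha), elliptical outlines with aspect ratios 1–6 and centroid offsets
  0–0.6 of reach length, perimeters within Ramanujan's approximation of
  the analytic ellipse value (relative error below $10^{-3}$ at the
  aspect ratios used); ponds above 50 ha are split across two consecutive
  reaches with area shares proportional to semi-major-axis overlap;
* sources either uniform (fixed areal yield of 10 kg ha$^{-1}$ yr$^{-1}$)
  or lognormal.

Each stage draws from its own stream seeded from the master seed, so adding
ponds never perturbs the network realization, and the full pipeline is
byte-reproducible from (config, seed) — the shipped benchmark configuration
is run twice in the tests and compared file by file.

What the generator does *not* emulate: real planform geometry beyond
ellipses, braided or diverted channels, spatial autocorrelation of sources,
and the covariance between pond size and network position found in real
reservoir systems. Passing tests therefore demonstrate the correctness of
the routing, metrics and estimators under the stated statistical structure,
not the regional numbers any particular river basin would produce — those
depend on calibrated uptake velocities and real hydrography.

## Numerical choices and degenerate inputs

* Routing follows a topological order with Kahan-compensated summation at
  junctions, so cumulative loads agree with a per-source path-product
  oracle to $10^{-9}$ relative and are invariant to sibling ordering.
* Reaches with no path to an outlet within the record set are excluded
  (with a message) before analysis; cycles are an error naming the cycle.
* Strahler orders are recomputed from topology when absent, by the
  equal-orders-merge rule.
* A zero-length reach has zero travel time and passes load through; zero
  discharge on a pond segment is an error (the reciprocal hydraulic load
  diverges).
* Ponds with zero entering load (possible only when all upstream and
  internal sources are zero) get `NA` proportions and a warning rather
  than a silent 0/0.
* Problem sizes in the tests — networks of 30–500 reaches, 20-network
  oracle sweeps, 100-replicate recovery experiments at n = 1000–5000 —
  were chosen as the smallest scales at which the distributional claims
  under test are sharp.

## Known limitations

Segmented-pond aggregation follows a stated convention (terminal-segment
outflow over external inflow), one of several defensible readings of
"proportion removed by the entire ponded water"; per-segment polygons are
required for per-segment connectivity (the whole-pond centroid is inherited
otherwise and logged as approximate in the data frame). The breakpoint CI
is normal-theory, adequate at the tested noise levels but optimistic for
very small samples. Seasonal dynamics, non-first-order kinetics and
phosphorus are out of scope.
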