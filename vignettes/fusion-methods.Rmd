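---
title: "Fusing mobile monitoring maps with fixed-site sensor time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing mobile monitoring maps with fixed-site sensor time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcfuse)
```

## The measurement problem

Urban air-pollution campaigns produce two complementary but individually
incomplete views of a pollutant field such as black carbon (BC):

* **Mobile monitoring** — instrumented vehicles sampling at 1 Hz while
  repeatedly driving every street — yields maps that are spatially dense
  (every ~30 m road segment) but *time-averaged*: each segment is only
  visited intermittently, so the map is a campaign aggregate.
* A **fixed-site low-cost sensor (LCS) network** yields time series that are
  temporally complete (e.g. 15-min bins over the whole campaign) but
  spatially sparse (tens of sites).

`bcfuse` reconstructs a spatiotemporally *complete* BC field — every road
segment, every 15-min bin — by fusing the two. The working assumption is
the one that makes multipollutant mobile maps informative about temporal
behavior: a small number of latent influences (sources, meteorology)
shape the spatial distribution of many pollutants *consistently over
time*, so spatial patterns learned from the time-averaged multipollutant
maps and spatial patterns learned from the BC time series are two views of
the same low-dimensional structure.

## Model

Let `X_M` (p pollutants × l locations) hold the time-averaged mobile maps,
where the location set is the road segments plus the sensor sites (segment
values are extended to the nearby sites by ordinary kriging, so both
systems share locations). Let `X_F` (s sites × t bins) hold the complete
sensor BC series. Two non-negative matrix factorizations (NMF) are fitted:

* `X_M ≈ W_P H_L` — `H_L` (k × l) holds k *pollutant-invariant spatial
  patterns*; `W_P` holds the pollutant signature of each pattern.
* `X_F ≈ W_S H_T` — `H_T` (q × t) holds q *characteristic time signals*;
  `W_S` (s × q) holds each signal's *time-invariant spatial pattern* at the
  sensor sites.

The two pattern sets overlap only at the sensor sites. With the binary
sampling matrix `Φ` (s × l) selecting site rows, the reprojection
coefficients

```
C = (Φ H_Lᵀ)⁺ W_S          (k × q, Moore–Penrose pseudoinverse)
```

express each time-invariant pattern as a least-squares combination of the
pollutant-invariant patterns. Because `H_Lᵀ` is spatially dense, `H_Lᵀ C`
*augments* the q site-level patterns to all l locations, and

```
X_BC = H_Lᵀ C H_T          (l × t)
```

is the fused, spatiotemporally complete BC estimate. `fuse()` runs this
chain end to end; `fit_reprojection()` and `reconstruct()` expose the
pieces, including the augmented patterns.

Two algebraic facts anchor the implementation and its tests:

* **Scaling invariance.** Rescaling any factor pair by a positive diagonal
  (the inherent ambiguity of NMF) cancels through the pseudoinverse:
  `X_BC` is unchanged. The normalization convention of
  `normalize_factors()` is therefore cosmetic for the fused field, and the
  suite asserts this numerically rather than assuming it.
* **Exact span.** If the true field is exactly a non-negative combination
  of r separable (pollutant × location × time) components and the factor
  matrices span them (k = q = r), the reconstruction is exact. The
  synthetic generator builds truth with exactly this structure so the
  pipeline has a known fixed point (`fuse(..., oracle = )` injects the
  true factors).

## Upstream data reduction

**Drive logs → segment maps** (`snap_to_segments()`, `drive_pass_means()`,
`median_of_means()`). Points snap to the nearest segment within 30 m
(lexicographic tie-break). A *pass* is a maximal run of consecutive points
by one vehicle on one segment with gaps ≤ 60 s; the gap rule is this
package's definition — re-visits at urban speeds are separated by well
over a minute. The map statistic is the median over passes of
per-pass means, a robust time-average; segments with fewer than 15 passes
(pooled over vehicles) are dropped entirely. Negative medians (instrument
noise at clean segments) are clipped to 0 and counted, since NMF requires
non-negativity.

**Raw sensor series → X_F** (`bin_series()`, `impute_gaps()`). Bins are
half-open 15-min intervals on the local clock (day/night and
weekday/weekend subsetting are local-clock concepts); a bin is kept when
at least half its expected raw samples are present; negatives participate
in the mean before clipping at 0. NMF needs a complete matrix, so interior
gaps are filled by per-site linear interpolation and edge gaps by the
site's median, with sites missing more than 20% of bins rejected rather
than imputed. Observed cells are never altered, and the per-site imputed
fraction is retained.

**Kriging** (`empirical_variogram()`, `fit_variogram()`,
`ordinary_krige()`). Exponential variograms (nugget, partial sill, range)
are fitted per pollutant by pair-count-weighted least squares; the
ordinary-kriging system is solved with the full segment set as the
neighborhood (a few hundred to a few thousand points — direct solves are
cheap at this scale) and predictions are clipped at 0. Sites within 1 m of
a segment point take its value directly. The variogram family and
neighborhood are this package's choices; kriging on raw (not log)
concentrations keeps the extended map on the scale the factorization
expects.

## Rank selection

`select_rank_knee()` fits NMF over a candidate grid, forms the relative
Frobenius error curve, and takes the knee: the point of maximum
perpendicular distance to the chord joining the curve's endpoints on the
axis-normalized curve. Defaults bracket typical use: candidates 2–9 for
the pollutant system and 2–40 for the sensor system. The knee is sharp
when the latent components are comparably strong and not too collinear;
on curves that decay smoothly into the noise floor the maximum-distance
point can land one rank early, which is flagged only through the returned
error curve — inspecting the curve is always recommended. An exactly
linear curve has no interior knee and is flagged `no_clear_knee`.

NMF itself uses Lee–Seung multiplicative updates on the Frobenius
objective with a deterministic non-negative double-SVD (NNDSVD-a)
initialization, stopping at a relative objective change below 1e-6 or
2000 iterations. Determinism matters more here than squeezing the last
fraction of a percent of loss: rank selection, cross-validation and the
command-line pipeline all promise bit-identical reruns. The objective
trace is recorded and asserted non-increasing.

## Numerical choices

* Pseudoinverse: SVD with relative cutoff `rcond = 1e-10`; the
  equivalence with a normal-equations solve on full-column-rank systems is
  part of the test suite.
* Negative entries of `X_BC` are clipped to 0 after reconstruction (the
  algebra is unconstrained; concentrations are physical) and counted on
  the returned object.
* BC's own mobile map stays among the p pollutants of `X_M` — it carries
  the strongest spatial information about BC and the field study includes
  it among its maps.
* All randomized drivers (CV partitions, random placements, the
  generator) draw from stage-derived seeds, so every result is
  reproducible from one root seed.

## The synthetic study scene

`scene_config()` / `generate_truth()` emulate a desk-scale analogue of a
~15 km² urban campaign: a grid network of 400 road segments (~30 m) over a
2 × 2 km domain, 60 sensor sites jittered within ~20 m of segments, 10
days × 96 15-min bins, and 6 pollutants driven by 4 latent sources plus a
regional background. Each source has a position, an exponential spatial
footprint (decay length 150–400 m, the scale of near-road primary
gradients), a non-negative pollutant signature, weekday/weekend diurnal
profiles, and lognormal day-to-day strengths. The background is spatially
flat but has its own diurnal and day-to-day variation — urban background
BC is far from constant in time, and a time-constant background would
leave source-remote sites unrealistically signal-free. Truth is therefore
exactly rank `n_sources + 1` in every unfolding, giving recovery tests a
known answer.

Sampling emulates the platforms. Two vehicles drive weekday circuits
between 09:00 and 16:00; each circuit follows a serpentine route over the
grid (so a 15-min window covers a spatially contiguous neighborhood, as a
real drive path does) with 9 s per segment and 2 circuits per vehicle per
drive day, yielding a median of ~32 visits per segment; 5% of segments
are visited only occasionally, exercising the ≥15-visit filter. Sensor
draws occur every 5 min with 10% multiplicative noise plus a small
additive floor (sd 0.05 µg/m³) that can push clean-site readings
negative; ~5% of each record is removed as contiguous outages. Mobile
1-Hz readings carry 10% multiplicative noise.

What the generator does *not* emulate: plume dynamics and wind (an
optional roaming transient source provides a model-violating stress
term), instrument drift, spatially correlated sensor error, and
seasonality. Passing tests therefore demonstrate internal consistency and
correct recovery under the model's own assumptions — not field skill on
real data.

## Evaluation protocols

`metrics()` reports Pearson r, NMB, NMAE and NRMSE (normalized by the
observed mean/sum, as fractions). The drivers mirror a field evaluation:

* **Lagrangian comparison** (`lagrangian_compare()`): per 15-min window
  and vehicle, the mean measured 1-Hz BC along the route against the mean
  model value over the *distinct* segments traversed (each counted once —
  dwell-time weighting is deliberately not applied). Windows need ≥300
  points (≥5 min of data). `areawide_field()` provides the
  no-spatial-information baseline the model must beat.
* **Campaign-integrated spatial comparison**
  (`campaign_spatial_compare()`): median-of-pass-means against the
  equivalently pass-aggregated model values.
* **Leave-site-out CV** (`leave_sites_out_cv()`): the site-side
  factorization and reprojection are refitted per iteration; the
  pollutant-side factorization does not depend on the site subset and is
  fitted once. Held-site series are scored on observed bins only. Default
  50 iterations keep the suite fast; 1000 are a config change.
* **Sensitivity drivers**: network size (`sensitivity_site_count()`),
  pollutant count (`sensitivity_pollutant_count()`, BC always retained;
  the single-pollutant case degenerates to using the BC map as the lone
  spatial pattern), vehicle holdout (`car_holdout()`), and
  weekday/weekend × day/night subsetting (`temporal_subset_report()`,
  daytime 09:00–16:00 by default).

## Sensor placement

`qr_pivot_select()` ranks candidate sites by column-pivoted QR on the
transpose of a spatial-mode basis — the greedy determinant surrogate of
the compressive-sensing placement literature. `placement_benchmark()`
takes the basis from the SVD of the all-sites fused field at the
candidate rows, weighted by singular values so directions beyond the
field's numerical rank cannot drive the selection, then refits the fusion
with only the chosen (or random) m sites and scores reconstruction
against truth at non-sensor locations. Two regimes matter when reading
the curves: below ~m = 16 (on the 60-site default scene) placement
genuinely matters and QR selection dominates random medians; beyond that
both curves sit on the sensor-noise floor and differences are noise. The
`match_tol = 0.5` default for "matches full-network performance" reflects
this: matching is judged on the scale of placement-induced error spread,
not of the irreducible floor. On the default scene the QR selection
reaches full-network performance around m = 10 of 60 while random
placement needs ≥16 — the scaled version of the contrast between a few
well-placed sensors and a much larger random network.

## Problem sizes and limitations

The default scene (l = 400 + 60, t = 960) keeps the full suite and the
acceptance script to a few minutes on one CPU; a paper-scale shape
(thousands of segments, 9600 bins) is a config choice and the binning path
is tested at 100 days × 15 min = 9600 columns directly. Known
limitations: no uncertainty quantification on `X_BC`; the pseudoinverse is
unregularized (an ill-conditioned `Φ H_Lᵀ` warns rather than shrinks);
kriging is isotropic and per-pollutant; and the multiplicative-update NMF
finds local minima — deterministic initialization trades global
optimality for reproducibility.
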