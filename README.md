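# bcfuse

Spatiotemporal fusion of mobile-monitoring maps and fixed-site sensor
networks for black carbon (BC) mapping.

## The problem

Two common urban air-quality data sets are individually incomplete:

* **Mobile monitoring** (instrumented cars sampling many pollutants at
  1 Hz on every street) gives *spatially dense but time-averaged* maps —
  each ~30 m road segment is visited repeatedly but intermittently.
* A **fixed-site low-cost sensor network** gives *temporally complete but
  spatially sparse* BC time series (e.g. 15-min bins at ~100 sites).

`bcfuse` combines them into a BC concentration field that is complete in
both dimensions — every road segment at every 15-min time step — for
exposure assessment at the scale where both neighborhoods and hours
matter. The package is aimed at researchers working with mobile +
sensor-network campaigns, and ships a synthetic-scene generator so the
whole pipeline can be exercised, validated and benchmarked without any
field data.

## The method

Let `X_M ∈ R^{p×l}` be the time-averaged pollutant × location matrix from
mobile monitoring (l = road segments plus sensor sites; segment values are
extended to sites by ordinary kriging), and `X_F ∈ R^{s×t}` the site ×
time BC matrix from the sensor network. Two non-negative matrix
factorizations extract shared spatial structure:

    X_M ≈ W_P H_L        H_L : k pollutant-invariant spatial patterns (k × l)
    X_F ≈ W_S H_T        W_S : q time-invariant spatial patterns (s × q)
                         H_T : q characteristic time signals (q × t)

The two pattern sets overlap at the sensor sites, selected by a binary
sampling matrix `Φ ∈ {0,1}^{s×l}`. A least-squares reprojection links
them through the Moore–Penrose pseudoinverse:

    C = (Φ H_Lᵀ)⁺ W_S    (k × q)

and the fused, spatiotemporally complete field is

    X_BC = H_Lᵀ C H_T    (l × t).

Factorization ranks default to k = 5 and q = 16 and can be knee-selected
from the reconstruction-error curve. Around this core the package
implements drive-log aggregation (median-of-drive-pass-mean segment maps
with a ≥15-visit filter), sensor binning and gap imputation, variogram
fitting and ordinary kriging, Lagrangian and leave-site-out evaluation
protocols, pivoted-QR sensor placement, and a command-line pipeline.

## Worked example

Simulate a small campaign (196 segments, 30 sensor sites, 5 days, 3
latent sources plus background), reduce both data streams, fuse them, and
evaluate along the vehicles' own sampling paths:

```r
library(bcfuse)

cf    <- scene_config(p = 6, n_segments = 196, n_sites = 30,
                      n_days = 5, n_sources = 3)
scene <- generate_truth(cf, seed = 42)
pts   <- sample_mobile(scene, seed = 42)    # 1-Hz drive logs, 2 vehicles
raw   <- sample_sensors(scene, seed = 42)   # raw site BC series

asg <- snap_to_segments(pts, scene$segments)
pm  <- drive_pass_means(pts, asg)
map <- median_of_means(pm, min_visits = 15, segments = scene$segments)
map
#> segment_map: 6 pollutants x 186 locations
#>   pollutants: bc, no, no2, co, co2, ufp

sm <- impute_gaps(bin_series(raw, scene$sites, cf$campaign_start, cf$n_days))
sm
#> sensor_matrix: 30 sites x 480 bins (15 min)
#>   observed 95.1%, clipped 0 negative bin means

model <- fuse(map, sm, sites = scene$sites, k = 4, q = 4, seed = 42)
model
#> fusion_model: k = 4, q = 4
#>   reprojection residual (relative) 0.1417, effective rank 4
#> bc_field: 216 locations x 480 time bins (ug/m3)

lagrangian_compare(pts, asg, model$field)$metrics
#> n = 45: r = 0.996, NMB = 0.5%, NMAE = 1.6%, NRMSE = 2.1%
```

Reading the output: 10 of 196 segments fell below the 15-visit floor and
were dropped; the fused field covers the 186 retained segments plus the
30 sites at all 480 bins. The Lagrangian check pairs, for each 15-min
window, the mean measured 1-Hz BC along the route with the mean model
value over the segments traversed — r = 0.996 with ~2% error against
measurements carrying 10% noise. Against the (normally unknowable) true
field the reconstruction error is 4.3%:

```r
truth <- truth_bc(scene)[match(model$map$locations, scene$locations), ]
sqrt(sum((model$field$values - truth)^2) / sum(truth^2))
#> [1] 0.043
```

A command-line pipeline wraps the same steps
(`simulate | aggregate | krige | factorize | fuse | evaluate |
place-sensors`):

```sh
Rscript inst/cli/bcfuse.R simulate --config cfg.yaml --out run/ --seed 1
Rscript inst/cli/bcfuse.R fuse     --config cfg.yaml --out run/ --seed 1
```

See `vignettes/fusion-methods.Rmd` for the model, its assumptions, the
synthetic scene, and all numerical choices.

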