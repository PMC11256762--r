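# Shared fixtures, built once per test run and memoized. All synthetic inputs
# are generated in code from fixed seeds; no data files.

.pipeline_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .pipeline_cache)) {
    assign(key, build(), envir = .pipeline_cache)
  }
  get(key, envir = .pipeline_cache)
}

# Default noisy study scene (6 pollutants, 400 segments, 60 sites, 10 days of
# 15-min bins, 4 sources, 10% noise) carried through the full ingestion
# pipeline: drive log -> snapped passes -> filtered segment map -> kriged
# extended map; raw sensor series -> binned, imputed sensor matrix.
default_pipeline <- function() {
  memo("default_pipeline", function() {
    cf <- scene_config()
    scene <- generate_truth(cf, seed = 7)
    pts <- sample_mobile(scene, seed = 7)
    raw <- sample_sensors(scene, seed = 7)
    asg <- snap_to_segments(pts, scene$segments)
    pm <- drive_pass_means(pts, asg)
    map <- median_of_means(pm, min_visits = 15, segments = scene$segments)
    sm <- impute_gaps(bin_series(raw, scene$sites, cf$campaign_start,
                                 cf$n_days))
    ext <- krige_map_to_sites(map, scene$sites)
    truth <- truth_bc(scene)[match(ext$locations, scene$locations), ]
    list(cf = cf, scene = scene, pts = pts, raw = raw, asg = asg, pm = pm,
         map = map, sm = sm, ext = ext, truth = truth)
  })
}

# Same scene dimensions with all measurement noise switched off.
noiseless_pipeline <- function() {
  memo("noiseless_pipeline", function() {
    cf <- scene_config(mobile_cv = 0, sensor_cv = 0, sensor_floor_sd = 0,
                       missing_frac = 0)
    scene <- generate_truth(cf, seed = 7)
    pts <- sample_mobile(scene, noise_cv = 0, seed = 7)
    raw <- sample_sensors(scene, seed = 7)
    asg <- snap_to_segments(pts, scene$segments)
    pm <- drive_pass_means(pts, asg)
    map <- median_of_means(pm, min_visits = 15, segments = scene$segments)
    sm <- impute_gaps(bin_series(raw, scene$sites, cf$campaign_start,
                                 cf$n_days))
    ext <- krige_map_to_sites(map, scene$sites)
    truth <- truth_bc(scene)[match(ext$locations, scene$locations), ]
    list(cf = cf, scene = scene, pts = pts, asg = asg, pm = pm, map = map,
         sm = sm, ext = ext, truth = truth)
  })
}

# Fused model on the default noisy pipeline at the scene's true latent rank.
default_fusion <- function() {
  memo("default_fusion", function() {
    pl <- default_pipeline()
    fuse(pl$ext, pl$sm, k = 5, q = 5, seed = 7)
  })
}

rel_frob <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# Small non-negative random matrix with planted non-negative rank.
planted_matrix <- function(m, n, r, seed, noise = 0) {
  set.seed(seed)
  W <- matrix(rgamma(m * r, 2), m)
  H <- matrix(rgamma(r * n, 2), r)
  X <- W %*% H
  if (noise > 0) X <- X * matrix(rlnorm(m * n, 0, noise), m)
  X
}
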