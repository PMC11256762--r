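test_that("sampling matrices select exactly the site rows", {
  # identity when sites == locations
  phi <- build_sampling_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(phi$matrix, diag(3))

  # unit rows at the right columns
  phi2 <- build_sampling_matrix(c("l2", "l4"), paste0("l", 1:5))
  expect_equal(phi2$matrix[1, ], c(0, 1, 0, 0, 0))
  expect_equal(phi2$matrix[2, ], c(0, 0, 0, 1, 0))
  expect_true(all(rowSums(phi2$matrix) == 1))
  expect_true(all(colSums(phi2$matrix) %in% c(0, 1)))

  # random permutation fixture: Phi X row-selects (indexing oracle)
  set.seed(6)
  locs <- sprintf("loc%02d", 1:12)
  sites <- sample(locs, 5)
  X <- matrix(rnorm(12 * 7), 12)
  phi3 <- build_sampling_matrix(sites, locs)
  expect_equal(phi3$matrix %*% X, X[match(sites, locs), ])

  expect_error(build_sampling_matrix(c("a", "zz"), c("a", "b")), "zz")
})

test_that("reprojection solves the least-squares linkage", {
  # Phi H_L^T = identity: C = W_S
  H_L <- diag(3)  # 3 patterns over 3 locations
  phi <- build_sampling_matrix(c("a", "b", "c"), c("a", "b", "c"))
  W_S <- matrix(runif(12), 3)
  rp <- fit_reprojection(H_L, phi, W_S)
  expect_equal(rp$C, W_S, tolerance = 1e-12)

  # consistent system: exact recovery of a known C
  set.seed(13)
  k <- 4; q <- 6; l <- 30; s <- 12
  H_L2 <- matrix(rgamma(k * l, 2), k)
  locs <- sprintf("p%02d", 1:l)
  site_ids <- sample(locs, s)
  phi2 <- build_sampling_matrix(site_ids, locs)
  C_true <- matrix(rnorm(k * q), k)
  W_S2 <- t(H_L2)[phi2$index, ] %*% C_true
  rp2 <- fit_reprojection(H_L2, phi2, W_S2)
  expect_equal(rp2$C, C_true, tolerance = 1e-8)
  expect_lt(rp2$residual, 1e-8)

  # normal-equations oracle on random overdetermined instances
  for (tr in 1:20) {
    A <- t(H_L2)[phi2$index, ]
    W <- matrix(rgamma(s * q, 2), s)
    rp3 <- fit_reprojection(H_L2, phi2, W)
    C_ne <- solve(crossprod(A), crossprod(A, W))
    expect_equal(rp3$C, C_ne, tolerance = 1e-8)
  }

  expect_error(fit_reprojection(H_L2, phi2, matrix(0, s, 2)), "zero")
  expect_warning(fit_reprojection(matrix(rgamma(8 * l, 2), 8), phi2,
                                  matrix(runif(s * 2), s)), NA)
})

test_that("reconstruction follows the factor chain and clips negatives", {
  H_L <- matrix(c(1, 1), 1, 2)   # one pattern over two locations
  C <- matrix(2, 1, 1)
  H_T <- matrix(c(3, 4), 1, 2)
  f <- reconstruct(H_L, C, H_T)
  expect_equal(f$values, matrix(c(6, 6, 8, 8), 2, 2))
  expect_equal(f$augmented_patterns, matrix(c(2, 2), 2, 1))

  f2 <- reconstruct(H_L, matrix(-1, 1, 1), H_T)
  expect_true(all(f2$values == 0))
  expect_identical(f2$n_clipped, 4L)
  expect_error(reconstruct(H_L, matrix(1, 2, 2), H_T), "shape")
})

test_that("the fused field is invariant to per-factor rescaling", {
  set.seed(88)
  k <- 4; q <- 5; l <- 40; s <- 15; tt <- 50
  H_L <- matrix(rgamma(k * l, 2), k)
  locs <- sprintf("x%02d", 1:l)
  site_ids <- sample(locs, s)
  phi <- build_sampling_matrix(site_ids, locs)
  W_S <- matrix(rgamma(s * q, 2), s)
  H_T <- matrix(rgamma(q * tt, 2), q)

  base <- reconstruct(H_L, fit_reprojection(H_L, phi, W_S), H_T)

  # rescale the pollutant-invariant patterns and refit: D cancels
  D <- diag(runif(k, 0.2, 5))
  H_Ld <- D %*% H_L
  f1 <- reconstruct(H_Ld, fit_reprojection(H_Ld, phi, W_S), H_T)
  expect_lt(rel_frob(f1$values, base$values), 1e-8)

  # rescale the site-side pair (W_S E, E^-1 H_T): product W_S H_T fixed
  E <- diag(runif(q, 0.2, 5))
  f2 <- reconstruct(H_L, fit_reprojection(H_L, phi, W_S %*% E),
                    solve(E) %*% H_T)
  expect_lt(rel_frob(f2$values, base$values), 1e-8)

  # site consistency: || Phi X_BC - W_S H_T ||_F <= residual * ||H_T||_F
  rp <- fit_reprojection(H_L, phi, W_S)
  unclipped <- reconstruct(H_L, rp, H_T, clip_negative = FALSE)
  lhs <- sqrt(sum((phi$matrix %*% unclipped$values - W_S %*% H_T)^2))
  expect_lte(lhs, rp$residual * sqrt(sum(H_T^2)) + 1e-10)
})

test_that("oracle-factor fusion is exact and spatially flat truth stays flat", {
  # hand-built flat world: every location identical
  p <- 3; l <- 8; s <- 3; tt <- 30
  locs <- c(sprintf("S%02d", 1:(l - s)), sprintf("L%02d", 1:s))
  tser <- 1 + abs(sin(seq_len(tt) / 4))
  lev <- c(1, 2, 0.5)
  X_M <- matrix(lev * mean(tser), p, l)
  rownames(X_M) <- c("bc", "no", "no2"); colnames(X_M) <- locs
  map <- structure(list(values = X_M, pollutants = rownames(X_M),
                        locations = locs, visit_counts = rep(20L, l),
                        coords = NULL, n_clipped = 0L),
                   class = "segment_map")
  t0 <- as.POSIXct("2017-05-22", tz = "UTC")
  sensor <- structure(list(
    values = matrix(tser, s, tt, byrow = TRUE,
                    dimnames = list(sprintf("L%02d", 1:s), NULL)),
    observed_mask = matrix(TRUE, s, tt),
    sites = data.frame(site_id = sprintf("L%02d", 1:s)),
    site_ids = sprintf("L%02d", 1:s),
    time_bins = t0 + seq_len(tt) * 900, bin_width = 15L,
    campaign_start = t0, imputed_fraction = rep(0, s), n_clipped = 0L),
    class = "sensor_matrix")
  mod <- fuse(map, sensor, k = 1, q = 1, seed = 1)
  sdcol <- apply(mod$field$values, 2, function(v) diff(range(v)) / mean(v))
  expect_true(all(sdcol < 0.01))  # homogeneous limit: flat columns

  # oracle factors on a structured synthetic scene: exact recovery
  cf <- scene_config(p = 4, n_segments = 100, n_sites = 15, n_days = 2,
                     n_sources = 2, mobile_cv = 0, sensor_cv = 0,
                     sensor_floor_sd = 0, missing_frac = 0)
  scene <- generate_truth(cf, seed = 3)
  raw <- sample_sensors(scene, seed = 3)
  sm <- impute_gaps(bin_series(raw, scene$sites, cf$campaign_start,
                               cf$n_days))
  X_M2 <- truth_xm(scene)
  map2 <- structure(list(values = X_M2, pollutants = scene$pollutants,
                         locations = scene$locations,
                         visit_counts = rep(99L, ncol(X_M2)),
                         coords = scene$coords, n_clipped = 0L),
                    class = "segment_map")
  mod2 <- fuse(map2, sm, oracle = oracle_factors(scene))
  expect_lt(rel_frob(mod2$field$values, truth_bc(scene)), 1e-6)
})

test_that("BC fields round-trip through disk", {
  set.seed(1)
  t0 <- as.POSIXct("2017-05-22", tz = "UTC")
  f <- structure(list(values = matrix(rgamma(40, 2), 8),
                      augmented_patterns = NULL,
                      locations = sprintf("S%02d", 1:8),
                      time_bins = t0 + (1:5) * 900, n_clipped = 2L),
                 class = "bc_field")
  rownames(f$values) <- f$locations
  path <- file.path(tempdir(), "field.csv")
  write_bc_field(f, path)
  back <- read_bc_field(path)
  expect_equal(back$values, f$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$locations, f$locations)
  expect_equal(as.numeric(back$time_bins), as.numeric(f$time_bins))
  expect_identical(back$n_clipped, 2L)
})
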