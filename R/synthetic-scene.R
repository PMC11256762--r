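#' Synthetic-scene configuration
#'
#' Defines the ground-truth world the generator emulates: a small urban
#' domain with a grid road network, a handful of latent emission sources
#' whose spatial footprints (exponential decay kernels) and diurnal/weekday
#' behavior are shared across pollutants, a fixed-site BC sensor network,
#' and mobile sampling by two vehicles. The default scene is a desk-scale
#' analogue of a ~15 km^2 urban campaign: 6 pollutants, 400 road segments,
#' 60 sensor sites, 10 days of 15-min bins (960 time steps), 4 sources, and
#' 10% multiplicative measurement noise on both platforms.
#'
#' The truth cube is exactly separable into `n_sources + 1` non-negative
#' (pollutant x location x time) rank-1 components (the +1 is a flat
#' background), so factorization-rank recovery and exact-span fusion tests
#' have a known answer.
#'
#' @param p number of pollutants (BC first).
#' @param n_segments number of ~30 m road segments (grid).
#' @param n_sites number of fixed sensor sites.
#' @param n_days campaign length in days.
#' @param bin_width time-bin width in minutes.
#' @param n_sources number of latent sources.
#' @param domain domain side length in meters.
#' @param mobile_cv multiplicative (lognormal) CV of 1-Hz mobile readings.
#' @param sensor_cv multiplicative CV of raw sensor readings.
#' @param sensor_floor_sd sd (ug/m3) of the additive sensor noise floor
#'   (draws can go negative, exercising clipping).
#' @param missing_frac fraction of each site's record lost to gaps.
#' @param raw_period_s raw sensor sampling interval in seconds.
#' @param campaign_start campaign start (POSIXct midnight, local clock);
#'   default 2017-05-22, a Monday, so the 10-day scene has 8 weekdays.
#' @param background_scale multiplier on the flat per-pollutant background
#'   (0 removes the background component entirely, making the truth cube's
#'   latent rank equal the source count).
#' @param transient_source add a roaming source violating the shared-pattern
#'   model (stress-test option, default FALSE).
#' @return a `scene_config` list.
#' @export
scene_config <- function(p = 6L, n_segments = 400L, n_sites = 60L,
                         n_days = 10L, bin_width = 15L, n_sources = 4L,
                         domain = 2000, mobile_cv = 0.1, sensor_cv = 0.1,
                         sensor_floor_sd = 0.05, missing_frac = 0.05,
                         raw_period_s = 300,
                         campaign_start = as.POSIXct("2017-05-22 00:00:00",
                                                     tz = "UTC"),
                         background_scale = 1,
                         transient_source = FALSE) {
  stopifnot(p >= 2L, n_sources >= 1L, n_segments > 0L, n_days > 0L,
            1440L %% bin_width == 0L, n_sites <= n_segments)
  structure(list(p = as.integer(p), n_segments = as.integer(n_segments),
                 n_sites = as.integer(n_sites), n_days = as.integer(n_days),
                 bin_width = as.integer(bin_width),
                 n_sources = as.integer(n_sources), domain = domain,
                 mobile_cv = mobile_cv, sensor_cv = sensor_cv,
                 sensor_floor_sd = sensor_floor_sd,
                 missing_frac = missing_frac, raw_period_s = raw_period_s,
                 campaign_start = campaign_start,
                 background_scale = background_scale,
                 transient_source = isTRUE(transient_source)),
            class = "scene_config")
}

pollutant_names <- function(p) {
  c("bc", "no", "no2", "co", "co2", "ufp", "pm25", "o3", "ch4", "so2")[seq_len(p)]
}

#' Generate a ground-truth synthetic scene
#'
#' Builds the full deterministic-given-seed world: road network, sensor
#' sites, sources, and the truth concentration cube
#' `conc(i, j, n) = background_i b(n) + sum_r sig_ir exp(-d(j, r)/L_r) c_r(n)`
#' where `c_r(n)` is source r's day-type diurnal profile scaled by a
#' lognormal day strength, and `b(n)` is the regional background's own
#' diurnal/day-to-day profile (spatially flat). The cube covers the combined location set
#' (segments then sites), matching the location ordering the fusion
#' pipeline produces.
#'
#' @param config a `scene_config`.
#' @param seed integer seed; the scene is a pure function of (config, seed).
#' @return object of class `synthetic_scene`; notable fields: `segments`
#'   (a `road_segments`), `sites` (data.frame), `locations` (ids,
#'   segments then sites), `coords`, `cube` (p x L x t array), `A` (p x R
#'   pollutant loadings), `B` (R x L spatial patterns), `Ct` (R x t temporal
#'   signals), `time_bins`, `pollutants`, `latent_rank` (= n_sources + 1).
#' @export
generate_truth <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(derive_seed(seed, "truth"))
  cf <- config
  l <- cf$n_segments; s <- cf$n_sites
  bins_per_day <- 1440L %/% cf$bin_width
  t_bins <- cf$n_days * bins_per_day
  has_bg <- cf$background_scale > 0
  R <- cf$n_sources + as.integer(has_bg)

  # grid road network of ~30 m segments
  nx <- ceiling(sqrt(l))
  spacing <- cf$domain / nx
  gx <- ((seq_len(l) - 1L) %% nx + 0.5) * spacing
  gy <- ((seq_len(l) - 1L) %/% nx + 0.5) * spacing
  seg_ids <- sprintf("S%04d", seq_len(l))
  geom <- lapply(seq_len(l), function(i)
    rbind(c(gx[i] - 15, gy[i]), c(gx[i] + 15, gy[i])))
  segments <- road_segments(seg_ids, geom)

  # sensor sites: jittered off a random subset of segments (within 30 m)
  host <- sort(sample.int(l, s))
  sx <- gx[host] + runif(s, -15, 15)
  sy <- gy[host] + runif(s, -15, 15)
  sites <- data.frame(site_id = sprintf("L%03d", seq_len(s)),
                      x = sx, y = sy,
                      nearest_segment_id = seg_ids[host],
                      stringsAsFactors = FALSE)

  coords <- rbind(cbind(gx, gy), cbind(sx, sy))
  locations <- c(seg_ids, sites$site_id)
  L <- l + s

  # sources: spatially spread anchors, exponential footprints
  anchors <- matrix(c(0.25, 0.25, 0.75, 0.30, 0.30, 0.75, 0.70, 0.70,
                      0.50, 0.15, 0.15, 0.55, 0.85, 0.85, 0.55, 0.50),
                    ncol = 2, byrow = TRUE)
  if (cf$n_sources > nrow(anchors)) {
    anchors <- rbind(anchors, matrix(runif(2 * (cf$n_sources - nrow(anchors))),
                                     ncol = 2))
  }
  src_xy <- anchors[seq_len(cf$n_sources), , drop = FALSE] * cf$domain +
    matrix(runif(2 * cf$n_sources, -0.05, 0.05) * cf$domain,
           ncol = 2)
  decay <- runif(cf$n_sources, 150, 400)
  amp <- runif(cf$n_sources, 2, 6)
  # pollutant signatures: Dirichlet-like, with a guaranteed BC contribution
  sig <- vapply(seq_len(cf$n_sources), function(r) {
    w <- rgamma(cf$p, shape = 2)
    w[1] <- w[1] + 0.5 * max(w)
    w / sum(w)
  }, numeric(cf$p))

  # A: p x R pollutant loadings (last column = flat background, if any)
  A <- sweep(sig, 2, amp, "*")
  if (has_bg) A <- cbind(A, cf$background_scale * runif(cf$p, 0.2, 0.5))

  # B: R x L spatial patterns (last row = 1 for the background)
  dsrc <- sqrt(outer(src_xy[, 1], coords[, 1], "-")^2 +
                 outer(src_xy[, 2], coords[, 2], "-")^2)
  B <- exp(-dsrc / decay)
  if (has_bg) B <- rbind(B, rep(1, L))

  # day-type diurnal profiles and lognormal day strengths
  hr <- ((seq_len(bins_per_day) - 0.5) * cf$bin_width) / 60
  profiles <- lapply(seq_len(cf$n_sources), function(r) {
    a1 <- runif(1, 0.5, 1.5); a2 <- runif(1, 0.5, 1.5)
    a3 <- runif(1, 0.2, 0.8)
    list(weekday = 0.25 + a1 * exp(-((hr - 8) / 1.5)^2) +
           a2 * exp(-((hr - 17.5) / 2)^2),
         weekend = 0.25 + a3 * exp(-((hr - 13) / 3)^2))
  })
  dates <- as.Date(cf$campaign_start) + seq_len(cf$n_days) - 1L
  wk <- format(dates, "%u") %in% c("6", "7")
  day_type <- ifelse(wk, "weekend", "weekday")
  strengths <- matrix(rlnorm(cf$n_sources * cf$n_days, 0, 0.3),
                      cf$n_sources, cf$n_days)
  Ct <- matrix(0, R, t_bins)
  for (r in seq_len(cf$n_sources)) {
    daily <- lapply(seq_len(cf$n_days), function(d)
      profiles[[r]][[day_type[d]]] * strengths[r, d])
    Ct[r, ] <- unlist(daily)
  }
  if (has_bg) {
    # regional background varies diurnally and day to day (urban BC
    # background is far from constant), spatially flat
    bg_prof <- list(
      weekday = 0.7 + 0.5 * exp(-((hr - 8) / 3)^2) +
        0.3 * exp(-((hr - 18) / 3)^2),
      weekend = 0.8 + 0.3 * exp(-((hr - 13) / 4)^2))
    bg_strength <- rlnorm(cf$n_days, 0, 0.2)
    Ct[R, ] <- unlist(lapply(seq_len(cf$n_days), function(d)
      bg_prof[[day_type[d]]] * bg_strength[d]))
  }

  cube <- array(0, dim = c(cf$p, L, t_bins))
  for (i in seq_len(cf$p))
    cube[i, , ] <- t(B) %*% (A[i, ] * Ct)

  if (cf$transient_source) {
    # roaming transient: violates the shared-pattern model by design
    path <- cbind(runif(t_bins) * cf$domain, runif(t_bins) * cf$domain)
    dtr <- sqrt(outer(coords[, 1], path[, 1], "-")^2 +
                  outer(coords[, 2], path[, 2], "-")^2)
    burst <- exp(-dtr / 150) * rlnorm(1, 0, 0.2)
    for (i in seq_len(cf$p)) cube[i, , ] <- cube[i, , ] + 0.5 * burst
  }

  time_bins <- cf$campaign_start +
    seq(0, by = cf$bin_width * 60, length.out = t_bins)
  structure(list(config = cf, seed = as.integer(seed), segments = segments,
                 sites = sites, locations = locations, coords = coords,
                 n_segments = l, source_xy = src_xy, decay = decay,
                 A = A, B = B, Ct = Ct, cube = cube,
                 pollutants = pollutant_names(cf$p), time_bins = time_bins,
                 day_type = day_type, latent_rank = R),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cf <- x$config
  cat(sprintf("synthetic_scene: %d pollutants, %d segments + %d sites, %d x %d-min bins\n",
              cf$p, cf$n_segments, cf$n_sites, dim(x$cube)[3], cf$bin_width))
  cat(sprintf("  %d sources (+1 background), latent rank %d, seed %d\n",
              cf$n_sources, x$latent_rank, x$seed))
  invisible(x)
}

#' Ground-truth accessors
#'
#' `truth_bc` returns the true BC location x time slab (over segments then
#' sites); `truth_xm` the true time-averaged pollutant x location matrix;
#' `oracle_factors` the exact latent factor matrices in the shapes the
#' fusion expects (`H_L` R x L spatial patterns, `W_S` s x R site loadings
#' of the BC temporal components, `H_T` R x t temporal signals), for use
#' with `fuse(..., oracle = )`.
#'
#' @param scene a `synthetic_scene`.
#' @return matrix or list of matrices; see description.
#' @export
truth_bc <- function(scene) scene$cube[1, , ]

#' @rdname truth_bc
#' @export
truth_xm <- function(scene) {
  m <- scene$A %*% (rowMeans(scene$Ct) * scene$B)
  dimnames(m) <- list(scene$pollutants, scene$locations)
  m
}

#' @rdname truth_bc
#' @export
oracle_factors <- function(scene) {
  site_idx <- scene$n_segments + seq_len(nrow(scene$sites))
  W_S <- t(scene$B[, site_idx, drop = FALSE] * scene$A[1, ])
  list(H_L = scene$B, W_S = W_S, H_T = scene$Ct,
       locations = scene$locations)
}

#' Simulate mobile drive logs
#'
#' Two instrumented vehicles repeatedly drive the road network on weekdays
#' between 09:00 and 16:00 (the weekday- and daytime-biased schedule of a
#' typical mobile campaign). Each drive day holds `n_circuits` circuits per
#' vehicle; a circuit traverses the grid in a serpentine
#' (row-by-row, alternating direction) order — so any 15-min window covers a
#' spatially contiguous neighborhood, as a real drive path does — starting
#' from a random point along the loop and in a random direction, emitting
#' `dwell` 1-Hz points per segment at its midpoint (small GPS jitter).
#' A random `rare_frac` of segments is "restricted": visited with
#' probability `rare_prob` per circuit only, so some segments fall below the
#' minimum-visit filter. Point values are the truth at (segment, bin) times
#' mean-1 lognormal noise.
#'
#' @param scene a `synthetic_scene`.
#' @param n_circuits circuits per vehicle per drive day.
#' @param drive_days day indices (1-based) with mobile sampling; default all
#'   weekdays of the campaign.
#' @param vehicles vehicle ids (default two cars).
#' @param noise_cv 1-Hz multiplicative CV; default from the scene config.
#' @param rare_frac,rare_prob restricted-segment fraction and per-circuit
#'   inclusion probability.
#' @param dwell seconds (= 1-Hz points) per segment visit.
#' @param jitter GPS position jitter half-width in meters.
#' @param seed integer seed.
#' @return data.table drive log: `timestamp`, `vehicle_id`, `x`, `y`, one
#'   column per pollutant.
#' @export
sample_mobile <- function(scene, n_circuits = 2L, drive_days = NULL,
                          vehicles = c("GV1", "GV2"), noise_cv = NULL,
                          rare_frac = 0.05, rare_prob = 0.25, dwell = 9L,
                          jitter = 3, seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  cf <- scene$config
  set.seed(derive_seed(seed, "mobile"))
  if (is.null(noise_cv)) noise_cv <- cf$mobile_cv
  if (is.null(drive_days)) drive_days <- which(scene$day_type == "weekday")
  if (any(drive_days < 1L | drive_days > cf$n_days))
    stop("drive schedule outside the campaign period")
  l <- scene$n_segments
  rare <- sample.int(l, round(rare_frac * l))
  window_s <- 7 * 3600  # 09:00-16:00
  slot <- window_s / n_circuits
  sdlog <- sqrt(log(1 + noise_cv^2))
  mid <- scene$segments$midpoint
  p <- cf$p
  # serpentine loop over the segment grid (row-major, alternating direction)
  nx <- ceiling(sqrt(l))
  row <- (seq_len(l) - 1L) %/% nx
  col <- (seq_len(l) - 1L) %% nx
  serp <- order(row, ifelse(row %% 2L == 0L, col, -col))
  out <- vector("list", length(vehicles) * length(drive_days) * n_circuits)
  ii <- 0L
  for (v in vehicles) for (d in drive_days) for (ci in seq_len(n_circuits)) {
    drop <- rare[runif(length(rare)) >= rare_prob]
    route <- serp[!serp %in% drop]
    # random entry point and direction along the loop
    off <- sample.int(length(route), 1L)
    route <- c(route[off:length(route)], route[seq_len(off - 1L)])
    if (runif(1) < 0.5) route <- rev(route)
    segs <- route
    js <- rep(segs, each = dwell)
    npt <- length(js)
    start <- (d - 1L) * 86400 + 9 * 3600 + (ci - 1L) * slot +
      runif(1, 0, max(slot - npt, 1))
    ts <- cf$campaign_start + start + seq_len(npt) - 1
    bin <- time_bin_index(ts, cf$campaign_start, cf$bin_width)
    bin <- pmin(bin, dim(scene$cube)[3])
    conc <- matrix(0, npt, p)
    for (i in seq_len(p))
      conc[, i] <- scene$cube[cbind(i, js, bin)] *
        rlnorm(npt, -sdlog^2 / 2, sdlog)
    ii <- ii + 1L
    out[[ii]] <- data.table::data.table(
      timestamp = ts, vehicle_id = v,
      x = mid[js, 1] + runif(npt, -jitter, jitter),
      y = mid[js, 2] + runif(npt, -jitter, jitter))
    for (i in seq_len(p)) out[[ii]][[scene$pollutants[i]]] <- conc[, i]
  }
  data.table::rbindlist(out[seq_len(ii)])
}

#' Simulate raw fixed-site BC sensor series
#'
#' Draws raw BC samples at each sensor site every `raw_period_s` seconds:
#' truth at the site's location and bin, times mean-1 lognormal noise, plus
#' an additive Gaussian noise floor (which can push low readings negative).
#' Per site, `missing_frac` of the record is removed as a few contiguous
#' gaps, emulating outages.
#'
#' @param scene a `synthetic_scene`.
#' @param noise_cv,floor_sd,missing_frac,raw_period_s override the scene
#'   config values.
#' @param n_gaps number of contiguous outage windows per site.
#' @param seed integer seed.
#' @return data.table raw series: `site_id`, `timestamp`, `bc`.
#' @export
sample_sensors <- function(scene, noise_cv = NULL, floor_sd = NULL,
                           missing_frac = NULL, raw_period_s = NULL,
                           n_gaps = 3L, seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  cf <- scene$config
  set.seed(derive_seed(seed, "sensors"))
  noise_cv <- noise_cv %||% cf$sensor_cv
  floor_sd <- floor_sd %||% cf$sensor_floor_sd
  missing_frac <- missing_frac %||% cf$missing_frac
  raw_period_s <- raw_period_s %||% cf$raw_period_s
  n_raw <- as.integer(cf$n_days * 86400 / raw_period_s)
  offs <- seq_len(n_raw) * raw_period_s - raw_period_s / 2
  ts <- cf$campaign_start + offs
  bin <- time_bin_index(ts, cf$campaign_start, cf$bin_width)
  sdlog <- sqrt(log(1 + noise_cv^2))
  s <- nrow(scene$sites)
  out <- vector("list", s)
  for (si in seq_len(s)) {
    loc <- scene$n_segments + si
    v <- scene$cube[cbind(1L, loc, bin)] *
      rlnorm(n_raw, -sdlog^2 / 2, sdlog) + rnorm(n_raw, 0, floor_sd)
    keep <- rep(TRUE, n_raw)
    if (missing_frac > 0) {
      gap_len <- max(1L, round(missing_frac * n_raw / n_gaps))
      starts <- sample.int(n_raw - gap_len, n_gaps)
      for (g in starts) keep[g:(g + gap_len - 1L)] <- FALSE
    }
    out[[si]] <- data.table::data.table(
      site_id = scene$sites$site_id[si], timestamp = ts[keep],
      bc = v[keep])
  }
  data.table::rbindlist(out)
}
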