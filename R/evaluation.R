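#' Model-evaluation metrics
#'
#' Computes the four summary statistics used throughout the evaluation
#' protocols: Pearson correlation, normalized mean bias
#' `NMB = sum(pred - obs) / sum(obs)`, normalized mean absolute error
#' `NMAE = sum(|pred - obs|) / sum(obs)`, and normalized root-mean-squared
#' error `NRMSE = RMSE / mean(obs)`. All normalized metrics are fractions
#' (multiply by 100 for percent). With a zero-variance series the Pearson
#' correlation is undefined and reported as `NA`; with `sum(obs) == 0` the
#' normalized metrics are `NA`.
#'
#' @param obs,pred equal-length numeric vectors (>= 2 finite pairs).
#' @return object of class `metric_report`: list with `pearson_r`, `nmb`,
#'   `nmae`, `nrmse`, `n`.
#' @export
metrics <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  n <- length(obs)
  if (n < 2L) stop("need at least 2 finite (obs, pred) pairs")
  r <- if (sd(obs) == 0 || sd(pred) == 0) NA_real_ else cor(obs, pred)
  so <- sum(obs)
  if (so == 0) {
    nmb <- nmae <- nrmse <- NA_real_
  } else {
    nmb <- sum(pred - obs) / so
    nmae <- sum(abs(pred - obs)) / so
    nrmse <- sqrt(mean((pred - obs)^2)) / mean(obs)
  }
  structure(list(pearson_r = r, nmb = nmb, nmae = nmae, nrmse = nrmse,
                 n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d: r = %.3f, NMB = %.1f%%, NMAE = %.1f%%, NRMSE = %.1f%%\n",
              x$n, x$pearson_r, 100 * x$nmb, 100 * x$nmae, 100 * x$nrmse))
  invisible(x)
}

field_bin_info <- function(field, campaign_start = NULL, bin_width = NULL) {
  if (is.null(campaign_start)) campaign_start <- field$time_bins[1]
  if (is.null(bin_width))
    bin_width <- as.numeric(difftime(field$time_bins[2], field$time_bins[1],
                                     units = "mins"))
  if (is.null(campaign_start))
    stop("field carries no time coordinates; pass campaign_start/bin_width")
  list(start = campaign_start, width = bin_width)
}

#' Lagrangian comparison of model and mobile measurements
#'
#' Follows the vehicle's sampling path: for each time bin and vehicle, pairs
#' (i) the mean of the measured 1-Hz BC along the route in that window with
#' (ii) the mean of the model's values for the distinct road segments
#' traversed in that window (each segment counted once). Windows with fewer
#' than `min_points` 1-Hz points are dropped.
#'
#' @param points drive-point data.frame (with `timestamp`, `vehicle_id` and
#'   a BC column).
#' @param assignment segment id per point ([snap_to_segments()]).
#' @param field a `bc_field` covering the drive period.
#' @param bc_col name of the BC column in `points`.
#' @param min_points minimum 1-Hz points per window (default 300, i.e. >= 5
#'   min of data).
#' @param campaign_start,bin_width override the field's time coordinates.
#' @return list with `windows` (data.table: `vehicle_id`, `bin`, `measured`,
#'   `predicted`, `n_points`, `n_segments`) and `metrics`
#'   (a `metric_report` over windows).
#' @export
lagrangian_compare <- function(points, assignment, field, bc_col = "bc",
                               min_points = 300L, campaign_start = NULL,
                               bin_width = NULL) {
  bi <- field_bin_info(field, campaign_start, bin_width)
  dt <- data.table::data.table(
    vehicle_id = points$vehicle_id,
    bin = time_bin_index(points$timestamp, bi$start, bi$width),
    segment_id = assignment, bc = points[[bc_col]])
  dt <- dt[!is.na(segment_id) & bin >= 1L & bin <= ncol(field$values)]
  # segments absent from the field (e.g. dropped by the visit filter) carry
  # no model value and cannot enter the comparison
  dt <- dt[segment_id %in% field$locations]
  if (nrow(dt) == 0L) stop("no drive points overlap the field period")
  meas <- dt[, .(measured = mean(bc), n_points = .N), by = .(vehicle_id, bin)]
  loc_idx <- match(dt$segment_id, field$locations)
  dt[, val := field$values[cbind(loc_idx, bin)]]
  pred <- unique(dt, by = c("vehicle_id", "bin", "segment_id"))[
    , .(predicted = mean(val), n_segments = .N), by = .(vehicle_id, bin)]
  w <- merge(meas, pred, by = c("vehicle_id", "bin"))
  w <- w[n_points >= min_points]
  if (nrow(w) < 2L) stop("fewer than 2 Lagrangian windows survive min_points")
  list(windows = w[], metrics = metrics(w$measured, w$predicted))
}

#' Campaign-integrated spatial comparison
#'
#' Compares, per road segment, the campaign-aggregated mobile measurement
#' (median of drive-pass means of BC) with the equivalently aggregated model
#' prediction: the median over the same passes of the model value at
#' (segment, time bin of the pass midpoint).
#'
#' @param pass_means output of [drive_pass_means()] (must carry `t_mid`).
#' @param field a `bc_field`.
#' @param bc_col BC column name in `pass_means`.
#' @param min_visits segment visit filter, as in [median_of_means()].
#' @param campaign_start,bin_width override the field's time coordinates.
#' @return list with `segments` (data.table: `segment_id`, `measured`,
#'   `predicted`, `visit_count`) and `metrics`.
#' @export
campaign_spatial_compare <- function(pass_means, field, bc_col = "bc",
                                     min_visits = 15L,
                                     campaign_start = NULL,
                                     bin_width = NULL) {
  bi <- field_bin_info(field, campaign_start, bin_width)
  pm <- data.table::as.data.table(pass_means)
  pm <- pm[segment_id %in% field$locations]
  if (nrow(pm) == 0L) stop("no passes overlap the field locations")
  pm[, bin := pmin(pmax(time_bin_index(t_mid, bi$start, bi$width), 1L),
                   ncol(field$values))]
  loc_idx <- match(pm$segment_id, field$locations)
  pm[, model_val := field$values[cbind(loc_idx, bin)]]
  agg <- pm[, .(measured = median(get(bc_col)),
                predicted = median(model_val), visit_count = .N),
            by = segment_id]
  agg <- agg[visit_count >= min_visits]
  if (nrow(agg) < 2L) stop("fewer than 2 segments meet the visit threshold")
  list(segments = agg[], metrics = metrics(agg$measured, agg$predicted))
}

# Fit the site-side factorization and reprojection for one training subset
# and return predictions at requested location indices. The pollutant-side
# patterns H_L are shared across subsets, so callers precompute them.
refit_site_subset <- function(H_L, sensor, map_locations, train_ids,
                              q, seed, rcond = 1e-10, nmf_args = list()) {
  X_F <- sensor$values[train_ids, , drop = FALSE]
  q_eff <- min(q, length(train_ids) - 1L)
  smod <- do.call(nmf, c(list(X = X_F, rank = q_eff, seed = seed), nmf_args))
  phi <- build_sampling_matrix(train_ids, map_locations)
  rp <- fit_reprojection(H_L, phi, smod$left, rcond = rcond)
  list(sensor_model = smod, reprojection = rp,
       predict_at = function(loc_idx) {
         v <- t(H_L)[loc_idx, , drop = FALSE] %*% rp$C %*% smod$right
         v[v < 0] <- 0
         v
       })
}

#' Leave-site-out cross-validation of the fusion model
#'
#' Repeatedly holds out a random fraction of sensor sites, refits the
#' site-side factorization and reprojection on the training sites only (the
#' pollutant x location factorization does not depend on the site subset and
#' is fitted once), and scores the reconstructed time series at the held-out
#' sites against their observed bins.
#'
#' @param map extended `segment_map` covering all sites.
#' @param sensor completed `sensor_matrix`.
#' @param k,q factorization ranks.
#' @param holdout_fraction fraction of sites held out per iteration.
#' @param n_iter number of refits (default 50).
#' @param seed integer seed; partitions and fits are reproducible.
#' @param rcond pseudoinverse cutoff.
#' @param nmf_args extra [nmf()] arguments.
#' @return list with `per_site` (data.table: `iter`, `site_id`, `r`, `nmb`,
#'   `nmae`, `nrmse`) and `summary` (median and 10th/90th percentile of each
#'   metric across site-iterations), plus `k`, `q`.
#' @export
leave_sites_out_cv <- function(map, sensor, k = 5L, q = 5L,
                               holdout_fraction = 0.3, n_iter = 50L,
                               seed = 1L, rcond = 1e-10, nmf_args = list()) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  site_ids <- sensor$site_ids
  s <- length(site_ids)
  n_hold <- max(1L, round(holdout_fraction * s))
  if (s - n_hold < k)
    stop(sprintf("training-site count %d < k = %d", s - n_hold, k))
  pmod <- do.call(nmf, c(list(X = map$values, rank = k, seed = seed),
                         nmf_args))
  H_L <- pmod$right
  set.seed(derive_seed(seed, "cv"))
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    hold <- sort(sample.int(s, n_hold))
    train_ids <- site_ids[-hold]
    fit <- refit_site_subset(H_L, sensor, map$locations, train_ids, q,
                             seed = seed, rcond = rcond,
                             nmf_args = nmf_args)
    loc_idx <- match(site_ids[hold], map$locations)
    pred <- fit$predict_at(loc_idx)
    res <- lapply(seq_along(hold), function(j) {
      obs_ok <- sensor$observed_mask[hold[j], ]
      m <- metrics(sensor$values[hold[j], obs_ok], pred[j, obs_ok])
      data.table::data.table(iter = it, site_id = site_ids[hold[j]],
                             r = m$pearson_r, nmb = m$nmb, nmae = m$nmae,
                             nrmse = m$nrmse)
    })
    rows[[it]] <- data.table::rbindlist(res)
  }
  per_site <- data.table::rbindlist(rows)
  qs <- function(v) quantile(v, c(0.1, 0.5, 0.9), na.rm = TRUE)
  summary <- sapply(per_site[, .(r, nmb, nmae, nrmse)], qs)
  rownames(summary) <- c("p10", "median", "p90")
  list(per_site = per_site, summary = summary, k = k, q = q)
}

#' Model performance versus sensor-network size
#'
#' For each training-network size, repeatedly samples that many sites,
#' refits the site-side model, and scores the reconstruction at the
#' remaining (held-out) sites. Sizes smaller than `k` are skipped with a
#' warning; at the full network size the score is necessarily in-sample.
#'
#' @param map,sensor,k,q,seed,rcond,nmf_args as in [leave_sites_out_cv()].
#' @param sizes integer vector of training-network sizes.
#' @param n_iter random subsets per size.
#' @return list with `curve` (data.table: `size`, `r_median`, `r_q25`,
#'   `r_q75`) and `per_iter` (median held-site r per size and iteration).
#' @export
sensitivity_site_count <- function(map, sensor, sizes, k = 5L, q = 5L,
                                   n_iter = 20L, seed = 1L, rcond = 1e-10,
                                   nmf_args = list()) {
  site_ids <- sensor$site_ids
  s <- length(site_ids)
  ok <- sizes >= k & sizes <= s
  if (any(!ok)) warning("skipping network sizes outside [k, n_sites]: ",
                        paste(sizes[!ok], collapse = ", "))
  sizes <- sizes[ok]
  pmod <- nmf(map$values, rank = k, seed = seed)
  H_L <- pmod$right
  set.seed(derive_seed(seed, "sitecount"))
  rows <- list()
  for (sz in sizes) for (it in seq_len(n_iter)) {
    train <- sort(sample.int(s, sz))
    held <- setdiff(seq_len(s), train)
    if (length(held) == 0L) held <- train  # full network: in-sample score
    fit <- refit_site_subset(H_L, sensor, map$locations, site_ids[train], q,
                             seed = seed, rcond = rcond, nmf_args = nmf_args)
    pred <- fit$predict_at(match(site_ids[held], map$locations))
    rvals <- vapply(seq_along(held), function(j) {
      obs_ok <- sensor$observed_mask[held[j], ]
      suppressWarnings(cor(sensor$values[held[j], obs_ok], pred[j, obs_ok]))
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.table::data.table(size = sz, iter = it,
                             r_median = median(rvals, na.rm = TRUE))
  }
  per_iter <- data.table::rbindlist(rows)
  curve <- per_iter[, .(r_median = median(r_median),
                        r_q25 = quantile(r_median, 0.25),
                        r_q75 = quantile(r_median, 0.75)), by = size]
  list(curve = curve[], per_iter = per_iter[])
}

#' Model performance versus number of pollutants
#'
#' Restricts the multipollutant map to random pollutant subsets of each
#' requested size (BC always included), refits the pollutant-side
#' factorization with rank capped at `size - 1`, and scores held-out-site
#' reconstruction as in [leave_sites_out_cv()]. The single-pollutant case is
#' degenerate — the BC map itself is the one spatial pattern (no
#' factorization possible) — and is reported as such.
#'
#' @param map extended `segment_map` (BC among the pollutants).
#' @param sensor completed `sensor_matrix`.
#' @param sizes pollutant-subset sizes (each >= 1).
#' @param k pollutant-side rank cap.
#' @param q site-side rank.
#' @param holdout_fraction held-out site fraction per iteration.
#' @param n_iter random (subset, holdout) draws per size.
#' @param seed,rcond,nmf_args as elsewhere.
#' @return list with `curve` (data.table: `size`, `k_used`, `r_median`,
#'   `r_q25`, `r_q75`) and `per_iter`.
#' @export
sensitivity_pollutant_count <- function(map, sensor, sizes, k = 5L, q = 5L,
                                        holdout_fraction = 0.3,
                                        n_iter = 10L, seed = 1L,
                                        rcond = 1e-10, nmf_args = list()) {
  if (!"bc" %in% map$pollutants)
    stop("the map must include BC among its pollutants")
  p <- length(map$pollutants)
  stopifnot(all(sizes >= 1L), all(sizes <= p))
  others <- setdiff(map$pollutants, "bc")
  site_ids <- sensor$site_ids
  s <- length(site_ids)
  n_hold <- max(1L, round(holdout_fraction * s))
  set.seed(derive_seed(seed, "polcount"))
  rows <- list()
  for (sz in sizes) for (it in seq_len(n_iter)) {
    sub <- c("bc", if (sz > 1L) sample(others, sz - 1L))
    X <- map$values[sub, , drop = FALSE]
    k_eff <- max(1L, min(k, sz - 1L))
    if (sz == 1L) {
      H_L <- X  # single pattern: the BC map itself
    } else {
      H_L <- nmf(X, rank = k_eff, seed = seed)$right
    }
    hold <- sort(sample.int(s, n_hold))
    fit <- refit_site_subset(H_L, sensor, map$locations,
                             site_ids[-hold], q, seed = seed,
                             rcond = rcond, nmf_args = nmf_args)
    pred <- fit$predict_at(match(site_ids[hold], map$locations))
    rvals <- vapply(seq_along(hold), function(j) {
      obs_ok <- sensor$observed_mask[hold[j], ]
      suppressWarnings(cor(sensor$values[hold[j], obs_ok], pred[j, obs_ok]))
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.table::data.table(size = sz, iter = it,
                             k_used = as.integer(k_eff),
                             r_median = median(rvals, na.rm = TRUE))
  }
  per_iter <- data.table::rbindlist(rows)
  curve <- per_iter[, .(k_used = k_used[1], r_median = median(r_median),
                        r_q25 = quantile(r_median, 0.25),
                        r_q75 = quantile(r_median, 0.75)), by = size]
  list(curve = curve[], per_iter = per_iter[])
}

#' Vehicle-holdout evaluation
#'
#' Rebuilds the multipollutant map from the training vehicle(s) only,
#' refits the full fusion, and evaluates the Lagrangian comparison against
#' the held-out vehicle's 1-Hz BC data.
#'
#' @param points drive log with `vehicle_id`.
#' @param assignment segment ids per point.
#' @param segments a `road_segments`.
#' @param sensor completed `sensor_matrix`.
#' @param sites site metadata (`site_id,x,y`).
#' @param held_vehicle vehicle id to hold out.
#' @param min_visits segment visit filter for the training map.
#' @param k,q,seed,rcond passed to [fuse()].
#' @param min_points Lagrangian window threshold.
#' @return list with `metrics`, `windows`, and the fitted `model`.
#' @export
car_holdout <- function(points, assignment, segments, sensor, sites,
                        held_vehicle, min_visits = 15L, k = 5L, q = 5L,
                        seed = 1L, rcond = 1e-10, min_points = 300L) {
  vids <- unique(points$vehicle_id)
  if (!held_vehicle %in% vids)
    stop("held vehicle not present: ", held_vehicle)
  if (length(vids) < 2L) stop("need at least 2 vehicles")
  tr <- points$vehicle_id != held_vehicle
  pm <- drive_pass_means(points[tr, ], assignment[tr])
  map <- median_of_means(pm, min_visits = min_visits, segments = segments)
  model <- fuse(map, sensor, sites = sites, k = k, q = q, seed = seed,
                rcond = rcond)
  ho <- points$vehicle_id == held_vehicle
  lag <- lagrangian_compare(points[ho, ], assignment[ho], model$field,
                            min_points = min_points)
  list(metrics = lag$metrics, windows = lag$windows, model = model)
}

#' Metrics by weekday/weekend and day/night category
#'
#' Splits the time bins into the four categories weekday-day, weekday-night,
#' weekend-day and weekend-night (day defaults to the 09:00-16:00 local
#' window) and computes pooled metrics within each. Bins are labelled by
#' their start time on the local clock. Empty categories are omitted.
#'
#' @param obs,pred site x time matrices (or vectors) of observed and
#'   predicted values.
#' @param time_bins POSIXct bin starts (length = number of time columns).
#' @param day_hours numeric `c(start, end)` of the daytime window (default
#'   `c(9, 16)`).
#' @return named list of `metric_report`s; attribute `"category_sizes"`
#'   gives the bin count per category (the four sizes partition the bins).
#' @export
temporal_subset_report <- function(obs, pred, time_bins,
                                   day_hours = c(9, 16)) {
  if (is.vector(obs)) obs <- matrix(obs, nrow = 1)
  if (is.vector(pred)) pred <- matrix(pred, nrow = 1)
  stopifnot(ncol(obs) == length(time_bins), all(dim(obs) == dim(pred)))
  hr <- as.numeric(format(time_bins, "%H")) +
    as.numeric(format(time_bins, "%M")) / 60
  wkend <- format(time_bins, "%u") %in% c("6", "7")
  is_day <- hr >= day_hours[1] & hr < day_hours[2]
  cats <- list(
    weekday_day = !wkend & is_day, weekday_night = !wkend & !is_day,
    weekend_day = wkend & is_day, weekend_night = wkend & !is_day)
  out <- list()
  for (nm in names(cats)) {
    idx <- cats[[nm]]
    if (sum(idx) == 0L) next
    o <- as.vector(obs[, idx, drop = FALSE])
    p <- as.vector(pred[, idx, drop = FALSE])
    if (length(o) >= 2L) out[[nm]] <- metrics(o, p)
  }
  attr(out, "category_sizes") <- vapply(cats, sum, integer(1))
  out
}

#' Spatially flat reference field
#'
#' Replaces every location's time series with the areawide (location-mean)
#' series — the no-spatial-information baseline against which the fused
#' model's Lagrangian skill is contrasted.
#'
#' @param field a `bc_field`.
#' @return a `bc_field` with identical column means and no spatial contrast.
#' @export
areawide_field <- function(field) {
  m <- colMeans(field$values)
  out <- field
  out$values <- matrix(m, nrow = nrow(field$values),
                       ncol = ncol(field$values), byrow = TRUE)
  rownames(out$values) <- rownames(field$values)
  out
}
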