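test_that("summary metrics match their closed-form definitions", {
  expect_silent(m0 <- metrics(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(m0$pearson_r, 1)
  expect_equal(m0$nmb, 0); expect_equal(m0$nmae, 0); expect_equal(m0$nrmse, 0)

  m1 <- metrics(rep(1, 4), rep(2, 4))
  expect_true(is.na(m1$pearson_r))
  expect_equal(m1$nmb, 1); expect_equal(m1$nmae, 1); expect_equal(m1$nrmse, 1)

  set.seed(100)
  obs <- rlnorm(100); pred <- obs * rlnorm(100, 0, 0.3)
  m <- metrics(obs, pred)
  # independent recomputation from the formulas
  expect_equal(m$pearson_r,
               sum((obs - mean(obs)) * (pred - mean(pred))) /
                 sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2)),
               tolerance = 1e-12)
  expect_equal(m$nmb, (sum(pred) - sum(obs)) / sum(obs), tolerance = 1e-12)
  expect_equal(m$nmae, sum(abs(pred - obs)) / sum(obs), tolerance = 1e-12)
  expect_equal(m$nrmse, sqrt(sum((pred - obs)^2) / 100) / mean(obs),
               tolerance = 1e-12)
  expect_error(metrics(1, 1), "at least 2")
})

make_tiny_field <- function(values, locations, t0, nbins) {
  structure(list(values = values, locations = locations,
                 time_bins = t0 + (seq_len(nbins) - 1) * 900,
                 n_clipped = 0L), class = "bc_field")
}

test_that("Lagrangian windows pair route means with distinct-segment model means", {
  t0 <- as.POSIXct("2017-05-22 09:00:00", tz = "UTC")
  field <- make_tiny_field(matrix(c(2, 4), 2, 4), c("A", "B"), t0, 4)
  # vehicle GV1 alternates between A (model 2) and B (model 4) in window 1;
  # GV2 sits on B for the whole window (second window by vehicle)
  pts <- data.frame(
    timestamp = t0 + rep(0:9, 2),
    vehicle_id = rep(c("GV1", "GV2"), each = 10),
    bc = c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1, rep(2, 10)))
  asg <- c(rep(c("A", "B"), 5), rep("B", 10))
  lag <- suppressWarnings(lagrangian_compare(pts, asg, field,
                                             min_points = 2))
  expect_identical(nrow(lag$windows), 2L)
  w1 <- lag$windows[vehicle_id == "GV1"]
  expect_equal(w1$measured, 3)    # mean of the 1-Hz values
  expect_equal(w1$predicted, 3)   # (2 + 4) / 2, each segment once
  expect_identical(w1$n_segments, 2L)
  # stationary vehicle: predicted equals that segment's model value
  w2 <- lag$windows[vehicle_id == "GV2"]
  expect_equal(w2$predicted, 4)
  expect_identical(w2$n_segments, 1L)

  expect_error(lagrangian_compare(pts, rep("ZZ", 20), field,
                                  min_points = 2), "overlap")
})

test_that("campaign-spatial aggregation uses pass-time model values", {
  t0 <- as.POSIXct("2017-05-22 00:00:00", tz = "UTC")
  # model values for segment A over 6 bins: 1, 5, 3, 9, 9, 9
  field <- make_tiny_field(matrix(c(1, 5, 3, 9, 9, 9), 1, 6,
                                  byrow = TRUE), "A", t0, 6)
  pm <- data.table::data.table(
    segment_id = "A", pass_id = 1:3, vehicle_id = "GV1", n_points = 10L,
    t_mid = t0 + c(450, 1350, 2250),  # bins 1, 2, 3
    bc = c(2, 6, 4))
  # need >= 2 segments for metrics; add a second identical segment
  field2 <- make_tiny_field(rbind(field$values, field$values * 2),
                            c("A", "B"), t0, 6)
  pm2 <- data.table::rbindlist(list(
    pm, data.table::copy(pm)[, `:=`(segment_id = "B", bc = bc * 2)]))
  sp <- campaign_spatial_compare(pm2, field2, min_visits = 3)
  # predicted for A: median(1, 5, 3) = 3; measured median(2, 6, 4) = 4
  expect_equal(sp$segments[segment_id == "A"]$predicted, 3)
  expect_equal(sp$segments[segment_id == "A"]$measured, 4)

  # time-constant field: predicted equals the static value
  fieldc <- make_tiny_field(matrix(7, 2, 6,
                                   dimnames = list(c("A", "B"), NULL)),
                            c("A", "B"), t0, 6)
  spc <- campaign_spatial_compare(pm2, fieldc, min_visits = 3)
  expect_true(all(spc$segments$predicted == 7))
})

test_that("leave-site-out cross-validation is seeded and near-exact on this scene", {
  pl <- default_pipeline()
  cv1 <- leave_sites_out_cv(pl$ext, pl$sm, k = 5, q = 5, n_iter = 3,
                            seed = 21)
  cv2 <- leave_sites_out_cv(pl$ext, pl$sm, k = 5, q = 5, n_iter = 3,
                            seed = 21)
  expect_identical(cv1$per_site, cv2$per_site)
  expect_gt(cv1$summary["median", "r"], 0.8)

  # boundary: a single held-out site is well-defined
  cv3 <- leave_sites_out_cv(pl$ext, pl$sm, k = 5, q = 5,
                            holdout_fraction = 1 / 60, n_iter = 1,
                            seed = 3)
  expect_identical(nrow(cv3$per_site), 1L)
  expect_true(is.finite(cv3$per_site$r))

  expect_error(leave_sites_out_cv(pl$ext, pl$sm, k = 50, q = 5,
                                  holdout_fraction = 0.3, n_iter = 1),
               "training-site count")
})

test_that("performance rises with network size and saturates at the full network", {
  pl <- default_pipeline()
  sc <- sensitivity_site_count(pl$ext, pl$sm, sizes = c(8, 20, 60),
                               k = 5, q = 5, n_iter = 4, seed = 9)
  cv <- sc$curve[order(sc$curve$size)]
  # monotone within one IQR
  iqr <- cv$r_q75 - cv$r_q25
  expect_true(all(diff(cv$r_median) >= -pmax(iqr[-1], iqr[-3])))
  expect_warning(sensitivity_site_count(pl$ext, pl$sm, sizes = c(3, 20),
                                        k = 5, q = 5, n_iter = 1, seed = 1),
                 "skipping")
  # determinism
  sc2 <- sensitivity_site_count(pl$ext, pl$sm, sizes = c(8, 20, 60),
                                k = 5, q = 5, n_iter = 4, seed = 9)
  expect_identical(sc$per_iter, sc2$per_iter)
})

test_that("more pollutants never hurt on a shared-structure scene", {
  pl <- default_pipeline()
  pc <- sensitivity_pollutant_count(pl$ext, pl$sm, sizes = c(1, 2, 4, 6),
                                    k = 5, q = 5, n_iter = 4, seed = 17)
  cv <- pc$curve[order(pc$curve$size)]
  expect_identical(cv$k_used, c(1L, 1L, 3L, 5L))
  # median held-site r non-decreasing from small to full subsets, within IQR
  iqr <- pmax(cv$r_q75 - cv$r_q25, 0.02)
  expect_true(all(diff(cv$r_median) >= -iqr[-1]))
  no_bc <- pl$ext
  no_bc$pollutants <- sub("^bc$", "xx", no_bc$pollutants)
  rownames(no_bc$values) <- no_bc$pollutants
  expect_error(sensitivity_pollutant_count(no_bc, pl$sm, sizes = 2), "BC")
})

test_that("vehicle holdout gives symmetric skill for exchangeable cars", {
  pl <- default_pipeline()
  r <- vapply(c("GV1", "GV2"), function(v)
    car_holdout(pl$pts, pl$asg, pl$scene$segments, pl$sm, pl$scene$sites,
                held_vehicle = v, k = 5, q = 5,
                seed = 7)$metrics$pearson_r, numeric(1))
  expect_true(all(r > 0.7))
  expect_lt(abs(diff(r)), 0.1)
  expect_error(car_holdout(pl$pts, pl$asg, pl$scene$segments, pl$sm,
                           pl$scene$sites, held_vehicle = "nope"),
               "not present")
})

test_that("temporal category masks partition the bins and are scored separately", {
  t0 <- as.POSIXct("2017-05-22 00:00:00", tz = "UTC")  # Monday
  bins <- t0 + (0:959) * 900  # 10 days of 15-min bins
  set.seed(33)
  obs <- matrix(rlnorm(3 * 960), 3)
  pred <- obs * matrix(rlnorm(3 * 960, 0, 0.2), 3)  # stationary noise
  rep_all <- temporal_subset_report(obs, pred, bins)
  sizes <- attr(rep_all, "category_sizes")
  expect_identical(sum(sizes), 960L)
  expect_setequal(names(rep_all),
                  c("weekday_day", "weekday_night", "weekend_day",
                    "weekend_night"))
  rs <- vapply(rep_all, `[[`, numeric(1), "pearson_r")
  expect_lt(diff(range(rs)), 0.05)

  # weekday-only period: weekend categories absent
  rep_wd <- temporal_subset_report(obs[, 1:480], pred[, 1:480], bins[1:480])
  expect_false(any(grepl("weekend", names(rep_wd))))
})

test_that("the fused model out-predicts the areawide-average baseline along routes", {
  pl <- default_pipeline()
  mod <- default_fusion()
  lag_model <- lagrangian_compare(pl$pts, pl$asg, mod$field)
  lag_flat <- lagrangian_compare(pl$pts, pl$asg, areawide_field(mod$field))
  expect_gt(lag_model$metrics$pearson_r, lag_flat$metrics$pearson_r)
})
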