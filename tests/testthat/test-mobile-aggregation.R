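make_two_segments <- function() {
  road_segments(c("A", "B"),
                list(rbind(c(0, 0), c(30, 0)), rbind(c(0, 20), c(30, 20))))
}

test_that("snapping picks the nearest segment with the documented tie-break", {
  segs <- make_two_segments()
  pts <- data.frame(x = c(15, 15, 15), y = c(0, 10, 51))
  asg <- snap_to_segments(pts, segs, max_dist = 30)
  expect_identical(asg[1], "A")       # exactly on A's midpoint
  expect_identical(asg[2], "A")       # equidistant (10 m): lexicographic
  expect_true(is.na(asg[3]))          # 31 m beyond B, > max_dist

  one <- road_segments("only", list(rbind(c(0, 0), c(30, 0))))
  expect_true(is.na(snap_to_segments(data.frame(x = 15, y = 31), one, 30)))
  expect_error(snap_to_segments(pts, road_segments(character(), list())))
})

test_that("pass splitting follows the gap rule and means are exact", {
  t0 <- as.POSIXct("2017-05-22 09:00:00", tz = "UTC")
  pts <- data.frame(
    timestamp = t0 + c(0, 1, 2, 200),
    vehicle_id = "GV1", x = 15, y = 0,
    bc = c(1, 2, 3, 9))
  segs <- road_segments("A", list(rbind(c(0, 0), c(30, 0))))
  asg <- snap_to_segments(pts, segs)
  pm <- drive_pass_means(pts, asg)
  expect_identical(nrow(pm), 2L)          # 120+ s gap starts a new pass
  expect_equal(sort(pm$bc), c(2, 9))      # mean of [1,2,3] and [9]
})

test_that("pass means match a brute-force group-by oracle", {
  set.seed(31)
  n <- 600
  t0 <- as.POSIXct("2017-05-22 09:00:00", tz = "UTC")
  pts <- data.frame(
    timestamp = t0 + cumsum(sample(c(1, 1, 1, 1, 90), n, replace = TRUE)),
    vehicle_id = sample(c("GV1", "GV2"), n, replace = TRUE),
    x = 0, y = 0,
    bc = rlnorm(n), no = rnorm(n, 10, 2))
  asg <- sample(c("S1", "S2", "S3"), n, replace = TRUE)
  pm <- drive_pass_means(pts, asg, pollutants = c("bc", "no"))

  # oracle: explicit loop over time-ordered points per vehicle
  ord <- order(pts$vehicle_id, pts$timestamp)
  v <- pts$vehicle_id[ord]; s <- asg[ord]
  tt <- as.numeric(pts$timestamp[ord])
  pass <- cumsum(c(TRUE, v[-1] != v[-n] | s[-1] != s[-n] |
                     diff(tt) > 60))
  orc <- list()
  for (pid in unique(pass)) {
    i <- which(pass == pid)
    orc[[length(orc) + 1L]] <-
      data.frame(segment_id = s[i[1]],
                 bc = mean(pts$bc[ord][i]), no = mean(pts$no[ord][i]))
  }
  orc <- do.call(rbind, orc)
  expect_identical(nrow(pm), nrow(orc))
  expect_equal(sort(pm$bc), sort(orc$bc), tolerance = 1e-12)
  expect_equal(sort(pm$no), sort(orc$no), tolerance = 1e-12)
})

fake_pass_means <- function(n_seg, passes_per_seg, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_seg), function(i) {
    k <- passes_per_seg[i]
    data.table::data.table(
      segment_id = sprintf("S%03d", i), pass_id = seq_len(k),
      vehicle_id = "GV1",
      t_mid = as.POSIXct("2017-05-22", tz = "UTC") + seq_len(k) * 3600,
      n_points = 5L, bc = rnorm(k, 2), no = rnorm(k, 10))
  })
  data.table::rbindlist(rows)
}

test_that("median-of-means aggregation and the visit filter are exact", {
  pm <- data.table::data.table(
    segment_id = c("S1", "S1"), pass_id = 1:2, vehicle_id = "GV1",
    n_points = 3L, t_mid = Sys.time(), bc = c(2, 4))
  map <- median_of_means(pm, min_visits = 1)
  expect_equal(unname(map$values["bc", "S1"]), 3)  # even-count median

  # 14 passes with a 15-visit floor: segment absent; all dropped errors
  pm14 <- fake_pass_means(2, c(14, 20))
  map2 <- median_of_means(pm14, min_visits = 15)
  expect_false("S001" %in% map2$locations)
  expect_true("S002" %in% map2$locations)
  expect_error(median_of_means(pm14, min_visits = 25), "visit threshold")

  # random fixture vs sort-based oracle
  pmr <- fake_pass_means(50, sample(15:40, 50, replace = TRUE), seed = 77)
  mapr <- median_of_means(pmr, min_visits = 15)
  for (sid in sample(mapr$locations, 8)) {
    v <- pmr[segment_id == sid]$bc
    v_sorted <- sort(v)
    k <- length(v_sorted)
    med <- if (k %% 2 == 1) v_sorted[(k + 1) / 2] else
      (v_sorted[k / 2] + v_sorted[k / 2 + 1]) / 2
    expect_equal(unname(mapr$values["bc", sid]), max(med, 0),
                 tolerance = 1e-12)
  }
})

test_that("the map is complete, order-invariant and homogeneous of degree 1", {
  pmr <- fake_pass_means(30, sample(15:40, 30, replace = TRUE), seed = 5)
  map <- median_of_means(pmr, min_visits = 15)
  expect_false(anyNA(map$values))
  expect_true(all(map$values >= 0))
  expect_true(all(map$visit_counts >= 15))

  shuf <- pmr[sample(nrow(pmr))]
  map2 <- median_of_means(shuf, min_visits = 15)
  expect_equal(map$values[, map$locations], map2$values[, map$locations])

  pm2 <- data.table::copy(pmr)
  pm2[, c("bc", "no") := .(bc * 2, no * 2)]
  map_dbl <- median_of_means(pm2, min_visits = 15)
  # negatives clip at 0 in both, so doubling commutes with the pipeline
  expect_equal(map_dbl$values, 2 * map$values, tolerance = 1e-12)
})

test_that("drive logs, segment GeoJSON and maps round-trip through disk", {
  pl <- default_pipeline()
  td <- tempdir()

  f1 <- file.path(td, "log.csv")
  sub <- head(pl$pts, 500)
  write_drive_log(sub, f1)
  back <- read_drive_log(f1)
  expect_equal(as.numeric(back$timestamp), as.numeric(sub$timestamp))
  expect_equal(back$bc, sub$bc, tolerance = 1e-9)

  f2 <- file.path(td, "segs.geojson")
  write_segments_geojson(pl$scene$segments, f2)
  segs2 <- read_segments_geojson(f2)
  expect_identical(segs2$segment_id, pl$scene$segments$segment_id)
  expect_equal(segs2$midpoint, pl$scene$segments$midpoint,
               tolerance = 1e-9, ignore_attr = TRUE)

  f3 <- file.path(td, "map.csv")
  write_segment_map(pl$map, f3)
  map2 <- read_segment_map(f3)
  expect_identical(map2$locations, pl$map$locations)
  expect_equal(map2$values, pl$map$values, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(map2$visit_counts, pl$map$visit_counts)
})
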