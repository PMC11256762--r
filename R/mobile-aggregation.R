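#' Road segments
#'
#' Builds the road-segment set used for snapping and mapping. Each segment is
#' a planar polyline (typically a single ~30 m edge); a representative point
#' (vertex mean) is kept for kriging and plotting. Coordinates must be in a
#' projected planar system in meters; the package never reprojects.
#'
#' @param segment_id character vector of unique ids.
#' @param geometry list of numeric matrices (vertices x 2), one per segment.
#' @return object of class `road_segments`: list with `segment_id`,
#'   `geometry`, `length` (m), `midpoint` (n x 2 matrix).
#' @export
road_segments <- function(segment_id, geometry) {
  segment_id <- as.character(segment_id)
  if (anyDuplicated(segment_id)) stop("segment ids must be unique")
  if (length(segment_id) != length(geometry))
    stop("one geometry per segment id required")
  len <- vapply(geometry, function(g) {
    g <- as.matrix(g)
    if (nrow(g) < 2L) stop("segment geometry needs >= 2 vertices")
    sum(sqrt(rowSums(diff(g)^2)))
  }, numeric(1))
  if (any(len <= 0)) stop("segment length must be > 0")
  mid <- t(vapply(geometry, function(g) colMeans(as.matrix(g)), numeric(2)))
  structure(list(segment_id = segment_id,
                 geometry = lapply(geometry, as.matrix),
                 length = len, midpoint = mid),
            class = "road_segments")
}

# distance from points (n x 2) to one line segment a-b
dist_point_edge <- function(px, py, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * dx + (py - a[2]) * dy) / l2, 0), 1)
  sqrt((px - (a[1] + t * dx))^2 + (py - (a[2] + t * dy))^2)
}

#' Snap drive points to road segments
#'
#' Assigns each 1-Hz drive point to the nearest segment whose perpendicular
#' (polyline) distance is at most `max_dist`; points farther than `max_dist`
#' from every segment get `NA`. Ties in distance are broken toward the
#' lexicographically smallest `segment_id`. Points and segments must share
#' one planar projection; this is the caller's contract and cannot be
#' detected here.
#'
#' @param points data.frame with columns `x`, `y` (meters).
#' @param segments a `road_segments` object.
#' @param max_dist maximum snap distance in meters (default 30).
#' @return character vector of segment ids (NA where unassigned).
#' @export
snap_to_segments <- function(points, segments, max_dist = 30) {
  stopifnot(inherits(segments, "road_segments"))
  if (length(segments$segment_id) == 0L) stop("empty segment set")
  px <- points$x; py <- points$y
  n <- length(px)
  best_d <- rep(Inf, n)
  best_id <- rep(NA_character_, n)
  ord <- order(segments$segment_id)  # lexicographic first-wins tie-break
  for (s in ord) {
    g <- segments$geometry[[s]]
    d <- rep(Inf, n)
    for (e in seq_len(nrow(g) - 1L))
      d <- pmin(d, dist_point_edge(px, py, g[e, ], g[e + 1L, ]))
    upd <- d < best_d - 1e-9
    best_d[upd] <- d[upd]
    best_id[upd] <- segments$segment_id[s]
  }
  best_id[best_d > max_dist] <- NA_character_
  best_id
}

#' Per-pass mean concentrations
#'
#' Splits each vehicle's snapped point stream into drive passes and averages
#' the 1-Hz concentrations within each pass. A pass is a maximal run of
#' consecutive points from one vehicle on one segment with inter-point time
#' gaps of at most `max_gap` seconds; a vehicle change, a segment change, or
#' a longer gap starts a new pass.
#'
#' @param points data.frame with `timestamp` (POSIXct), `vehicle_id`, and one
#'   numeric column per pollutant.
#' @param assignment segment id per point, from [snap_to_segments()];
#'   unassigned points are dropped.
#' @param pollutants character vector naming the pollutant columns; default:
#'   all numeric columns except `x`/`y`.
#' @param max_gap pass-breaking gap in seconds (default 60).
#' @return data.table with one row per (segment, pass): `segment_id`,
#'   `vehicle_id`, `pass_id`, `t_mid` (pass midpoint time), `n_points`, and
#'   one mean-concentration column per pollutant.
#' @export
drive_pass_means <- function(points, assignment, pollutants = NULL,
                             max_gap = 60) {
  dt <- data.table::as.data.table(points)
  dt[, segment_id := assignment]
  dt <- dt[!is.na(segment_id)]
  if (nrow(dt) == 0L) stop("no points assigned to any segment")
  if (is.null(pollutants)) {
    num <- names(dt)[vapply(dt, is.numeric, logical(1))]
    pollutants <- setdiff(num, c("x", "y"))
  }
  data.table::setorder(dt, vehicle_id, timestamp)
  tnum <- as.numeric(dt$timestamp)
  newpass <- c(TRUE,
               dt$vehicle_id[-1] != dt$vehicle_id[-nrow(dt)] |
                 dt$segment_id[-1] != dt$segment_id[-nrow(dt)] |
                 diff(tnum) > max_gap)
  dt[, pass_id := cumsum(newpass)]
  out <- dt[, c(list(vehicle_id = vehicle_id[1],
                     t_mid = mean(timestamp), n_points = .N),
                lapply(.SD, mean)),
            by = .(segment_id, pass_id), .SDcols = pollutants]
  out[]
}

#' Median-of-drive-pass-mean segment map
#'
#' Aggregates per-pass means to the time-averaged pollutant x segment matrix:
#' for each segment and pollutant, the median over pass means. Segments with
#' fewer than `min_visits` passes (pooled across vehicles) are dropped from
#' the map entirely. Negative medians, which can arise from instrument noise
#' at clean segments, are clipped to 0 and counted — the downstream
#' factorization requires a non-negative matrix.
#'
#' @param pass_means output of [drive_pass_means()].
#' @param min_visits minimum pass count to retain a segment (default 15).
#' @param segments optional `road_segments`; when given, retained segments
#'   are ordered as in `segments` and representative coordinates attached
#'   (needed later for kriging).
#' @param pollutants pollutant columns; default: all numeric columns except
#'   bookkeeping ones.
#' @return object of class `segment_map`: list with `values` (pollutant x
#'   location matrix), `pollutants`, `locations`, `visit_counts`, `coords`
#'   (location x 2 or NULL), `n_clipped`.
#' @export
median_of_means <- function(pass_means, min_visits = 15L, segments = NULL,
                            pollutants = NULL) {
  stopifnot(min_visits >= 1L)
  pm <- data.table::as.data.table(pass_means)
  if (is.null(pollutants))
    pollutants <- setdiff(names(pm)[vapply(pm, is.numeric, logical(1))],
                          c("pass_id", "n_points", "t_mid"))
  med <- pm[, c(list(visit_count = .N),
                lapply(.SD, function(v) median(as.numeric(v)))),
            by = segment_id, .SDcols = pollutants]
  med <- med[visit_count >= min_visits]
  if (nrow(med) == 0L) stop("no segment meets visit threshold")
  coords <- NULL
  if (!is.null(segments)) {
    keep <- segments$segment_id[segments$segment_id %in% med$segment_id]
    med <- med[match(keep, segment_id)]
    coords <- segments$midpoint[match(keep, segments$segment_id), ,
                                drop = FALSE]
  }
  vals <- t(as.matrix(med[, ..pollutants]))
  cl <- clip_nonneg(vals)
  vals <- cl$values
  colnames(vals) <- med$segment_id
  rownames(vals) <- pollutants
  structure(list(values = vals, pollutants = pollutants,
                 locations = med$segment_id,
                 visit_counts = med$visit_count, coords = coords,
                 n_clipped = cl$n_clipped),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("segment_map: %d pollutants x %d locations",
              length(x$pollutants), length(x$locations)))
  if (x$n_clipped > 0) cat(sprintf(" (%d negative cells clipped)", x$n_clipped))
  cat("\n  pollutants:", paste(x$pollutants, collapse = ", "), "\n")
  invisible(x)
}

## ---- external formats ----

#' Drive-log delimited text I/O
#'
#' Drive logs are CSV with header `timestamp,vehicle_id,x,y,<pollutants>`;
#' timestamps ISO-8601 UTC.
#'
#' @param points drive-point data.frame.
#' @param path file path.
#' @return `read_drive_log`: data.frame with POSIXct `timestamp`.
#' @export
write_drive_log <- function(points, path) {
  dt <- data.table::as.data.table(points)
  dt[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_drive_log
#' @export
read_drive_log <- function(path) {
  dt <- data.table::fread(path)
  dt[, timestamp := as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")]
  dt[]
}

#' Road-segment GeoJSON I/O
#'
#' Segments are stored as a GeoJSON FeatureCollection of LineString features
#' with a `segment_id` property, in planar (projected) coordinates.
#'
#' @param segments a `road_segments` object.
#' @param path file path.
#' @return `read_segments_geojson`: a `road_segments` object.
#' @export
write_segments_geojson <- function(segments, path) {
  feats <- lapply(seq_along(segments$segment_id), function(i) {
    list(type = "Feature",
         properties = list(segment_id = segments$segment_id[i]),
         geometry = list(type = "LineString",
                         coordinates = apply(segments$geometry[[i]], 1,
                                             as.list, simplify = FALSE)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_segments_geojson
#' @export
read_segments_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  ids <- vapply(gj$features, function(f) f$properties$segment_id, character(1))
  geom <- lapply(gj$features, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(p) unlist(p)))
    unname(m)
  })
  road_segments(ids, geom)
}

#' Segment-map delimited text I/O
#'
#' One row per location with a `location_id` column, a `visit_count` column,
#' and one column per pollutant.
#'
#' @param map a `segment_map`.
#' @param path file path.
#' @return `read_segment_map`: a `segment_map` (without coordinates).
#' @export
write_segment_map <- function(map, path) {
  dt <- data.table::data.table(location_id = map$locations,
                               visit_count = map$visit_counts)
  for (i in seq_along(map$pollutants))
    dt[[map$pollutants[i]]] <- map$values[i, ]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_segment_map
#' @export
read_segment_map <- function(path) {
  dt <- data.table::fread(path)
  pol <- setdiff(names(dt), c("location_id", "visit_count"))
  vals <- t(as.matrix(dt[, ..pol]))
  colnames(vals) <- dt$location_id
  rownames(vals) <- pol
  structure(list(values = vals, pollutants = pol,
                 locations = dt$location_id,
                 visit_counts = dt$visit_count, coords = NULL,
                 n_clipped = 0L),
            class = "segment_map")
}
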