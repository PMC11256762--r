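#' Bin raw sensor series into a site x time matrix
#'
#' Averages raw fixed-site BC samples into half-open time bins
#' `[start, start + bin_width)` over the campaign, producing the site x time
#' matrix with a mask of observed bins. A bin is kept only if the fraction of
#' expected raw samples present is at least `min_coverage`; otherwise it is
#' missing (to be filled by [impute_gaps()]). Negative raw values — common in
#' low-cost optical BC data — participate in the bin mean, after which bin
#' values are clipped at 0.
#'
#' The expected samples per bin come from each site's median raw sampling
#' interval unless `sample_period` is given.
#'
#' @param raw data.frame with `site_id`, `timestamp` (POSIXct), `bc`.
#' @param sites data.frame with `site_id`, `x`, `y` (order defines matrix
#'   rows); every site must have raw samples.
#' @param campaign_start POSIXct start of the first bin.
#' @param n_days campaign length in days.
#' @param bin_width bin width in minutes; must divide 1440 (default 15).
#' @param min_coverage minimum fraction of expected samples per bin
#'   (default 0.5).
#' @param sample_period nominal raw sampling interval in seconds (optional).
#' @return object of class `sensor_matrix`: list with `values` (site x time,
#'   NA where unobserved), `observed_mask`, `sites`, `site_ids`,
#'   `time_bins` (POSIXct bin starts), `bin_width`, `campaign_start`,
#'   `imputed_fraction` (0 until imputation), `n_clipped`.
#' @export
bin_series <- function(raw, sites, campaign_start, n_days, bin_width = 15L,
                       min_coverage = 0.5, sample_period = NULL) {
  if (1440L %% as.integer(bin_width) != 0L)
    stop("bin_width must divide 1440 minutes")
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]")
  dt <- data.table::as.data.table(raw)
  missing_sites <- setdiff(sites$site_id, unique(dt$site_id))
  if (length(missing_sites))
    stop("site(s) with zero raw samples: ",
         paste(missing_sites, collapse = ", "))
  t_bins <- as.integer(n_days) * (1440L %/% as.integer(bin_width))
  dt[, bin := time_bin_index(timestamp, campaign_start, bin_width)]
  dt <- dt[bin >= 1L & bin <= t_bins]
  agg <- dt[, .(m = mean(bc), n = .N), by = .(site_id, bin)]
  if (is.null(sample_period)) {
    per <- dt[order(timestamp),
              .(dt_s = median(diff(as.numeric(timestamp)))), by = site_id]
  } else {
    per <- data.table::data.table(site_id = sites$site_id,
                                  dt_s = as.numeric(sample_period))
  }
  agg <- merge(agg, per, by = "site_id")
  agg[, expected := (bin_width * 60) / dt_s]
  agg <- agg[n / expected >= min_coverage]
  s <- nrow(sites)
  vals <- matrix(NA_real_, s, t_bins, dimnames = list(sites$site_id, NULL))
  ridx <- match(agg$site_id, sites$site_id)
  vals[cbind(ridx, agg$bin)] <- agg$m
  cl <- clip_nonneg(vals)
  mask <- !is.na(vals)
  time_bins <- campaign_start + seq(0, by = bin_width * 60,
                                    length.out = t_bins)
  structure(list(values = cl$values, observed_mask = mask, sites = sites,
                 site_ids = sites$site_id, time_bins = time_bins,
                 bin_width = as.integer(bin_width),
                 campaign_start = campaign_start,
                 imputed_fraction = setNames(rep(0, s), sites$site_id),
                 n_clipped = cl$n_clipped),
            class = "sensor_matrix")
}

#' Fill gaps in a sensor matrix
#'
#' Completes a binned sensor matrix for factorization: interior gaps are
#' filled by per-site linear interpolation in time; leading and trailing gaps
#' take the site's observed median. Observed cells are untouched. Sites with
#' more than `max_missing` of their bins unobserved are rejected rather than
#' imputed.
#'
#' @param sm a `sensor_matrix` from [bin_series()].
#' @param max_missing maximum tolerated unobserved fraction per site
#'   (default 0.2).
#' @return the completed `sensor_matrix` (no NA cells), with
#'   `imputed_fraction` recording the per-site fill fraction.
#' @export
impute_gaps <- function(sm, max_missing = 0.2) {
  stopifnot(inherits(sm, "sensor_matrix"))
  vals <- sm$values
  miss_frac <- rowMeans(!sm$observed_mask)
  bad <- which(miss_frac > max_missing)
  if (length(bad))
    stop("site(s) below observed-data threshold (",
         sprintf("%.0f%%", 100 * (1 - max_missing)), "): ",
         paste(rownames(vals)[bad], collapse = ", "))
  t_bins <- ncol(vals)
  for (i in seq_len(nrow(vals))) {
    obs <- which(sm$observed_mask[i, ])
    if (length(obs) == t_bins) next
    y <- vals[i, obs]
    filled <- approx(obs, y, xout = seq_len(t_bins), method = "linear",
                     rule = 1)$y
    med <- median(y)
    filled[seq_len(t_bins) < obs[1]] <- med
    filled[seq_len(t_bins) > obs[length(obs)]] <- med
    filled[obs] <- y  # observed cells bit-identical
    vals[i, ] <- filled
  }
  sm$values <- vals
  sm$imputed_fraction <- setNames(miss_frac, rownames(vals))
  sm
}

#' @export
print.sensor_matrix <- function(x, ...) {
  cat(sprintf("sensor_matrix: %d sites x %d bins (%d min)\n",
              nrow(x$values), ncol(x$values), x$bin_width))
  cat(sprintf("  observed %.1f%%, clipped %d negative bin means\n",
              100 * mean(x$observed_mask), x$n_clipped))
  invisible(x)
}

#' Raw sensor series and sensor-matrix I/O
#'
#' Raw series are CSV `site_id,timestamp,bc_ugm3` (ISO-8601 UTC timestamps);
#' site metadata are CSV `site_id,x,y`. A binned matrix round-trips as wide
#' CSV (rows = sites) plus a sidecar `<path>.mask` CSV of the observed mask.
#'
#' @param raw,sites,sm objects to write.
#' @param path file path.
#' @return readers return the corresponding object.
#' @export
write_sensor_series <- function(raw, path) {
  dt <- data.table::as.data.table(raw)
  dt <- dt[, .(site_id,
               timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               bc_ugm3 = bc)]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_sensor_series
#' @export
read_sensor_series <- function(path) {
  dt <- data.table::fread(path)
  dt[, timestamp := as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")]
  data.table::setnames(dt, "bc_ugm3", "bc")
  dt[]
}

#' @rdname write_sensor_series
#' @export
write_sites <- function(sites, path) {
  data.table::fwrite(data.table::as.data.table(sites[, c("site_id", "x", "y")]),
                     path)
  invisible(path)
}

#' @rdname write_sensor_series
#' @export
read_sites <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' @rdname write_sensor_series
#' @export
write_sensor_matrix <- function(sm, path) {
  dt <- data.table::data.table(site_id = rownames(sm$values))
  vals <- data.table::as.data.table(sm$values)
  data.table::setnames(vals, sprintf("bin%04d", seq_len(ncol(sm$values))))
  data.table::fwrite(cbind(dt, vals), path)
  mk <- data.table::as.data.table(sm$observed_mask * 1L)
  data.table::fwrite(cbind(dt, mk), paste0(path, ".mask"))
  meta <- list(bin_width = sm$bin_width,
               campaign_start = format(sm$campaign_start,
                                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sensor_series
#' @export
read_sensor_matrix <- function(path) {
  dt <- data.table::fread(path)
  vals <- as.matrix(dt[, -1])
  rownames(vals) <- dt$site_id
  colnames(vals) <- NULL
  mk <- data.table::fread(paste0(path, ".mask"))
  mask <- as.matrix(mk[, -1]) == 1L
  rownames(mask) <- mk$site_id
  colnames(mask) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  start <- as.POSIXct(meta$campaign_start, format = "%Y-%m-%dT%H:%M:%SZ",
                      tz = "UTC")
  structure(list(values = vals, observed_mask = mask,
                 sites = data.frame(site_id = dt$site_id),
                 site_ids = dt$site_id,
                 time_bins = start + seq(0, by = meta$bin_width * 60,
                                         length.out = ncol(vals)),
                 bin_width = as.integer(meta$bin_width),
                 campaign_start = start,
                 imputed_fraction = setNames(rep(NA_real_, nrow(vals)),
                                             dt$site_id),
                 n_clipped = 0L),
            class = "sensor_matrix")
}
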