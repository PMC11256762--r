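#' Empirical semivariogram
#'
#' Bins all point pairs by separation distance and computes the classical
#' semivariance estimate per bin: `gamma(h) = mean(0.5 * (z_i - z_j)^2)`
#' over pairs whose distance falls in the bin. Empty bins are omitted.
#'
#' @param coords numeric matrix (n x 2) of planar coordinates in meters.
#' @param values numeric vector of length n.
#' @param n_lags number of distance bins.
#' @param max_lag maximum pair distance considered; default half the maximum
#'   pairwise distance.
#' @return list with `lag` (bin centers), `gamma` (semivariances),
#'   `n_pairs` (pair counts), `max_lag`.
#' @export
empirical_variogram <- function(coords, values, n_lags = 15L,
                                max_lag = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points")
  d <- as.matrix(stats::dist(coords))
  dv <- d[upper.tri(d)]
  if (all(dv == 0)) stop("all pairwise distances are zero")
  if (is.null(max_lag)) max_lag <- max(dv) / 2
  if (max_lag <= 0) stop("max_lag must be positive")
  g <- outer(values, values, function(a, b) 0.5 * (a - b)^2)[upper.tri(d)]
  keep <- dv > 0 & dv <= max_lag
  dv <- dv[keep]; g <- g[keep]
  breaks <- seq(0, max_lag, length.out = n_lags + 1L)
  bin <- cut(dv, breaks, include.lowest = TRUE, labels = FALSE)
  lag <- tapply(dv, bin, mean)
  gamma <- tapply(g, bin, mean)
  n_pairs <- tapply(g, bin, length)
  list(lag = as.numeric(lag), gamma = as.numeric(gamma),
       n_pairs = as.integer(n_pairs), max_lag = max_lag)
}

# Semivariance of the three supported model families at distances h > 0.
# `range` is the distance parameter (effective range is ~3*range for the
# exponential model); gamma(0) = 0 by convention.
variogram_gamma <- function(h, kind, nugget, psill, range) {
  s <- switch(kind,
    exponential = 1 - exp(-h / range),
    gaussian    = 1 - exp(-(h / range)^2),
    spherical   = ifelse(h < range,
                         1.5 * h / range - 0.5 * (h / range)^3, 1),
    stop("unknown variogram kind: ", kind))
  out <- nugget + psill * s
  out[h == 0] <- 0
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget, partial sill and range of an exponential, spherical or
#' gaussian semivariogram to an empirical variogram, minimizing the pair-
#' count-weighted squared residuals with box constraints keeping all three
#' parameters non-negative. A small fixed grid of range starting values makes
#' the fit deterministic.
#'
#' @param emp output of [empirical_variogram()].
#' @param kind one of `"exponential"`, `"spherical"`, `"gaussian"`.
#' @return object of class `variogram_model`: list with `kind`, `nugget`,
#'   `psill`, `range`, `wss` (weighted residual sum of squares).
#' @export
fit_variogram <- function(emp, kind = c("exponential", "spherical",
                                        "gaussian")) {
  kind <- match.arg(kind)
  ok <- is.finite(emp$gamma)
  lag <- emp$lag[ok]; gam <- emp$gamma[ok]; w <- emp$n_pairs[ok]
  if (length(lag) < 3L) stop("need at least 3 non-empty lag bins")
  obj <- function(p) {
    sum(w * (variogram_gamma(lag, kind, p[1], p[2], p[3]) - gam)^2)
  }
  n0 <- max(min(gam), 0)
  s0 <- max(max(gam) - n0, 1e-8)
  best <- NULL
  for (r0 in max(lag) * c(0.1, 0.3, 1, 3)) {
    fit <- tryCatch(
      optim(c(n0, s0, r0), obj, method = "L-BFGS-B",
            lower = c(0, 0, max(lag) * 1e-4),
            upper = c(Inf, Inf, max(lag) * 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("variogram optimizer failed; empirical curve: ",
         paste(signif(gam, 4), collapse = ", "))
  structure(list(kind = kind, nugget = best$par[1], psill = best$par[2],
                 range = best$par[3], wss = best$value),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model (%s): nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$kind, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Ordinary kriging
#'
#' Solves the ordinary-kriging system (semivariance form with the
#' unbiasedness constraint enforced by a Lagrange multiplier) for each query
#' point, using the full training set as the neighborhood. With a zero
#' nugget the predictor interpolates the training data exactly. Negative
#' predictions (possible where kriging weights go negative) are clipped to
#' zero and counted.
#'
#' @param coords numeric matrix (n x 2) of training coordinates.
#' @param values numeric vector of n training values.
#' @param model a `variogram_model`.
#' @param query numeric matrix (m x 2) of prediction coordinates.
#' @param clip_negative clip negative predictions at 0 (default TRUE).
#' @return list with `pred` (length m), `var` (kriging variances),
#'   `weights` (n x m matrix), `lagrange` (length m), `n_clipped`.
#' @export
ordinary_krige <- function(coords, values, model, query,
                           clip_negative = TRUE) {
  coords <- as.matrix(coords); query <- as.matrix(query)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 training points")
  dtr <- as.matrix(stats::dist(coords))
  if (any(dtr[upper.tri(dtr)] == 0))
    stop("coincident training points; deduplicate or add jitter")
  A <- matrix(0, n + 1L, n + 1L)
  A[1:n, 1:n] <- variogram_gamma(dtr, model$kind, model$nugget, model$psill,
                                 model$range)
  A[n + 1L, 1:n] <- 1; A[1:n, n + 1L] <- 1
  # cross-distances training -> query
  dq <- sqrt(outer(coords[, 1], query[, 1], "-")^2 +
               outer(coords[, 2], query[, 2], "-")^2)
  B <- rbind(variogram_gamma(dq, model$kind, model$nugget, model$psill,
                             model$range),
             rep(1, nrow(query)))
  sol <- tryCatch(solve(A, B), error = function(e)
    stop("singular kriging system (", conditionMessage(e),
         "); consider jittering coordinates or adding a nugget"))
  wt <- sol[1:n, , drop = FALSE]
  mu <- sol[n + 1L, ]
  pred <- drop(crossprod(wt, values))
  kv <- colSums(wt * B[1:n, , drop = FALSE]) + mu
  n_clipped <- 0L
  if (clip_negative) {
    cl <- clip_nonneg(pred)
    pred <- cl$values; n_clipped <- cl$n_clipped
  }
  list(pred = pred, var = pmax(kv, 0), weights = wt, lagrange = mu,
       n_clipped = n_clipped)
}

#' Extend a segment concentration map to sensor sites by kriging
#'
#' For each pollutant independently: fit a variogram to the segment values
#' and krige them to the sensor-site coordinates, appending the sites to the
#' map's location set. This builds the combined location list
#' (segments + sites) over which the fused field is reconstructed. A site
#' lying within `snap_dist` of a segment's representative point takes that
#' segment's value directly.
#'
#' @param map a `segment_map` (see [median_of_means()]); must carry segment
#'   coordinates in `map$coords`.
#' @param sites data.frame with `site_id`, `x`, `y`.
#' @param kind variogram family, passed to [fit_variogram()].
#' @param n_lags,max_lag passed to [empirical_variogram()].
#' @param snap_dist distance (m) below which a site takes the nearest
#'   segment's value directly.
#' @return a `segment_map` whose locations are the original segments followed
#'   by the site ids, with `variograms` (per-pollutant models) attached.
#' @export
krige_map_to_sites <- function(map, sites, kind = "exponential",
                               n_lags = 15L, max_lag = NULL, snap_dist = 1) {
  stopifnot(inherits(map, "segment_map"), !is.null(map$coords))
  segc <- map$coords
  qxy <- as.matrix(sites[, c("x", "y")])
  p <- length(map$pollutants)
  newv <- matrix(NA_real_, p, nrow(sites))
  vgs <- vector("list", p); names(vgs) <- map$pollutants
  # snap shortcut: site essentially on a segment point
  dmin <- sqrt(outer(qxy[, 1], segc[, 1], "-")^2 +
                 outer(qxy[, 2], segc[, 2], "-")^2)
  near <- apply(dmin, 1, which.min)
  snap <- dmin[cbind(seq_len(nrow(qxy)), near)] < snap_dist
  for (i in seq_len(p)) {
    z <- map$values[i, ]
    emp <- empirical_variogram(segc, z, n_lags = n_lags, max_lag = max_lag)
    vg <- fit_variogram(emp, kind = kind)
    kr <- ordinary_krige(segc, z, vg, qxy)
    newv[i, ] <- kr$pred
    if (any(snap)) newv[i, snap] <- z[near[snap]]
    vgs[[i]] <- vg
  }
  out <- map
  out$values <- cbind(map$values, newv)
  colnames(out$values) <- c(map$locations, sites$site_id)
  out$locations <- c(map$locations, sites$site_id)
  out$coords <- rbind(segc, qxy)
  out$visit_counts <- c(map$visit_counts, rep(NA_integer_, nrow(sites)))
  out$site_ids <- sites$site_id
  out$variograms <- vgs
  out
}

#' Export fitted variograms as JSON
#'
#' @param variograms named list of `variogram_model`s.
#' @param path output JSON path.
#' @export
write_variograms <- function(variograms, path) {
  jsonlite::write_json(lapply(variograms, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
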