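#' Binary sampling matrix
#'
#' Builds the s x l row-selection operator that restricts a location-indexed
#' vector to the sensor sites: row i carries a single 1 in the column of site
#' i's location. Applied to any location x time field it returns the site x
#' time subsample.
#'
#' @param site_ids character vector of site (location) ids, in sensor-matrix
#'   row order.
#' @param locations character vector of the full ordered location set.
#' @return object of class `sampling_matrix`: list with `matrix` (s x l),
#'   `site_order`, `location_order`, `index` (column of each row's 1).
#' @export
build_sampling_matrix <- function(site_ids, locations) {
  idx <- match(site_ids, locations)
  if (anyNA(idx))
    stop("site(s) not present in the location set: ",
         paste(site_ids[is.na(idx)], collapse = ", "))
  s <- length(site_ids); l <- length(locations)
  phi <- matrix(0, s, l)
  phi[cbind(seq_len(s), idx)] <- 1
  structure(list(matrix = phi, site_order = site_ids,
                 location_order = locations, index = idx),
            class = "sampling_matrix")
}

#' Reprojection coefficients linking the two factorizations
#'
#' Solves the least-squares reprojection `C = (Phi H_L^T)^+ W_S`: each column
#' of `C` expresses one time-invariant spatial pattern (a column of `W_S`,
#' from the site x time factorization) as a combination of the k pollutant-
#' invariant spatial patterns (rows of `H_L`, from the pollutant x location
#' factorization), using only the sensor sites where both pattern sets
#' overlap. The pseudoinverse uses an SVD with relative singular-value
#' cutoff `rcond`.
#'
#' @param H_L k x l pollutant-invariant pattern matrix.
#' @param phi a `sampling_matrix`.
#' @param W_S s x q time-invariant pattern matrix.
#' @param rcond relative singular-value cutoff (default 1e-10).
#' @return object of class `reprojection`: list with `C` (k x q), `rcond`,
#'   `effective_rank`, `residual` (Frobenius norm of
#'   `Phi H_L^T C - W_S`), `residual_rel`.
#' @export
fit_reprojection <- function(H_L, phi, W_S, rcond = 1e-10) {
  stopifnot(inherits(phi, "sampling_matrix"))
  A <- t(H_L)[phi$index, , drop = FALSE]  # Phi %*% t(H_L), by row selection
  k <- ncol(A); s <- nrow(A)
  if (s < k)
    warning(sprintf("only %d sites for %d patterns; reprojection fit is underdetermined",
                    s, k))
  if (any(colSums(abs(W_S)) == 0))
    stop("all-zero column(s) in W_S: ",
         paste(which(colSums(abs(W_S)) == 0), collapse = ", "))
  sv <- svd(A)
  eff_rank <- sum(sv$d > rcond * sv$d[1])
  if (eff_rank < k)
    warning(sprintf("Phi H_L^T is rank deficient (effective rank %d < k = %d)",
                    eff_rank, k))
  C <- pinv_sv(A, rcond) %*% W_S
  res <- sqrt(sum((A %*% C - W_S)^2))
  structure(list(C = C, rcond = rcond, effective_rank = eff_rank,
                 residual = res,
                 residual_rel = res / sqrt(sum(W_S^2))),
            class = "reprojection")
}

#' Reconstruct the complete BC field
#'
#' Forms `X_BC = H_L^T C H_T`: the augmented spatial patterns `H_L^T C`
#' (each time-invariant pattern expressed over the full dense location set)
#' multiplied by the characteristic time signals. Negative entries — the
#' reconstruction is unconstrained — are clipped to 0 and counted.
#'
#' @param H_L k x l pollutant-invariant pattern matrix.
#' @param C k x q reprojection coefficients (or a `reprojection` object).
#' @param H_T q x t characteristic time signals.
#' @param locations,time_bins optional labels carried on the result.
#' @param clip_negative clip negatives (default TRUE).
#' @return object of class `bc_field`: list with `values` (l x t),
#'   `augmented_patterns` (l x q), `locations`, `time_bins`, `n_clipped`.
#' @export
reconstruct <- function(H_L, C, H_T, locations = NULL, time_bins = NULL,
                        clip_negative = TRUE) {
  if (inherits(C, "reprojection")) C <- C$C
  if (ncol(t(H_L)) != nrow(C) || ncol(C) != nrow(H_T))
    stop(sprintf("shape mismatch: H_L^T is %d x %d, C is %d x %d, H_T is %d x %d",
                 ncol(H_L), nrow(H_L), nrow(C), ncol(C), nrow(H_T), ncol(H_T)))
  aug <- t(H_L) %*% C          # l x q augmented patterns
  vals <- aug %*% H_T          # l x t
  n_clipped <- 0L
  if (clip_negative) {
    cl <- clip_nonneg(vals)
    vals <- cl$values; n_clipped <- cl$n_clipped
  }
  if (!is.null(locations)) rownames(vals) <- locations
  structure(list(values = vals, augmented_patterns = aug,
                 locations = locations %||% rownames(vals),
                 time_bins = time_bins, n_clipped = n_clipped),
            class = "bc_field")
}

#' @export
print.bc_field <- function(x, ...) {
  cat(sprintf("bc_field: %d locations x %d time bins (ug/m3)",
              nrow(x$values), ncol(x$values)))
  if (x$n_clipped > 0)
    cat(sprintf(", %d negative cells clipped", x$n_clipped))
  cat("\n")
  invisible(x)
}

#' End-to-end fusion of mobile maps and sensor time series
#'
#' Runs the full fusion pipeline: (1) extend the pollutant x segment map to
#' the sensor sites by ordinary kriging (skipped if the map already covers
#' them), so the location set is segments + sites; (2) factorize the
#' pollutant x location matrix at rank `k` and the site x time matrix at
#' rank `q` (ranks may be knee-selected); (3) build the sampling matrix,
#' fit the reprojection coefficients, and reconstruct the complete BC field.
#' All intermediates are retained.
#'
#' `oracle` bypasses the NMF fits with externally supplied factor matrices
#' (`list(H_L =, W_S =, H_T =)`) — a testing hook for exact-recovery checks
#' on synthetic scenes with known latent structure.
#'
#' @param map a `segment_map` (pollutant x segment, or already extended).
#' @param sensor a completed `sensor_matrix`.
#' @param sites data.frame `site_id,x,y`; needed when `map` must be kriged.
#' @param k,q factorization ranks (defaults 5 and 16); `"auto"` selects by
#'   knee point over `k_range` / `q_range`.
#' @param k_range,q_range candidate ranks for `"auto"` selection.
#' @param seed seed for the factorizations.
#' @param rcond pseudoinverse cutoff.
#' @param variogram_kind kriging variogram family.
#' @param oracle optional list with `H_L`, `W_S`, `H_T` to bypass NMF.
#' @param nmf_args extra arguments passed to [nmf()].
#' @return object of class `fusion_model`: list with `map` (extended),
#'   `pollutant_model`, `sensor_model` (factor models or NULL in oracle
#'   mode), `phi`, `reprojection`, `field` (`bc_field`), `k`, `q`, `seed`.
#' @export
fuse <- function(map, sensor, sites = NULL, k = 5L, q = 16L,
                 k_range = 2:9, q_range = 2:40, seed = 1L, rcond = 1e-10,
                 variogram_kind = "exponential", oracle = NULL,
                 nmf_args = list()) {
  stopifnot(inherits(map, "segment_map"), inherits(sensor, "sensor_matrix"))
  if (anyNA(sensor$values))
    stop("stage fusion: sensor matrix has missing cells; run impute_gaps() first")
  site_ids <- sensor$site_ids
  if (!all(site_ids %in% map$locations)) {
    if (is.null(sites))
      stop("stage kriging: map does not cover the sensor sites and no site coordinates given")
    map <- krige_map_to_sites(map, sites, kind = variogram_kind)
  }
  X_M <- map$values
  X_F <- sensor$values
  pm <- sm <- NULL
  rank_curves <- list()
  if (is.null(oracle)) {
    if (identical(k, "auto")) {
      ks <- select_rank_knee(X_M, k_range[k_range < min(dim(X_M))],
                             seed = seed)
      k <- ks$rank; rank_curves$k <- ks[c("ranks", "rel_error")]
      pm <- ks$models[[as.character(k)]]
    } else {
      pm <- do.call(nmf, c(list(X = X_M, rank = k, seed = seed), nmf_args))
    }
    if (identical(q, "auto")) {
      qs <- select_rank_knee(X_F, q_range[q_range < min(dim(X_F))],
                             seed = seed)
      q <- qs$rank; rank_curves$q <- qs[c("ranks", "rel_error")]
      sm <- qs$models[[as.character(q)]]
    } else {
      sm <- do.call(nmf, c(list(X = X_F, rank = q, seed = seed), nmf_args))
    }
    H_L <- pm$right
    W_S <- sm$left
    H_T <- sm$right
  } else {
    H_L <- oracle$H_L; W_S <- oracle$W_S; H_T <- oracle$H_T
    if (!is.null(oracle$locations)) {
      # align oracle patterns with the map's (possibly filtered) locations
      li <- match(map$locations, oracle$locations)
      if (anyNA(li)) stop("oracle factors do not cover all map locations")
      H_L <- H_L[, li, drop = FALSE]
    }
    if (ncol(H_L) != length(map$locations))
      stop("oracle H_L does not match the map's location set")
    k <- nrow(H_L); q <- ncol(W_S)
  }
  phi <- build_sampling_matrix(site_ids, map$locations)
  rp <- fit_reprojection(H_L, phi, W_S, rcond = rcond)
  field <- reconstruct(H_L, rp, H_T, locations = map$locations,
                       time_bins = sensor$time_bins)
  structure(list(map = map, pollutant_model = pm, sensor_model = sm,
                 phi = phi, reprojection = rp, field = field,
                 k = as.integer(k), q = as.integer(q),
                 seed = as.integer(seed), rank_curves = rank_curves,
                 oracle_mode = !is.null(oracle)),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("fusion_model: k = %d, q = %d%s\n", x$k, x$q,
              if (x$oracle_mode) " (oracle factors)" else ""))
  cat(sprintf("  reprojection residual (relative) %.4g, effective rank %d\n",
              x$reprojection$residual_rel, x$reprojection$effective_rank))
  print(x$field)
  invisible(x)
}

#' BC-field I/O
#'
#' Writes the reconstructed field as wide CSV (rows = locations, one column
#' per time bin) with a JSON manifest carrying the time coordinates.
#'
#' @param field a `bc_field`.
#' @param path file path for the CSV; manifest goes to `<path>.json`.
#' @return `read_bc_field`: a `bc_field`.
#' @export
write_bc_field <- function(field, path) {
  dt <- data.table::data.table(location_id = field$locations)
  vals <- data.table::as.data.table(field$values)
  data.table::setnames(vals, sprintf("bin%04d", seq_len(ncol(field$values))))
  data.table::fwrite(cbind(dt, vals), path)
  meta <- list(n_clipped = field$n_clipped,
               time_bins = if (!is.null(field$time_bins))
                 format(field$time_bins, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bc_field
#' @export
read_bc_field <- function(path) {
  dt <- data.table::fread(path)
  vals <- as.matrix(dt[, -1])
  rownames(vals) <- dt$location_id
  colnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tb <- NULL
  if (!is.null(meta$time_bins))
    tb <- as.POSIXct(meta$time_bins, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  structure(list(values = vals, augmented_patterns = NULL,
                 locations = dt$location_id, time_bins = tb,
                 n_clipped = meta$n_clipped %||% 0L),
            class = "bc_field")
}
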