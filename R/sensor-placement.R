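#' Pivoted-QR sensor placement
#'
#' Greedy data-driven placement in the compressive-sensing style: given a
#' basis of r spatial modes over candidate locations (rows), a
#' column-pivoted QR factorization of the basis transpose ranks locations by
#' how much they constrain the basis (a greedy determinant surrogate). The
#' first `m` pivots are the chosen locations. With `m > ncol(basis)` the
#' caller should pad the basis with further singular vectors; the LAPACK
#' pivot order over all columns is still returned deterministically.
#'
#' @param basis numeric matrix, locations x r (e.g. leading left singular
#'   vectors of a location x time data matrix).
#' @param m number of locations to select.
#' @return object of class `placement_result`: list with `selected`
#'   (indices, in selection order), `m`, `r` (basis columns used),
#'   `pivot` (full pivot order).
#' @export
qr_pivot_select <- function(basis, m) {
  basis <- as.matrix(basis)
  n_loc <- nrow(basis)
  if (m > n_loc) stop("m exceeds the number of candidate locations")
  r_use <- min(m, ncol(basis))
  qrp <- qr(t(basis[, seq_len(r_use), drop = FALSE]), LAPACK = TRUE)
  pivot <- qrp$pivot
  structure(list(selected = pivot[seq_len(m)], m = as.integer(m),
                 r = as.integer(r_use), pivot = pivot),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("placement_result: %d locations selected from a %d-mode basis\n",
              x$m, x$r))
  cat("  order:", paste(head(x$selected, 10), collapse = ", "),
      if (x$m > 10) "...", "\n")
  invisible(x)
}

#' Optimal-versus-random sensor-placement benchmark
#'
#' Compares QR-pivot placement against random placement on a synthetic
#' scene: for each network size m, the fusion model is refitted using only
#' the chosen (resp. randomly drawn) sensor sites, and the reconstructed BC
#' field is scored against the known truth at the non-sensor locations
#' (relative Frobenius error). The placement basis is taken from the SVD of
#' the all-sites model's reconstructed field, restricted to the candidate
#' site rows. Also reports the smallest m at which each strategy matches the
#' all-sites model within `match_tol` relative error.
#'
#' @param map extended `segment_map` covering all candidate sites.
#' @param sensor completed `sensor_matrix` (all candidate sites).
#' @param truth location x time matrix of true BC over `map$locations`.
#' @param m_values network sizes to evaluate (each >= 2).
#' @param n_random random placements per size.
#' @param k,q factorization ranks (q is capped at m - 1 for small m).
#' @param seed integer seed.
#' @param rcond,nmf_args as elsewhere.
#' @param match_tol relative margin over the full-model error defining
#'   "matches full-model performance" (default 0.5: the reconstruction-error
#'   floor is dominated by sensor noise, so matching is judged on the scale
#'   of the placement-induced error spread, not the floor itself).
#' @return list with `m_values`, `optimal_error`, `random_error`
#'   (length(m) x n_random matrix), `full_error`, `crossover_optimal`,
#'   `crossover_random` (NA if never reached), `selection` (site indices in
#'   pivot order), `basis_rank`.
#' @export
placement_benchmark <- function(map, sensor, truth, m_values,
                                n_random = 20L, k = 5L, q = 5L, seed = 1L,
                                rcond = 1e-10, nmf_args = list(),
                                match_tol = 0.5) {
  site_ids <- sensor$site_ids
  s <- length(site_ids)
  stopifnot(all(m_values >= 2L), all(m_values <= s))
  m_values <- sort(unique(as.integer(m_values)))
  pmod <- do.call(nmf, c(list(X = map$values, rank = k, seed = seed),
                         nmf_args))
  H_L <- pmod$right
  seg_idx <- which(!map$locations %in% site_ids)
  truth_seg <- truth[seg_idx, , drop = FALSE]
  nrm <- sqrt(sum(truth_seg^2))

  fit_err <- function(ids) {
    fit <- refit_site_subset(H_L, sensor, map$locations, ids,
                             q = min(q, length(ids) - 1L), seed = seed,
                             rcond = rcond, nmf_args = nmf_args)
    pred <- fit$predict_at(seg_idx)
    sqrt(sum((pred - truth_seg)^2)) / nrm
  }

  full_error <- fit_err(site_ids)
  # placement basis: left singular vectors of the all-sites model field,
  # evaluated at the candidate site rows
  full_fit <- refit_site_subset(H_L, sensor, map$locations, site_ids,
                                q = q, seed = seed, rcond = rcond,
                                nmf_args = nmf_args)
  field_full <- full_fit$predict_at(seq_along(map$locations))
  sv <- svd(field_full)
  r_basis <- min(max(m_values), s, sum(sv$d > 1e-8 * sv$d[1]))
  # singular-value weighting: pivots respect field energy, so directions
  # beyond the numerical rank cannot drive the selection
  basis <- sv$u[match(site_ids, map$locations), seq_len(r_basis),
                drop = FALSE] %*% diag(sv$d[seq_len(r_basis)], r_basis)

  sel <- qr_pivot_select(basis, max(m_values))
  set.seed(derive_seed(seed, "placement"))
  opt_err <- numeric(length(m_values))
  rnd_err <- matrix(NA_real_, length(m_values), n_random)
  for (i in seq_along(m_values)) {
    m <- m_values[i]
    opt_err[i] <- fit_err(site_ids[sel$selected[seq_len(m)]])
    for (j in seq_len(n_random))
      rnd_err[i, j] <- fit_err(site_ids[sample.int(s, m)])
  }
  crossover <- function(errs) {
    hit <- which(errs <= full_error * (1 + match_tol))
    if (length(hit)) m_values[min(hit)] else NA_integer_
  }
  list(m_values = m_values, optimal_error = opt_err,
       random_error = rnd_err, full_error = full_error,
       crossover_optimal = crossover(opt_err),
       crossover_random = crossover(apply(rnd_err, 1, median)),
       selection = sel$selected, basis_rank = r_basis)
}

#' Export a placement result
#'
#' Writes the ranked site ids as delimited text and the scalar metadata as
#' JSON.
#'
#' @param result a `placement_result`.
#' @param site_ids character ids of the candidate locations.
#' @param path output path for the TSV; metadata goes to `<path>.json`.
#' @export
write_placement <- function(result, site_ids, path) {
  data.table::fwrite(
    data.table::data.table(rank = seq_len(result$m),
                           site_id = site_ids[result$selected]),
    path, sep = "\t")
  jsonlite::write_json(list(m = result$m, r = result$r),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
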