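#' Non-negative matrix factorization with multiplicative updates
#'
#' Factorizes a non-negative matrix `X` (m x n) as `W %*% H` with
#' `W >= 0` (m x rank) and `H >= 0` (rank x n), minimizing the Frobenius
#' loss `||X - WH||_F`. Initialization is a deterministic non-negative
#' double-SVD (NNDSVD) scheme with zero entries replaced by a small
#' data-scaled constant, so repeated calls with the same inputs are
#' bit-identical; `seed` only affects the optional random perturbation used
#' when `init = "random"`.
#'
#' Used on both systems of the fusion model: the pollutant x location matrix
#' (spatial source patterns) and the site x time matrix (characteristic time
#' signals and their spatial loadings).
#'
#' @param X non-negative numeric matrix, no missing values.
#' @param rank integer factorization rank, `1 <= rank <= min(dim(X))`.
#' @param seed integer seed (used only by random initialization).
#' @param tol relative change in Frobenius loss at which to stop.
#' @param max_iter maximum multiplicative-update iterations.
#' @param init `"nndsvd"` (deterministic, default) or `"random"`.
#' @return An object of class `factor_model`: list with `left` (W), `right`
#'   (H), `rank`, `objective_trace` (Frobenius loss per iteration, starting
#'   at the initialization), `seed`, `converged`, `iterations`.
#' @export
nmf <- function(X, rank, seed = 1L, tol = 1e-6, max_iter = 2000L,
                init = c("nndsvd", "random")) {
  init <- match.arg(init)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; NMF input must be complete")
  if (any(X < 0)) stop("X contains negative entries; NMF requires X >= 0")
  m <- nrow(X); n <- ncol(X)
  if (rank < 1 || rank > min(m, n))
    stop(sprintf("rank must satisfy 1 <= rank <= min(dim(X)) = %d", min(m, n)))

  if (init == "nndsvd") {
    WH <- nndsvd_init(X, rank)
  } else {
    set.seed(as.integer(seed))
    sc <- sqrt(mean(X) / rank)
    WH <- list(W = matrix(runif(m * rank), m) * sc,
               H = matrix(runif(rank * n), rank) * sc)
  }
  W <- WH$W; H <- WH$H
  eps <- 1e-12
  loss <- function(W, H) sqrt(sum((X - W %*% H)^2))
  trace <- numeric(max_iter + 1L)
  trace[1L] <- loss(W, H)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # Lee-Seung multiplicative updates for the Frobenius objective
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    trace[it + 1L] <- loss(W, H)
    rel <- abs(trace[it] - trace[it + 1L]) / max(trace[it], eps)
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(list(left = W, right = H, rank = as.integer(rank),
                 objective_trace = trace[seq_len(it + 1L)],
                 seed = as.integer(seed), converged = converged,
                 iterations = it),
            class = "factor_model")
}

# Deterministic NNDSVD initialization (Boutsidis & Gallopoulos), "a" variant:
# structurally zero entries are replaced by mean(X)/100 so multiplicative
# updates can move every entry.
nndsvd_init <- function(X, rank) {
  sv <- svd(X, nu = rank, nv = rank)
  m <- nrow(X); n <- ncol(X)
  W <- matrix(0, m, rank); H <- matrix(0, rank, n)
  # leading singular triplet is non-negative up to sign for X >= 0
  u1 <- sv$u[, 1]; v1 <- sv$v[, 1]
  if (sum(u1) < 0) { u1 <- -u1; v1 <- -v1 }
  W[, 1] <- sqrt(sv$d[1]) * abs(u1)
  H[1, ] <- sqrt(sv$d[1]) * abs(v1)
  if (rank > 1) {
    for (j in 2:rank) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  fill <- mean(X) / 100
  W[W <= 0] <- fill
  H[H <= 0] <- fill
  list(W = W, H = H)
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d x %d = (%d x %d)(%d x %d), rank %d\n",
              nrow(x$left), ncol(x$right), nrow(x$left), x$rank, x$rank,
              ncol(x$right), x$rank))
  cat(sprintf("  final Frobenius loss %.6g after %d iterations (%s)\n",
              tail(x$objective_trace, 1), x$iterations,
              if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  invisible(x)
}

#' Knee-point selection of the factorization rank
#'
#' Fits [nmf()] at each candidate rank, forms the relative Frobenius
#' reconstruction-error curve, and picks the knee as the point of maximum
#' perpendicular distance from the chord joining the curve's endpoints
#' (computed on the axis-normalized curve). With both curve endpoints on the
#' chord, a degenerate (near-linear) curve has no interior knee; the result
#' is then flagged `no_clear_knee` and the first candidate is returned.
#'
#' @param X non-negative matrix.
#' @param ranks increasing integer vector of candidate ranks (>= 4 values).
#' @param seed passed to each [nmf()] fit.
#' @param ... further arguments to [nmf()] (e.g. `tol`, `max_iter`).
#' @return list with `rank` (chosen), `ranks`, `rel_error` (curve),
#'   `distance` (chord distances), `no_clear_knee` flag, `models`
#'   (the fitted `factor_model`s, named by rank).
#' @export
select_rank_knee <- function(X, ranks, seed = 1L, ...) {
  ranks <- as.integer(ranks)
  if (length(ranks) < 4L) stop("need at least 4 candidate ranks")
  if (is.unsorted(ranks, strictly = TRUE)) stop("ranks must be increasing")
  nX <- sqrt(sum(X^2))
  models <- lapply(ranks, function(r) nmf(X, rank = r, seed = seed, ...))
  names(models) <- ranks
  err <- vapply(models, function(mod) tail(mod$objective_trace, 1) / nX,
                numeric(1))
  if (any(diff(err) > 1e-4 * err[1]))
    warning("reconstruction-error curve is not monotone non-increasing; ",
            "knee computed on the observed curve")
  kn <- knee_point(ranks, err)
  list(rank = ranks[kn$index], ranks = ranks, rel_error = unname(err),
       distance = kn$distance, no_clear_knee = kn$degenerate,
       models = models)
}

# Max-distance-to-chord knee finder on a normalized curve (Kneedle-style).
knee_point <- function(x, y) {
  rx <- diff(range(x)); ry <- diff(range(y))
  if (ry <= 0) return(list(index = 1L, distance = rep(0, length(x)),
                           degenerate = TRUE))
  xn <- (x - min(x)) / rx
  yn <- (y - min(y)) / ry
  x1 <- xn[1]; y1 <- yn[1]; x2 <- tail(xn, 1); y2 <- tail(yn, 1)
  # distance from (xn, yn) to the chord through endpoints
  d <- abs((y2 - y1) * xn - (x2 - x1) * yn + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  i <- which.max(d)
  degenerate <- d[i] < 1e-9 || i == 1L || i == length(x)
  list(index = i, distance = d, degenerate = degenerate)
}

#' Rescale an NMF factor pair without changing the product
#'
#' Applies a positive diagonal rescaling `W -> W D^{-1}`, `H -> D H` so that
#' under the default convention each column of the left factor sums to 1
#' (the left factor then reads as fractional abundances, the right factor as
#' pattern concentrations). The product `W %*% H` is unchanged to machine
#' precision, and the downstream fused field is invariant to this choice.
#'
#' @param model a `factor_model`.
#' @param convention `"left_colsum1"` (default) or `"right_rowsum1"`.
#' @return a rescaled `factor_model`.
#' @export
normalize_factors <- function(model,
                              convention = c("left_colsum1", "right_rowsum1")) {
  convention <- match.arg(convention)
  W <- model$left; H <- model$right
  if (convention == "left_colsum1") {
    d <- colSums(W)
    bad <- which(d <= 0)
    if (length(bad))
      stop("left factor column(s) ", paste(bad, collapse = ", "),
           " sum to zero; cannot normalize")
    W <- sweep(W, 2, d, "/")
    H <- H * d
  } else {
    d <- rowSums(H)
    bad <- which(d <= 0)
    if (length(bad))
      stop("right factor row(s) ", paste(bad, collapse = ", "),
           " sum to zero; cannot normalize")
    H <- H / d
    W <- sweep(W, 2, d, "*")
  }
  model$left <- W; model$right <- H
  model
}

#' Write / read a factor model as delimited text plus JSON metadata
#'
#' Serializes the two factor matrices as TSV files (`<stem>_left.tsv`,
#' `<stem>_right.tsv`) and the scalar fields as `<stem>_meta.json`.
#'
#' @param model a `factor_model`.
#' @param stem file path stem (no extension).
#' @return `write_factor_model`: the stem, invisibly. `read_factor_model`:
#'   the reconstructed `factor_model`.
#' @export
write_factor_model <- function(model, stem) {
  data.table::fwrite(data.table::as.data.table(model$left),
                     paste0(stem, "_left.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(model$right),
                     paste0(stem, "_right.tsv"), sep = "\t")
  meta <- list(rank = model$rank, seed = model$seed,
               converged = model$converged, iterations = model$iterations,
               objective_trace = model$objective_trace)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(stem) {
  W <- as.matrix(data.table::fread(paste0(stem, "_left.tsv")))
  H <- as.matrix(data.table::fread(paste0(stem, "_right.tsv")))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  structure(list(left = unname(W), right = unname(H),
                 rank = as.integer(meta$rank), seed = as.integer(meta$seed),
                 converged = meta$converged, iterations = meta$iterations,
                 objective_trace = meta$objective_trace),
            class = "factor_model")
}
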