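#' @importFrom stats cor median optim quantile rbinom rgamma rlnorm rnorm runif sd approx setNames
#' @importFrom utils head tail
#' @import data.table
NULL

.datatable.aware <- TRUE

# Moore-Penrose pseudoinverse via SVD with a relative singular-value cutoff.
# Singular values below rcond * max(sv) are treated as zero.
pinv_sv <- function(A, rcond = 1e-10) {
  stopifnot(is.matrix(A), all(is.finite(A)))
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# Clip a numeric object at zero, returning the clipped object and the count of
# altered entries (concentrations are physical; instrument noise and
# unconstrained reconstruction can both produce negatives).
clip_nonneg <- function(x) {
  neg <- which(x < 0)
  x[neg] <- 0
  list(values = x, n_clipped = length(neg))
}

# Derive a stage seed from a root seed so that independent pipeline stages
# draw from independent, reproducible streams. Kept below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Index of the time bin (1-based) containing each POSIXct instant, given the
# campaign start and bin width in minutes. Bins are half-open [start, start+w).
time_bin_index <- function(times, campaign_start, bin_width) {
  idx <- floor(as.numeric(difftime(times, campaign_start, units = "mins")) /
                 bin_width) + 1L
  as.integer(idx)
}
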