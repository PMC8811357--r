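#' @useDynLib cmbselect, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm kmeans quantile glm binomial plogis predict rnorm
#'   runif sd
#' @importFrom utils head write.csv read.csv
NULL

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so nested seeded generators do not perturb each other.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Derive a stream-specific 31-bit seed from a base seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647)
}

# Separable 2-D convolution with replicate (nearest-edge) padding.
conv_sep2d <- function(m, kx, ky) {
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  if (rx > 0L) {
    pad <- m[c(rep(1L, rx), seq_len(n), rep(n, rx)), , drop = FALSE]
    out <- matrix(0, n, p)
    for (t in seq_along(kx))
      out <- out + kx[t] * pad[(t - 1L) + seq_len(n), , drop = FALSE]
    m <- out
  }
  if (ry > 0L) {
    pad <- m[, c(rep(1L, ry), seq_len(p), rep(p, ry)), drop = FALSE]
    out <- matrix(0, n, p)
    for (t in seq_along(ky))
      out <- out + ky[t] * pad[, (t - 1L) + seq_len(p), drop = FALSE]
    m <- out
  }
  m
}

# Gaussian and Gaussian-derivative kernels (order 0, 1, 2), sampled on an
# integer grid of half-width ceiling(3.5 sigma).
gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  x <- seq.int(-r, r)
  g <- dnorm(x, sd = sigma)
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -(x / sigma^2) * g
    return(k - mean(k))            # zero response to constants
  }
  if (order == 2L) {
    k <- ((x^2 - sigma^2) / sigma^4) * g
    return(k - mean(k))
  }
  stop("unsupported derivative order")
}

# Apply a function slice-by-slice along the third axis of a 3-D array.
apply_slices <- function(vol, fun, ...) {
  out <- vol
  for (k in seq_len(dim(vol)[3]))
    out[, , k] <- fun(vol[, , k], ...)
  out
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
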