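#' @useDynLib puvfcd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd cov dnorm
#' @importFrom utils read.csv write.csv
NULL

# Run code with a temporary RNG state seeded by `seed`; restores the caller's
# stream afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed below 2^31 from a base seed and a stream label.
child_seed <- function(seed, stream) {
  s <- (as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483629
  as.integer(s) + 1L
}

# Shift a 3D array by (dx,dy,dz), filling vacated entries with `fill`.
shift_array <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  src_x <- sx - dx; src_y <- sy - dy; src_z <- sz - dz
  kx <- src_x >= 1 & src_x <= d[1]
  ky <- src_y >= 1 & src_y <= d[2]
  kz <- src_z >= 1 & src_z <= d[3]
  out[sx[kx], sy[ky], sz[kz]] <- a[src_x[kx], src_y[ky], src_z[kz]]
  out
}

# Separable convolution of a 3D array with one odd-length 1D kernel per axis,
# zero padding. If `renormalize`, divides by the convolution of an all-ones
# array so truncated boundary windows are renormalized (constants stay
# constant).
separable_conv3d <- function(a, kernels, renormalize = TRUE) {
  stopifnot(length(kernels) == 3L)
  conv_axis <- function(x, k, axis) {
    r <- (length(k) - 1L) %/% 2L
    out <- array(0, dim = dim(x))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      sh <- switch(axis,
                   shift_array(x, off, 0L, 0L),
                   shift_array(x, 0L, off, 0L),
                   shift_array(x, 0L, 0L, off))
      out <- out + k[j] * sh
    }
    out
  }
  res <- a
  for (ax in 1:3) res <- conv_axis(res, kernels[[ax]], ax)
  if (renormalize) {
    ones <- array(1, dim = dim(a))
    w <- ones
    for (ax in 1:3) w <- conv_axis(w, kernels[[ax]], ax)
    res <- res / w
  }
  res
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# Exact Euclidean distance (mm) from every voxel to the nearest TRUE site.
distance_to <- function(sites, spacing) {
  stopifnot(length(dim(sites)) == 3L, any(sites))
  .cpp_edt3d(as.logical(sites), as.integer(dim(sites)), as.numeric(spacing))
}

# Moving-sum box filter (edge^3 window) and matching per-voxel window sizes.
box_sum3d <- function(a, edge) {
  stopifnot(edge >= 1L, edge %% 2L == 1L)
  k <- rep(1, edge)
  conv <- function(x) {
    r <- (edge - 1L) %/% 2L
    for (ax in 1:3) {
      acc <- array(0, dim = dim(x))
      for (off in seq(-r, r)) {
        acc <- acc + switch(ax,
                            shift_array(x, off, 0L, 0L),
                            shift_array(x, 0L, off, 0L),
                            shift_array(x, 0L, 0L, off))
      }
      x <- acc
    }
    x
  }
  conv(a)
}

box_count3d <- function(dims, edge) {
  box_sum3d(array(1, dim = dims), edge)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
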