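# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Shift an array along one dimension, replicating edge values.
#' @noRd
shift_replicate <- function(a, offset, along) {
  d <- dim(a)
  n <- d[along]
  idx <- pmin.int(pmax.int(seq_len(n) + offset, 1L), n)
  if (length(d) == 2L) {
    if (along == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
  } else if (length(d) == 3L) {
    if (along == 1L) {
      a[idx, , , drop = FALSE]
    } else if (along == 2L) {
      a[, idx, , drop = FALSE]
    } else {
      a[, , idx, drop = FALSE]
    }
  } else {
    stop("only 2-D and 3-D arrays are supported")
  }
}

# Separable convolution along one dimension with edge replication.
#' @noRd
convolve_along <- function(a, k, along) {
  nk <- length(k)
  if (nk == 1L) return(a)
  r <- (nk - 1L) %/% 2L
  out <- array(0, dim(a))
  for (j in seq_len(nk)) {
    out <- out + k[j] * shift_replicate(a, j - r - 1L, along)
  }
  out
}

#' @noRd
gaussian_smooth_array <- function(a, sigma) {
  k <- gauss_kernel(sigma)
  for (ax in seq_along(dim(a))) a <- convolve_along(a, k, ax)
  a
}

# Central-difference spatial gradient along one dimension (edge replicated,
# so boundary estimates reduce to half the one-sided difference).
#' @noRd
axis_gradient <- function(a, along) {
  (shift_replicate(a, 1L, along) - shift_replicate(a, -1L, along)) / 2
}

# Nearest-voxel index for continuous positions: half-up rounding so the
# convention is deterministic and direction-free (voxel centres at integers).
#' @noRd
nearest_voxel <- function(pos) {
  floor(pos + 0.5)
}

# Column-major flat index for an n x d matrix of (in-bounds) voxel indices.
#' @noRd
flat_index <- function(vox, shape) {
  f <- vox[, 1L]
  mult <- 1
  for (k in seq_along(shape)[-1L]) {
    mult <- mult * shape[k - 1L]
    f <- f + (vox[, k] - 1) * mult
  }
  f
}

#' @noRd
voxel_in_bounds <- function(vox, shape) {
  ok <- rep(TRUE, nrow(vox))
  for (k in seq_along(shape)) {
    ok <- ok & vox[, k] >= 1 & vox[, k] <= shape[k]
  }
  ok
}

#' @noRd
as_position_matrix <- function(pos, dim = NULL) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
  if (!is.null(dim) && ncol(pos) != dim) {
    stop(sprintf("position has %d coordinates, field has %d", ncol(pos), dim))
  }
  pos
}

#' @noRd
row_norms <- function(m) sqrt(rowSums(m^2))
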