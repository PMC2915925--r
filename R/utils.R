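# shared numeric helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient of variation
#'
#' @param x numeric vector.
#' @param na.rm drop missing values.
#' @return sd(x)/mean(x).
#' @export
cv <- function(x, na.rm = TRUE) stats::sd(x, na.rm = na.rm) / mean(x, na.rm = na.rm)

# discrete Gaussian kernel, normalized to sum 1; radius covers +/- 3 sigma
gaussian_kernel_1d <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  r <- radius %||% max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# shift an array along one axis with replicate (edge) padding
shift_along <- function(a, s, axis) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + s, 1L), d[axis])
  if (length(d) == 2L) {
    if (axis == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
  } else {
    if (axis == 1L) a[idx, , , drop = FALSE]
    else if (axis == 2L) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
}

#' Separable Gaussian smoothing of a 2D or 3D array
#'
#' Convolves each axis in turn with a discrete Gaussian kernel (replicate
#' padding at the borders). An axis with `sigma = 0` is left untouched, so the
#' same routine serves both the 3D point-spread blur of the stack simulator
#' and the per-slice (2D) low-pass filter.
#'
#' @param a numeric array, 2 or 3 dimensional.
#' @param sigma per-axis kernel SD in voxels, recycled to `length(dim(a))`.
#' @return array of the same shape.
#' @export
gaussian_smooth <- function(a, sigma) {
  d <- dim(a)
  stopifnot(length(d) %in% c(2L, 3L))
  sigma <- rep_len(sigma, length(d))
  for (axis in seq_along(d)) {
    if (sigma[axis] <= 0) next
    k <- gaussian_kernel_1d(sigma[axis])
    r <- (length(k) - 1L) / 2L
    out <- array(0, d)
    for (j in seq_along(k)) {
      out <- out + k[j] * shift_along(a, j - r - 1L, axis)
    }
    a <- out
  }
  a
}

# derive a reproducible child seed (kept well under 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}
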