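#' Construct a 3D image stack
#'
#' A thin container for a confocal z-stack: a non-negative intensity array
#' indexed `(z, y, x)` plus the physical voxel size.
#'
#' @param voxels 3D numeric array, dimensions `(n_z, n_y, n_x)`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be three strictly positive values (dz, dy, dx)")
  }
  if (any(voxels < 0)) stop("stack intensities must be non-negative")
  structure(list(voxels = voxels, voxel_size = voxel_size), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d z-slices of %d x %d px, voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Maximum-intensity projection along z
#'
#' @param stack an [image_stack].
#' @return a `(n_y, n_x)` matrix.
#' @export
max_project <- function(stack) {
  apply(stack$voxels, c(2, 3), max)
}

#' Label connected components in a 2D or 3D mask
#'
#' 3D masks use 26-connectivity by default (6 optional); 2D masks are treated
#' as single-slice volumes, so 26-connectivity reduces to 8-connectivity.
#'
#' @param mask logical array (2D matrix or 3D array).
#' @param connectivity 6 or 26.
#' @return integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  two_d <- length(d) == 2L
  if (two_d) {
    dim(mask) <- c(1L, d)
    d <- dim(mask)
  }
  out <- label_components_3d_cpp(as.logical(mask), as.integer(d),
                                 as.integer(connectivity))
  if (two_d) {
    dim(out) <- d[2:3]
  }
  out
}
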