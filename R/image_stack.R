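#' ImageStack: a single-channel 3D fluorescence stack with calibration
#'
#' The package-wide container for one channel of a microscopy acquisition.
#' Voxels are stored as a 3D numeric array indexed `[z, y, x]` (plane,
#' row, column) -- this axis order is the single convention used
#' everywhere in spotsense. Physical calibration travels with the data:
#' `pixel_size_xy` is the lateral size of one pixel and `z_spacing` the
#' distance between consecutive optical sections, both in micrometres.
#'
#' Coordinates reported by the package are 0-based voxel indices in
#' `(z, y, x)` order; physical positions are obtained as
#' `(z * z_spacing, y * pixel_size_xy, x * pixel_size_xy)` micrometres.
#'
#' @param voxels numeric 3D array `[z, y, x]`, finite and non-negative.
#'   A 2D matrix is promoted to a single-plane stack.
#' @param channel_name character scalar naming the channel (e.g. "guide").
#' @param pixel_size_xy lateral pixel size in micrometres (> 0).
#' @param z_spacing plane spacing in micrometres (> 0).
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(0, c(4, 16, 16)), "guide")
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, channel_name = "unnamed",
                        pixel_size_xy = 0.13, z_spacing = 0.3) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, c(1L, nrow(voxels), ncol(voxels)))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array indexed (z, y, x)", call. = FALSE)
  }
  storage.mode(voxels) <- "double"
  if (any(dim(voxels) < 1L)) stop("all stack dimensions must be >= 1", call. = FALSE)
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    stop("voxel intensities must be finite", call. = FALSE)
  }
  if (any(voxels < 0)) stop("voxel intensities must be non-negative", call. = FALSE)
  stopifnot(is.character(channel_name), length(channel_name) == 1L)
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0) {
    stop("`pixel_size_xy` must be > 0 (micrometres)", call. = FALSE)
  }
  if (!is.numeric(z_spacing) || z_spacing <= 0) {
    stop("`z_spacing` must be > 0 (micrometres)", call. = FALSE)
  }
  structure(
    list(
      voxels = voxels,
      channel_name = channel_name,
      pixel_size_xy = as.numeric(pixel_size_xy),
      z_spacing = as.numeric(z_spacing)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> channel '%s': %d plane(s) x %d x %d px, %.4g um/px xy, %.4g um z-step\n",
    x$channel_name, d[1], d[2], d[3], x$pixel_size_xy, x$z_spacing
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Test whether two stacks share physical calibration
#'
#' @param a,b `image_stack` objects.
#' @param tol relative tolerance on the calibration values.
#' @return logical scalar.
#' @keywords internal
same_calibration <- function(a, b, tol = 1e-6) {
  isTRUE(abs(a$pixel_size_xy - b$pixel_size_xy) <= tol * a$pixel_size_xy) &&
    isTRUE(abs(a$z_spacing - b$z_spacing) <= tol * a$z_spacing)
}
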