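# TIFF and tabular I/O. Stacks are written one channel per file as
# multi-page grayscale TIFF (one page per z-plane). The tiff package
# stores samples either as integers scaled to [0,1] or as 32-bit floats
# in [0,1], so write_stack picks an encoding per stack:
#   * all values integral and <= 65535  -> 16-bit, scale 65535 (bit-exact)
#   * otherwise -> 32-bit float, scaled by a power of two >= max value
#     (the rescale itself is lossless in binary floating point; only
#     float32 quantisation of the mantissa remains, ~1e-7 relative)
# The scale and calibration go to a JSON sidecar `<path>.meta.json` so a
# later read_stack can restore original units without external input.

.sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write a 3D image stack to a multi-page TIFF
#'
#' One TIFF page per z-plane, grayscale, lossless. Integer-valued stacks
#' with maximum <= 65535 are stored as 16-bit and round-trip bit-exactly;
#' all other stacks are stored as 32-bit float (values preserved to
#' single precision). A JSON sidecar (`<path>.meta.json`) records the
#' intensity scale, channel name and physical calibration.
#'
#' @param stack an [image_stack()].
#' @param path output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  v <- stack$voxels
  mx <- max(v)
  integral <- all(v == round(v))
  if (integral && mx <= 65535) {
    scale <- 65535
    bits <- 16L
  } else {
    # smallest power of two >= mx keeps every value in [0, 1] and makes
    # the scaling exactly invertible in floating point
    scale <- 2^max(0, ceiling(log2(max(mx, .Machine$double.eps))))
    bits <- 32L
  }
  nz <- dim(v)[1]
  pages <- lapply(seq_len(nz), function(z) v[z, , ] / scale)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits,
                    compression = "none", reduce = FALSE),
    error = function(e) stop("cannot write TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  meta <- list(
    channel_name = stack$channel_name,
    pixel_size_xy = stack$pixel_size_xy,
    z_spacing = stack$z_spacing,
    intensity_scale = scale,
    bits_per_sample = bits,
    axis_order = "zyx"
  )
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into an ImageStack
#'
#' Pages become z-planes in `(z, y, x)` order; a single-page TIFF becomes
#' a stack with one plane. If a spotsense sidecar (`<path>.meta.json`) is
#' present, the stored intensity scale and calibration are applied;
#' explicit `pixel_size_xy` / `z_spacing` arguments override the sidecar.
#'
#' @param path TIFF file to read.
#' @param pixel_size_xy,z_spacing calibration in micrometres; `NULL`
#'   means take it from the sidecar (or package defaults if none).
#' @param channel_name channel label; `NULL` defers to sidecar/filename.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_xy = NULL, z_spacing = NULL,
                       channel_name = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) stop("not a readable TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) > 2L) {
      stop("multi-sample (colour) TIFF pages are not supported; ",
           "stacks must be single-channel grayscale", call. = FALSE)
    }
  }
  meta <- NULL
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                     error = function(e) NULL)
  }
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  d1 <- dim(pages[[1]])
  v <- array(0, c(length(pages), d1[1], d1[2]))
  for (z in seq_along(pages)) {
    if (!identical(dim(pages[[z]]), d1)) {
      stop("TIFF pages differ in size; not a z-stack", call. = FALSE)
    }
    v[z, , ] <- pages[[z]] * scale
  }
  if (scale == 65535) v <- round(v)  # undo 16-bit quantisation exactly
  image_stack(
    v,
    channel_name = channel_name %||% meta$channel_name %||%
      tools::file_path_sans_ext(basename(path)),
    pixel_size_xy = pixel_size_xy %||% meta$pixel_size_xy %||% 0.13,
    z_spacing = z_spacing %||% meta$z_spacing %||% 0.3
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a spot table
#'
#' Spot tables are plain CSV with a fixed column order
#' `cell_id, z, y, x, intensity` and a leading comment line declaring the
#' 0-based `(z, y, x)` coordinate convention. `read_spot_table()`
#' validates the required columns and returns a data.frame.
#'
#' @param spots data.frame with columns `cell_id`, `z`, `y`, `x`,
#'   `intensity` (extra columns are kept, after the required ones).
#' @param path CSV file path.
#' @return `write_spot_table()` returns `path` invisibly;
#'   `read_spot_table()` returns the data.frame.
#' @export
write_spot_table <- function(spots, path) {
  req <- c("cell_id", "z", "y", "x", "intensity")
  missing_cols <- setdiff(req, names(spots))
  if (length(missing_cols)) {
    stop("spot table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  spots <- spots[, c(req, setdiff(names(spots), req)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# spotsense spot table; coordinates are 0-based voxel indices in (z,y,x) order", con)
  utils::write.csv(spots, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  req <- c("cell_id", "z", "y", "x", "intensity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("not a spot table (missing ", paste(missing_cols, collapse = ", "),
         "): ", path, call. = FALSE)
  }
  df
}

#' Write / read a scene manifest
#'
#' A manifest is a small YAML file grouping the channel files of one
#' imaging scene: for each channel its TIFF path (relative to the
#' manifest), its dye role (`dapi`, `guide`, `detection_wt`,
#' `detection_mut` or `generic`) and the shared calibration.
#'
#' @param channels named list; each element a list with fields `file`
#'   and `role`.
#' @param pixel_size_xy,z_spacing calibration in micrometres.
#' @param path YAML file path.
#' @param cell_labels optional path of the cell-label TIFF.
#' @return `write_manifest()` returns `path` invisibly;
#'   `read_manifest()` the parsed list.
#' @export
write_manifest <- function(channels, pixel_size_xy, z_spacing, path,
                           cell_labels = NULL) {
  m <- list(
    pixel_size_xy = pixel_size_xy,
    z_spacing = z_spacing,
    channels = channels
  )
  if (!is.null(cell_labels)) m$cell_labels <- cell_labels
  yaml::write_yaml(m, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$channels) || is.null(m$pixel_size_xy) || is.null(m$z_spacing)) {
    stop("manifest lacks channels/calibration: ", path, call. = FALSE)
  }
  m
}
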