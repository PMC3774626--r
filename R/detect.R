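# Spot detection: spot-size-matched linear filtering, 3D regional
# maxima, threshold curves, and automatic plateau threshold selection.

# --- separable convolution -------------------------------------------------

# 1D convolution along axis 1 (z), 2 (y) or 3 (x) of a 3D array with
# symmetric (reflective, edge-included) padding; compiled kernel.
.conv_axis <- function(a, k, axis) {
  array(cpp_conv_axis(a, dim(a), k, axis), dim(a))
}

.gauss_kernel <- function(sigma, deriv2 = FALSE) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (!deriv2) return(g)
  k <- ((x^2 - sigma^2) / sigma^4) * g
  k - mean(k)   # zero net weight: constant images map exactly to zero
}

#' Enhance spot-like structures with a Laplacian-of-Gaussian filter
#'
#' Applies the negated, scale-normalised Laplacian of Gaussian matched
#' to the expected spot size, so diffraction-limited spots become
#' positive peaks in the output. Sigmas are given in micrometres and
#' converted to voxels through the stack's calibration. The filter is
#' linear (`enhance(a*I) = a*enhance(I)`) and separable; borders use
#' reflective padding. Single-plane stacks are filtered in 2D only.
#'
#' @param stack an [image_stack()].
#' @param spot_sigma_xy,spot_sigma_z expected spot Gaussian sigma in
#'   micrometres (defaults match the package's simulated PSF).
#' @return An `image_stack` of the filtered response (same shape;
#'   values may be negative).
#' @export
enhance <- function(stack, spot_sigma_xy = 0.17, spot_sigma_z = 0.45) {
  stopifnot(inherits(stack, "image_stack"))
  if (spot_sigma_xy <= 0 || spot_sigma_z <= 0) {
    stop("filter sigmas must be > 0", call. = FALSE)
  }
  v <- stack$voxels
  d <- dim(v)
  sxy <- spot_sigma_xy / stack$pixel_size_xy
  sz <- spot_sigma_z / stack$z_spacing
  if (sxy < 1 || (d[1] > 1L && sz < 1)) {
    warning("filter sigma below one voxel in some axis; the spot filter is undersampled",
            call. = FALSE)
  }
  g_xy <- .gauss_kernel(sxy); g2_xy <- .gauss_kernel(sxy, deriv2 = TRUE)
  use_z <- d[1] > 1L
  if (use_z) {
    g_z <- .gauss_kernel(sz); g2_z <- .gauss_kernel(sz, deriv2 = TRUE)
    cx <- .conv_axis(v, g_xy, 3L)
    cxy <- .conv_axis(cx, g_xy, 2L)
    dzz <- sz^2 * .conv_axis(cxy, g2_z, 1L)
    dyy <- sxy^2 * .conv_axis(.conv_axis(cx, g2_xy, 2L), g_z, 1L)
    dxx <- sxy^2 * .conv_axis(.conv_axis(.conv_axis(v, g2_xy, 3L), g_xy, 2L), g_z, 1L)
    resp <- -(dzz + dyy + dxx)
  } else {
    dyy <- sxy^2 * .conv_axis(.conv_axis(v, g_xy, 3L), g2_xy, 2L)
    dxx <- sxy^2 * .conv_axis(.conv_axis(v, g2_xy, 3L), g_xy, 2L)
    resp <- -(dyy + dxx)
  }
  out <- stack
  out$voxels <- resp
  # filtered responses are signed; bypass the non-negative constructor check
  out
}

# --- regional maxima -------------------------------------------------------

# all 26 (or 8 for single-plane) unit offsets
.neighbor_offsets <- function(three_d) {
  o <- expand.grid(dz = if (three_d) -1:1 else 0L, dy = -1:1, dx = -1:1)
  o[!(o$dz == 0 & o$dy == 0 & o$dx == 0), , drop = FALSE]
}

# maximum over the 26-neighborhood; voxels outside the image count as -Inf
.neighborhood_max <- function(v) {
  array(cpp_neighborhood_max(v, dim(v)), dim(v))
}

#' Find regional maxima of a filtered stack
#'
#' A regional maximum is a voxel strictly above all of its 26-connected
#' neighbours (8-connected for single-plane stacks), or a connected
#' plateau of equal value all of whose in-image neighbours are strictly
#' lower. Each plateau contributes one representative candidate at the
#' plateau voxel closest to its centroid (centroid floored toward the
#' origin; lexicographic `(z, y, x)` tie-break). A plateau with no
#' strictly lower in-image neighbour (e.g. a constant image) is not a
#' maximum. Candidates whose value falls below `min_value` are dropped.
#'
#' @param filtered an [image_stack()], normally the output of
#'   [enhance()].
#' @param min_value drop candidates below this filtered intensity;
#'   `NULL` uses the 1st percentile of the filtered image, which only
#'   bounds the list without touching real structure.
#' @return data.frame with 0-based voxel coordinates `z`, `y`, `x`, the
#'   filtered `value`, and `border` (TRUE when the maximum touches the
#'   outermost voxel shell), sorted by `(z, y, x)`.
#' @export
regional_maxima <- function(filtered, min_value = NULL) {
  stopifnot(inherits(filtered, "image_stack"))
  v <- filtered$voxels
  d <- dim(v)
  if (is.null(min_value)) min_value <- stats::quantile(v, 0.01, names = FALSE)
  nbmax <- .neighborhood_max(v)

  strict <- which(v > nbmax)
  eq <- v == nbmax
  out_z <- integer(0); out_y <- integer(0); out_x <- integer(0)
  out_v <- numeric(0); out_b <- logical(0)

  coords <- function(lin) {
    lin0 <- lin - 1L
    z <- lin0 %% d[1]
    y <- (lin0 %/% d[1]) %% d[2]
    x <- lin0 %/% (d[1] * d[2])
    cbind(z, y, x)
  }
  on_border <- function(zc, yc, xc) {
    (d[1] > 1L & (zc == 0L | zc == d[1] - 1L)) |
      yc == 0L | yc == d[2] - 1L | xc == 0L | xc == d[3] - 1L
  }

  if (length(strict)) {
    cc <- coords(strict)
    out_z <- cc[, 1]; out_y <- cc[, 2]; out_x <- cc[, 3]
    out_v <- v[strict]
    out_b <- on_border(cc[, 1], cc[, 2], cc[, 3])
  }

  # plateau components: BFS over equal-valued 26-connectivity, seeded at
  # voxels whose neighbourhood max equals their own value
  eq_lin <- which(eq)
  if (length(eq_lin)) {
    off <- .neighbor_offsets(d[1] > 1L)
    off_lin <- off$dz + off$dy * d[1] + off$dx * d[1] * d[2]
    visited <- logical(length(v))
    n_total <- prod(d)
    for (seed in eq_lin) {
      if (visited[seed]) next
      val <- v[seed]
      comp <- seed
      visited[seed] <- TRUE
      frontier <- seed
      good <- TRUE
      while (length(frontier)) {
        fc <- coords(frontier)
        nxt <- integer(0)
        for (j in seq_len(nrow(off))) {
          okz <- if (d[1] > 1L) fc[, 1] + off$dz[j] >= 0L & fc[, 1] + off$dz[j] <= d[1] - 1L else rep(TRUE, nrow(fc))
          ok <- okz &
            fc[, 2] + off$dy[j] >= 0L & fc[, 2] + off$dy[j] <= d[2] - 1L &
            fc[, 3] + off$dx[j] >= 0L & fc[, 3] + off$dx[j] <= d[3] - 1L
          if (!any(ok)) next
          nb <- frontier[ok] + off_lin[j]
          nb <- nb[!visited[nb] & v[nb] == val]
          if (length(nb)) {
            visited[nb] <- TRUE
            nxt <- c(nxt, nb)
          }
        }
        nxt <- unique(nxt)
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      # component is a maximum iff every member had no greater neighbour
      # (i.e. all members are eq voxels) and it is not the whole image
      if (length(comp) == n_total || any(!eq[comp])) good <- FALSE
      if (good) {
        cc <- coords(comp)
        cz <- floor(mean(cc[, 1])); cy <- floor(mean(cc[, 2])); cx <- floor(mean(cc[, 3]))
        d2 <- (cc[, 1] - cz)^2 + (cc[, 2] - cy)^2 + (cc[, 3] - cx)^2
        best <- which(d2 == min(d2))
        if (length(best) > 1L) {
          ord <- order(cc[best, 1], cc[best, 2], cc[best, 3])
          best <- best[ord[1]]
        }
        out_z <- c(out_z, cc[best, 1]); out_y <- c(out_y, cc[best, 2])
        out_x <- c(out_x, cc[best, 3]); out_v <- c(out_v, val)
        out_b <- c(out_b, any(on_border(cc[, 1], cc[, 2], cc[, 3])))
      }
    }
  }

  keep <- out_v >= min_value
  res <- data.frame(z = as.integer(out_z[keep]), y = as.integer(out_y[keep]),
                    x = as.integer(out_x[keep]), value = out_v[keep],
                    border = out_b[keep])
  res[order(res$z, res$y, res$x), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

# --- threshold curve and selection -----------------------------------------

#' Build a spot-count-versus-threshold curve
#'
#' Sweeps a uniform grid of thresholds over the candidate intensity
#' range and records, for each threshold T, the number of candidates
#' with filtered value >= T. The count is non-increasing in T by
#' construction (this is asserted on every call); a clean image shows a
#' plateau in this curve between the background-spot and RNA-spot
#' populations.
#'
#' @param candidates data.frame from [regional_maxima()] (needs a
#'   `value` column), or a numeric vector of candidate values.
#' @param n_thresholds number of grid points (>= 10).
#' @return data.frame of class `threshold_curve` with columns
#'   `threshold` and `count`.
#' @export
threshold_curve <- function(candidates, n_thresholds = 100) {
  vals <- if (is.data.frame(candidates)) candidates$value else as.numeric(candidates)
  if (length(vals) == 0L) {
    stop("cannot build a threshold curve from zero candidates", call. = FALSE)
  }
  if (n_thresholds < 10) stop("n_thresholds must be >= 10", call. = FALSE)
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) hi <- lo + max(abs(lo), 1) * 1e-9  # all-equal candidates
  grid <- seq(lo, hi, length.out = n_thresholds)
  counts <- vapply(grid, function(t) sum(vals >= t), integer(1))
  as_threshold_curve(grid, counts)
}

#' @rdname threshold_curve
#' @param thresholds strictly increasing numeric grid.
#' @param counts non-negative, non-increasing counts, one per
#'   threshold.
#' @export
as_threshold_curve <- function(thresholds, counts) {
  stopifnot(length(thresholds) == length(counts), length(thresholds) >= 2,
            all(diff(thresholds) > 0))
  if (any(counts < 0) || any(diff(counts) > 0)) {
    stop("counts must be non-negative and non-increasing in the threshold",
         call. = FALSE)
  }
  structure(
    data.frame(threshold = as.numeric(thresholds),
               count = as.numeric(counts)),
    class = c("threshold_curve", "data.frame")
  )
}

# smoothed derivative of log N(T) on the curve grid; NA where undefined.
# Central differences over the positive-count region, then a centred
# moving average whose half-width shrinks symmetrically at the ends.
.log_deriv <- function(curve, smoothing_window) {
  stopifnot(smoothing_window >= 3, smoothing_window %% 2 == 1)
  n <- nrow(curve)
  if (smoothing_window > n) {
    stop("smoothing window exceeds the curve length", call. = FALSE)
  }
  pos <- which(curve$count > 0)
  d_raw <- rep(NA_real_, n)
  if (length(pos) >= 3) {
    k <- max(pos)      # counts are non-increasing: positives are 1..k
    i <- 2:(k - 1)
    g <- log(curve$count[1:k])
    d_raw[i] <- (g[i + 1] - g[i - 1]) / (curve$threshold[i + 1] - curve$threshold[i - 1])
  }
  sm <- rep(NA_real_, n)
  idx <- which(!is.na(d_raw))
  if (length(idx)) {
    lo <- min(idx); hi <- max(idx)
    half <- (smoothing_window - 1) %/% 2
    for (i in idx) {
      h <- min(half, i - lo, hi - i)
      sm[i] <- mean(d_raw[(i - h):(i + h)])
    }
  }
  sm
}

#' Select the plateau threshold of a threshold curve
#'
#' Picks the threshold at which the spot count is least sensitive to
#' moving the threshold: the grid point minimising the smoothed
#' |d log N / dT|. The search covers the interior of the curve, to the
#' right of the curve's first dominant descent: leading grid points up
#' to (and including) the first index where the smoothed descent rate
#' reaches half its maximum are excluded, because left of the
#' lowest-intensity candidate population log N is quasi-flat for the
#' trivial reason that N is still enormous, not because signal and
#' background are separated. Trailing points where the count has
#' already flattened onto its final positive value are excluded too, as
#' are the zero-count tail and the grid end points (no central
#' difference there). Grid points where fewer than `min_count`
#' candidates survive are also excluded: with so few counts the
#' derivative of log N is dominated by count discreteness and produces
#' spurious exact flats. Ties break toward the lower threshold.
#'
#' @param curve a [threshold_curve()].
#' @param smoothing_window odd integer >= 3; width of the centred moving
#'   average applied to the derivative.
#' @param min_count smallest surviving count at which the log-derivative
#'   is considered estimable (the exclusion never triggers in the
#'   plateau region of a real image, where hundreds of spots survive).
#' @return list with `threshold` and `index` (position on the grid).
#' @export
select_threshold <- function(curve, smoothing_window = 7, min_count = 20) {
  stopifnot(inherits(curve, "threshold_curve"))
  sm <- .log_deriv(curve, smoothing_window)
  defined <- which(!is.na(sm))
  k <- max(which(curve$count > 0))
  last_pos <- curve$count[k]
  # indices where the log-derivative is statistically estimable
  meaningful <- defined[curve$count[defined] >= min_count &
                          curve$count[defined] > last_pos]
  eligible <- integer(0)
  if (length(meaningful)) {
    rate <- abs(sm)
    peak <- max(rate[meaningful])
    descent <- meaningful[rate[meaningful] >= peak / 2]
    i0 <- if (length(descent)) descent[1] else 0L
    eligible <- meaningful[meaningful > i0]
    if (!length(eligible)) eligible <- meaningful
  }
  if (!length(eligible)) {
    # degenerate curve (e.g. a single cliff or very few candidates):
    # fall back to any interior point with a defined derivative
    eligible <- defined
  }
  if (!length(eligible)) {
    stop("no interior grid point with positive count; cannot select a threshold",
         call. = FALSE)
  }
  best <- eligible[which.min(abs(sm[eligible]))]
  list(threshold = curve$threshold[best], index = best)
}

#' Call spots in a stack
#'
#' The full detection pipeline: [enhance()] the stack, extract
#' [regional_maxima()], build the [threshold_curve()], choose the
#' plateau threshold with [select_threshold()] (unless a manual
#' `threshold` is given), and keep the candidates at or above it.
#'
#' @param stack an [image_stack()].
#' @param sigma_xy,sigma_z spot filter sigmas in micrometres.
#' @param threshold manual threshold on the filtered intensity; `NULL`
#'   selects automatically.
#' @param n_thresholds,smoothing_window threshold-grid resolution and
#'   derivative smoothing (see [select_threshold()]).
#' @param labels optional integer `(y, x)` cell-label matrix; adds
#'   per-cell counts (see [count_per_cell()]).
#' @return A list of class `spot_set`: `spots` (data.frame `z, y, x,
#'   value, border`, plus `cell_id` when labels are given), `threshold`,
#'   `threshold_index` (NA for manual thresholds off the grid), `curve`,
#'   `per_cell` (or NULL), and `auto` (logical).
#' @examples
#' sc <- make_scene(scene_params(shape = c(6, 64, 64), n_cells = 2,
#'                               spots_per_cell_mean = 8, seed = 3))
#' ss <- call_spots(sc$channels$guide)
#' nrow(ss$spots)
#' @export
call_spots <- function(stack, sigma_xy = 0.17, sigma_z = 0.45,
                       threshold = NULL, n_thresholds = 100,
                       smoothing_window = 7, labels = NULL) {
  filtered <- enhance(stack, sigma_xy, sigma_z)
  cand <- regional_maxima(filtered)
  if (nrow(cand) == 0L) {
    stop("no candidate spots found in channel '", stack$channel_name, "'",
         call. = FALSE)
  }
  curve <- threshold_curve(cand, n_thresholds)
  auto <- is.null(threshold)
  if (auto) {
    sel <- select_threshold(curve, smoothing_window)
    threshold <- sel$threshold
    index <- sel$index
  } else {
    hits <- which(abs(curve$threshold - threshold) < 1e-12)
    index <- if (length(hits)) hits[1] else NA_integer_
  }
  spots <- cand[cand$value >= threshold, , drop = FALSE]
  rownames(spots) <- NULL
  per_cell <- NULL
  if (!is.null(labels)) {
    spots$cell_id <- .spot_cell_ids(spots, labels)
    per_cell <- count_per_cell(spots, labels)
  }
  structure(
    list(spots = spots, threshold = threshold, threshold_index = index,
         curve = curve, per_cell = per_cell, auto = auto,
         channel_name = stack$channel_name,
         pixel_size_xy = stack$pixel_size_xy, z_spacing = stack$z_spacing),
    class = "spot_set"
  )
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf(
    "<spot_set> channel '%s': %d spot(s) at threshold %.4g (%s)\n",
    x$channel_name, nrow(x$spots), x$threshold,
    if (x$auto) "auto-selected" else "manual"
  ))
  invisible(x)
}

.spot_cell_ids <- function(spots, labels) {
  if (nrow(spots) == 0L) return(integer(0))
  as.integer(labels[cbind(spots$y + 1L, spots$x + 1L)])
}

#' Count spots per cell
#'
#' Assigns each spot to the cell label at its `(y, x)` position. Label 0
#' (outside any cell) is reported as its own row; every label present in
#' the map appears even when its count is zero, and counts sum to the
#' number of spots.
#'
#' @param spots a `spot_set` from [call_spots()] or a spot data.frame
#'   with 0-based `y`, `x` columns.
#' @param labels integer `(y, x)` matrix of cell labels, matching the
#'   image extent.
#' @return data.frame with `cell_id` and `spot_count`.
#' @export
count_per_cell <- function(spots, labels) {
  df <- if (inherits(spots, "spot_set")) spots$spots else spots
  stopifnot(is.matrix(labels))
  if (nrow(df) > 0 &&
      (max(df$y) >= nrow(labels) || max(df$x) >= ncol(labels))) {
    stop("label map smaller than the spot coordinate range", call. = FALSE)
  }
  ids <- .spot_cell_ids(df, labels)
  universe <- sort(unique(c(0L, as.integer(labels[labels > 0L]),
                            if (length(ids)) ids)))
  counts <- vapply(universe, function(u) sum(ids == u), integer(1))
  out <- data.frame(cell_id = universe, spot_count = counts)
  stopifnot(sum(out$spot_count) == nrow(df))
  out
}
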