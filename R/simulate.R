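# Synthetic smFISH scene generator. Candidate spots in real FISH images
# form two intensity populations -- genuine RNA spots and dimmer
# background spots -- and the separation between them is what the
# quality metric measures. The simulator reproduces exactly that
# structure: bright diffraction-limited spots plus a dimmer background
# spot population, both rendered with the same anisotropic Gaussian PSF
# over a Poisson + read-noise camera model, with full ground truth.

#' Parameters for a synthetic smFISH scene
#'
#' Returns the default parameter set for [make_scene()]; any field can
#' be overridden by name. Defaults describe a typical high-NA widefield
#' acquisition: 0.13 um pixels, 0.3 um plane spacing, PSF sigma 0.17 um
#' lateral and 0.45 um axial, spot amplitudes of a few thousand photons
#' over a ~100 photon background.
#'
#' @param ... named overrides of any parameter listed below.
#' @return A list of class `scene_params` with fields:
#' \describe{
#'   \item{shape}{image dimensions `c(z, y, x)` in voxels.}
#'   \item{pixel_size_xy, z_spacing}{calibration, micrometres.}
#'   \item{n_cells}{number of cells placed in the field.}
#'   \item{spots_per_cell_mean, spots_per_cell_dispersion}{per-cell RNA
#'     count distribution; dispersion 0 gives Poisson, > 0 gives
#'     negative binomial with `size = mean / dispersion`.}
#'   \item{psf_sigma_xy, psf_sigma_z}{PSF Gaussian sigmas, micrometres.}
#'   \item{signal_amplitude}{mean integrated intensity (photons) of a
#'     true RNA spot.}
#'   \item{contrast_ratio}{signal amplitude divided by mean background-
#'     spot amplitude; the synthetic stand-in for hybridization
#'     quality.}
#'   \item{background_spot_density}{mean number of background spots per
#'     cell.}
#'   \item{background_level}{uniform background, photons per voxel.}
#'   \item{read_noise_sd}{Gaussian read noise sd, photons.}
#'   \item{shot_noise}{logical; apply Poisson shot noise.}
#'   \item{amplitude_cv}{log-normal coefficient of variation of spot
#'     amplitudes within each population.}
#'   \item{cell_radius_um, nucleus_fraction}{cell disk radius and the
#'     relative nucleus size used for the DAPI-like channel.}
#'   \item{labeling_efficiency_wt, labeling_efficiency_mut}{probability
#'     that an RNA of the matching allele carries a detection-probe
#'     spot.}
#'   \item{cross_channel_prob}{probability that an RNA is (wrongly)
#'     rendered in the other allele's detection channel.}
#'   \item{allele_fraction_mut}{fraction of RNAs carrying the mutant
#'     allele; `NA` disables the detection channels entirely.}
#'   \item{max_overlap_fraction}{warn when the expected fraction of
#'     spots closer than 2 PSF sigmas to another spot exceeds this.}
#'   \item{seed}{RNG seed; scenes are bit-reproducible given the seed.}
#' }
#' @examples
#' p <- scene_params(n_cells = 4, spots_per_cell_mean = 10)
#' p$shape
#' @export
scene_params <- function(...) {
  p <- list(
    shape = c(20L, 512L, 512L),
    pixel_size_xy = 0.13,
    z_spacing = 0.3,
    n_cells = 20L,
    spots_per_cell_mean = 50,
    spots_per_cell_dispersion = 0,
    psf_sigma_xy = 0.17,
    psf_sigma_z = 0.45,
    signal_amplitude = 5000,
    contrast_ratio = 8,
    background_spot_density = 30,
    background_level = 100,
    read_noise_sd = 3,
    shot_noise = TRUE,
    amplitude_cv = 0.25,
    cell_radius_um = 5.8,
    nucleus_fraction = 0.55,
    labeling_efficiency_wt = 0.9,
    labeling_efficiency_mut = 0.9,
    cross_channel_prob = 0,
    allele_fraction_mut = NA_real_,
    max_overlap_fraction = 0.1,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) {
    stop("unknown scene parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(over)] <- over
  p$shape <- as.integer(p$shape)
  stopifnot(length(p$shape) == 3L, all(p$shape >= 1L))
  if (p$contrast_ratio <= 0) stop("contrast_ratio must be > 0", call. = FALSE)
  probs <- c(p$labeling_efficiency_wt, p$labeling_efficiency_mut,
             p$cross_channel_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("labeling/cross-channel probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.na(p$allele_fraction_mut) &&
      (p$allele_fraction_mut < 0 || p$allele_fraction_mut > 1)) {
    stop("allele_fraction_mut must lie in [0, 1]", call. = FALSE)
  }
  class(p) <- "scene_params"
  p
}

# log-normal draws with arithmetic mean m and coefficient of variation cv
.rlnorm_mean_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Lay n_cells non-overlapping disks on a jittered grid covering (y, x).
# Returns centres (0-based, continuous) and the common radius in px.
.place_cells <- function(n_cells, ny, nx, radius_px) {
  if (n_cells == 0L) {
    return(list(cy = numeric(0), cx = numeric(0), radius = radius_px))
  }
  ncol <- ceiling(sqrt(n_cells * nx / ny))
  nrow <- ceiling(n_cells / ncol)
  sy <- ny / nrow
  sx <- nx / ncol
  # radius <= 0.44 * spacing and jitter <= 0.05 * spacing together
  # guarantee the disks never overlap (worst-case gap 0.02 * spacing)
  radius <- min(radius_px, 0.44 * min(sy, sx))
  idx <- seq_len(n_cells) - 1L
  gy <- (idx %/% ncol) + 0.5
  gx <- (idx %% ncol) + 0.5
  jit_y <- stats::runif(n_cells, -0.05, 0.05) * sy
  jit_x <- stats::runif(n_cells, -0.05, 0.05) * sx
  cy <- pmin(pmax(gy * sy + jit_y, radius + 1), ny - radius - 2)
  cx <- pmin(pmax(gx * sx + jit_x, radius + 1), nx - radius - 2)
  list(cy = cy, cx = cx, radius = radius)
}

# Compute the voxel block of one PSF-shaped spot. The spot integrates
# to `amplitude`: each axis contributes the Gaussian probability mass
# falling in each voxel (difference of normal CDFs at the voxel edges),
# so total intensity is conserved up to the mass lost outside the
# +-4 sigma rendering window and outside the image. Returns NULL or a
# list of 1-based index vectors and the intensity block; the caller
# adds it in place (keeping the big voxel array un-copied).
.spot_block <- function(d, z, y, x, amplitude, sz, sy, sx) {
  axis_w <- function(mu, sigma, n) {
    r <- ceiling(4 * sigma)
    lo <- max(0, floor(mu) - r)
    hi <- min(n - 1, ceiling(mu) + r)
    if (lo > hi) return(NULL)
    i <- lo:hi
    w <- stats::pnorm(i + 0.5, mu, sigma) - stats::pnorm(i - 0.5, mu, sigma)
    list(i = i + 1L, w = w)
  }
  wz <- axis_w(z, sz, d[1]); wy <- axis_w(y, sy, d[2]); wx <- axis_w(x, sx, d[3])
  if (is.null(wz) || is.null(wy) || is.null(wx)) return(NULL)
  list(iz = wz$i, iy = wy$i, ix = wx$i,
       block = amplitude * (wz$w %o% wy$w %o% wx$w))
}

# Sample spot positions uniformly inside a cell disk (continuous 0-based
# voxel coordinates). z stays >= 1 voxel away from the axial faces so
# spots are not flattened against the stack boundary.
.sample_positions <- function(n, cy, cx, radius, nz) {
  if (n == 0L) {
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0)))
  }
  rr <- (radius - 1) * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  zlo <- min(1, (nz - 1) / 2)
  data.frame(
    z = stats::runif(n, zlo, nz - 1 - zlo),
    y = cy + rr * sin(th),
    x = cx + rr * cos(th)
  )
}

#' Generate a synthetic multi-channel smFISH scene with ground truth
#'
#' Renders a DAPI-like nucleus channel and a guide (mRNA) channel; when
#' `allele_fraction_mut` is set, also two allele-specific detection
#' channels. Each RNA appears as a 3D anisotropic Gaussian spot whose
#' integrated intensity equals its amplitude; background spots are
#' rendered identically at amplitude `signal_amplitude / contrast_ratio`.
#' Noise is Poisson shot noise on signal plus background, followed by
#' additive Gaussian read noise (negative camera values are clipped at
#' zero). Scenes are bit-reproducible given `params$seed`.
#'
#' @param params a [scene_params()] object.
#' @return A list of class `ground_truth_scene`:
#' \describe{
#'   \item{params}{the generating parameters.}
#'   \item{true_spots}{data.frame of RNA spots: `cell_id`, continuous
#'     0-based `z, y, x`, `amplitude`, `allele` ("wt"/"mut"/"none"),
#'     and per-channel labeling flags `in_wt`, `in_mut`.}
#'   \item{background_spots}{same minus allele columns.}
#'   \item{cell_label_map}{integer `(y, x)` matrix, 0 outside cells.}
#'   \item{channels}{named list of [image_stack()]s: `dapi`, `guide`,
#'     and optionally `detection_wt`, `detection_mut`.}
#' }
#' @examples
#' sc <- make_scene(scene_params(shape = c(6, 64, 64), n_cells = 2,
#'                               spots_per_cell_mean = 5, seed = 7))
#' nrow(sc$true_spots)
#' @export
make_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  set.seed(p$seed)
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  sz <- p$psf_sigma_z / p$z_spacing
  sxy <- p$psf_sigma_xy / p$pixel_size_xy
  radius_px <- p$cell_radius_um / p$pixel_size_xy

  cells <- .place_cells(p$n_cells, ny, nx, radius_px)

  # cell label map: nearest disk membership (disks never overlap)
  labels <- matrix(0L, ny, nx)
  for (k in seq_len(p$n_cells)) {
    yy <- pmax(1, floor(cells$cy[k] - cells$radius)):pmin(ny, ceiling(cells$cy[k] + cells$radius) + 1)
    xx <- pmax(1, floor(cells$cx[k] - cells$radius)):pmin(nx, ceiling(cells$cx[k] + cells$radius) + 1)
    dy <- (yy - 1) - cells$cy[k]
    dx <- (xx - 1) - cells$cx[k]
    inside <- outer(dy^2, dx^2, "+") <= cells$radius^2
    sub <- labels[yy, xx, drop = FALSE]
    sub[inside] <- k
    labels[yy, xx] <- sub
  }

  # per-cell RNA counts
  n_rna <- if (p$n_cells == 0L) integer(0)
  else if (p$spots_per_cell_dispersion > 0) {
    stats::rnbinom(p$n_cells, mu = p$spots_per_cell_mean,
                   size = p$spots_per_cell_mean / p$spots_per_cell_dispersion)
  } else {
    stats::rpois(p$n_cells, p$spots_per_cell_mean)
  }

  true_spots <- do.call(rbind, lapply(seq_len(p$n_cells), function(k) {
    pos <- .sample_positions(n_rna[k], cells$cy[k], cells$cx[k],
                             cells$radius, nz)
    if (nrow(pos)) cbind(cell_id = k, pos) else NULL
  }))
  if (is.null(true_spots)) {
    true_spots <- data.frame(cell_id = integer(0), z = numeric(0),
                             y = numeric(0), x = numeric(0))
  }
  nspots <- nrow(true_spots)
  true_spots$amplitude <- .rlnorm_mean_cv(nspots, p$signal_amplitude,
                                          p$amplitude_cv)

  # allele assignment and detection-channel labeling
  snp_mode <- !is.na(p$allele_fraction_mut)
  if (snp_mode) {
    is_mut <- stats::runif(nspots) < p$allele_fraction_mut
    true_spots$allele <- ifelse(is_mut, "mut", "wt")
    eff <- ifelse(is_mut, p$labeling_efficiency_mut, p$labeling_efficiency_wt)
    labeled <- stats::runif(nspots) < eff
    cross <- stats::runif(nspots) < p$cross_channel_prob
    true_spots$in_mut <- (is_mut & labeled) | (!is_mut & cross)
    true_spots$in_wt <- (!is_mut & labeled) | (is_mut & cross)
  } else {
    true_spots$allele <- rep("none", nspots)
    true_spots$in_wt <- true_spots$in_mut <- rep(FALSE, nspots)
  }

  # background spots, uniform within cells, dimmer by contrast_ratio
  n_bg <- if (p$n_cells == 0L) integer(0)
  else stats::rpois(p$n_cells, p$background_spot_density)
  background_spots <- do.call(rbind, lapply(seq_len(p$n_cells), function(k) {
    pos <- .sample_positions(n_bg[k], cells$cy[k], cells$cx[k],
                             cells$radius, nz)
    if (nrow(pos)) cbind(cell_id = k, pos) else NULL
  }))
  if (is.null(background_spots)) {
    background_spots <- data.frame(cell_id = integer(0), z = numeric(0),
                                   y = numeric(0), x = numeric(0))
  }
  background_spots$amplitude <- .rlnorm_mean_cv(
    nrow(background_spots), p$signal_amplitude / p$contrast_ratio,
    p$amplitude_cv
  )

  # crowding check: fraction of spots with a neighbour within 2 sigma_xy
  all_pos <- rbind(true_spots[c("z", "y", "x")],
                   background_spots[c("z", "y", "x")])
  if (nrow(all_pos) > 1) {
    crowd_r2 <- (2 * sxy)^2
    n_all <- nrow(all_pos)
    close <- 0L
    for (i in seq_len(n_all)) {
      d2 <- (all_pos$y - all_pos$y[i])^2 + (all_pos$x - all_pos$x[i])^2 +
        ((all_pos$z - all_pos$z[i]) * sz / max(sxy, 1e-9))^2
      if (sum(d2 <= crowd_r2) > 1L) close <- close + 1L
    }
    if (close / n_all > p$max_overlap_fraction) {
      warning(sprintf(
        "%.0f%% of simulated spots overlap within 2 PSF sigmas; counts may be unreliable",
        100 * close / n_all
      ), call. = FALSE)
    }
  }

  render_channel <- function(spots_list) {
    v <- array(0, c(nz, ny, nx))
    for (s in spots_list) {
      for (i in seq_len(nrow(s))) {
        b <- .spot_block(c(nz, ny, nx), s$z[i], s$y[i], s$x[i],
                         s$amplitude[i], sz, sxy, sxy)
        if (!is.null(b)) {
          v[b$iz, b$iy, b$ix] <- v[b$iz, b$iy, b$ix] + b$block
        }
      }
    }
    v <- v + p$background_level
    if (p$shot_noise) {
      v <- array(stats::rpois(length(v), v), dim(v))
    }
    if (p$read_noise_sd > 0) {
      v <- v + array(stats::rnorm(length(v), 0, p$read_noise_sd), dim(v))
    }
    pmax(v, 0)
  }

  mk <- function(v, name) image_stack(v, name, p$pixel_size_xy, p$z_spacing)

  guide <- render_channel(list(true_spots, background_spots))

  # DAPI analogue: smooth nuclear ellipses, no spots
  dapi <- array(0, c(nz, ny, nx))
  if (p$n_cells > 0L) {
    nuc_r <- p$nucleus_fraction * cells$radius
    plane <- matrix(0, ny, nx)
    for (k in seq_len(p$n_cells)) {
      dy <- ((seq_len(ny) - 1) - cells$cy[k]) / nuc_r
      dx <- ((seq_len(nx) - 1) - cells$cx[k]) / (0.8 * nuc_r)
      d2 <- outer(dy^2, dx^2, "+")
      plane <- plane + 4 * p$background_level * exp(-d2 / 0.5) * (d2 <= 2.5)
    }
    zprof <- exp(-((seq_len(nz) - 1) - (nz - 1) / 2)^2 / (2 * (nz / 3)^2))
    for (z in seq_len(nz)) dapi[z, , ] <- plane * zprof[z]
  }
  dapi <- dapi + p$background_level
  if (p$shot_noise) dapi <- array(stats::rpois(length(dapi), dapi), dim(dapi))
  if (p$read_noise_sd > 0) {
    dapi <- dapi + array(stats::rnorm(length(dapi), 0, p$read_noise_sd), dim(dapi))
  }
  channels <- list(dapi = mk(pmax(dapi, 0), "dapi"), guide = mk(guide, "guide"))

  if (snp_mode) {
    det_bg <- function() {
      nb <- if (p$n_cells == 0L) integer(0)
      else stats::rpois(p$n_cells, p$background_spot_density)
      out <- do.call(rbind, lapply(seq_len(p$n_cells), function(k) {
        pos <- .sample_positions(nb[k], cells$cy[k], cells$cx[k],
                                 cells$radius, nz)
        if (nrow(pos)) cbind(cell_id = k, pos) else NULL
      }))
      if (is.null(out)) {
        out <- data.frame(cell_id = integer(0), z = numeric(0),
                          y = numeric(0), x = numeric(0))
      }
      out$amplitude <- .rlnorm_mean_cv(nrow(out),
                                       p$signal_amplitude / p$contrast_ratio,
                                       p$amplitude_cv)
      out
    }
    wt_spots <- true_spots[true_spots$in_wt, , drop = FALSE]
    mut_spots <- true_spots[true_spots$in_mut, , drop = FALSE]
    channels$detection_wt <- mk(render_channel(list(wt_spots, det_bg())),
                                "detection_wt")
    channels$detection_mut <- mk(render_channel(list(mut_spots, det_bg())),
                                 "detection_mut")
  }

  structure(
    list(
      params = p,
      true_spots = true_spots,
      background_spots = background_spots,
      cell_label_map = labels,
      cell_centers = data.frame(cell_id = seq_len(p$n_cells),
                                y = cells$cy, x = cells$cx,
                                radius_px = rep(cells$radius, p$n_cells)),
      channels = channels
    ),
    class = "ground_truth_scene"
  )
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_scene> %d cell(s), %d RNA spot(s), %d background spot(s), channels: %s\n",
    x$params$n_cells, nrow(x$true_spots), nrow(x$background_spots),
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Generate a series of scenes across contrast ratios
#'
#' One scene per contrast ratio; scene `i` uses seed
#' `base$seed + i - 1`, so the series is reproducible from the base
#' seed. The series emulates deteriorating hybridization: fewer probes
#' bind each RNA, so the RNA-spot amplitude falls toward the (fixed)
#' background-spot population and the two intensity distributions
#' merge. Concretely, the background-spot amplitude
#' `base$signal_amplitude / base$contrast_ratio` is held constant
#' across the series and each scene's signal amplitude is that value
#' times its contrast ratio; all other parameters stay at `base`.
#'
#' @param base a [scene_params()] object.
#' @param contrast_ratios numeric vector of contrast ratios (> 0).
#' @return Named list of `ground_truth_scene`s, names `"contrast_<r>"`.
#' @export
make_condition_series <- function(base, contrast_ratios) {
  stopifnot(inherits(base, "scene_params"), length(contrast_ratios) >= 1)
  bg_amplitude <- base$signal_amplitude / base$contrast_ratio
  scenes <- lapply(seq_along(contrast_ratios), function(i) {
    p <- base
    p$contrast_ratio <- contrast_ratios[i]
    p$signal_amplitude <- bg_amplitude * contrast_ratios[i]
    p$seed <- base$seed + i - 1L
    make_scene(p)
  })
  names(scenes) <- paste0("contrast_", contrast_ratios)
  scenes
}

#' Generate a two-allele (SNP) scene
#'
#' Convenience wrapper around [make_scene()] that requires
#' `allele_fraction_mut` to be set. Each RNA is assigned the mutant
#' allele with probability `allele_fraction_mut`; a detection-channel
#' spot is rendered at the same position with the matching allele's
#' labeling efficiency, and in the wrong channel with probability
#' `cross_channel_prob`.
#'
#' @param params a [scene_params()] with `allele_fraction_mut` set.
#' @return A `ground_truth_scene` with `detection_wt` and
#'   `detection_mut` channels.
#' @export
make_snp_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  if (is.na(params$allele_fraction_mut)) {
    stop("make_snp_scene() requires allele_fraction_mut to be set",
         call. = FALSE)
  }
  make_scene(params)
}
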