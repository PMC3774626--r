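# SNP FISH colocalization: every RNA is marked by a guide-probe spot;
# allele-specific detection probes produce a spot in the wild-type or
# mutant channel at (nearly) the same position. Matching detection
# spots to guide spots within a physical radius classifies each RNA as
# wild-type, mutant, unlabeled (no detection spot) or ambiguous
# (detection spots of both alleles).

.spot_df <- function(x) {
  if (inherits(x, "spot_set")) x$spots else x
}

#' Match spots between two channels by physical proximity
#'
#' Pairs guide-channel spots with detection-channel spots whose
#' anisotropic physical distance (z scaled by `z_spacing`, y/x by
#' `pixel_size_xy`, in micrometres) is at most `radius_um`. Matching is
#' greedy by ascending distance with each spot used at most once, which
#' makes every accepted pair mutual nearest neighbours among the spots
#' still unmatched. Distance ties break by lexicographic `(z, y, x)`
#' voxel order of the guide then detection spot, so the result is
#' deterministic.
#'
#' @param guide,detection `spot_set`s from [call_spots()] (their
#'   calibrations must agree) or spot data.frames with 0-based
#'   `z, y, x` columns.
#' @param radius_um matching radius in micrometres.
#' @param pixel_size_xy,z_spacing calibration; required only when data
#'   frames are passed.
#' @return data.frame with `guide_idx`, `detection_idx` (row numbers in
#'   the respective spot tables) and `distance_um`.
#' @export
match_channels <- function(guide, detection, radius_um = 0.4,
                           pixel_size_xy = NULL, z_spacing = NULL) {
  if (inherits(guide, "spot_set") && inherits(detection, "spot_set")) {
    if (!same_calibration(guide, detection)) {
      stop("guide and detection channels have different calibration",
           call. = FALSE)
    }
    pixel_size_xy <- guide$pixel_size_xy
    z_spacing <- guide$z_spacing
  }
  if (is.null(pixel_size_xy) || is.null(z_spacing)) {
    stop("calibration needed: pass spot_sets or pixel_size_xy/z_spacing",
         call. = FALSE)
  }
  g <- .spot_df(guide)
  d <- .spot_df(detection)
  empty <- data.frame(guide_idx = integer(0), detection_idx = integer(0),
                      distance_um = numeric(0))
  if (nrow(g) == 0L || nrow(d) == 0L) return(empty)

  dz <- outer(g$z, d$z, "-") * z_spacing
  dy <- outer(g$y, d$y, "-") * pixel_size_xy
  dx <- outer(g$x, d$x, "-") * pixel_size_xy
  dist <- sqrt(dz^2 + dy^2 + dx^2)
  cand <- which(dist <= radius_um, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)

  gi <- cand[, 1]; di <- cand[, 2]
  dd <- dist[cand]
  ord <- order(dd, g$z[gi], g$y[gi], g$x[gi], d$z[di], d$y[di], d$x[di])
  gi <- gi[ord]; di <- di[ord]; dd <- dd[ord]
  g_used <- logical(nrow(g)); d_used <- logical(nrow(d))
  keep <- logical(length(gi))
  for (i in seq_along(gi)) {
    if (!g_used[gi[i]] && !d_used[di[i]]) {
      keep[i] <- TRUE
      g_used[gi[i]] <- TRUE
      d_used[di[i]] <- TRUE
    }
  }
  data.frame(guide_idx = gi[keep], detection_idx = di[keep],
             distance_um = dd[keep])
}

#' Classify each guide spot by allele-specific colocalization
#'
#' Runs [match_channels()] between the guide spots and each detection
#' channel independently, then assigns each guide spot one call:
#' `wt` (wild-type match only), `mut` (mutant match only), `ambiguous`
#' (matches in both channels within the radius), or `unlabeled`
#' (no match). With `resolve_by_distance = TRUE`, ambiguous spots are
#' instead given to the nearer detection spot (ties stay ambiguous).
#'
#' @param guide,wt,mut `spot_set`s (or spot data.frames; then supply
#'   the calibration).
#' @param radius_um matching radius in micrometres (default 0.4, about
#'   three 0.13-um pixels: larger than the localisation error of a
#'   diffraction-limited spot, smaller than typical spot spacing).
#' @param resolve_by_distance resolve double matches by distance.
#' @param pixel_size_xy,z_spacing calibration for data.frame input.
#' @param labels optional `(y, x)` cell-label matrix; adds `cell_id` to
#'   the records (0 = outside any cell) if the guide spots lack one.
#' @return data.frame of class `coloc_records`, one row per guide spot:
#'   `cell_id` (if known), `z, y, x`, `wt_distance_um`,
#'   `mut_distance_um` (NA when unmatched) and `call`.
#' @export
classify_spots <- function(guide, wt, mut, radius_um = 0.4,
                           resolve_by_distance = FALSE,
                           pixel_size_xy = NULL, z_spacing = NULL,
                           labels = NULL) {
  g <- .spot_df(guide)
  if (inherits(guide, "spot_set")) {
    pixel_size_xy <- pixel_size_xy %||% guide$pixel_size_xy
    z_spacing <- z_spacing %||% guide$z_spacing
  }
  m_wt <- match_channels(guide, wt, radius_um, pixel_size_xy, z_spacing)
  m_mut <- match_channels(guide, mut, radius_um, pixel_size_xy, z_spacing)

  n <- nrow(g)
  wt_d <- rep(NA_real_, n); mut_d <- rep(NA_real_, n)
  wt_d[m_wt$guide_idx] <- m_wt$distance_um
  mut_d[m_mut$guide_idx] <- m_mut$distance_um

  call <- rep("unlabeled", n)
  call[!is.na(wt_d) & is.na(mut_d)] <- "wt"
  call[is.na(wt_d) & !is.na(mut_d)] <- "mut"
  both <- !is.na(wt_d) & !is.na(mut_d)
  call[both] <- "ambiguous"
  if (resolve_by_distance && any(both)) {
    nearer_wt <- both & wt_d < mut_d
    nearer_mut <- both & mut_d < wt_d
    call[nearer_wt] <- "wt"
    call[nearer_mut] <- "mut"
  }

  cell_id <- if (!is.null(g$cell_id)) {
    g$cell_id
  } else if (!is.null(labels) && n > 0) {
    .spot_cell_ids(g, labels)
  } else {
    rep(NA_integer_, n)
  }

  out <- data.frame(
    cell_id = cell_id,
    z = if (n) g$z else integer(0),
    y = if (n) g$y else integer(0),
    x = if (n) g$x else integer(0),
    wt_distance_um = wt_d,
    mut_distance_um = mut_d,
    call = factor(call, levels = c("wt", "mut", "unlabeled", "ambiguous"))
  )
  class(out) <- c("coloc_records", "data.frame")
  out
}

#' Per-cell allele tallies
#'
#' Tallies the colocalization calls per cell: guide spots, wild-type,
#' mutant, unlabeled and ambiguous counts, and the mutant fraction among
#' allele-labeled (wt + mut) spots. Cell id 0 collects guide spots
#' outside any cell; spots without a cell id are pooled under NA.
#' Package-level totals over all cells are attached as the `"totals"`
#' attribute.
#'
#' @param records a [classify_spots()] result.
#' @return data.frame with one row per cell: `cell_id`, `n_guide`,
#'   `n_wt`, `n_mut`, `n_unlabeled`, `n_ambiguous`,
#'   `fraction_mut_of_labeled` (NA when no labeled spots). The
#'   partition `n_guide = n_wt + n_mut + n_unlabeled + n_ambiguous`
#'   holds in every row.
#' @export
summarize_cells <- function(records) {
  if (nrow(records) == 0L) {
    out <- data.frame(cell_id = integer(0), n_guide = integer(0),
                      n_wt = integer(0), n_mut = integer(0),
                      n_unlabeled = integer(0), n_ambiguous = integer(0),
                      fraction_mut_of_labeled = numeric(0))
    attr(out, "totals") <- c(n_guide = 0L, n_wt = 0L, n_mut = 0L,
                             n_unlabeled = 0L, n_ambiguous = 0L)
    return(out)
  }
  cells <- unique(records$cell_id)
  cells <- cells[order(cells, na.last = TRUE)]
  rows <- lapply(cells, function(cid) {
    r <- if (is.na(cid)) records[is.na(records$cell_id), ]
    else records[!is.na(records$cell_id) & records$cell_id == cid, ]
    n_wt <- sum(r$call == "wt"); n_mut <- sum(r$call == "mut")
    labeled <- n_wt + n_mut
    data.frame(
      cell_id = cid, n_guide = nrow(r), n_wt = n_wt, n_mut = n_mut,
      n_unlabeled = sum(r$call == "unlabeled"),
      n_ambiguous = sum(r$call == "ambiguous"),
      fraction_mut_of_labeled = if (labeled > 0) n_mut / labeled else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$n_guide ==
                  out$n_wt + out$n_mut + out$n_unlabeled + out$n_ambiguous))
  tot <- c(n_guide = sum(out$n_guide), n_wt = sum(out$n_wt),
           n_mut = sum(out$n_mut), n_unlabeled = sum(out$n_unlabeled),
           n_ambiguous = sum(out$n_ambiguous))
  attr(out, "totals") <- tot
  out
}

#' Stacked per-cell allele bar plot
#'
#' One stacked bar per cell showing its wild-type / mutant / unlabeled /
#' ambiguous composition.
#'
#' @param cell_summary a [summarize_cells()] result.
#' @return a ggplot object.
#' @export
plot_cell_alleles <- function(cell_summary) {
  cs <- cell_summary[!is.na(cell_summary$cell_id) & cell_summary$cell_id > 0, ]
  long <- do.call(rbind, lapply(seq_len(nrow(cs)), function(i) {
    data.frame(
      cell = cs$cell_id[i],
      class = factor(c("wt", "mut", "unlabeled", "ambiguous"),
                     levels = c("wt", "mut", "unlabeled", "ambiguous")),
      n = c(cs$n_wt[i], cs$n_mut[i], cs$n_unlabeled[i], cs$n_ambiguous[i])
    )
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(cell), y = n, fill = class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(wt = "#4477AA", mut = "#EE6677",
                                          unlabeled = "grey75",
                                          ambiguous = "#CCBB44")) +
    ggplot2::labs(x = "cell", y = "RNA count", fill = "allele call") +
    ggplot2::theme_minimal()
}
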