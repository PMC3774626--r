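# Scoring detections against simulator ground truth.

#' Score detected spots against ground truth
#'
#' Greedy distance matching (as in [match_channels()]) between detected
#' spots and true spot positions within `radius_um`; matched pairs are
#' true positives, unmatched detections false positives, unmatched true
#' spots false negatives.
#'
#' @param spots a `spot_set` or spot data.frame with 0-based `z, y, x`.
#' @param truth data.frame of true positions (e.g.
#'   `scene$true_spots`).
#' @param radius_um match radius in micrometres.
#' @param pixel_size_xy,z_spacing calibration when `spots` is a plain
#'   data.frame.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
score_detection <- function(spots, truth, radius_um = 0.4,
                            pixel_size_xy = NULL, z_spacing = NULL) {
  if (inherits(spots, "spot_set")) {
    pixel_size_xy <- pixel_size_xy %||% spots$pixel_size_xy
    z_spacing <- z_spacing %||% spots$z_spacing
  }
  det <- .spot_df(spots)
  m <- match_channels(det, truth, radius_um, pixel_size_xy, z_spacing)
  tp <- nrow(m)
  fp <- nrow(det) - tp
  fn <- nrow(truth) - tp
  precision <- if (nrow(det)) tp / nrow(det) else NA_real_
  recall <- if (nrow(truth)) tp / nrow(truth) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}
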