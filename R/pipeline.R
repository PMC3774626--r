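# End-to-end workflow: simulate -> detect -> quality -> snpcall, driven
# by a serialisable configuration so any run can be reproduced from its
# archived config file and seed.

#' Build a run configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()]. Everything is a plain list and serialises to YAML,
#' so an archived config plus its seed reproduces a run bit-exactly.
#'
#' @param out_dir run directory (created if missing).
#' @param stages character subset of
#'   `c("simulate", "detect", "quality", "snpcall")`, executed in that
#'   order.
#' @param scene a [scene_params()] object (or a named list of overrides
#'   passed to `scene_params()`).
#' @param sigma_xy,sigma_z detection filter sigmas, micrometres.
#' @param n_thresholds,smoothing_window threshold-grid size and
#'   derivative smoothing window.
#' @param threshold optional manual detection threshold.
#' @param snp_radius_um colocalization radius, micrometres.
#' @param condition_label label used in the quality summary.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "detect", "quality"),
                       scene = scene_params(),
                       sigma_xy = 0.17, sigma_z = 0.45,
                       n_thresholds = 100, smoothing_window = 7,
                       threshold = NULL, snp_radius_um = 0.4,
                       condition_label = "condition") {
  if (is.list(scene) && !inherits(scene, "scene_params")) {
    scene <- do.call(scene_params, scene)
  }
  bad <- setdiff(stages, c("simulate", "detect", "quality", "snpcall"))
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, stages = stages, scene = scene,
         sigma_xy = sigma_xy, sigma_z = sigma_z,
         n_thresholds = n_thresholds, smoothing_window = smoothing_window,
         threshold = threshold, snp_radius_um = snp_radius_um,
         condition_label = condition_label),
    class = "run_config"
  )
}

.write_scene_outputs <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch_entries <- list()
  for (nm in names(scene$channels)) {
    f <- paste0(nm, ".tif")
    write_stack(scene$channels[[nm]], file.path(dir, f))
    role <- switch(nm, dapi = "dapi", guide = "guide",
                   detection_wt = "detection_wt",
                   detection_mut = "detection_mut", "generic")
    ch_entries[[nm]] <- list(file = f, role = role)
  }
  lab <- scene$cell_label_map
  write_stack(
    image_stack(array(lab, c(1L, nrow(lab), ncol(lab))), "cell_labels",
                scene$params$pixel_size_xy, scene$params$z_spacing),
    file.path(dir, "cell_labels.tif")
  )
  ts <- scene$true_spots
  utils::write.csv(
    data.frame(kind = rep("rna", nrow(ts)), ts),
    file.path(dir, "ground_truth.csv"), row.names = FALSE
  )
  bs <- scene$background_spots
  if (nrow(bs)) {
    utils::write.csv(data.frame(kind = "background", bs),
                     file.path(dir, "ground_truth_background.csv"),
                     row.names = FALSE)
  }
  write_manifest(ch_entries, scene$params$pixel_size_xy,
                 scene$params$z_spacing, file.path(dir, "manifest.yaml"),
                 cell_labels = "cell_labels.tif")
  invisible(dir)
}

#' Run the simulate/detect/quality/snpcall pipeline
#'
#' Executes the configured stages in order and writes every
#' intermediate under `config$out_dir`: channel TIFFs, the manifest and
#' ground truth (`scene/`), spot tables and threshold curves per
#' channel (`detect/`), the condition summary (`quality/`) and the
#' colocalization records and per-cell allele table (`snpcall/`), plus
#' `config.yaml` and a `log.txt` with seeds and per-stage timing.
#' Re-running the same config reproduces all CSV outputs bit-exactly.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory stage results:
#'   `scene`, `spot_sets`, `summary`, `records`, `cells`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_ser <- config
  cfg_ser$scene <- unclass(cfg_ser$scene)
  yaml::write_yaml(unclass(cfg_ser), file.path(config$out_dir, "config.yaml"))
  log_lines <- c(
    sprintf("spotsense %s pipeline run", as.character(utils::packageVersion("spotsense"))),
    sprintf("stages: %s", paste(config$stages, collapse = ", ")),
    sprintf("scene seed: %d", config$scene$seed)
  )
  res <- list(out_dir = config$out_dir)
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %-8s %.2fs", name,
                                       proc.time()[["elapsed"]] - t0))
    out
  }

  if ("simulate" %in% config$stages) {
    res$scene <- run_stage("simulate", function() {
      sc <- make_scene(config$scene)
      .write_scene_outputs(sc, file.path(config$out_dir, "scene"))
      sc
    })
  }
  if ("detect" %in% config$stages) {
    if (is.null(res$scene)) {
      stop("stage 'detect' failed: no scene available (include 'simulate')",
           call. = FALSE)
    }
    res$spot_sets <- run_stage("detect", function() {
      ddir <- file.path(config$out_dir, "detect")
      dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
      spot_channels <- setdiff(names(res$scene$channels), "dapi")
      sets <- lapply(spot_channels, function(nm) {
        ss <- call_spots(res$scene$channels[[nm]], config$sigma_xy,
                         config$sigma_z, threshold = config$threshold,
                         n_thresholds = config$n_thresholds,
                         smoothing_window = config$smoothing_window,
                         labels = res$scene$cell_label_map)
        tab <- ss$spots
        tab$intensity <- tab$value
        write_spot_table(tab[c("cell_id", "z", "y", "x", "intensity")],
                         file.path(ddir, paste0(nm, "_spots.csv")))
        utils::write.csv(as.data.frame(ss$curve),
                         file.path(ddir, paste0(nm, "_curve.csv")),
                         row.names = FALSE)
        ss
      })
      names(sets) <- spot_channels
      sets
    })
  }
  if ("quality" %in% config$stages) {
    if (is.null(res$spot_sets)) {
      stop("stage 'quality' failed: no detections (include 'detect')",
           call. = FALSE)
    }
    res$summary <- run_stage("quality", function() {
      qdir <- file.path(config$out_dir, "quality")
      ss <- res$spot_sets$guide
      sens <- sensitivity(ss$curve, ss$threshold_index,
                          config$smoothing_window)
      per_cell <- ss$per_cell[ss$per_cell$cell_id > 0, ]
      summ <- summarize_condition(per_cell$spot_count, list(sens),
                                  config$condition_label)
      condition_report(list(), summ, out_dir = qdir)
      summ
    })
  }
  if ("snpcall" %in% config$stages) {
    if (is.null(res$spot_sets) ||
        !all(c("guide", "detection_wt", "detection_mut") %in% names(res$spot_sets))) {
      stop("stage 'snpcall' failed: needs guide and detection channels ",
           "(set allele_fraction_mut and include 'detect')", call. = FALSE)
    }
    res$records <- run_stage("snpcall", function() {
      sdir <- file.path(config$out_dir, "snpcall")
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      rec <- classify_spots(res$spot_sets$guide,
                            res$spot_sets$detection_wt,
                            res$spot_sets$detection_mut,
                            radius_um = config$snp_radius_um)
      utils::write.csv(as.data.frame(rec),
                       file.path(sdir, "records.csv"), row.names = FALSE)
      cells <- summarize_cells(rec)
      utils::write.csv(cells, file.path(sdir, "cells.csv"),
                       row.names = FALSE)
      grDevices::pdf(file.path(sdir, "cells.pdf"), width = 7, height = 4)
      print(plot_cell_alleles(cells))
      grDevices::dev.off()
      rec
    })
    res$cells <- summarize_cells(res$records)
  }
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(res)
}

#' Demo: condition series versus a high-quality reference
#'
#' Generates a series of scenes of falling contrast ratio (the
#' synthetic stand-in for deteriorating hybridization conditions) plus
#' one high-contrast reference scene, runs detection and quality
#' scoring on each, and returns the condition comparison table with the
#' reference first. With `out_dir` set, the table, CDFs and plots are
#' written via [condition_report()].
#'
#' @param contrast_ratios contrasts for the degraded conditions.
#' @param reference_contrast contrast of the reference scene.
#' @param base a [scene_params()] used for every scene (its seed fixes
#'   the whole series).
#' @param out_dir optional report directory.
#' @return the [condition_report()] data.frame.
#' @export
demo_turbo_vs_overnight <- function(contrast_ratios = c(8, 4, 2, 1.25),
                                    reference_contrast = 20,
                                    base = scene_params(),
                                    out_dir = NULL) {
  scenes <- make_condition_series(base, c(reference_contrast, contrast_ratios))
  summaries <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    ss <- call_spots(sc$channels$guide, labels = sc$cell_label_map)
    sens <- sensitivity(ss$curve, ss$threshold_index)
    per_cell <- ss$per_cell[ss$per_cell$cell_id > 0, ]
    lab <- if (i == 1) sprintf("reference (contrast %g)", reference_contrast)
    else sprintf("contrast %g", contrast_ratios[i - 1])
    summarize_condition(per_cell$spot_count, list(sens), lab)
  })
  condition_report(summaries[-1], summaries[[1]], out_dir = out_dir)
}

#' Detect spots for one channel of a scene manifest
#'
#' Reads the named channel (and cell labels, if present) from a scene
#' manifest, runs [call_spots()], and writes `<channel>_spots.csv`,
#' `<channel>_curve.csv` and `<channel>_summary.json` to `out_dir`.
#'
#' @param manifest_path path of a manifest written by [write_manifest()].
#' @param channel channel name in the manifest.
#' @param out_dir output directory (created if missing).
#' @inheritParams call_spots
#' @return the `spot_set`, invisibly.
#' @export
detect_from_manifest <- function(manifest_path, channel, out_dir,
                                 sigma_xy = 0.17, sigma_z = 0.45,
                                 threshold = NULL, n_thresholds = 100,
                                 smoothing_window = 7) {
  m <- read_manifest(manifest_path)
  if (!channel %in% names(m$channels)) {
    stop("channel '", channel, "' not in manifest", call. = FALSE)
  }
  base <- dirname(manifest_path)
  stk <- read_stack(file.path(base, m$channels[[channel]]$file),
                    pixel_size_xy = m$pixel_size_xy,
                    z_spacing = m$z_spacing, channel_name = channel)
  labels <- NULL
  if (!is.null(m$cell_labels)) {
    lab_stack <- read_stack(file.path(base, m$cell_labels))
    labels <- matrix(as.integer(lab_stack$voxels[1, , ]),
                     dim(lab_stack$voxels)[2], dim(lab_stack$voxels)[3])
  }
  ss <- call_spots(stk, sigma_xy, sigma_z, threshold = threshold,
                   n_thresholds = n_thresholds,
                   smoothing_window = smoothing_window, labels = labels)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- ss$spots
  tab$intensity <- tab$value
  if (is.null(tab$cell_id)) tab$cell_id <- 0L
  write_spot_table(tab[c("cell_id", "z", "y", "x", "intensity")],
                   file.path(out_dir, paste0(channel, "_spots.csv")))
  utils::write.csv(as.data.frame(ss$curve),
                   file.path(out_dir, paste0(channel, "_curve.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(channel = channel, threshold = ss$threshold, auto = ss$auto,
         n_spots = nrow(ss$spots),
         per_cell = if (!is.null(ss$per_cell)) ss$per_cell else NULL),
    file.path(out_dir, paste0(channel, "_summary.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(ss)
}

#' Colocalization SNP calling from a scene manifest
#'
#' Detects spots in the guide and the two detection channels of a
#' manifest, classifies every guide spot by colocalization and writes
#' `records.csv`, `cells.csv` and a per-cell stacked bar plot.
#'
#' @param manifest_path manifest with `guide`, `detection_wt` and
#'   `detection_mut` channels.
#' @param out_dir output directory.
#' @param radius_um colocalization radius, micrometres.
#' @inheritParams call_spots
#' @return list with `records` and `cells`, invisibly.
#' @export
snpcall_from_manifest <- function(manifest_path, out_dir, radius_um = 0.4,
                                  sigma_xy = 0.17, sigma_z = 0.45) {
  m <- read_manifest(manifest_path)
  need <- c("guide", "detection_wt", "detection_mut")
  if (!all(need %in% names(m$channels))) {
    stop("manifest lacks channels: ",
         paste(setdiff(need, names(m$channels)), collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  labels <- NULL
  if (!is.null(m$cell_labels)) {
    lab_stack <- read_stack(file.path(base, m$cell_labels))
    labels <- matrix(as.integer(lab_stack$voxels[1, , ]),
                     dim(lab_stack$voxels)[2], dim(lab_stack$voxels)[3])
  }
  sets <- lapply(need, function(ch) {
    stk <- read_stack(file.path(base, m$channels[[ch]]$file),
                      pixel_size_xy = m$pixel_size_xy,
                      z_spacing = m$z_spacing, channel_name = ch)
    call_spots(stk, sigma_xy, sigma_z,
               labels = if (ch == "guide") labels else NULL)
  })
  names(sets) <- need
  rec <- classify_spots(sets$guide, sets$detection_wt, sets$detection_mut,
                        radius_um = radius_um)
  cells <- summarize_cells(rec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(rec), file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  grDevices::pdf(file.path(out_dir, "cells.pdf"), width = 7, height = 4)
  print(plot_cell_alleles(cells))
  grDevices::dev.off()
  invisible(list(records = rec, cells = cells))
}
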