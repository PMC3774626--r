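# Signal-quality scoring. The sensitivity of the chosen threshold --
# how fast log N(T) is changing where the threshold sits -- measures how
# cleanly the RNA-spot intensity population separates from background
# spots: a wide plateau (score near 0) means anyone would count the same
# number of spots; a steep curve means the count depends strongly on an
# arbitrary threshold choice.

#' Threshold-sensitivity score of an image
#'
#' Computes |smoothed d log N / dT| at a grid index of a threshold
#' curve, multiplied by the grid step: the relative change in detected
#' spot count per threshold step. The derivative is a central
#' difference of log N over the positive-count region, smoothed with a
#' centred moving average (window shrunk symmetrically near the ends of
#' the defined range). Low scores indicate clean, quantifiable signal.
#'
#' The grid-step scaling makes the score scale-free: multiplying all
#' candidate intensities (and hence the grid) by a constant leaves it
#' unchanged.
#'
#' @param curve a [threshold_curve()].
#' @param threshold_index grid index at which to evaluate (normally the
#'   index returned by [select_threshold()]).
#' @param smoothing_window odd integer >= 3.
#' @return list of class `sensitivity_score`: `value` (>= 0),
#'   `threshold`, `threshold_index`, `smoothing_window`.
#' @examples
#' cv <- threshold_curve(c(rep(1, 50), rep(10, 50)), 20)
#' sensitivity(cv, select_threshold(cv)$index)$value
#' @export
sensitivity <- function(curve, threshold_index, smoothing_window = 7) {
  stopifnot(inherits(curve, "threshold_curve"))
  n <- nrow(curve)
  if (is.na(threshold_index) || threshold_index < 1 || threshold_index > n) {
    stop("threshold_index outside the curve grid", call. = FALSE)
  }
  sm <- .log_deriv(curve, smoothing_window)
  if (is.na(sm[threshold_index])) {
    stop("spot count is zero at or adjacent to the threshold; sensitivity undefined",
         call. = FALSE)
  }
  step <- curve$threshold[2] - curve$threshold[1]
  structure(
    list(value = abs(sm[threshold_index]) * step,
         threshold = curve$threshold[threshold_index],
         threshold_index = threshold_index,
         smoothing_window = smoothing_window),
    class = "sensitivity_score"
  )
}

#' @export
print.sensitivity_score <- function(x, ...) {
  cat(sprintf("<sensitivity_score> %.4g at threshold %.4g (window %d)\n",
              x$value, x$threshold, x$smoothing_window))
  invisible(x)
}

#' Summarise one experimental condition
#'
#' Aggregates per-cell spot counts and per-image sensitivity scores for
#' one condition: mean count, unbiased SD (n - 1 denominator),
#' SEM = SD / sqrt(n_cells), the empirical CDF of the per-cell counts,
#' and mean +/- SEM of the image-level sensitivity scores.
#'
#' @param per_cell_counts numeric vector (or data.frame with a
#'   `spot_count` column) of per-cell counts; at least 2 cells.
#' @param per_image_scores list of [sensitivity()] scores or a numeric
#'   vector; may be empty.
#' @param label condition name.
#' @return list of class `condition_summary` with fields `label`,
#'   `n_cells`, `mean_count`, `sd_count`, `sem_count`, `counts`, `cdf`
#'   (a function), `sensitivity_mean`, `sensitivity_sem`, `n_images`.
#' @export
summarize_condition <- function(per_cell_counts, per_image_scores = list(),
                                label = "condition") {
  counts <- if (is.data.frame(per_cell_counts)) per_cell_counts$spot_count
  else as.numeric(per_cell_counts)
  if (length(counts) < 2) {
    stop("need at least 2 cells to estimate dispersion", call. = FALSE)
  }
  scores <- vapply(per_image_scores,
                   function(s) if (inherits(s, "sensitivity_score")) s$value else as.numeric(s),
                   numeric(1))
  n <- length(counts)
  sdv <- stats::sd(counts)
  structure(
    list(
      label = label,
      n_cells = n,
      mean_count = mean(counts),
      sd_count = sdv,
      sem_count = sdv / sqrt(n),
      counts = counts,
      cdf = stats::ecdf(counts),
      sensitivity_mean = if (length(scores)) mean(scores) else NA_real_,
      sensitivity_sem = if (length(scores) > 1) {
        stats::sd(scores) / sqrt(length(scores))
      } else NA_real_,
      n_images = length(scores)
    ),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    "<condition_summary> '%s': %d cells, %.2f +/- %.2f (SEM) spots/cell; sensitivity %.4g over %d image(s)\n",
    x$label, x$n_cells, x$mean_count, x$sem_count,
    x$sensitivity_mean, x$n_images
  ))
  invisible(x)
}

#' Compare two conditions with a two-tailed t-test
#'
#' Welch's unequal-variance two-tailed t-test on the per-cell counts of
#' two conditions (Student's pooled-variance test available via
#' `student = TRUE`). When both samples have zero variance, the test is
#' degenerate: equal means give t = 0, p = 1 by convention; unequal
#' means give an infinite statistic and p = 0.
#'
#' @param a,b [summarize_condition()] objects or raw numeric count
#'   vectors (n >= 2 each).
#' @param student use the pooled-variance Student test instead of Welch.
#' @return list with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `method`.
#' @export
compare_conditions <- function(a, b, student = FALSE) {
  xa <- if (inherits(a, "condition_summary")) a$counts else as.numeric(a)
  xb <- if (inherits(b, "condition_summary")) b$counts else as.numeric(b)
  if (length(xa) < 2 || length(xb) < 2) {
    stop("both conditions need at least 2 observations", call. = FALSE)
  }
  if (stats::var(xa) == 0 && stats::var(xb) == 0) {
    same <- isTRUE(all.equal(mean(xa), mean(xb)))
    return(list(
      statistic = if (same) 0 else sign(mean(xa) - mean(xb)) * Inf,
      p_value = if (same) 1 else 0,
      df = NA_real_, mean_a = mean(xa), mean_b = mean(xb),
      method = "degenerate (zero variance in both groups)"
    ))
  }
  tt <- stats::t.test(xa, xb, var.equal = student,
                      alternative = "two.sided")
  list(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    mean_a = mean(xa), mean_b = mean(xb),
    method = tt$method
  )
}

#' Tabulate and plot a series of conditions against a reference
#'
#' Builds the condition-comparison table (mean counts and mean
#' sensitivity with their errors, plus differences from the reference
#' condition) and, when `out_dir` is given, writes `summary.csv`,
#' `cdf.csv` and PDF plots of mean sensitivity and mean counts per
#' condition with the reference drawn as a horizontal dotted line.
#'
#' @param series list of [summarize_condition()] objects (may be empty).
#' @param reference a [summarize_condition()] used as the baseline.
#' @param out_dir optional output directory (created if missing).
#' @return data.frame with one row per condition (reference first) and
#'   columns `condition`, `n_cells`, `mean_count`, `sd_count`,
#'   `sem_count`, `sensitivity_mean`, `sensitivity_sem`,
#'   `sensitivity_vs_reference`, `count_vs_reference`.
#' @export
condition_report <- function(series, reference, out_dir = NULL) {
  stopifnot(inherits(reference, "condition_summary"))
  all_s <- c(list(reference), series)
  tab <- do.call(rbind, lapply(all_s, function(s) {
    data.frame(
      condition = s$label, n_cells = s$n_cells,
      mean_count = s$mean_count, sd_count = s$sd_count,
      sem_count = s$sem_count,
      sensitivity_mean = s$sensitivity_mean,
      sensitivity_sem = s$sensitivity_sem,
      stringsAsFactors = FALSE
    )
  }))
  tab$sensitivity_vs_reference <- tab$sensitivity_mean - reference$sensitivity_mean
  tab$count_vs_reference <- tab$mean_count - reference$mean_count

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "summary.csv"), row.names = FALSE)
    cdf_rows <- do.call(rbind, lapply(all_s, function(s) {
      x <- sort(unique(s$counts))
      data.frame(condition = s$label, count = x, cdf = s$cdf(x),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(cdf_rows, file.path(out_dir, "cdf.csv"), row.names = FALSE)
    ptab <- tab
    ptab$condition <- factor(ptab$condition, levels = tab$condition)
    p1 <- ggplot2::ggplot(ptab,
                          ggplot2::aes(x = condition, y = sensitivity_mean)) +
      ggplot2::geom_col(fill = "grey60") +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = sensitivity_mean - sensitivity_sem,
        ymax = sensitivity_mean + sensitivity_sem), width = 0.2) +
      ggplot2::geom_hline(yintercept = reference$sensitivity_mean,
                          linetype = "dotted") +
      ggplot2::labs(y = "threshold sensitivity (mean +/- SEM)",
                    x = NULL, title = "Signal quality by condition") +
      ggplot2::theme_minimal()
    p2 <- ggplot2::ggplot(ptab, ggplot2::aes(x = condition, y = mean_count)) +
      ggplot2::geom_col(fill = "grey60") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_count - sd_count,
                                          ymax = mean_count + sd_count),
                             width = 0.2) +
      ggplot2::geom_hline(yintercept = reference$mean_count,
                          linetype = "dotted") +
      ggplot2::labs(y = "spots per cell (mean +/- SD)", x = NULL,
                    title = "Spot counts by condition") +
      ggplot2::theme_minimal()
    grDevices::pdf(file.path(out_dir, "sensitivity.pdf"), width = 6, height = 4)
    print(p1)
    grDevices::dev.off()
    grDevices::pdf(file.path(out_dir, "counts.pdf"), width = 6, height = 4)
    print(p2)
    grDevices::dev.off()
  }
  tab
}
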