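# Independent reference implementations used as oracles. These are
# deliberately written with plain voxel-by-voxel loops and simple
# recursion, sharing no code with the package internals they check.

# Brute-force regional maxima: scan every voxel, flood-fill its
# equal-valued connected component with an explicit stack, and accept
# the component when no in-image neighbour is greater and at least one
# is strictly lower. Representative: component member closest to the
# floored centroid, lexicographic (z, y, x) tie-break.
oracle_regional_maxima <- function(v) {
  d <- dim(v)
  three_d <- d[1] > 1L
  visited <- array(FALSE, d)
  out <- list()
  neighbors <- function(z, y, x) {
    res <- NULL
    zr <- if (three_d) (z - 1):(z + 1) else z
    for (zz in zr) for (yy in (y - 1):(y + 1)) for (xx in (x - 1):(x + 1)) {
      if (zz == z && yy == y && xx == x) next
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
      res <- rbind(res, c(zz, yy, xx))
    }
    res
  }
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (visited[z, y, x]) next
    val <- v[z, y, x]
    comp <- matrix(c(z, y, x), 1)
    stack <- list(c(z, y, x))
    visited[z, y, x] <- TRUE
    is_max <- TRUE
    has_lower <- FALSE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nb <- neighbors(cur[1], cur[2], cur[3])
      for (i in seq_len(nrow(nb))) {
        p <- nb[i, ]
        nv <- v[p[1], p[2], p[3]]
        if (nv == val) {
          if (!visited[p[1], p[2], p[3]]) {
            visited[p[1], p[2], p[3]] <- TRUE
            comp <- rbind(comp, p)
            stack[[length(stack) + 1L]] <- p
          }
        } else if (nv > val) {
          is_max <- FALSE
        } else {
          has_lower <- TRUE
        }
      }
    }
    if (is_max && has_lower) {
      cz <- floor(mean(comp[, 1] - 1)); cy <- floor(mean(comp[, 2] - 1))
      cx <- floor(mean(comp[, 3] - 1))
      d2 <- (comp[, 1] - 1 - cz)^2 + (comp[, 2] - 1 - cy)^2 + (comp[, 3] - 1 - cx)^2
      cand <- which(d2 == min(d2))
      if (length(cand) > 1) {
        o <- order(comp[cand, 1], comp[cand, 2], comp[cand, 3])
        cand <- cand[o[1]]
      }
      border <- any(
        (three_d & (comp[, 1] == 1 | comp[, 1] == d[1])) |
          comp[, 2] == 1 | comp[, 2] == d[2] |
          comp[, 3] == 1 | comp[, 3] == d[3]
      )
      out[[length(out) + 1L]] <- data.frame(
        z = comp[cand, 1] - 1L, y = comp[cand, 2] - 1L,
        x = comp[cand, 3] - 1L, value = val, border = border
      )
    }
  }
  if (!length(out)) {
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      value = numeric(0), border = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$z, res$y, res$x), ]
  rownames(res) <- NULL
  res
}

# Exhaustive matching oracle: maximum-cardinality, then minimum
# total-distance assignment within the radius, by recursion over guide
# spots. Only for tiny instances.
oracle_match <- function(dist, radius) {
  ng <- nrow(dist); nd <- ncol(dist)
  best <- list(card = -1L, total = Inf, pairs = NULL)
  recurse <- function(g, used, pairs, total) {
    if (g > ng) {
      card <- nrow(pairs) %||% 0L
      if (card > best$card ||
          (card == best$card && total < best$total - 1e-12)) {
        best <<- list(card = card, total = total, pairs = pairs)
      }
      return(invisible())
    }
    recurse(g + 1L, used, pairs, total)          # leave guide g unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && dist[g, j] <= radius) {
        used[j] <- TRUE
        recurse(g + 1L, used, rbind(pairs, c(g, j)), total + dist[g, j])
        used[j] <- FALSE
      }
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  recurse(1L, logical(nd), NULL, 0)
  best
}

# Independent recomputation of the sensitivity definition: central
# difference of log N over positive counts, centred moving average with
# symmetric shrink, |.| times grid step. Uses different code paths
# (diff-based derivative, explicit loop smoother).
oracle_sensitivity <- function(thresholds, counts, idx, window) {
  pos <- counts > 0
  k <- max(which(pos))
  g <- log(counts[1:k])
  d <- rep(NA_real_, length(counts))
  if (k >= 3) {
    ii <- 2:(k - 1)
    d[ii] <- (g[ii + 1] - g[ii - 1]) / (thresholds[ii + 1] - thresholds[ii - 1])
  }
  ok <- which(!is.na(d))
  lo <- min(ok); hi <- max(ok)
  half <- (window - 1) / 2
  h <- min(half, idx - lo, hi - idx)
  smoothed <- mean(d[(idx - h):(idx + h)])
  abs(smoothed) * (thresholds[2] - thresholds[1])
}

# small scene defaults used across the unit tests (fast to render; the
# overlap warning is disabled because these structural tests do not
# depend on spots being resolvable)
tiny_scene_params <- function(...) {
  scene_params(shape = c(6L, 64L, 64L), n_cells = 2L,
               spots_per_cell_mean = 6, background_spot_density = 3,
               cell_radius_um = 1.8, max_overlap_fraction = 1,
               seed = 42L, ...)
}
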