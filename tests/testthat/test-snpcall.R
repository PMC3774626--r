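px <- 0.13; zs <- 0.3

test_that("matching pairs identical positions at distance zero and respects the radius", {
  g <- data.frame(z = 0L, y = 0L, x = 0L, value = 1)
  d0 <- data.frame(z = 0L, y = 0L, x = 0L, value = 1)
  m <- match_channels(g, d0, radius_um = 0.4, pixel_size_xy = px, z_spacing = zs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$distance_um, 0)

  # xy offset just past the radius: 0.4 um / 0.13 um/px = 3.0769 px
  d_far <- data.frame(z = 0L, y = 0L, x = 4L, value = 1)
  expect_equal(nrow(match_channels(g, d_far, 0.4, px, zs)), 0L)
  d_in <- data.frame(z = 0L, y = 0L, x = 3L, value = 1)
  expect_equal(nrow(match_channels(g, d_in, 0.4, px, zs)), 1L)

  # distances are anisotropic: 1 plane = 0.3 um counts more than 1 px
  d_z <- data.frame(z = 1L, y = 0L, x = 0L, value = 1)
  m_z <- match_channels(g, d_z, 0.4, px, zs)
  expect_equal(m_z$distance_um, 0.3)

  # empty inputs give empty matchings
  expect_equal(nrow(match_channels(g[0, ], d0, 0.4, px, zs)), 0L)
})

test_that("each spot is used at most once, greedily by ascending distance", {
  # two guides compete for one detection spot: the nearer guide wins
  g <- data.frame(z = c(0L, 0L), y = c(0L, 0L), x = c(3L, 0L), value = 1)
  d <- data.frame(z = 0L, y = 0L, x = 1L, value = 1)
  m <- match_channels(g, d, radius_um = 0.4, pixel_size_xy = px, z_spacing = zs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$guide_idx, 2L)  # 1 px beats 2 px

  # exact distance tie: lexicographic (z, y, x) order of the guide wins
  gt <- data.frame(z = c(0L, 0L), y = c(0L, 0L), x = c(2L, 0L), value = 1)
  mt <- match_channels(gt, d, 0.4, pixel_size_xy = px, z_spacing = zs)
  expect_equal(mt$guide_idx, 2L)  # guide at x = 0 sorts first
})

test_that("greedy matching equals the exhaustive optimum on separated instances", {
  set.seed(31)
  radius <- 0.4
  for (rep in 1:20) {
    # guides far apart; detections jittered off a subset of guides, so
    # every spot has at most one partner in range and the optimal
    # matching is unique
    ng <- sample(3:7, 1)
    g <- data.frame(z = sample(0:8, ng, replace = TRUE),
                    y = seq(5, by = 12, length.out = ng),
                    x = sample(5:50, ng), value = 1)
    take <- sort(sample(ng, sample(1:ng, 1)))
    d <- g[take, ]
    d$x <- d$x + sample(c(-1, 0, 1), length(take), replace = TRUE)
    extra <- data.frame(z = 0L, y = max(g$y) + 40, x = 5L, value = 1)
    d <- rbind(d, extra)
    m <- match_channels(g, d, radius, px, zs)
    dz <- outer(g$z, d$z, "-") * zs
    dy <- outer(g$y, d$y, "-") * px
    dx <- outer(g$x, d$x, "-") * px
    dist <- sqrt(dz^2 + dy^2 + dx^2)
    opt <- oracle_match(dist, radius)
    expect_equal(nrow(m), opt$card)
    expect_equal(sum(m$distance_um), opt$total, tolerance = 1e-12)
    expect_setequal(paste(m$guide_idx, m$detection_idx),
                    paste(opt$pairs[, 1], opt$pairs[, 2]))
  }
})

test_that("calibration mismatches between spot sets are refused", {
  sc <- make_scene(tiny_scene_params(seed = 13L))
  ss <- call_spots(sc$channels$guide)
  other <- sc$channels$guide
  other$pixel_size_xy <- 0.2
  ss2 <- suppressWarnings(call_spots(other))  # coarser pixels undersample
  expect_error(match_channels(ss, ss2), "calibration")
  expect_error(match_channels(ss$spots, ss2$spots, 0.4), "calibration needed")
})

test_that("classification follows the colocalization partition rules", {
  g <- data.frame(z = c(0L, 0L, 0L, 0L), y = c(0L, 10L, 20L, 30L),
                  x = c(0L, 0L, 0L, 0L), value = 1,
                  cell_id = c(1L, 1L, 2L, 2L))
  wt <- data.frame(z = 0L, y = c(0L, 20L), x = c(0L, 0L), value = 1)
  mut <- data.frame(z = 0L, y = c(10L, 20L), x = c(0L, 0L), value = 1)
  rec <- classify_spots(g, wt, mut, radius_um = 0.4,
                        pixel_size_xy = px, z_spacing = zs)
  expect_equal(as.character(rec$call), c("wt", "mut", "ambiguous", "unlabeled"))
  expect_equal(rec$wt_distance_um[1], 0)
  expect_true(all(rec$wt_distance_um[!is.na(rec$wt_distance_um)] <= 0.4))

  # no detection spots: everything unlabeled
  rec0 <- classify_spots(g, wt[0, ], mut[0, ], 0.4,
                         pixel_size_xy = px, z_spacing = zs)
  expect_true(all(rec0$call == "unlabeled"))

  # swapping the channels swaps the calls exactly
  swp <- classify_spots(g, mut, wt, 0.4, pixel_size_xy = px, z_spacing = zs)
  expect_equal(as.character(swp$call), c("mut", "wt", "ambiguous", "unlabeled"))

  # nearest-wins resolution of double matches
  g2 <- data.frame(z = 0L, y = 0L, x = 0L, value = 1)
  wt2 <- data.frame(z = 0L, y = 1L, x = 0L, value = 1)
  mut2 <- data.frame(z = 0L, y = 2L, x = 0L, value = 1)
  amb <- classify_spots(g2, wt2, mut2, 0.4, pixel_size_xy = px, z_spacing = zs)
  expect_equal(as.character(amb$call), "ambiguous")
  res <- classify_spots(g2, wt2, mut2, 0.4, resolve_by_distance = TRUE,
                        pixel_size_xy = px, z_spacing = zs)
  expect_equal(as.character(res$call), "wt")
})

test_that("per-cell summaries partition the guide spots and conserve totals", {
  g <- data.frame(z = 0L, y = seq(0, 90, 10), x = 0L, value = 1,
                  cell_id = c(rep(1L, 6), rep(2L, 3), 0L))
  wt <- g[c(1:5, 7), c("z", "y", "x", "value")]
  mut <- g[8, c("z", "y", "x", "value")]
  rec <- classify_spots(g, wt, mut, 0.4, pixel_size_xy = px, z_spacing = zs)
  cs <- summarize_cells(rec)
  expect_true(all(cs$n_guide ==
                    cs$n_wt + cs$n_mut + cs$n_unlabeled + cs$n_ambiguous))
  tot <- attr(cs, "totals")
  expect_equal(unname(tot["n_guide"]), nrow(g))
  c1 <- cs[cs$cell_id == 1, ]
  expect_equal(c1$n_wt, 5)
  expect_equal(c1$fraction_mut_of_labeled, 0)
  c2 <- cs[cs$cell_id == 2, ]
  expect_equal(c2$n_wt, 1)
  expect_equal(c2$n_mut, 1)
  expect_equal(c2$fraction_mut_of_labeled, 0.5)
  # outside-cell bucket kept separately as cell 0
  expect_true(0L %in% cs$cell_id)

  empty <- summarize_cells(rec[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(unname(attr(empty, "totals")["n_guide"]), 0L)

  p <- plot_cell_alleles(cs)
  expect_s3_class(p, "ggplot")
})
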