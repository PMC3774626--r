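make_gaussian_spot_stack <- function(nz = 9, ny = 21, nx = 21,
                                     mu = c(4, 10, 10), sz = 1.5, sxy = 1.3,
                                     amp = 100) {
  # voxel j (1-based) covers 0-based coordinates [j - 1.5, j - 0.5]
  m1 <- function(n, mu, s) pnorm(seq_len(n) - 0.5, mu, s) -
    pnorm(seq_len(n) - 1.5, mu, s)
  v <- amp * (m1(nz, mu[1], sz) %o% m1(ny, mu[2], sxy) %o% m1(nx, mu[3], sxy))
  image_stack(v, "test", 0.13, 0.3)
}

test_that("the spot filter annihilates constants, is linear, and peaks on matched spots", {
  const <- image_stack(array(7, c(5, 16, 16)))
  f <- enhance(const)
  expect_lt(max(abs(f$voxels)), 1e-10)

  s <- make_gaussian_spot_stack()
  f1 <- enhance(s)
  s2 <- s; s2$voxels <- 2 * s$voxels
  f2 <- enhance(s2)
  expect_equal(f2$voxels, 2 * f1$voxels, tolerance = 1e-12)

  peak <- which(f1$voxels == max(f1$voxels), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(5, 11, 11))  # 1-based center voxel

  expect_warning(enhance(s, spot_sigma_xy = 0.05), "undersampled")
  expect_error(enhance(s, spot_sigma_xy = 0), "> 0")
})

test_that("regional maxima handle isolated peaks, constants and plateaus", {
  v <- array(0, c(1, 5, 5)); v[1, 3, 3] <- 10
  st <- image_stack(v)
  rm1 <- regional_maxima(st, min_value = -Inf)
  expect_equal(nrow(rm1), 1L)
  expect_equal(rm1$z, 0L); expect_equal(rm1$y, 2L); expect_equal(rm1$x, 2L)
  expect_equal(rm1$value, 10)

  # constant image: the whole-image plateau is not a maximum
  expect_equal(nrow(regional_maxima(image_stack(array(3, c(4, 6, 6))),
                                    min_value = -Inf)), 0L)

  # 2x2 plateau above a lower surround: one representative at the
  # floored centroid
  v <- array(0, c(1, 6, 6)); v[1, 3:4, 3:4] <- 5
  rm2 <- regional_maxima(image_stack(v), min_value = -Inf)
  expect_equal(nrow(rm2), 1L)
  expect_equal(c(rm2$y, rm2$x), c(2L, 2L))  # floor of centroid (2.5, 2.5)
  expect_equal(rm2$value, 5)
})

test_that("regional maxima match a brute-force neighbourhood scan on random stacks", {
  set.seed(101)
  for (i in 1:30) {
    v <- array(sample(0:5, 4 * 8 * 8, replace = TRUE), c(4, 8, 8))
    got <- regional_maxima(image_stack(v), min_value = -Inf)
    want <- oracle_regional_maxima(v)
    expect_identical(got$z, want$z)
    expect_identical(got$y, want$y)
    expect_identical(got$x, want$x)
    expect_equal(got$value, want$value)
    expect_identical(got$border, want$border)
  }
  # and for single-plane (8-connected) images
  for (i in 1:10) {
    v <- array(sample(0:4, 49, replace = TRUE), c(1, 7, 7))
    got <- regional_maxima(image_stack(v), min_value = -Inf)
    want <- oracle_regional_maxima(v)
    expect_equal(got[c("z", "y", "x", "value")],
                 want[c("z", "y", "x", "value")])
  }
})

test_that("threshold curves count survivors on a uniform grid, non-increasing", {
  cv <- threshold_curve(c(1, 2, 3), n_thresholds = 10)
  expect_s3_class(cv, "threshold_curve")
  expect_equal(cv$count[1], 3)
  expect_equal(cv$count[nrow(cv)], 1)
  expect_true(all(diff(cv$count) <= 0))
  # exact counts at the three candidate values
  expect_equal(vapply(c(1, 2, 3),
                      function(t) cv$count[which.min(abs(cv$threshold - t))],
                      numeric(1)), c(3, 2, 1))

  # all-equal candidates: count drops from total to zero at one point
  cve <- threshold_curve(rep(4, 7), n_thresholds = 10)
  expect_equal(cve$count[1], 7)
  expect_true(all(cve$count[-1] == 0))

  # random candidate sets match brute-force counting at every grid point
  set.seed(7)
  for (i in 1:20) {
    vals <- rlnorm(50, 3, 1)
    cv <- threshold_curve(vals, 25)
    brute <- vapply(cv$threshold, function(t) sum(vals >= t), numeric(1))
    expect_equal(cv$count, brute)
  }

  expect_error(threshold_curve(numeric(0)), "zero candidates")
  expect_error(threshold_curve(1:5, n_thresholds = 5), ">= 10")
  expect_error(as_threshold_curve(1:5, c(5, 4, 6, 2, 1)), "non-increasing")
})

test_that("threshold selection finds an exact plateau and breaks ties low", {
  # steep drop, long exact plateau at N = 60, steep drop
  thr <- seq(0, 99)
  counts <- c(seq(1000, 70, length.out = 20), rep(60, 60),
              seq(50, 1, length.out = 20))
  cv <- as_threshold_curve(thr, counts)
  sel <- select_threshold(cv, smoothing_window = 7)
  plateau_idx <- which(counts == 60)
  # the plateau interior is exactly flat: the earliest flat point wins
  expect_true(sel$index %in% plateau_idx)
  expect_equal(sel$index, min(which(abs(spotsense:::.log_deriv(cv, 7)[plateau_idx]) <
                                      1e-12) + plateau_idx[1] - 1L))
  expect_equal(sel$threshold, cv$threshold[sel$index])
})

test_that("call_spots composes the stages and honours manual thresholds", {
  sc <- make_scene(tiny_scene_params(seed = 3L))
  auto <- call_spots(sc$channels$guide, labels = sc$cell_label_map)
  expect_s3_class(auto, "spot_set")
  # |SpotSet| equals N(threshold) on its own curve
  expect_equal(nrow(auto$spots), auto$curve$count[auto$threshold_index])

  manual <- call_spots(sc$channels$guide, threshold = auto$threshold,
                       labels = sc$cell_label_map)
  expect_equal(manual$spots, auto$spots)
  expect_false(manual$auto)

  high <- call_spots(sc$channels$guide,
                     threshold = max(auto$curve$threshold) + 1)
  expect_equal(nrow(high$spots), 0L)
})

test_that("auto-threshold recovers the exact count on a clean noiseless scene", {
  p <- scene_params(shape = c(14L, 160L, 160L), n_cells = 4L,
                    spots_per_cell_mean = 6, cell_radius_um = 3.4,
                    background_spot_density = 0, background_level = 0,
                    read_noise_sd = 0, shot_noise = FALSE, seed = 21L)
  sc <- make_scene(p)
  # premise: spots are well separated (no pair merges into one blob)
  ts <- sc$true_spots
  dmin <- min(dist(cbind(ts$z * p$z_spacing / p$pixel_size_xy, ts$y, ts$x)))
  expect_gt(dmin, 4 * p$psf_sigma_xy / p$pixel_size_xy)
  ss <- call_spots(sc$channels$guide)
  expect_equal(nrow(ss$spots), nrow(ts))
})

test_that("detection is translation-equivariant away from borders", {
  base <- make_gaussian_spot_stack(nz = 12, ny = 40, nx = 40,
                                   mu = c(5, 15, 18))
  shifted <- make_gaussian_spot_stack(nz = 12, ny = 40, nx = 40,
                                      mu = c(6, 17, 21))
  f1 <- regional_maxima(enhance(base), min_value = 1)
  f2 <- regional_maxima(enhance(shifted), min_value = 1)
  top1 <- f1[which.max(f1$value), ]
  top2 <- f2[which.max(f2$value), ]
  expect_equal(c(top2$z - top1$z, top2$y - top1$y, top2$x - top1$x),
               c(1L, 2L, 3L))
})

test_that("per-cell counting partitions the spot set", {
  labels <- matrix(0L, 20, 20)
  labels[2:10, 2:10] <- 1L
  labels[12:18, 12:18] <- 2L
  spots <- data.frame(z = c(0L, 0L, 0L, 0L), y = c(3L, 4L, 13L, 0L),
                      x = c(3L, 5L, 14L, 19L), value = c(5, 6, 7, 8))
  tab <- count_per_cell(spots, labels)
  expect_equal(tab$spot_count[tab$cell_id == 1], 2)
  expect_equal(tab$spot_count[tab$cell_id == 2], 1)
  expect_equal(tab$spot_count[tab$cell_id == 0], 1)
  expect_equal(sum(tab$spot_count), nrow(spots))

  empty <- count_per_cell(spots[0, ], labels)
  expect_true(all(empty$spot_count == 0))
  expect_setequal(empty$cell_id, c(0L, 1L, 2L))

  expect_error(count_per_cell(data.frame(z = 0L, y = 25L, x = 0L, value = 1),
                              labels), "label map")
})
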