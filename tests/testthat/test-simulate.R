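test_that("scene generation is bit-reproducible under a fixed seed", {
  p <- tiny_scene_params()
  a <- make_scene(p)
  b <- make_scene(p)
  expect_identical(a$channels$guide$voxels, b$channels$guide$voxels)
  expect_identical(a$channels$dapi$voxels, b$channels$dapi$voxels)
  expect_identical(a$true_spots, b$true_spots)
  c_ <- make_scene(tiny_scene_params(seed = 43L))
  expect_false(identical(a$channels$guide$voxels, c_$channels$guide$voxels))
})

test_that("an empty scene is pure noise around the background level", {
  p <- tiny_scene_params(spots_per_cell_mean = 0, background_spot_density = 0)
  sc <- make_scene(p)
  m <- mean(sc$channels$guide$voxels)
  expect_lt(abs(m - p$background_level) / p$background_level, 0.01)
})

test_that("noiseless rendered spots integrate to their amplitudes", {
  p <- scene_params(
    shape = c(20L, 64L, 64L), n_cells = 2L, spots_per_cell_mean = 6,
    cell_radius_um = 1.8, background_spot_density = 0,
    background_level = 0, read_noise_sd = 0, shot_noise = FALSE, seed = 9L
  )
  sc <- make_scene(p)
  ts <- sc$true_spots
  expect_gt(nrow(ts), 0)
  # per-spot Gaussian mass actually inside the image volume
  sz <- p$psf_sigma_z / p$z_spacing
  sxy <- p$psf_sigma_xy / p$pixel_size_xy
  mass <- function(mu, sigma, n) pnorm(n - 0.5, mu, sigma) - pnorm(-0.5, mu, sigma)
  expected <- sum(ts$amplitude * mass(ts$z, sz, 20) *
                    mass(ts$y, sxy, 64) * mass(ts$x, sxy, 64))
  total <- sum(sc$channels$guide$voxels)
  # total intensity matches the analytic in-volume mass closely ...
  expect_lt(abs(total - expected) / expected, 0.003)
  # ... and the best-contained spot loses less than 1% of its amplitude
  in_mass <- mass(ts$z, sz, 20) * mass(ts$y, sxy, 64) * mass(ts$x, sxy, 64)
  expect_gt(max(in_mass), 0.99)
})

test_that("scene parameters are validated", {
  expect_error(scene_params(contrast_ratio = 0), "contrast_ratio")
  expect_error(scene_params(labeling_efficiency_wt = 1.5), "probabilities")
  expect_error(scene_params(allele_fraction_mut = 2), "allele_fraction_mut")
  expect_error(scene_params(bogus = 1), "unknown scene parameter")
})

test_that("true spots lie inside their cell's label region and counts add up", {
  sc <- make_scene(tiny_scene_params(seed = 7L))
  ts <- sc$true_spots
  lab_at <- sc$cell_label_map[cbind(round(ts$y) + 1L, round(ts$x) + 1L)]
  expect_true(all(lab_at == ts$cell_id))
  per_cell_truth <- table(factor(ts$cell_id, levels = 1:sc$params$n_cells))
  expect_equal(sum(per_cell_truth), nrow(ts))
})

test_that("candidate intensities are bimodal at high contrast, unimodal near contrast 1", {
  mode_count <- function(contrast) {
    p <- scene_params(shape = c(8L, 128L, 128L), n_cells = 4L,
                      spots_per_cell_mean = 40,
                      background_spot_density = 40, cell_radius_um = 3.2,
                      contrast_ratio = contrast, background_level = 0,
                      read_noise_sd = 0, shot_noise = FALSE,
                      max_overlap_fraction = 1, seed = 5L)
    sc <- make_scene(p)
    filt <- enhance(sc$channels$guide)
    cand <- regional_maxima(filt, min_value = 1e-6)
    # fixed-bandwidth density of log intensity; count prominent modes
    den <- density(log(cand$value), bw = 0.25, n = 256)
    y <- den$y
    peaks <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
    sum(y[peaks] > 0.1 * max(y))
  }
  expect_gte(mode_count(8), 2L)
  expect_equal(mode_count(1), 1L)
})

test_that("condition series fixes the background-spot amplitude and scales signal", {
  base <- tiny_scene_params()
  scenes <- make_condition_series(base, c(8, 4, 2, 1))
  expect_length(scenes, 4L)
  sig <- vapply(scenes, function(s) s$params$signal_amplitude, numeric(1))
  bg <- sig / vapply(scenes, function(s) s$params$contrast_ratio, numeric(1))
  expect_equal(unname(bg), rep(base$signal_amplitude / base$contrast_ratio, 4))
  expect_true(all(diff(sig) < 0))  # separation falls with the ratio
  # a single ratio at base settings is the plain scene
  one <- make_condition_series(base, base$contrast_ratio)
  expect_identical(one[[1]]$channels$guide$voxels,
                   make_scene(base)$channels$guide$voxels)
})

test_that("SNP scenes render detection spots per allele and efficiency", {
  # fraction 0: the mutant channel holds no true-spot renders
  p0 <- tiny_scene_params(allele_fraction_mut = 0,
                          labeling_efficiency_wt = 1,
                          labeling_efficiency_mut = 1)
  sc0 <- make_snp_scene(p0)
  expect_true(all(sc0$true_spots$allele == "wt"))
  expect_false(any(sc0$true_spots$in_mut))
  expect_true(all(sc0$true_spots$in_wt))

  # fraction 0.5, efficiency 1, no noise: every guide spot has exactly
  # one detection-channel render at its own position
  p1 <- tiny_scene_params(allele_fraction_mut = 0.5,
                          labeling_efficiency_wt = 1,
                          labeling_efficiency_mut = 1,
                          background_spot_density = 0, background_level = 0,
                          read_noise_sd = 0, shot_noise = FALSE)
  sc1 <- make_snp_scene(p1)
  expect_true(all(xor(sc1$true_spots$in_wt, sc1$true_spots$in_mut)))
  expect_equal(sc1$true_spots$in_mut, sc1$true_spots$allele == "mut")

  expect_error(make_snp_scene(tiny_scene_params()), "allele_fraction_mut")
})

test_that("labeled allele fractions recover the simulated fraction", {
  # binomial check at the ground-truth level across seeds
  for (s in c(1L, 2L, 3L)) {
    p <- scene_params(shape = c(8L, 160L, 160L), n_cells = 6L,
                      spots_per_cell_mean = 60, cell_radius_um = 2.4,
                      allele_fraction_mut = 0.5, max_overlap_fraction = 1,
                      seed = s)
    sc <- make_snp_scene(p)
    lab <- sc$true_spots[sc$true_spots$in_wt | sc$true_spots$in_mut, ]
    n <- nrow(lab)
    frac <- mean(lab$in_mut)
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  }
})

test_that("a crowded scene warns about spot overlap", {
  expect_warning(
    make_scene(tiny_scene_params(spots_per_cell_mean = 150,
                                 cell_radius_um = 1.2,
                                 max_overlap_fraction = 0.1)),
    "overlap"
  )
})
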