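test_that("particle diameter generator matches log-normal moments and is seeded", {
  # zero-variance degenerate case: every diameter equals the median
  expect_equal(gen_particle_diameters(5, log_mu = log(57), log_sigma = 0,
                                      seed = 1),
               rep(57, 5))

  # geometric mean converges to exp(log_mu) (closed-form log-normal median)
  d <- gen_particle_diameters(1e4, log_mu = log(57), log_sigma = 0.35,
                              seed = 1)
  expect_lt(abs(exp(mean(log(d))) / 57 - 1), 0.02)
  expect_lt(abs(median(d) / 57 - 1), 0.02)

  # seeded determinism and stream isolation
  expect_identical(gen_particle_diameters(100, log(57), 0.35, seed = 9),
                   gen_particle_diameters(100, log(57), 0.35, seed = 9))

  expect_error(gen_particle_diameters(0, log(57), 0.3), "invalid-parameter")
  expect_error(gen_particle_diameters(10, log(57), -1), "invalid-parameter")
})

test_that("reflectance scene generator renders disks with exact ground truth", {
  # empty scene: constant background, empty truth
  sp0 <- scene_spec(image_shape = c(64, 64), n_clusters = 0, noise_sd = 0,
                    psf_sigma = 0)
  g0 <- gen_reflectance_image(sp0)
  expect_equal(nrow(g0$truth), 0)
  expect_true(all(g0$image$intensities == sp0$background_level))

  # construction invariant: requested count, centroids inside the annulus
  sp <- scene_spec(image_shape = c(256, 256), n_clusters = 50, seed = 7,
                   diameter_log_mu = log(0.4), diameter_log_sigma = 0.3)
  g <- gen_reflectance_image(sp)
  expect_equal(nrow(g$truth), 50)
  half_um <- 0.5 * 256 * sp$pixel_size
  rr <- sqrt((g$truth$x_um - half_um)^2 + (g$truth$y_um - half_um)^2)
  expect_true(all(rr >= 2 * sp$cytoplasm_annulus[1] * half_um - 1e-9))
  expect_true(all(rr <= 2 * sp$cytoplasm_annulus[2] * half_um + 1e-9))

  # analytic disk-area oracle: one unblurred noiseless 1 um disk at
  # 0.1 um/px covers pi * 5^2 px within a one-pixel boundary ring
  sp1 <- scene_spec(image_shape = c(128, 128), pixel_size = 0.1,
                    n_clusters = 1, diameter_log_mu = log(1),
                    diameter_log_sigma = 0, psf_sigma = 0, noise_sd = 0,
                    seed = 3)
  g1 <- gen_reflectance_image(sp1)
  fg_px <- sum(g1$image$intensities > sp1$background_level)
  r_px <- 0.5 / 0.1
  expect_lt(abs(fg_px - pi * r_px^2), 2 * pi * r_px + pi)

  # impossible placement: degenerate annulus budget exhausts
  sp_bad <- scene_spec(image_shape = c(64, 64), n_clusters = 5,
                       cytoplasm_annulus = c(0.49999, 0.5))
  expect_error(gen_reflectance_image(sp_bad), "placement")
})

test_that("uptake series generator satisfies the first-order model", {
  # direct evaluation of the saturating model at t = 27 h
  s <- gen_uptake_series(2.31, 0.158, sample_times = 27, replicates = 1,
                         noise_sd = 0, seed = 1)
  expect_equal(s$value, 2.31 * (1 - exp(-0.158 * 27)), tolerance = 1e-12)
  expect_equal(s$value, 2.279, tolerance = 1e-3)

  # k = 0: nothing is ever absorbed
  s0 <- gen_uptake_series(2, 0, sample_times = c(0, 3, 6), replicates = 2,
                          noise_sd = 0, seed = 1)
  expect_true(all(s0$value == 0))

  # noiseless series are non-decreasing in t and exact to machine precision
  s2 <- gen_uptake_series(1.8, 0.4, sample_times = c(0, 1, 2, 5, 30),
                          replicates = 1, noise_sd = 0, seed = 2)
  expect_true(all(diff(s2$value) >= 0))
  expect_lt(max(abs(s2$value - 1.8 * (1 - exp(-0.4 * s2$time_h)))), 1e-12)

  expect_identical(gen_uptake_series(2, 0.2, noise_sd = 0.1, seed = 5),
                   gen_uptake_series(2, 0.2, noise_sd = 0.1, seed = 5))
  expect_error(gen_uptake_series(-1, 0.1), "invalid-parameter")
  expect_error(gen_uptake_series(1, -0.1), "invalid-parameter")
})

test_that("cell mask generator digitizes perturbed spheres reproducibly", {
  sp <- cell_mask_spec(grid_shape = c(96, 96, 96), voxel_size = 0.25,
                       radius = 10, roughness_amplitude = 0)
  m <- gen_cell_mask(sp)
  vol <- sum(m$values) * 0.25^3
  expect_lt(abs(vol / (4 / 3 * pi * 1000) - 1), 0.03)

  sp_r <- cell_mask_spec(grid_shape = c(64, 64, 64), voxel_size = 0.25,
                         radius = 6, roughness_amplitude = 1.5,
                         roughness_frequency = 8, seed = 4)
  expect_identical(gen_cell_mask(sp_r)$values, gen_cell_mask(sp_r)$values)

  expect_error(gen_cell_mask(cell_mask_spec(grid_shape = c(32, 32, 32),
                                            voxel_size = 0.25, radius = 10)),
               "geometry")
  expect_error(cell_mask_spec(radius = 5, roughness_amplitude = 5),
               "invalid-parameter")
})

test_that("study bundle mirrors the group x timepoint design deterministically", {
  cfg <- study_config(groups = c(0, 5, 10, 20), timepoints = c(3, 6, 27),
                      replicates = 3, master_seed = 11)
  b <- gen_group_study(cfg)
  expect_equal(nrow(b$uptake), 4 * 3 * 3)
  cells <- table(b$uptake$group_min, b$uptake$time_h)
  expect_equal(dim(cells), c(4L, 3L))
  expect_true(all(cells == 3))

  # single-cell design
  b1 <- gen_group_study(study_config(groups = 0, timepoints = 3,
                                     replicates = 1, a_max = 2, k = 0.1))
  expect_equal(nrow(b1$uptake), 1)

  # reruns from the same master seed are identical
  b2 <- gen_group_study(cfg)
  expect_identical(b$uptake, b2$uptake)

  expect_error(study_config(groups = numeric(0)), "invalid-config")
})
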