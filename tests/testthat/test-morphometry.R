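test_that("refractive-index classification respects the band definitions", {
  # uniform nucleus-band volume
  v <- voxel_volume(array(1.355, c(4, 4, 4)), 0.5)
  m <- classify_ri(v)
  expect_equal(sum(m$nucleus$values), 64)
  expect_equal(sum(m$membrane$values) + sum(m$lipid$values) +
                 sum(m$cytoplasm$values), 0)

  # constructed shells: per-band voxel counts equal construction counts
  a <- array(1.30, c(10, 10, 10))
  a[2:9, 2:9, 2:9] <- 1.335   # membrane shell
  a[3:8, 3:8, 3:8] <- 1.345   # cytoplasm (no named band)
  a[4:7, 4:7, 4:7] <- 1.355   # nucleus
  a[5:6, 5:6, 5:6] <- 1.38    # lipid droplets
  m2 <- classify_ri(voxel_volume(a, 0.5))
  expect_equal(sum(m2$lipid$values), 2^3)
  expect_equal(sum(m2$nucleus$values), 4^3 - 2^3)
  expect_equal(sum(m2$cytoplasm$values), 6^3 - 4^3)
  expect_equal(sum(m2$membrane$values), 8^3 - 6^3)
  # masks are disjoint
  total <- m2$membrane$values + m2$nucleus$values + m2$lipid$values +
    m2$cytoplasm$values
  expect_true(all(total <= 1))

  # the 1.34-1.35 gap belongs to no named band
  g <- classify_ri(voxel_volume(array(1.345, c(3, 3, 3)), 0.5))
  expect_equal(sum(g$membrane$values) + sum(g$nucleus$values) +
                 sum(g$lipid$values), 0)
  expect_equal(sum(g$cytoplasm$values), 27)

  expect_error(classify_ri(voxel_volume(array(1, c(3, 3, 3)), 0.5)), "type")
})

test_that("sphere morphometry matches the analytic surface and volume", {
  m <- gen_cell_mask(cell_mask_spec(grid_shape = c(96, 96, 96),
                                    voxel_size = 0.25, radius = 10))
  r <- measure_cell(m)
  expect_lt(abs(r$volume / (4 / 3 * pi * 10^3) - 1), 0.03)
  expect_lt(abs(r$surface_area / (4 * pi * 10^2) - 1), 0.03)
  expect_lt(abs(r$av_ratio / 0.3 - 1), 0.03)

  # the naive voxel-face count fails the same tolerance (negative control)
  rf <- measure_cell(m, method = "voxel-faces")
  expect_gt(abs(rf$surface_area / (4 * pi * 10^2) - 1), 0.03)

  expect_error(measure_cell(voxel_volume(array(0, c(4, 4, 4)), 0.5)),
               "empty-input")
})

test_that("cube morphometry and scaling behave dimensionally", {
  cube <- array(0, c(48, 48, 48))
  cube[5:44, 5:44, 5:44] <- 1  # 40 voxels a side at 0.25 um = 10 um
  r <- measure_cell(voxel_volume(cube, 0.25))
  expect_lt(abs(r$volume / 1000 - 1), 0.01)

  # doubling the voxel size doubles the shape: A/V halves
  r2 <- measure_cell(voxel_volume(cube, 0.5))
  expect_equal(r2$av_ratio, r$av_ratio / 2, tolerance = 0.01)
})

test_that("mesh surface area is rotation invariant", {
  e0 <- digitize_ellipsoid(c(6, 4.5, 3.5), 0.25, 64)
  e30 <- digitize_ellipsoid(c(6, 4.5, 3.5), 0.25, 64, rot_deg = 30,
                            axis = c(1, 1, 0))
  r0 <- measure_cell(e0)
  r30 <- measure_cell(e30)
  expect_lt(abs(r30$av_ratio / r0$av_ratio - 1), 0.02)
})

test_that("surface area grows monotonically with membrane roughness", {
  av <- vapply(c(0, 1, 2), function(a) {
    m <- gen_cell_mask(cell_mask_spec(grid_shape = c(72, 72, 72),
                                      voxel_size = 0.25, radius = 6,
                                      roughness_amplitude = a,
                                      roughness_frequency = 8, seed = 3))
    measure_cell(m)$av_ratio
  }, 1)
  expect_true(all(diff(av) > 0))
})

test_that("disconnected masks fall back to the largest component", {
  a <- array(0, c(20, 20, 20))
  a[3:10, 3:10, 3:10] <- 1
  a[15:17, 15:17, 15:17] <- 1
  expect_warning(r <- measure_cell(voxel_volume(a, 0.5)), "disconnected")
  expect_equal(r$volume, 8^3 * 0.5^3)
})

test_that("A/V study reports group effects per timepoint", {
  # two identical groups: exactly zero effect, F = 0, p = 1
  same_cells <- seq(0.28, 0.32, length.out = 8)
  ident <- data.frame(group_min = rep(c(0, 20), each = 8), time_h = 3,
                      av_ratio = rep(same_cells, 2))
  s_id <- av_ratio_study(ident, control_group = 0)
  expect_equal(s_id$percent_increase$percent_increase, 0, tolerance = 1e-12)
  expect_equal(s_id$comparisons$t3$p_anova, 1, tolerance = 1e-9)

  set.seed(7)
  base <- data.frame(
    group_min = rep(c(0, 20), each = 8), time_h = 3,
    av_ratio = c(rnorm(8, 0.30, 0.005), rnorm(8, 0.30, 0.005)))

  # a constructed ~17% effect is recovered within 3 points
  eff <- base
  eff$av_ratio[eff$group_min == 20] <- rnorm(8, 0.30 * 1.17, 0.005)
  s1 <- av_ratio_study(eff, control_group = 0)
  expect_lt(abs(s1$percent_increase$percent_increase - 17), 3)
  expect_lt(s1$comparisons$t3$p_anova, 0.01)

  # control-only input is an invalid design
  ctrl_only <- base[base$group_min == 0, ]
  expect_error(av_ratio_study(ctrl_only, control_group = 0),
               "invalid-design")
  expect_error(av_ratio_study(base[c(1, 9:16), ], control_group = 0),
               "invalid-design")
})

test_that("generator roughness raises measured surface area end to end", {
  spec0 <- cell_mask_spec(grid_shape = c(72, 72, 72), voxel_size = 0.25,
                          radius = 6, roughness_amplitude = 0, seed = 5)
  spec2 <- cell_mask_spec(grid_shape = c(72, 72, 72), voxel_size = 0.25,
                          radius = 6, roughness_amplitude = 2,
                          roughness_frequency = 8, seed = 5)
  a0 <- measure_cell(gen_cell_mask(spec0))$surface_area
  a2 <- measure_cell(gen_cell_mask(spec2))$surface_area
  expect_gt(a2, a0)
})
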