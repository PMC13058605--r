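test_that("normalization rescales to [0, 1] and is idempotent", {
  img <- reflectance_image(matrix(c(100, 500, 4195, 2000), 2), 0.2)
  n <- normalize_image(img)
  expect_equal(range(n$intensities), c(0, 1))
  expect_equal(n$intensities[1, 1], 0)
  expect_equal(n$intensities[1, 2], 1)  # 4195 maps to 1.0

  # constant image maps to all zeros by definition
  flat <- normalize_image(reflectance_image(matrix(7, 4, 4), 0.2))
  expect_true(all(flat$intensities == 0))

  # idempotence: the second pass is the identity
  expect_equal(normalize_image(n)$intensities, n$intensities)
})

test_that("segmentation recovers zero-noise scenes exactly and is seeded", {
  sp <- scene_spec(image_shape = c(512, 512), n_clusters = 20, noise_sd = 0,
                   psf_sigma = 0, diameter_log_mu = log(0.8),
                   diameter_log_sigma = 0.3, seed = 7)
  g <- gen_reflectance_image(sp)
  img <- normalize_image(g$image)
  mask <- segment_gnp(img, k_clusters = 2, seed = 1)
  expect_equal(max(mask$labels), expected_component_count(g$truth))
  expect_equal(max(mask$labels), 20)

  # determinism under a fixed seed
  mask2 <- segment_gnp(img, k_clusters = 2, seed = 1)
  expect_identical(mask$labels, mask2$labels)

  # featureless frame: nothing to find
  empty <- normalize_image(reflectance_image(matrix(0.2, 64, 64), 0.2))
  expect_equal(max(segment_gnp(empty, seed = 1)$labels), 0)

  expect_error(segment_gnp(img, k_clusters = 1), "invalid-parameter")
  two_level <- reflectance_image(matrix(rep(c(0, 1), 32), 8), 0.2)
  expect_error(segment_gnp(two_level, k_clusters = 3),
               "degenerate-clustering")
})

test_that("segmentation is invariant to a constant intensity offset", {
  sp <- scene_spec(image_shape = c(256, 256), n_clusters = 12,
                   noise_sd = 0.02, seed = 21)
  g <- gen_reflectance_image(sp)
  m1 <- segment_gnp(normalize_image(g$image), seed = 1)
  shifted <- reflectance_image(g$image$intensities + 5, g$image$pixel_size)
  m2 <- segment_gnp(normalize_image(shifted), seed = 1)
  expect_identical(m1$labels, m2$labels)
})

test_that("cluster count error does not grow as noise falls", {
  counts <- vapply(c(0.05, 0.02, 0), function(ns) {
    sp <- scene_spec(image_shape = c(256, 256), n_clusters = 15,
                     noise_sd = ns, diameter_log_mu = log(1),
                     diameter_log_sigma = 0.25, seed = 13)
    g <- gen_reflectance_image(sp)
    found <- max(segment_gnp(normalize_image(g$image), seed = 1)$labels)
    abs(found - expected_component_count(g$truth))
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster measurement applies the equivalent-diameter formula", {
  # closed form: 100 px at 0.1 um/px
  mask <- rasterize_disk_mask(1.06, 0.1)  # any disk; formula checked directly
  tab <- extract_clusters(mask)
  expect_equal(tab$equivalent_diameter_um,
               2 * sqrt(tab$pixel_count / pi) * 0.1)
  fake <- mask
  fake$labels <- array(0L, c(8, 8))
  fake$labels[3:7, 3:7] <- 1L  # plant a known 25-px component
  fake$labels[1, 1] <- 0L
  tab25 <- extract_clusters(fake)
  expect_equal(tab25$pixel_count, 25)
  expect_equal(tab25$equivalent_diameter_um, 2 * sqrt(25 / pi) * 0.1)

  # empty mask gives an empty table, not an error
  empty <- fake
  empty$labels <- array(0L, c(8, 8))
  expect_equal(nrow(extract_clusters(empty)), 0)

  # rasterization oracle: a true 1.0 um disk measures within 5%
  m1 <- rasterize_disk_mask(1.0, 0.1)
  d1 <- extract_clusters(m1)$equivalent_diameter_um
  expect_lt(abs(d1 / 1.0 - 1), 0.05)
})

test_that("equivalent diameter is unbiased across the reported size range", {
  set.seed(42)
  dtrue <- runif(100, 0.4, 2)
  rel_err <- vapply(dtrue, function(d) {
    est <- extract_clusters(rasterize_disk_mask(d, 0.1))$equivalent_diameter_um
    abs(est / d - 1)
  }, 1)
  expect_lt(median(rel_err), 0.05)
})

test_that("group summaries pool cluster sizes", {
  mk <- function(sizes) {
    df <- data.frame(image_id = "i", group_min = 0,
                     label = seq_along(sizes),
                     pixel_count = round(pi * (sizes / 2 / 0.1)^2),
                     equivalent_diameter_um = sizes,
                     centroid_x_um = 0, centroid_y_um = 0)
    class(df) <- c("cluster_table", "data.frame")
    df
  }
  s1 <- summarize_group(mk(c(1, 1, 1)), group_min = 0)
  expect_equal(c(s1$mean, s1$sd, s1$max), c(1, 0, 1))

  s2 <- summarize_group(mk(c(0.2, 0.6, 1.0)), group_min = 5)
  expect_equal(s2$mean, 0.6)
  expect_equal(s2$max, 1.0)

  # pooled mean of a log-normal group approaches the analytic mean
  d <- gen_particle_diameters(500, log_mu = log(0.5), log_sigma = 0.5,
                              seed = 8)
  s3 <- summarize_group(mk(d), group_min = 10)
  expect_lt(abs(s3$mean / (0.5 * exp(0.5^2 / 2)) - 1), 0.10)

  empty <- mk(1)[0, ]
  expect_error(summarize_group(empty), "empty-group")
})

test_that("percent reduction reproduces the reference group comparisons", {
  expect_equal(round(percent_reduction(0.597, 0.483), 1), 19.1)
  expect_equal(round(percent_reduction(0.597, 0.465), 2), 22.11)
  expect_equal(round(percent_reduction(0.597, 0.495), 2), 17.09)
  expect_equal(percent_reduction(0.7, 0.7), 0)
  expect_error(percent_reduction(0, 0.5), "invalid-parameter")
})

test_that("cluster histograms fit a log-normal in micrometre units", {
  d <- gen_particle_diameters(1e4, log_mu = log(0.5), log_sigma = 0.45,
                              seed = 5)
  s <- summarize_group(list(data.frame(equivalent_diameter_um = d)),
                       group_min = 0, bin_width = 0.05)
  f <- fit_cluster_histogram(s)
  expect_true(f$converged)
  expect_lt(abs(f$log_mu / log(0.5) - 1), 0.02)

  s2 <- summarize_group(list(data.frame(equivalent_diameter_um =
                                          c(0.1, 0.1, 0.3))),
                        group_min = 0, bin_width = 0.1)
  expect_error(fit_cluster_histogram(s2), "underdetermined-fit")
})

test_that("exposure regression reports r, R^2 and the model F-test", {
  x <- c(0, 5, 10, 20)
  y <- c(0.597, 0.483, 0.465, 0.495)
  lin <- exposure_regression(x, y, degree = 1, level = "group_means")
  quad <- exposure_regression(x, y, degree = 2, level = "group_means")
  expect_equal(lin$r_squared, 0.3392, tolerance = 0.005 / 0.3392)
  expect_equal(quad$r_squared, 0.9579, tolerance = 0.005 / 0.9579)

  # r^2 identity for straight-line fits
  expect_equal(lin$r_squared, lin$pearson_r^2, tolerance = 1e-12)
  set.seed(3)
  xi <- rnorm(50); yi <- 0.4 * xi + rnorm(50)
  li <- exposure_regression(xi, yi, degree = 1)
  expect_equal(li$r_squared, li$pearson_r^2, tolerance = 1e-12)

  # saturated straight line through two distinct points: R^2 = 1, p undefined
  sat <- exposure_regression(c(0, 10), c(1, 2), degree = 1)
  expect_equal(sat$r_squared, 1, tolerance = 1e-12)
  expect_true(is.na(sat$p_model))

  expect_error(exposure_regression(c(0, 5), c(1, 2), degree = 2),
               "underdetermined-fit")
})
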