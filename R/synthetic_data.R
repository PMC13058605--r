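# Evaluate expr with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("invalid-parameter: seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable per-item seed derived from a master seed; stays inside 32-bit range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647)
}

#' Draw log-normal particle diameters
#'
#' Seeded i.i.d. log-normal sample, the distribution that describes the
#' diameters reported by nanoparticle tracking analysis for colloidal gold.
#'
#' @param n Number of particles (>= 1).
#' @param log_mu Log-scale location, log(nm); \code{exp(log_mu)} is the
#'   median diameter.
#' @param log_sigma Log-scale shape (>= 0); 0 gives identical diameters.
#' @param seed RNG seed.
#' @return Numeric vector of n diameters (nm).
#' @export
#' @examples
#' d <- gen_particle_diameters(1000, log_mu = log(57), log_sigma = 0.35, seed = 1)
gen_particle_diameters <- function(n, log_mu = log(57), log_sigma = 0.35,
                                   seed = 1) {
  if (n < 1) stop("invalid-parameter: n must be >= 1")
  if (log_sigma < 0) stop("invalid-parameter: log_sigma must be >= 0")
  with_seed(seed, stats::rlnorm(n, meanlog = log_mu, sdlog = log_sigma))
}

#' Scene specification for a synthetic reflectance image
#'
#' Describes a label-free confocal reflectance scene: bright nanoparticle
#' clusters with log-normal equivalent diameters placed uniformly inside a
#' cytoplasmic annulus, blurred by a Gaussian point-spread function and
#' corrupted by additive Gaussian noise. Default diameter parameters give a
#' cluster population with mean +/- SD close to 0.60 +/- 0.52 um, matching
#' an untreated-cell condition; the default frame mimics a 1024 x 1024
#' acquisition at 0.2 um/pixel (about the 200 nm lateral resolution of a
#' pinhole-restricted 60x reflectance setup).
#'
#' @param image_shape Pixels, c(height, width).
#' @param pixel_size um per pixel (> 0).
#' @param n_clusters Number of clusters to place (>= 0).
#' @param diameter_log_mu,diameter_log_sigma Log-normal parameters of the
#'   true cluster equivalent diameters, log(um) and dimensionless.
#' @param cytoplasm_annulus c(inner, outer) radii as fractions of the image
#'   half-extent, 0 <= inner < outer <= 0.5 of the short side.
#' @param psf_sigma Gaussian PSF sigma in um (0 disables blurring).
#' @param background_level Background intensity in [0, 1].
#' @param noise_sd Additive Gaussian noise SD on the [0, 1] intensity scale.
#' @param seed RNG seed.
#' @return A list of class \code{"scene_spec"}.
#' @export
scene_spec <- function(image_shape = c(1024, 1024), pixel_size = 0.2,
                       n_clusters = 150,
                       diameter_log_mu = log(0.45), diameter_log_sigma = 0.75,
                       cytoplasm_annulus = c(0.15, 0.45),
                       psf_sigma = 0.085, background_level = 0.1,
                       noise_sd = 0.02, seed = 1) {
  if (pixel_size <= 0) stop("invalid-parameter: pixel_size must be > 0")
  if (n_clusters < 0) stop("invalid-parameter: n_clusters must be >= 0")
  if (diameter_log_sigma < 0) stop("invalid-parameter: diameter_log_sigma >= 0")
  if (noise_sd < 0) stop("invalid-parameter: noise_sd must be >= 0")
  if (psf_sigma < 0) stop("invalid-parameter: psf_sigma must be >= 0")
  if (length(cytoplasm_annulus) != 2 ||
      cytoplasm_annulus[1] < 0 || cytoplasm_annulus[1] >= cytoplasm_annulus[2] ||
      cytoplasm_annulus[2] > 0.5)
    stop("invalid-parameter: annulus must satisfy 0 <= inner < outer <= 0.5")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, n_clusters = as.integer(n_clusters),
                 diameter_log_mu = diameter_log_mu,
                 diameter_log_sigma = diameter_log_sigma,
                 cytoplasm_annulus = cytoplasm_annulus,
                 psf_sigma = psf_sigma, background_level = background_level,
                 noise_sd = noise_sd, seed = seed),
            class = "scene_spec")
}

#' Generate a synthetic reflectance image with ground truth
#'
#' Renders each cluster as a filled disk of its true equivalent diameter
#' (so the diameter recovered by segmentation has a well-defined target),
#' convolves with the Gaussian PSF, adds noise and clips to [0, 1].
#' Placement uses uniform rejection sampling inside the annulus with a
#' 10,000-attempt budget; overlaps are allowed, and clusters whose disks
#' touch another disk are flagged \code{merged} in the ground truth since a
#' segmenter will see them as one component.
#'
#' @param spec A \code{\link{scene_spec}}.
#' @return A list with \code{image} (a \code{\link{reflectance_image}}) and
#'   \code{truth}, a data frame of (x_um, y_um, diameter_um, merged).
#' @export
gen_reflectance_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  px <- spec$pixel_size
  half_um <- 0.5 * min(h, w) * px
  r_in <- 2 * spec$cytoplasm_annulus[1] * half_um
  r_out <- 2 * spec$cytoplasm_annulus[2] * half_um
  cx <- w * px / 2; cy <- h * px / 2

  res <- with_seed(spec$seed, {
    n <- spec$n_clusters
    xs <- ys <- numeric(n)
    attempts <- 0L
    placed <- 0L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > 10000L)
        stop("placement: annulus too small to place ", n,
             " clusters within the attempt budget")
      x <- stats::runif(1, -r_out, r_out)
      y <- stats::runif(1, -r_out, r_out)
      rr <- sqrt(x^2 + y^2)
      if (rr >= r_in && rr <= r_out) {
        placed <- placed + 1L
        xs[placed] <- cx + x
        ys[placed] <- cy + y
      }
    }
    d <- if (n > 0)
      stats::rlnorm(n, spec$diameter_log_mu, spec$diameter_log_sigma)
    else numeric(0)
    noise <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    else 0
    list(xs = xs, ys = ys, d = d, noise = noise)
  })

  img <- matrix(spec$background_level, h, w)
  # pixel centres in um (row = y, col = x)
  if (spec$n_clusters > 0) {
    xc <- (seq_len(w) - 0.5) * px
    yc <- (seq_len(h) - 0.5) * px
    for (i in seq_len(spec$n_clusters)) {
      rad <- res$d[i] / 2
      ci <- which(abs(xc - res$xs[i]) <= rad + px)
      ri <- which(abs(yc - res$ys[i]) <= rad + px)
      if (length(ci) == 0 || length(ri) == 0) next
      dx <- xc[ci] - res$xs[i]
      dy <- yc[ri] - res$ys[i]
      inside <- outer(dy^2, dx^2, "+") <= rad^2
      sub <- img[ri, ci, drop = FALSE]
      sub[inside] <- 1
      img[ri, ci] <- sub
    }
  }
  if (spec$psf_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = spec$psf_sigma / px))
  }
  img <- img + res$noise
  img <- pmin(pmax(img, 0), 1)

  merged <- rep(FALSE, spec$n_clusters)
  if (spec$n_clusters > 1) {
    for (i in seq_len(spec$n_clusters - 1)) {
      for (j in (i + 1):spec$n_clusters) {
        gap <- sqrt((res$xs[i] - res$xs[j])^2 + (res$ys[i] - res$ys[j])^2)
        if (gap <= (res$d[i] + res$d[j]) / 2) merged[i] <- merged[j] <- TRUE
      }
    }
  }
  truth <- data.frame(x_um = res$xs, y_um = res$ys,
                      diameter_um = res$d, merged = merged)
  list(image = reflectance_image(img, pixel_size = px), truth = truth)
}

#' Simulate an ICP-AES uptake time course
#'
#' Replicate measurements of the saturating first-order uptake curve
#' \eqn{Y(t) = A_{max}(1 - e^{-kt})} with additive Gaussian noise. With
#' \code{noise_sd = 0} the series satisfies the model exactly, including a
#' zero value at t = 0 (no intracellular particles at administration).
#'
#' @param a_max_true Asymptotic uptake, mg/L.
#' @param k_true Absorption rate constant, 1/h (>= 0).
#' @param sample_times Hours since administration (>= 0).
#' @param replicates Replicates per time point (>= 1).
#' @param noise_sd Measurement noise SD, mg/L.
#' @param seed RNG seed.
#' @param group_min Ultrasound exposure label for the series, minutes.
#' @return An \code{\link{uptake_series}} data frame.
#' @export
#' @examples
#' gen_uptake_series(2.31, 0.158, c(3, 6, 27), replicates = 3,
#'                   noise_sd = 0.1, seed = 1, group_min = 20)
gen_uptake_series <- function(a_max_true, k_true, sample_times = c(3, 6, 27),
                              replicates = 3, noise_sd = 0.15, seed = 1,
                              group_min = NA_real_) {
  if (a_max_true <= 0) stop("invalid-parameter: a_max_true must be > 0")
  if (k_true < 0) stop("invalid-parameter: k_true must be >= 0")
  if (any(sample_times < 0)) stop("invalid-parameter: times must be >= 0")
  if (replicates < 1) stop("invalid-parameter: replicates must be >= 1")
  if (noise_sd < 0) stop("invalid-parameter: noise_sd must be >= 0")
  tt <- rep(sort(sample_times), each = replicates)
  mu <- a_max_true * (1 - exp(-k_true * tt))
  val <- with_seed(seed, mu + stats::rnorm(length(tt), 0, noise_sd))
  uptake_series(time_h = tt, value = val, group_min = group_min,
                replicate = rep(seq_len(replicates), length(sample_times)))
}

#' Specification of a synthetic voxelised cell mask
#'
#' A radially perturbed sphere \eqn{r(\theta,\varphi) = R + a\,s(\theta,\varphi)}
#' standing in for a tomographically reconstructed cell. The roughness field
#' s is a band-limited sum of random plane-wave sinusoids evaluated on the
#' unit sphere, normalised to [-1, 1], so surface corrugation grows smoothly
#' and monotonically with \code{roughness_amplitude} - the knob used to
#' emulate the membrane perturbation that raises the surface-area-to-volume
#' ratio after sonoporation.
#'
#' @param grid_shape Voxels per axis, c(nx, ny, nz).
#' @param voxel_size um per voxel edge (isotropic).
#' @param radius Nominal cell radius, um.
#' @param roughness_amplitude Perturbation amplitude a, um
#'   (0 <= a < radius).
#' @param roughness_frequency Angular frequency of the perturbation, cycles
#'   per circumference.
#' @param seed RNG seed.
#' @return A list of class \code{"cell_mask_spec"}.
#' @export
cell_mask_spec <- function(grid_shape = c(96, 96, 96), voxel_size = 0.25,
                           radius = 10, roughness_amplitude = 0,
                           roughness_frequency = 6, seed = 1) {
  if (radius <= 0) stop("invalid-parameter: radius must be > 0")
  if (roughness_amplitude < 0 || roughness_amplitude >= radius)
    stop("invalid-parameter: need 0 <= roughness_amplitude < radius")
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 radius = radius, roughness_amplitude = roughness_amplitude,
                 roughness_frequency = roughness_frequency, seed = seed),
            class = "cell_mask_spec")
}

# Band-limited roughness field on the unit sphere: sum of random-direction
# sinusoids cos(f w.u + phase), normalised to [-1, 1].
roughness_field <- function(ux, uy, uz, frequency, seed, n_waves = 6) {
  pars <- with_seed(seed, {
    w <- matrix(stats::rnorm(3 * n_waves), 3, n_waves)
    w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
    list(w = w, phase = stats::runif(n_waves, 0, 2 * pi),
         amp = stats::runif(n_waves, 0.5, 1))
  })
  s <- 0
  for (i in seq_len(n_waves)) {
    proj <- pars$w[1, i] * ux + pars$w[2, i] * uy + pars$w[3, i] * uz
    s <- s + pars$amp[i] * cos(frequency * proj + pars$phase[i])
  }
  s / sum(pars$amp)
}

#' Generate a voxelised cell mask
#'
#' @param spec A \code{\link{cell_mask_spec}}.
#' @return A binary \code{\link{voxel_volume}} (1 = inside the cell).
#' @export
#' @examples
#' m <- gen_cell_mask(cell_mask_spec(radius = 5, grid_shape = c(48, 48, 48)))
gen_cell_mask <- function(spec) {
  stopifnot(inherits(spec, "cell_mask_spec"))
  dims <- spec$grid_shape
  half_extent <- min(dims) / 2 * spec$voxel_size
  if (spec$radius + spec$roughness_amplitude >= half_extent)
    stop("geometry: sphere (radius + roughness) does not fit in the grid")
  ax <- lapply(dims, function(n) (seq_len(n) - (n + 1) / 2) * spec$voxel_size)
  x <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
  r <- sqrt(x^2 + y^2 + z^2)
  r_safe <- pmax(r, 1e-12)
  r_local <- spec$radius
  if (spec$roughness_amplitude > 0) {
    s <- roughness_field(x / r_safe, y / r_safe, z / r_safe,
                         spec$roughness_frequency, spec$seed)
    r_local <- spec$radius + spec$roughness_amplitude * s
  }
  mask <- array(as.numeric(r <= r_local), dims)
  voxel_volume(mask, voxel_size = spec$voxel_size)
}

#' Configuration of a synthetic multi-group uptake study
#'
#' Defaults reproduce a 4-group x 3-timepoint design: ultrasound exposures
#' of 0, 5, 10 and 20 minutes, cells fixed 0, 3 and 24 h after irradiation;
#' because particles are administered 3 h before irradiation the kinetic
#' clock reads t = 3, 6 and 27 h. Default asymptotes and rate constants are
#' the values recovered by \code{\link{fit_first_order}} from the bundled
#' ICP-AES group-summary table, so the generator emulates the measured
#' uptake behaviour of each exposure group.
#'
#' @param groups Ultrasound exposure per group, minutes.
#' @param timepoints Hours since particle administration.
#' @param replicates ICP-AES replicates per group x timepoint.
#' @param a_max,k Per-group asymptote (mg/L) and rate constant (1/h).
#' @param noise_sd Replicate noise SD, mg/L.
#' @param n_images Reflectance images per group (0 to skip imaging).
#' @param scene Base \code{\link{scene_spec}} for the images.
#' @param n_cells_odt Voxel masks per group (0 to skip morphometry inputs).
#' @param mask Base \code{\link{cell_mask_spec}}.
#' @param roughness_by_group Roughness amplitude per group, um.
#' @param master_seed Seed from which all per-item seeds are derived.
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(groups = c(0, 5, 10, 20),
                         timepoints = c(3, 6, 27),
                         replicates = 3,
                         a_max = c(2.00, 1.79, 2.29, 2.31),
                         k = c(0.1497, 0.1509, 0.1071, 0.1581),
                         noise_sd = 0.15,
                         n_images = 0,
                         scene = scene_spec(),
                         n_cells_odt = 0,
                         mask = cell_mask_spec(),
                         roughness_by_group = NULL,
                         master_seed = 1) {
  if (length(groups) == 0) stop("invalid-config: group list must be nonempty")
  if (length(a_max) == 1) a_max <- rep(a_max, length(groups))
  if (length(k) == 1) k <- rep(k, length(groups))
  if (length(a_max) != length(groups) || length(k) != length(groups))
    stop("invalid-config: a_max and k must match the number of groups")
  structure(list(groups = groups, timepoints = timepoints,
                 replicates = replicates, a_max = a_max, k = k,
                 noise_sd = noise_sd, n_images = n_images, scene = scene,
                 n_cells_odt = n_cells_odt, mask = mask,
                 roughness_by_group = roughness_by_group,
                 master_seed = master_seed),
            class = "study_config")
}

#' Generate a full synthetic study bundle
#'
#' Produces every input the analysis pipeline consumes for a multi-group
#' design: an uptake table (one row per group x timepoint x replicate),
#' optional reflectance images with ground truth, and optional voxel masks.
#' All randomness flows from per-item seeds derived from the master seed,
#' so two calls with the same configuration are identical.
#'
#' @param config A \code{\link{study_config}}.
#' @return A list of class \code{"study_bundle"}: \code{uptake} (data frame),
#'   \code{images} (nested list by group), \code{masks} (nested list by
#'   group), \code{config}.
#' @export
gen_group_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  g <- config$groups
  uptake <- vector("list", length(g))
  for (i in seq_along(g)) {
    s <- gen_uptake_series(config$a_max[i], config$k[i],
                           sample_times = config$timepoints,
                           replicates = config$replicates,
                           noise_sd = config$noise_sd,
                           seed = derive_seed(config$master_seed, i),
                           group_min = g[i])
    uptake[[i]] <- s
  }
  uptake <- do.call(rbind, uptake)
  class(uptake) <- c("uptake_series", "data.frame")

  images <- NULL
  if (config$n_images > 0) {
    images <- stats::setNames(vector("list", length(g)), paste0(g, "min"))
    for (i in seq_along(g)) {
      images[[i]] <- lapply(seq_len(config$n_images), function(j) {
        sp <- config$scene
        sp$seed <- derive_seed(config$master_seed, 1000 + i * 100 + j)
        out <- gen_reflectance_image(sp)
        out$image$group_min <- g[i]
        out$image$image_id <- sprintf("g%02d_img%02d", g[i], j)
        out
      })
    }
  }

  masks <- NULL
  if (config$n_cells_odt > 0) {
    rough <- config$roughness_by_group
    if (is.null(rough)) rough <- rep(config$mask$roughness_amplitude, length(g))
    masks <- stats::setNames(vector("list", length(g)), paste0(g, "min"))
    for (i in seq_along(g)) {
      masks[[i]] <- lapply(seq_len(config$n_cells_odt), function(j) {
        sp <- config$mask
        sp$roughness_amplitude <- rough[i]
        sp$seed <- derive_seed(config$master_seed, 5000 + i * 100 + j)
        m <- gen_cell_mask(sp)
        m$group_min <- g[i]
        m$cell_id <- sprintf("g%02d_cell%02d", g[i], j)
        m
      })
    }
  }

  structure(list(uptake = uptake, images = images, masks = masks,
                 config = config),
            class = "study_bundle")
}
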