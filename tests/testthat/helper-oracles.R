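# Shared fixtures and independent oracles used across test files.

# Expected connected-component count of a scene: union-find over the true
# disks, merging any pair whose disks overlap (a segmenter sees one blob).
expected_component_count <- function(truth) {
  n <- nrow(truth)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      gap <- sqrt((truth$x_um[i] - truth$x_um[j])^2 +
                    (truth$y_um[i] - truth$y_um[j])^2)
      if (gap <= (truth$diameter_um[i] + truth$diameter_um[j]) / 2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# Rasterize one disk into a labelled mask (pixel centres at (i - 0.5) * px).
rasterize_disk_mask <- function(diameter_um, pixel_size, n_px = NULL) {
  if (is.null(n_px)) n_px <- ceiling(diameter_um / pixel_size) + 6
  ctr <- n_px / 2 * pixel_size
  xc <- (seq_len(n_px) - 0.5) * pixel_size
  inside <- outer((xc - ctr)^2, (xc - ctr)^2, "+") <= (diameter_um / 2)^2
  structure(list(labels = array(as.integer(inside), c(n_px, n_px)),
                 pixel_size = pixel_size, image_id = "disk",
                 group_min = NA_real_, threshold = NA_real_),
            class = "segmentation_mask")
}

# Brute-force grid-search oracle for the 1-parameter kinetic fit: argmin of
# the SSE over a k grid, with a central finite-difference Jacobian for the
# standard error (independent of the analytic-Jacobian path in the package).
grid_search_kinetic <- function(t, y, a_max, k_max = 2, step = 1e-5) {
  ks <- seq(0, k_max, by = step)
  sse <- vapply(ks, function(k) sum((y - a_max * (1 - exp(-k * t)))^2), 1)
  i <- which.min(sse)
  k_hat <- ks[i]
  h <- 1e-6
  pred <- function(k) a_max * (1 - exp(-k * t))
  jac <- (pred(k_hat + h) - pred(k_hat - h)) / (2 * h)
  df <- length(y) - 1
  se <- sqrt(sse[i] / df / sum(jac^2))
  list(k = k_hat, se_k = se, sse = sse[i])
}

# Digitize an (optionally rotated) ellipsoid as a binary voxel volume.
digitize_ellipsoid <- function(semi_axes, voxel_size, n_vox,
                               rot_deg = 0, axis = c(0, 0, 1)) {
  ax <- (seq_len(n_vox) - (n_vox + 1) / 2) * voxel_size
  x <- array(rep(ax, times = n_vox^2), rep(n_vox, 3))
  y <- array(rep(rep(ax, each = n_vox), times = n_vox), rep(n_vox, 3))
  z <- array(rep(ax, each = n_vox^2), rep(n_vox, 3))
  if (rot_deg != 0) {
    th <- rot_deg * pi / 180
    u <- axis / sqrt(sum(axis^2))
    # Rodrigues rotation of the coordinate frame
    rot <- function(px, py, pz) {
      dotp <- u[1] * px + u[2] * py + u[3] * pz
      cx <- u[2] * pz - u[3] * py
      cy <- u[3] * px - u[1] * pz
      cz <- u[1] * py - u[2] * px
      list(x = px * cos(th) + cx * sin(th) + u[1] * dotp * (1 - cos(th)),
           y = py * cos(th) + cy * sin(th) + u[2] * dotp * (1 - cos(th)),
           z = pz * cos(th) + cz * sin(th) + u[3] * dotp * (1 - cos(th)))
    }
    r <- rot(x, y, z)
    x <- r$x; y <- r$y; z <- r$z
  }
  inside <- (x / semi_axes[1])^2 + (y / semi_axes[2])^2 +
    (z / semi_axes[3])^2 <= 1
  voxel_volume(array(as.numeric(inside), rep(n_vox, 3)),
               voxel_size = voxel_size)
}
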