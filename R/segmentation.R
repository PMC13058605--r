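#' Reflectance image container
#'
#' @param intensities Nonnegative numeric matrix (rows = y, cols = x).
#' @param pixel_size um per pixel (> 0).
#' @param group_min Ultrasound exposure of the imaged group, minutes.
#' @param image_id Identifier carried into cluster tables.
#' @return A list of class \code{"reflectance_image"}.
#' @export
reflectance_image <- function(intensities, pixel_size, group_min = NA_real_,
                              image_id = NA_character_) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("invalid-parameter: intensities must be a numeric matrix")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("invalid-parameter: intensities must be finite and >= 0")
  if (pixel_size <= 0) stop("invalid-parameter: pixel_size must be > 0")
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 group_min = group_min, image_id = image_id),
            class = "reflectance_image")
}

#' @export
print.reflectance_image <- function(x, ...) {
  cat(sprintf("Reflectance image %s: %d x %d px at %.3g um/px (group %s min)\n",
              x$image_id, nrow(x$intensities), ncol(x$intensities),
              x$pixel_size, format(x$group_min)))
  invisible(x)
}

#' Min-max normalise a reflectance image
#'
#' Rescales intensities to [0, 1]; a constant image maps to all zeros.
#' Normalisation makes segmentation thresholds comparable across frames
#' acquired with different gain.
#'
#' @param img A \code{\link{reflectance_image}}.
#' @return The image with intensities in [0, 1].
#' @export
normalize_image <- function(img) {
  stopifnot(inherits(img, "reflectance_image"))
  v <- img$intensities
  rng <- range(v)
  img$intensities <- if (rng[1] == rng[2]) {
    array(0, dim(v))
  } else {
    (v - rng[1]) / (rng[2] - rng[1])
  }
  dim(img$intensities) <- dim(v)
  img
}

# 4- or 8-connected labelling of a binary matrix. EBImage::bwlabel is
# 4-connected; for 8-connectivity, labels that touch only diagonally are
# merged with a union-find pass over the label adjacency graph.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  if (connectivity == 8 && max(lab) > 1) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_along(parent), find, 1L)
      dense <- match(root, sort(unique(root)))
      lab[lab > 0] <- dense[lab[lab > 0]]
    }
  }
  lab
}

#' Segment nanoparticle clusters in a reflectance image
#'
#' Label-free cluster detection: K-means clustering of pixel intensities
#' combined with intensity thresholding. Foreground pixels are those
#' assigned to the brightest K-means cluster AND above the
#' \code{threshold_quantile} intensity quantile (the conservative
#' intersection of the two rules); connected components smaller than
#' \code{min_cluster_pixels} are discarded as noise.
#'
#' @param img A normalised \code{\link{reflectance_image}} (see
#'   \code{\link{normalize_image}}).
#' @param k_clusters Number of K-means intensity classes (>= 2; default 3:
#'   background, cellular reflectance, bright nanoparticle signal).
#' @param threshold_quantile Intensity quantile defining the threshold
#'   component of the rule (default 0.95).
#' @param min_cluster_pixels Minimum component size in pixels (default 4).
#' @param connectivity 4 or 8 (default 8).
#' @param seed RNG seed for the K-means restarts (10 restarts, best inertia).
#' @return A list of class \code{"segmentation_mask"}: \code{labels}
#'   (integer matrix, 0 = background), \code{pixel_size}, \code{image_id},
#'   \code{group_min}, \code{threshold} (intensity cut actually applied).
#' @export
segment_gnp <- function(img, k_clusters = 3, threshold_quantile = 0.95,
                        min_cluster_pixels = 4, connectivity = 8, seed = 1) {
  stopifnot(inherits(img, "reflectance_image"))
  if (k_clusters < 2) stop("invalid-parameter: k_clusters must be >= 2")
  v <- as.vector(img$intensities)
  ndistinct <- length(unique(v))
  empty_mask <- function() {
    structure(list(labels = array(0L, dim(img$intensities)),
                   pixel_size = img$pixel_size, image_id = img$image_id,
                   group_min = img$group_min, threshold = NA_real_),
              class = "segmentation_mask")
  }
  if (ndistinct == 1) return(empty_mask())  # featureless frame: nothing to find
  if (ndistinct < k_clusters)
    stop("degenerate-clustering: fewer distinct intensities (", ndistinct,
         ") than k_clusters (", k_clusters, ")")

  # Random restarts alone can miss the small bright population (every
  # sampled start lands in the background mass and the bright tail gets
  # absorbed into the top background cluster). One extra deterministic
  # start - spread quantile centres with the maximum pinned as a centre -
  # reliably seeds a bright cluster; the best inertia of all starts wins.
  km <- with_seed(seed, stats::kmeans(v, centers = k_clusters, nstart = 10,
                                      iter.max = 100))
  spread <- unique(c(stats::quantile(v, (seq_len(k_clusters - 1) - 0.5) /
                                       (k_clusters - 1), names = FALSE),
                     max(v)))
  if (length(spread) == k_clusters) {
    km2 <- try(stats::kmeans(v, centers = spread, iter.max = 100),
               silent = TRUE)
    if (!inherits(km2, "try-error") && km2$tot.withinss < km$tot.withinss)
      km <- km2
  }
  bright <- which.max(km$centers)
  thr <- stats::quantile(v, threshold_quantile, names = FALSE)
  fg <- matrix(km$cluster == bright & v >= thr, nrow(img$intensities))

  lab <- label_components(fg, connectivity)
  if (max(lab) > 0 && min_cluster_pixels > 1) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_cluster_pixels)
    lab[] <- match(lab, keep, nomatch = 0L)
  }
  structure(list(labels = array(as.integer(lab), dim(lab)),
                 pixel_size = img$pixel_size, image_id = img$image_id,
                 group_min = img$group_min, threshold = thr),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("Segmentation mask %s: %d components, threshold %.4g\n",
              x$image_id, max(x$labels), x$threshold))
  invisible(x)
}

#' Measure segmented clusters
#'
#' One row per connected component, with the equivalent circular diameter
#' \eqn{d = 2\sqrt{A_{px}/\pi} \cdot p} (p = pixel size): the diameter of the
#' circle with the same area as the component.
#'
#' @param mask A \code{\link{segment_gnp}} result.
#' @param pixel_size um per pixel; defaults to the mask's own.
#' @return A data frame of class \code{"cluster_table"} with columns
#'   image_id, group_min, label, pixel_count, equivalent_diameter_um,
#'   centroid_x_um, centroid_y_um.
#' @export
extract_clusters <- function(mask, pixel_size = mask$pixel_size) {
  stopifnot(inherits(mask, "segmentation_mask"))
  lab <- mask$labels
  n <- max(lab)
  if (n == 0) {
    out <- data.frame(image_id = character(0), group_min = numeric(0),
                      label = integer(0), pixel_count = integer(0),
                      equivalent_diameter_um = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0))
    class(out) <- c("cluster_table", "data.frame")
    return(out)
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  count <- tabulate(l, nbins = n)
  cy <- tapply(rows, l, mean) * pixel_size
  cx <- tapply(cols, l, mean) * pixel_size
  out <- data.frame(
    image_id = rep(mask$image_id, n), group_min = rep(mask$group_min, n),
    label = seq_len(n), pixel_count = count,
    equivalent_diameter_um = 2 * sqrt(count / pi) * pixel_size,
    centroid_x_um = as.numeric(cx), centroid_y_um = as.numeric(cy))
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Pool cluster sizes over a group's images
#'
#' Cluster sizes from all images of an exposure group are pooled (not
#' averaged per image first): the reported SD is the spread of individual
#' cluster sizes, which is what makes the large size dispersion of
#' reflectance-detected clusters visible in the summary.
#'
#' @param tables A \code{cluster_table} or list of them.
#' @param group_min Exposure label for the summary, minutes.
#' @param bin_width Histogram bin width in um (default 0.1).
#' @return A list of class \code{"cluster_size_summary"}: group_min,
#'   n_clusters, mean, sd, max (um), diameters, histogram.
#' @export
summarize_group <- function(tables, group_min = NA_real_, bin_width = 0.1) {
  if (is.data.frame(tables)) tables <- list(tables)
  d <- unlist(lapply(tables, function(t) t$equivalent_diameter_um))
  if (length(d) == 0) stop("empty-group: no clusters to summarize")
  structure(list(group_min = group_min, n_clusters = length(d),
                 mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0,
                 max = max(d), diameters = d,
                 histogram = histogram_diameters(d, bin_width)),
            class = "cluster_size_summary")
}

#' @export
print.cluster_size_summary <- function(x, ...) {
  cat(sprintf("Group %s min: %d clusters, %.3f +/- %.3f um (max %.3f)\n",
              format(x$group_min), x$n_clusters, x$mean, x$sd, x$max))
  invisible(x)
}

#' Percent reduction of a treated mean relative to control
#'
#' @param control_mean,treated_mean Group mean cluster sizes (um);
#'   control must be > 0.
#' @return \code{100 * (control_mean - treated_mean) / control_mean}.
#' @export
#' @examples
#' percent_reduction(0.597, 0.483)  # 19.1
percent_reduction <- function(control_mean, treated_mean) {
  if (any(control_mean <= 0)) stop("invalid-parameter: control_mean must be > 0")
  100 * (control_mean - treated_mean) / control_mean
}

#' Log-normal fit of a group's cluster-size histogram
#'
#' Delegates to \code{\link{fit_lognormal}} on the group's pooled
#' equivalent-diameter histogram (um units); the fitted distribution's mean
#' and SD summarise the cluster-size population.
#'
#' @param summary A \code{\link{summarize_group}} result.
#' @param ... Passed to \code{\link{fit_lognormal}}.
#' @return A \code{"lognormal_fit"}.
#' @export
fit_cluster_histogram <- function(summary, ...) {
  stopifnot(inherits(summary, "cluster_size_summary"))
  fit_lognormal(summary$histogram, ...)
}

#' Regress cluster size on ultrasound exposure time
#'
#' Ordinary least squares of size on a degree-1 or degree-2 polynomial of
#' exposure minutes, either on individual cluster sizes or on the per-group
#' mean sizes. Reports the Pearson correlation (degree 1), the centred
#' coefficient of determination and the model F-test p-value with
#' (degree, n - degree - 1) degrees of freedom.
#'
#' @param x Exposure minutes per observation.
#' @param y Sizes in um (individual or group means).
#' @param degree 1 (linear) or 2 (quadratic).
#' @param level Label recording whether y are \code{"individual"} sizes or
#'   \code{"group_means"}; does not change the computation.
#' @return A list of class \code{"regression_result"}: degree, coefficients,
#'   pearson_r (degree 1, else NA), r_squared, p_model, n_points, level.
#' @export
#' @examples
#' exposure_regression(c(0, 5, 10, 20), c(0.597, 0.483, 0.465, 0.495),
#'                     degree = 2, level = "group_means")
exposure_regression <- function(x, y, degree = 1,
                                level = c("individual", "group_means")) {
  level <- match.arg(level)
  if (!degree %in% c(1, 2)) stop("invalid-parameter: degree must be 1 or 2")
  n <- length(x)
  if (n != length(y)) stop("invalid-parameter: x and y lengths differ")
  if (n < degree + 1)
    stop("underdetermined-fit: need >= ", degree + 1, " points, got ", n)
  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  # saturated fits (n = degree + 1) have no residual df: R^2 = 1, p undefined
  p_model <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    degree = degree,
    coefficients = unname(stats::coef(fit)),
    pearson_r = if (degree == 1) stats::cor(x, y) else NA_real_,
    r_squared = sm$r.squared,
    p_model = p_model,
    n_points = n, level = level
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Degree-%d exposure regression (%s, n = %d)\n",
              x$degree, x$level, x$n_points))
  cat(sprintf("  R^2 = %.4f, p(model) = %.4g%s\n", x$r_squared, x$p_model,
              if (x$degree == 1) sprintf(", Pearson r = %.4f", x$pearson_r)
              else ""))
  invisible(x)
}
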