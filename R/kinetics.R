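#' Physical constants for ICP-AES particle-count conversion
#'
#' Bundle of constants used to convert a measured gold mass concentration
#' (mg/L) in a digested cell sample into a per-cell gold nanoparticle count.
#' Defaults describe 50 nm gold particles and a sample of 1e6 cells whose
#' 2 mL digest was diluted to 10 mL before measurement (dilution factor 5,
#' effective sample volume 0.010 L).
#'
#' @param M_Au Molar mass of gold in g/mol.
#' @param N_Au Number of gold atoms per particle (3 849 991 for a 50 nm GNP).
#' @param N_C Number of cells in the digested sample.
#' @param N_A Avogadro's number in 1/mol.
#' @param V_sample Effective sample volume in litres (diluted volume whose
#'   concentration is measured; 0.010 L = 2 mL digest x dilution factor 5).
#' @param dilution_factor Dilution applied between digest and measurement.
#'
#' @return A list of class \code{"gnp_constants"}.
#' @export
#' @examples
#' k <- gnp_constants()
#' concentration_to_particles(0.25, k)  # ~0.20 x10^4 particles per cell
gnp_constants <- function(M_Au = 196.966657,
                          N_Au = 3849991,
                          N_C = 1e6,
                          N_A = 6.022e23,
                          V_sample = 0.010,
                          dilution_factor = 5) {
  vals <- c(M_Au = M_Au, N_Au = N_Au, N_C = N_C, N_A = N_A,
            V_sample = V_sample, dilution_factor = dilution_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid-parameter: all constants must be finite and > 0")
  structure(as.list(vals), class = "gnp_constants")
}

#' Undo the measurement dilution of an ICP-AES reading
#'
#' @param measured_c Measured concentration in the diluted sample (mg/L).
#' @param constants A \code{\link{gnp_constants}} object.
#' @return Concentration in the original digest volume (mg/L).
#' @export
adjust_dilution <- function(measured_c, constants = gnp_constants()) {
  if (any(measured_c < 0)) stop("invalid-parameter: concentration must be >= 0")
  measured_c * constants$dilution_factor
}

#' Convert gold mass concentration to particles per cell
#'
#' Converts an ICP-AES gold concentration C_m (mg/L, in the diluted sample of
#' volume \code{V_sample}) into the number of nanoparticles per cell:
#' \deqn{N_{np} = \frac{C_m \cdot 10^{-3} \cdot V_{sample} \cdot N_A}
#'                     {M_{Au} \cdot N_{Au} \cdot N_C}}
#' reported on the 10^4-particles-per-cell scale. The conversion is exactly
#' linear in \code{c_m}; with the default constants the slope is
#' 0.794124 (x10^4 particles per cell per mg/L).
#'
#' @param c_m Gold concentration in mg/L (vectorised).
#' @param constants A \code{\link{gnp_constants}} object.
#' @return Particle count per cell on the x10^4 scale.
#' @export
concentration_to_particles <- function(c_m, constants = gnp_constants()) {
  if (any(!is.finite(c_m)) || any(c_m < 0))
    stop("invalid-parameter: c_m must be finite and >= 0")
  n_np <- (c_m * 1e-3 * constants$V_sample * constants$N_A) /
    (constants$M_Au * constants$N_Au * constants$N_C)
  n_np / 1e4
}

#' Ratio of treated to control uptake
#'
#' @param treated_mean,control_mean Group mean concentrations (same units).
#' @return \code{treated_mean / control_mean}.
#' @export
fold_change <- function(treated_mean, control_mean) {
  if (any(control_mean <= 0)) stop("invalid-parameter: control_mean must be > 0")
  treated_mean / control_mean
}

#' Assemble an uptake time series
#'
#' @param time_h Hours since nanoparticle administration.
#' @param value Measurement at each time (mg/L gold, or converted counts).
#' @param group_min Ultrasound exposure of the group, minutes.
#' @param replicate Optional replicate identifier.
#' @return A data frame of class \code{"uptake_series"}, sorted by time.
#' @export
uptake_series <- function(time_h, value, group_min = NA_real_,
                          replicate = seq_along(time_h)) {
  if (any(time_h < 0)) stop("invalid-parameter: times must be >= 0")
  df <- data.frame(group_min = group_min, time_h = time_h,
                   replicate = replicate, value = value)
  df <- df[order(df$time_h), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("uptake_series", "data.frame")
  df
}

#' Fit a fixed-asymptote first-order absorption model
#'
#' Fits \eqn{Y(t) = A_{max}(1 - e^{-kt})} with the asymptote fixed, estimating
#' only the absorption rate constant \eqn{k \ge 0} by least squares. With the
#' asymptote pinned to the last observed uptake ("maximum uptake capacity")
#' and the series anchored at the origin (no intracellular particles at 0 h),
#' a three-timepoint series yields four points, one free parameter and three
#' degrees of freedom.
#'
#' Inference: \code{se_k} comes from the linearised Jacobian
#' \eqn{\partial Y/\partial k = A_{max} t e^{-kt}} at the optimum with residual
#' variance \code{sse/df}, \code{df = n - 1}; \code{p_k} is a two-sided t test
#' of \eqn{k = 0}; \code{p_model} is an F test of the model against the
#' constant-mean model with \code{(1, df)} degrees of freedom. R-squared is
#' centred on the mean of all fitted observations, origin included.
#'
#' @param series An \code{\link{uptake_series}} (or data frame with columns
#'   \code{time_h} and \code{value}).
#' @param a_max Fixed asymptote, same units as \code{value}; defaults to the
#'   mean observed value at the latest time point.
#' @param include_origin Anchor the fit with a (0, 0) observation when no
#'   t = 0 measurement is present (default TRUE).
#' @param k_upper Upper bound of the line search for k (1/h).
#' @return An object of class \code{"kinetic_fit"} with elements \code{k},
#'   \code{se_k}, \code{df}, \code{r_squared}, \code{p_model}, \code{p_k},
#'   \code{sse}, \code{a_max}, \code{converged}, \code{n_points}.
#' @export
#' @examples
#' s <- uptake_series(c(0, 3, 6, 27), c(0, 0.91, 1.38, 2.31), group_min = 20)
#' fit_first_order(s, a_max = 2.31)
fit_first_order <- function(series, a_max = NULL, include_origin = TRUE,
                            k_upper = 50) {
  if (!is.data.frame(series) || !all(c("time_h", "value") %in% names(series)))
    stop("invalid-parameter: series needs columns time_h and value")
  t <- series$time_h
  y <- series$value
  if (!is.null(a_max) && a_max <= 0) stop("invalid-parameter: a_max must be > 0")
  if (include_origin && !any(t == 0)) {
    t <- c(0, t)
    y <- c(0, y)
  }
  if (length(unique(t[t > 0])) < 2)
    stop("invalid-parameter: need >= 2 distinct positive times")
  if (all(y == 0)) stop("degenerate-fit: all observations are zero")
  if (is.null(a_max)) a_max <- mean(y[t == max(t)])

  sse_at <- function(k) sum((y - a_max * (1 - exp(-k * t)))^2)
  # The SSE profile flattens once exp(-k t) underflows at all positive
  # times, so a plain golden-section search over (0, k_upper) can stall on
  # the plateau. Bracket the minimum on a linear + log grid first, then
  # refine inside the bracketing interval.
  grid <- sort(unique(c(0, seq(0, k_upper, length.out = 201),
                        exp(seq(log(1e-5), log(k_upper), length.out = 100)))))
  sse_grid <- vapply(grid, sse_at, 1)
  i <- which.min(sse_grid)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  if (lo == hi) {
    k <- lo
    sse <- sse_grid[i]
  } else {
    opt <- stats::optimize(sse_at, interval = c(lo, hi), tol = 1e-12)
    k <- opt$minimum
    sse <- opt$objective
    if (sse_grid[i] <= sse) { k <- grid[i]; sse <- sse_grid[i] }
  }

  n <- length(y)
  df <- n - 1L
  sst <- sum((y - mean(y))^2)
  r_squared <- 1 - sse / sst
  jac <- a_max * t * exp(-k * t)
  sigma2 <- sse / df
  se_k <- sqrt(sigma2 / sum(jac^2))
  if (se_k > 0) {
    p_k <- 2 * stats::pt(-abs(k / se_k), df)
  } else {
    p_k <- if (k > 0) 0 else 1
  }
  f_stat <- (sst - sse) / sigma2
  p_model <- stats::pf(f_stat, 1, df, lower.tail = FALSE)

  structure(list(k = k, se_k = se_k, df = df, r_squared = r_squared,
                 p_model = p_model, p_k = p_k, sse = sse, a_max = a_max,
                 n_points = n, converged = TRUE),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("First-order absorption fit (fixed asymptote)\n")
  cat(sprintf("  A_max = %.4g (fixed), k = %.4g 1/h (SE %.3g), df = %d\n",
              x$a_max, x$k, x$se_k, x$df))
  cat(sprintf("  R^2 = %.4f, p(model) = %.3g, p(k) = %.3g\n",
              x$r_squared, x$p_model, x$p_k))
  invisible(x)
}

#' Predict from a first-order absorption fit
#'
#' @param object A \code{"kinetic_fit"}.
#' @param times Hours at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Predicted uptake at \code{times}.
#' @export
predict.kinetic_fit <- function(object, times, ...) {
  object$a_max * (1 - exp(-object$k * times))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param values_by_group Named list of numeric replicate vectors, one per
#'   group; every group needs at least two replicates.
#' @return An object of class \code{"group_comparison"} with the ANOVA F
#'   statistic, its p-value, and a pairwise table of Tukey-adjusted
#'   mean differences (one row per unordered group pair).
#' @export
#' @examples
#' compare_groups(list(ctrl = c(1, 1.2, 0.9), us = c(2.1, 2.0, 2.3)))
compare_groups <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2)
    stop("invalid-design: need >= 2 groups")
  if (any(vapply(values_by_group, length, 1L) < 2))
    stop("invalid-design: every group needs >= 2 replicates")
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("g", seq_along(values_by_group))

  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group),
                       vapply(values_by_group, length, 1L)))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  f_statistic <- tab[["F value"]][1]
  p_anova <- tab[["Pr(>F)"]][1]
  if (!is.finite(f_statistic)) { f_statistic <- 0; p_anova <- 1 }

  tk <- stats::TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                         mean_diff = tk[, "diff"],
                         p_adjusted = tk[, "p adj"],
                         row.names = NULL)
  structure(list(f_statistic = f_statistic, p_anova = p_anova,
                 pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.3g\n", x$f_statistic, x$p_anova))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}
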