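#' Bin particle diameters into a size histogram
#'
#' Builds right-open bins of fixed width covering the observed range, the
#' binning convention used by nanoparticle-tracking software before a size
#' distribution is curve-fitted. The last bin is closed so the maximum
#' observation is kept and the total count is preserved.
#'
#' @param diameters Positive particle diameters (nm or um).
#' @param bin_width Bin width in the same units; must be > 0.
#' @return A list of class \code{"size_histogram"}: \code{bin_edges}
#'   (length n_bins + 1, strictly increasing), \code{counts},
#'   \code{is_density = FALSE}.
#' @export
#' @examples
#' histogram_diameters(c(57, 57, 57), 10)
histogram_diameters <- function(diameters, bin_width) {
  if (length(diameters) == 0) stop("empty-input: no diameters supplied")
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("invalid-parameter: diameters must be finite and > 0")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("invalid-parameter: bin_width must be > 0")
  lo <- min(diameters)
  hi <- max(diameters)
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / bin_width - 1e-9)))
  edges <- lo + bin_width * (0:n_bins)
  idx <- pmin(floor((diameters - lo) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = as.numeric(counts),
                 is_density = FALSE),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("Size histogram: %d bins on [%.4g, %.4g], total %s %.4g\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              if (x$is_density) "density" else "count", sum(x$counts)))
  invisible(x)
}

bin_centers <- function(hist) {
  e <- hist$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Fit a log-normal curve to a size histogram
#'
#' Fits \code{amplitude * dlnorm(x, log_mu, log_sigma)} to per-bin values at
#' the bin centres by damped (Levenberg-Marquardt) least squares, the
#' standard way particle-sizing instruments summarise a size distribution.
#' Starting values come from the histogram-weighted log-moments, so the fit
#' is deterministic.
#'
#' @param hist A \code{\link{histogram_diameters}} result (counts or density);
#'   at least three occupied bins are required to identify the three
#'   parameters.
#' @param init Optional list with starting values \code{log_mu},
#'   \code{log_sigma}, \code{amplitude}.
#' @param max_iter Iteration cap for the damped least-squares loop.
#' @return An object of class \code{"lognormal_fit"}: \code{log_mu},
#'   \code{log_sigma}, \code{amplitude}, \code{mode}
#'   (\eqn{e^{\mu - \sigma^2}}), \code{mean}, \code{sd} (moments of the
#'   fitted distribution), \code{sse}, \code{converged},
#'   \code{n_iterations}.
#' @export
#' @examples
#' d <- gen_particle_diameters(5000, log_mu = log(57), log_sigma = 0.35, seed = 1)
#' fit_lognormal(histogram_diameters(d, 5))
fit_lognormal <- function(hist, init = NULL, max_iter = 200) {
  stopifnot(inherits(hist, "size_histogram") ||
              (is.list(hist) && all(c("bin_edges", "counts") %in% names(hist))))
  x <- bin_centers(hist)
  y <- hist$counts
  occ <- y > 0
  if (sum(occ) < 3)
    stop("underdetermined-fit: need >= 3 occupied bins, got ", sum(occ))

  if (is.null(init)) {
    w <- y[occ] / sum(y[occ])
    lx <- log(x[occ])
    mu0 <- sum(w * lx)
    s0 <- sqrt(max(sum(w * (lx - mu0)^2), 1e-4))
    a0 <- max(y) / max(stats::dlnorm(x, mu0, s0))
    init <- list(log_mu = mu0, log_sigma = s0, amplitude = a0)
  }

  dat <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ A * dlnorm(x, mu, sigma),
    data = dat,
    start = list(A = init$amplitude, mu = init$log_mu, sigma = init$log_sigma),
    lower = c(A = 0, mu = -Inf, sigma = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )
  est <- stats::coef(fit)
  mu <- unname(est["mu"]); sigma <- unname(est["sigma"]); A <- unname(est["A"])
  conv <- isTRUE(fit$convInfo$isConv)
  structure(list(
    log_mu = mu, log_sigma = sigma, amplitude = A,
    mode = exp(mu - sigma^2),
    mean = exp(mu + sigma^2 / 2),
    sd = exp(mu + sigma^2 / 2) * sqrt(exp(sigma^2) - 1),
    sse = sum(stats::resid(fit)^2),
    converged = conv,
    n_iterations = fit$convInfo$finIter
  ), class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "Log-normal fit: log_mu = %.4f, log_sigma = %.4f, amplitude = %.4g\n",
    x$log_mu, x$log_sigma, x$amplitude))
  cat(sprintf("  mode = %.4g, mean = %.4g, sd = %.4g, SSE = %.3g (%s, %d it.)\n",
              x$mode, x$mean, x$sd, x$sse,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Modal diameter of a fitted log-normal distribution
#'
#' The mode of a log-normal density with log-scale location \eqn{\mu} and
#' shape \eqn{\sigma} is \eqn{e^{\mu - \sigma^2}}: the diameter at which the
#' fitted concentration peaks.
#'
#' @param fit A converged \code{\link{fit_lognormal}} result.
#' @return Modal diameter, same units as the fitted data.
#' @export
modal_diameter <- function(fit) {
  if (!isTRUE(fit$converged))
    stop("invalid-state: fit did not converge; mode is not meaningful")
  exp(fit$log_mu - fit$log_sigma^2)
}
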