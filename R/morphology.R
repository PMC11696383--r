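#' Scott's-rule bandwidth
#'
#' Bandwidth for Gaussian-kernel density estimation,
#' `w = constant * sd(x) * n^(-1/5)` with the n-1 sample standard
#' deviation.  The proportionality constant defaults to 1 (the classic
#' kernel-density form of the rule) and is exposed because software
#' implementations differ in it.
#'
#' @param samples Numeric vector, `n >= 2`, non-degenerate.
#' @param constant Multiplier on `sd * n^(-1/5)`.
#' @return Bandwidth in the units of `samples`.
#' @export
scott_bandwidth <- function(samples, constant = 1) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 2L) stop("degenerate sample: need at least 2 observations")
  s <- stats::sd(samples)
  if (s == 0) stop("degenerate sample: zero standard deviation")
  constant * s * n^(-1 / 5)
}

#' Gaussian-kernel density estimate
#'
#' Evaluates `f(x) = 1/(n w) * sum_i phi((x - X_i) / w)` with `phi` the
#' standard normal density, on a grid spanning the data range extended by 5
#' bandwidths on each side (so the trapezoidal integral of the estimate is
#' 1 to high accuracy).
#'
#' @param samples Numeric sample, `n >= 1`.
#' @param bandwidth Kernel scale `w > 0`; `NULL` uses [scott_bandwidth()].
#' @param grid Evaluation points; `NULL` builds the default grid.
#' @param grid_size Number of default grid points.
#' @return A `kde_estimate`: list with `grid`, `density`, `bandwidth`, `n`.
#' @export
kde <- function(samples, bandwidth = NULL, grid = NULL, grid_size = 512L) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 1L) stop("empty sample")
  if (is.null(bandwidth)) bandwidth <- scott_bandwidth(samples)
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(grid)) {
    grid <- seq(min(samples) - 5 * bandwidth, max(samples) + 5 * bandwidth,
                length.out = grid_size)
  }
  # column-wise accumulation keeps memory at O(n) per grid point
  density <- vapply(grid, function(x) {
    mean(stats::dnorm((x - samples) / bandwidth)) / bandwidth
  }, numeric(1))
  structure(list(grid = grid, density = density, bandwidth = bandwidth,
                 n = n),
            class = "kde_estimate")
}

#' @export
print.kde_estimate <- function(x, ...) {
  cat(sprintf("<kde_estimate> n = %d, bandwidth = %.6g, grid of %d points [%.4g, %.4g]\n",
              x$n, x$bandwidth, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Trapezoidal integral of a density estimate
#'
#' @param est A `kde_estimate`.
#' @return The trapezoidal integral of `density` over `grid` (close to 1 on
#'   the default grid).
#' @export
kde_integral <- function(est) {
  stopifnot(inherits(est, "kde_estimate"))
  sum(diff(est$grid) * (utils::head(est$density, -1) +
                          utils::tail(est$density, -1)) / 2)
}

#' Tukey fences from quartiles
#'
#' `q1 - 1.5 * IQR` and `q3 + 1.5 * IQR`, the whisker endpoints used to flag
#' outliers.  Reported unclamped (not pulled in to the nearest data point).
#'
#' @param q1,q3 First and third quartiles.
#' @return Named numeric vector `c(lower = ..., upper = ...)`.
#' @export
tukey_fences <- function(q1, q3) {
  iqr <- q3 - q1
  c(lower = q1 - 1.5 * iqr, upper = q3 + 1.5 * iqr)
}

#' Box statistics with Tukey fences and outliers
#'
#' Quartiles (by the [summarize_stats()] convention), mean, the 1.5-IQR
#' fences and the samples falling outside them.
#'
#' @param samples Non-empty numeric vector.
#' @param type Quantile convention.
#' @return A `box_stats`: list with `q1`, `q2`, `q3`, `mean`,
#'   `lower_fence`, `upper_fence`, `outliers`, `n`.
#' @export
box_stats <- function(samples, type = 7) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty sample")
  q <- unname(stats::quantile(samples, c(0.25, 0.5, 0.75), type = type))
  fences <- tukey_fences(q[1L], q[3L])
  structure(
    list(q1 = q[1L], q2 = q[2L], q3 = q[3L], mean = mean(samples),
         lower_fence = unname(fences["lower"]),
         upper_fence = unname(fences["upper"]),
         outliers = samples[samples < fences["lower"] |
                              samples > fences["upper"]],
         n = length(samples)),
    class = "box_stats"
  )
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf(
    "<box_stats> n = %d | q1 %.4g | median %.4g | q3 %.4g | mean %.4g\n  fences [%.4g, %.4g], %d outlier(s)\n",
    x$n, x$q1, x$q2, x$q3, x$mean, x$lower_fence, x$upper_fence,
    length(x$outliers)))
  invisible(x)
}
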