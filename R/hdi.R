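#' Highest density interval
#'
#' Shortest interval containing a stated probability mass. For a unimodal
#' continuous distribution the HDI is found by minimising the interval width
#' \code{q(p + mass) - q(p)} over the left tail probability \code{p}; for a
#' flat stretch of density (where several intervals tie) the central interval
#' is returned. For posterior samples the shortest window over the order
#' statistics is used; a kernel-density check warns when the sample looks
#' multimodal, in which case the shortest single interval is still returned.
#'
#' @param x either a numeric vector of (at least 1000) posterior samples, or a
#'   quantile function such as \code{function(p) qgamma(p, 21, 5)}.
#' @param mass probability mass the interval must contain (default 0.95).
#' @param ... unused.
#' @return numeric vector \code{c(lower, upper)}.
#' @examples
#' hdi(function(p) qgamma(p, shape = 21, rate = 5))
#' @export
hdi <- function(x, mass = 0.95, ...) UseMethod("hdi")

#' @export
hdi.function <- function(x, mass = 0.95, ...) {
  stopifnot(mass > 0, mass <= 1)
  if (mass == 1) {
    return(c(lower = x(0), upper = x(1)))
  }
  width <- function(p) x(p + mass) - x(p)
  opt <- optimize(width, interval = c(0, 1 - mass), tol = .Machine$double.eps^0.5)
  p_central <- (1 - mass) / 2
  # flat/degenerate densities: several intervals tie -> report the central one
  p <- if (width(p_central) <= opt$objective + 1e-12) p_central else opt$minimum
  c(lower = x(p), upper = x(p + mass))
}

#' @export
hdi.numeric <- function(x, mass = 0.95, ...) {
  stopifnot(length(x) >= 2, mass > 0, mass <= 1)
  xs <- sort(x)
  n <- length(xs)
  if (length(x) < 1000) {
    warning("fewer than 1000 samples; HDI estimate may be unstable")
  }
  k <- max(1L, ceiling(mass * n))
  if (k >= n) {
    return(c(lower = xs[1L], upper = xs[n]))
  }
  widths <- xs[(k + 1L):n] - xs[1:(n - k)]
  if (.looks_multimodal(xs)) {
    warning("sample density looks multimodal; returning shortest single interval")
  }
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + k])
}

.looks_multimodal <- function(x) {
  if (length(unique(x)) < 10) return(FALSE)
  d <- density(x)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  sum(y[peaks] > 0.15 * max(y)) > 1
}

#' HDI of a Gamma or Beta distribution
#'
#' Convenience wrappers around \code{\link{hdi}} for the two conjugate
#' posterior families used throughout the package (Gamma-Poisson survival
#' posteriors, Dirichlet marginal Beta tropism posteriors).
#'
#' @param shape,rate Gamma parameters.
#' @param shape1,shape2 Beta parameters.
#' @param mass probability mass (default 0.95).
#' @return numeric \code{c(lower, upper)}.
#' @export
hdi_gamma <- function(shape, rate, mass = 0.95) {
  if (shape <= 1) {
    # mode at zero: HDI is the left-anchored interval
    return(c(lower = 0, upper = qgamma(mass, shape, rate)))
  }
  hdi.function(function(p) qgamma(p, shape, rate), mass = mass)
}

#' @rdname hdi_gamma
#' @export
hdi_beta <- function(shape1, shape2, mass = 0.95) {
  if (shape1 <= 1 && shape2 > 1) {
    return(c(lower = 0, upper = qbeta(mass, shape1, shape2)))
  }
  if (shape2 <= 1 && shape1 > 1) {
    return(c(lower = qbeta(1 - mass, shape1, shape2), upper = 1))
  }
  hdi.function(function(p) qbeta(p, shape1, shape2), mass = mass)
}

#' Compare two highest density intervals
#'
#' Two groups are called different when their intervals are disjoint; this is
#' the package's significance criterion for posterior comparisons. Intervals
#' are treated as closed, so touching endpoints are not different.
#'
#' @param a,b numeric intervals \code{c(lower, upper)}.
#' @return \code{"different"} or \code{"not-different"}.
#' @examples
#' compare_hdi(c(0, 1), c(2, 3))
#' @export
compare_hdi <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
  if (a[2] < b[1] || b[2] < a[1]) "different" else "not-different"
}
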