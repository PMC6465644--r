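# In-vivo PDX behavior: engraftment, Gamma-Poisson survival posteriors,
# migration distances, standard deviational ellipses with bootstrap CIs.

#' Engraftment efficiency
#'
#' Percentage of injected embryos showing at least one fluorescent focus at
#' 1 dpi.
#'
#' @param cohort an \code{\link{gen_embryo_cohort}} result, or a per-embryo
#'   data frame with an \code{n_foci_1dpi} column.
#' @param n_injected number of injected embryos; taken from the cohort when
#'   omitted.
#' @return percentage in [0, 100].
#' @export
engraftment_efficiency <- function(cohort, n_injected = NULL) {
  if (inherits(cohort, "embryo_cohort")) {
    emb <- cohort$embryos
    if (is.null(n_injected)) n_injected <- cohort$n_injected
  } else {
    emb <- cohort
    if (is.null(n_injected)) n_injected <- nrow(emb)
  }
  if (is.null(n_injected) || n_injected == 0) {
    stop("n_injected must be positive")
  }
  100 * sum(emb$n_foci_1dpi >= 1) / n_injected
}

#' Gamma-Poisson survival posterior
#'
#' Survival rate is quantified as the foci count per scored embryo; counts
#' are modeled as Poisson with a conjugate Gamma(a0, b0) prior on the mean,
#' giving posterior Gamma(a0 + sum(counts), b0 + n) whose 95 percent highest
#' density interval is the comparison interval (\code{\link{compare_hdi}}).
#'
#' @param counts non-negative integer foci counts, one per embryo.
#' @param a0,b0 Gamma prior shape and rate (default 1, 1: weakly
#'   informative).
#' @param mass HDI mass (default 0.95).
#' @return object of class \code{survival_summary} with the posterior
#'   parameters, posterior mean and \code{hdi95}.
#' @examples
#' survival_posterior(c(5, 5, 5, 5))  # posterior Gamma(21, 5), mean 4.2
#' @export
survival_posterior <- function(counts, a0 = 1, b0 = 1, mass = 0.95) {
  if (length(counts) == 0) stop("counts must be non-empty")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  shape <- a0 + sum(counts)
  rate <- b0 + length(counts)
  structure(
    list(counts = counts, shape = shape, rate = rate,
         mean = shape / rate, hdi95 = hdi_gamma(shape, rate, mass)),
    class = "survival_summary"
  )
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("<survival_summary> n=%d embryos, posterior Gamma(%g, %g): mean %.2f foci, 95%% HDI [%.2f, %.2f]\n",
              length(x$counts), x$shape, x$rate, x$mean,
              x$hdi95[1], x$hdi95[2]))
  invisible(x)
}

#' Mean migration distances with bootstrap confidence intervals
#'
#' Mean absolute anteroposterior (|x|) and dorsoventral (|y|) offsets of the
#' foci from the injection site, with percentile bootstrap CIs.
#'
#' @param foci data frame with \code{x_um} and \code{y_um}.
#' @param B bootstrap resamples (default 9999; 0 skips the CIs).
#' @param conf confidence level (default 0.95).
#' @return list with \code{mean_ap}, \code{mean_dv} and (if \code{B > 0})
#'   \code{ci_ap}, \code{ci_dv}.
#' @export
mean_migration <- function(foci, B = 9999, conf = 0.95) {
  stopifnot(nrow(foci) >= 1)
  ax <- abs(foci$x_um)
  ay <- abs(foci$y_um)
  out <- list(mean_ap = mean(ax), mean_dv = mean(ay), n = length(ax))
  if (B > 0) {
    n <- length(ax)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    bx <- colMeans(matrix(ax[idx], nrow = n))
    by <- colMeans(matrix(ay[idx], nrow = n))
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    out$ci_ap <- unname(quantile(bx, probs))
    out$ci_dv <- unname(quantile(by, probs))
  }
  out
}

#' Standard deviational ellipse of a 2-D point pattern
#'
#' One-standard-deviation summary ellipse of the dispersion of foci: the
#' center is the coordinate mean, the orientation and semi-axes come from the
#' eigen-decomposition of the 2x2 sample covariance, with semi-axis lengths
#' \code{sqrt(2 * eigenvalue)} so that for a bivariate normal the ellipse
#' contains about 63 percent of the mass. \code{theta} is the major-axis
#' angle from the +x axis in [0, pi).
#'
#' @param points two-column matrix or data frame of coordinates (or a foci
#'   data frame with \code{x_um}/\code{y_um}).
#' @return object of class \code{deviational_ellipse} with \code{center},
#'   \code{semi_major}, \code{semi_minor}, \code{theta} and \code{area}.
#' @export
deviational_ellipse <- function(points) {
  xy <- .as_xy(points)
  if (nrow(xy) < 2) stop("need at least 2 points for a deviational ellipse")
  ctr <- colMeans(xy)
  S <- cov(xy)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  semi <- sqrt(2 * ev)
  v <- e$vectors[, 1]
  theta <- atan2(v[2], v[1]) %% pi
  structure(
    list(center = c(x = unname(ctr[1]), y = unname(ctr[2])),
         semi_major = semi[1], semi_minor = semi[2],
         theta = theta, area = pi * semi[1] * semi[2], n = nrow(xy)),
    class = "deviational_ellipse"
  )
}

.as_xy <- function(points) {
  if (is.data.frame(points) && all(c("x_um", "y_um") %in% names(points))) {
    points <- points[, c("x_um", "y_um")]
  }
  xy <- as.matrix(points)
  stopifnot(ncol(xy) == 2, is.numeric(xy), all(is.finite(xy)))
  colnames(xy) <- c("x", "y")
  xy
}

#' @export
print.deviational_ellipse <- function(x, ...) {
  cat(sprintf("<deviational_ellipse> n=%d, center (%.1f, %.1f) um, semi-axes %.1f x %.1f um, theta %.1f deg, area %.0f um^2\n",
              x$n, x$center[1], x$center[2], x$semi_major, x$semi_minor,
              180 * x$theta / pi, x$area))
  invisible(x)
}

#' Bootstrap confidence intervals for a deviational ellipse
#'
#' Resamples the points with replacement \code{B} times and reports
#' percentile CIs for the center coordinates, the two semi-axis lengths and
#' the orientation. The orientation CI is computed on the doubled-angle
#' circular scale (2*theta on the circle) to avoid the wrap-around at pi.
#'
#' @inheritParams deviational_ellipse
#' @param B bootstrap resamples (default 9999).
#' @param conf confidence level (default 0.95).
#' @return object of class \code{ellipse_ci}: list of \code{c(lower, upper)}
#'   intervals for \code{center_x}, \code{center_y}, \code{semi_major},
#'   \code{semi_minor}, \code{theta}, plus the point estimate.
#' @export
bootstrap_ellipse <- function(points, B = 9999, conf = 0.95) {
  xy <- .as_xy(points)
  if (nrow(xy) < 5) stop("need at least 5 points to bootstrap an ellipse")
  est <- deviational_ellipse(xy)
  n <- nrow(xy)
  stats <- matrix(NA_real_, nrow = B, ncol = 5,
                  dimnames = list(NULL, c("center_x", "center_y",
                                          "semi_major", "semi_minor",
                                          "theta")))
  for (b in seq_len(B)) {
    eb <- deviational_ellipse(xy[sample.int(n, n, replace = TRUE), ,
                                 drop = FALSE])
    stats[b, ] <- c(eb$center[1], eb$center[2], eb$semi_major,
                    eb$semi_minor, eb$theta)
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- lapply(c("center_x", "center_y", "semi_major", "semi_minor"),
               function(nm) unname(quantile(stats[, nm], probs)))
  names(ci) <- c("center_x", "center_y", "semi_major", "semi_minor")
  # orientation on the doubled-angle circle
  z <- 2 * stats[, "theta"]
  mu <- atan2(mean(sin(z)), mean(cos(z)))
  dev <- atan2(sin(z - mu), cos(z - mu))
  qs <- unname(quantile(dev, probs))
  ci$theta <- ((mu + qs) / 2) %% pi
  if (diff(qs) < 1e-12) ci$theta <- rep(est$theta, 2)
  structure(list(estimate = est, ci = ci, B = B, conf = conf),
            class = "ellipse_ci")
}

#' @export
print.ellipse_ci <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  %d%% bootstrap CIs (B=%d):\n", round(100 * x$conf), x$B))
  for (nm in names(x$ci)) {
    cat(sprintf("    %-10s [%.2f, %.2f]\n", nm, x$ci[[nm]][1], x$ci[[nm]][2]))
  }
  invisible(x)
}

.disjoint <- function(a, b) a[2] < b[1] || b[2] < a[1]

#' Compare the spatial dispersion of two samples
#'
#' Bootstrap rule (default): the two patterns are \code{"different"} when the
#' bootstrap CIs of both semi-axis lengths are pairwise disjoint (a credible
#' difference in dispersion), or when the rectangular CI regions of the two
#' centers are disjoint, i.e. the center CIs separate in at least one
#' coordinate (a credible difference in location); otherwise
#' \code{"not-different"}. A permutation alternative is available: group
#' labels are permuted and two-sided p-values computed for the centroid
#' distance and the log ellipse-area ratio, with the difference called when
#' either Bonferroni-adjusted p-value falls below \code{1 - conf}.
#'
#' @param a,b two-column point sets (at least 5 points each).
#' @param B resamples/permutations (default 9999).
#' @param conf confidence level (default 0.95).
#' @param method \code{"bootstrap"} (default) or \code{"permutation"}.
#' @return \code{"different"} or \code{"not-different"}.
#' @export
compare_dispersion <- function(a, b, B = 9999, conf = 0.95,
                               method = c("bootstrap", "permutation")) {
  method <- match.arg(method)
  xa <- .as_xy(a); xb <- .as_xy(b)
  stopifnot(nrow(xa) >= 5, nrow(xb) >= 5)
  if (method == "bootstrap") {
    ca <- bootstrap_ellipse(xa, B = B, conf = conf)$ci
    cb <- bootstrap_ellipse(xb, B = B, conf = conf)$ci
    axes_diff <- .disjoint(ca$semi_major, cb$semi_major) &&
      .disjoint(ca$semi_minor, cb$semi_minor)
    center_diff <- .disjoint(ca$center_x, cb$center_x) ||
      .disjoint(ca$center_y, cb$center_y)
    if (axes_diff || center_diff) "different" else "not-different"
  } else {
    stat <- function(xa, xb) {
      ea <- deviational_ellipse(xa); eb <- deviational_ellipse(xb)
      c(cent = sqrt(sum((ea$center - eb$center)^2)),
        area = abs(log((ea$area + 1e-9) / (eb$area + 1e-9))))
    }
    obs <- stat(xa, xb)
    pool <- rbind(xa, xb)
    na <- nrow(xa)
    perm <- matrix(NA_real_, B, 2)
    for (i in seq_len(B)) {
      idx <- sample.int(nrow(pool), na)
      perm[i, ] <- stat(pool[idx, , drop = FALSE],
                        pool[-idx, , drop = FALSE])
    }
    p <- (1 + colSums(t(t(perm) >= obs))) / (B + 1)
    if (any(p < (1 - conf) / 2)) "different" else "not-different"
  }
}

#' Per-sample behavior summary
#'
#' Runs the full behavior quantification for one cohort: engraftment
#' efficiency, Gamma-Poisson survival posteriors of the scored embryos at 1
#' and 2 dpi, mean migration distances, the deviational ellipse (with
#' bootstrap CIs when \code{B > 0}), and the ten-region tropism profile with
#' random/clumped classification and preferred regions. Behavior analyses use
#' the foci of the scored embryos at \code{dpi}.
#'
#' @param cohort an \code{embryo_cohort}.
#' @param atlas region atlas.
#' @param dpi day post-injection analysed for migration/tropism (default 1).
#' @param B bootstrap resamples for migration and ellipse CIs (default 9999;
#'   0 skips the CIs).
#' @param a0,b0 survival prior (see \code{\link{survival_posterior}}).
#' @param dirichlet_prior tropism prior (see
#'   \code{\link{region_probabilities}}).
#' @param conf confidence/HDI level (default 0.95).
#' @return object of class \code{behavior_summary}.
#' @export
behavior_summary <- function(cohort, atlas = region_atlas(), dpi = 1,
                             B = 9999, a0 = 1, b0 = 1,
                             dirichlet_prior = rep(1, 10), conf = 0.95) {
  stopifnot(inherits(cohort, "embryo_cohort"))
  emb <- cohort$embryos
  scored <- emb[emb$scored, , drop = FALSE]
  foci <- cohort$foci[cohort$foci$dpi == dpi, , drop = FALSE]
  foci <- assign_regions(foci, atlas)
  surv1 <- survival_posterior(scored$n_foci_1dpi, a0, b0, mass = conf)
  surv2 <- survival_posterior(scored$n_foci_2dpi, a0, b0, mass = conf)
  migration <- if (nrow(foci) >= 1) mean_migration(foci, B = B, conf = conf)
  ellipse <- if (nrow(foci) >= 2) deviational_ellipse(foci)
  ellipse_ci <- if (B > 0 && nrow(foci) >= 5) {
    bootstrap_ellipse(foci, B = B, conf = conf)
  }
  tropism <- if (nrow(foci) >= 1) {
    region_probabilities(foci, prior = dirichlet_prior, mass = conf,
                         atlas = atlas)
  }
  structure(
    list(sample_id = cohort$sample_id,
         engraftment_pct = engraftment_efficiency(cohort),
         survival_1dpi = surv1, survival_2dpi = surv2,
         migration = migration, ellipse = ellipse, ellipse_ci = ellipse_ci,
         tropism = tropism,
         dispersion = if (!is.null(tropism)) classify_distribution(tropism),
         preferred = if (!is.null(tropism)) preferred_regions(tropism),
         dpi = dpi, n_foci = nrow(foci)),
    class = "behavior_summary"
  )
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("<behavior_summary> %s (dpi %d, %d foci)\n",
              x$sample_id, x$dpi, x$n_foci))
  cat(sprintf("  engraftment %.1f%%, survival mean %.2f foci/embryo (1 dpi), %.2f (2 dpi)\n",
              x$engraftment_pct, x$survival_1dpi$mean, x$survival_2dpi$mean))
  if (!is.null(x$migration)) {
    cat(sprintf("  mean migration AP %.0f um, DV %.0f um\n",
                x$migration$mean_ap, x$migration$mean_dv))
  }
  if (!is.null(x$dispersion)) {
    cat(sprintf("  dispersion: %s; preferred regions: %s\n", x$dispersion,
                if (length(x$preferred)) paste(x$preferred, collapse = ", ")
                else "none"))
  }
  invisible(x)
}
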