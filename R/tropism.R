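# Dirichlet-multinomial tropism: per-region posterior probabilities with
# marginal Beta HDIs, random/clumped classification and preferred regions.

#' Region tropism posterior
#'
#' Counts of foci per atlas region are modeled as multinomial with a
#' conjugate Dirichlet prior (uniform Dirichlet(1, ..., 1) by default). The
#' posterior is Dirichlet(prior + counts); reported per-region probabilities
#' are the posterior means and the per-region intervals are HDIs of the
#' marginal Beta distributions.
#'
#' @param x either a labeled foci data frame (with a \code{region} column;
#'   see \code{\link{assign_regions}}) or a named/ordered count vector of
#'   length 10 in atlas region order.
#' @param prior Dirichlet prior weights, length 10 (default uniform).
#' @param mass HDI mass (default 0.95).
#' @param atlas region atlas fixing the region order.
#' @return object of class \code{tropism_profile}: counts, posterior
#'   \code{alpha}, \code{prob_mean} (sums to 1), \code{hdi} (10 x 2 matrix)
#'   and \code{n}.
#' @examples
#' counts <- c(CHT = 10, setNames(rep(0, 9), setdiff(region_atlas()$region, "CHT")))
#' region_probabilities(counts)$prob_mean["CHT"]  # 11/20 under uniform prior
#' @export
region_probabilities <- function(x, prior = rep(1, 10), mass = 0.95,
                                 atlas = region_atlas()) {
  atlas <- validate_atlas(atlas)
  regions <- atlas$region
  stopifnot(length(prior) == 10, all(prior >= 0))
  if (is.data.frame(x)) {
    if (!"region" %in% names(x)) {
      stop("foci must carry a region label; run assign_regions() first")
    }
    if (nrow(x) == 0) stop("no labeled foci")
    counts <- table(factor(x$region, levels = regions))
    counts <- setNames(as.integer(counts), regions)
  } else {
    stopifnot(length(x) == 10, all(x >= 0))
    counts <- if (is.null(names(x))) setNames(as.integer(x), regions)
              else setNames(as.integer(x[regions]), regions)
    if (anyNA(counts)) stop("count names must match the atlas regions")
  }
  alpha <- prior + counts
  a0 <- sum(alpha)
  hdi_mat <- t(vapply(alpha, function(a) hdi_beta(a, a0 - a, mass),
                      numeric(2)))
  dimnames(hdi_mat) <- list(regions, c("lower", "upper"))
  structure(
    list(counts = counts, alpha = setNames(alpha, regions),
         prob_mean = setNames(alpha / a0, regions),
         hdi = hdi_mat, mass = mass, n = sum(counts)),
    class = "tropism_profile"
  )
}

#' @export
print.tropism_profile <- function(x, ...) {
  cat(sprintf("<tropism_profile> %d foci over 10 regions (%.0f%% HDIs)\n",
              x$n, 100 * x$mass))
  tab <- data.frame(counts = as.integer(x$counts),
                    prob = round(x$prob_mean, 3),
                    lower = round(x$hdi[, 1], 3),
                    upper = round(x$hdi[, 2], 3))
  print(tab)
  invisible(x)
}

#' Random versus clumped dispersion
#'
#' A tropism profile is \code{"clumped"} when at least one pair of regions
#' shows a credible difference in occupancy probability, operationalized as
#' disjoint marginal HDIs, and \code{"random"} otherwise. With ten regions
#' there are 45 pairwise comparisons, so by default each marginal HDI is
#' widened to the Sidak-adjusted simultaneous mass
#' \code{mass^(1 / choose(10, 2))}, which keeps the family-wise probability
#' of a spurious clump call near \code{1 - mass}; \code{adjust = "none"}
#' compares the unadjusted per-region HDIs instead.
#'
#' @param profile a \code{\link{region_probabilities}} result.
#' @param adjust \code{"sidak"} (default) or \code{"none"}.
#' @param mass nominal simultaneous mass (default the profile's mass).
#' @return \code{"random"} or \code{"clumped"}.
#' @export
classify_distribution <- function(profile, adjust = c("sidak", "none"),
                                  mass = NULL) {
  stopifnot(inherits(profile, "tropism_profile"))
  adjust <- match.arg(adjust)
  if (is.null(mass)) mass <- profile$mass
  k <- length(profile$alpha)
  m <- if (adjust == "sidak") mass^(1 / choose(k, 2)) else mass
  a0 <- sum(profile$alpha)
  h <- t(vapply(profile$alpha, function(a) hdi_beta(a, a0 - a, m),
                numeric(2)))
  if (any(outer(h[, 2], h[, 1], `<`))) "clumped" else "random"
}

#' Preferred migration regions
#'
#' Regions whose marginal HDI lies entirely above the uniform expectation
#' (1/10 for the ten-region atlas), i.e. regions credibly enriched for foci.
#'
#' @param profile a \code{\link{region_probabilities}} result.
#' @param threshold enrichment bound (default \code{1/10}).
#' @return character vector of region names (possibly empty).
#' @export
preferred_regions <- function(profile, threshold = NULL) {
  stopifnot(inherits(profile, "tropism_profile"))
  if (is.null(threshold)) threshold <- 1 / length(profile$alpha)
  names(profile$alpha)[profile$hdi[, 1] > threshold]
}
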