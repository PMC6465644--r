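#' Generative profile of one xenografted sample
#'
#' A \code{sample_profile} holds the ground truth from which the synthetic
#' study generator draws every measured quantity for one patient sample or
#' cell line: engraftment probability, expected foci burden and its 1-to-2 dpi
#' decay, the spatial dispersion mode and region tropism, the ALDH-bright and
#' CD34+ fractions of the flow sample, and the clinical outcome label.
#'
#' @param sample_id unique sample identifier.
#' @param lineage one of \code{"AML"}, \code{"ALL"}, \code{"non-leukemic"},
#'   \code{"cell-line"}.
#' @param fab_subtype free-text FAB/WHO label (e.g. \code{"M4"}).
#' @param engraft_prob probability an injected embryo shows at least one
#'   fluorescent focus at 1 dpi.
#' @param foci_mean expected foci count per engrafted embryo at 1 dpi.
#' @param survival_decay multiplicative factor on \code{foci_mean} from 1 to
#'   2 dpi (1 = no loss).
#' @param dispersion_mode \code{"clumped"} or \code{"random"}; random forces
#'   uniform tropism weights (0.1 per region).
#' @param tropism_weights length-10 vector of region probabilities in atlas
#'   order (see \code{\link{region_atlas}}); must sum to 1 within 1e-9.
#' @param aldh_bright_frac expected fraction of intact singlet events falling
#'   in the ALDH-bright/SSC-low gate.
#' @param cd34_frac_within expected CD34+ fraction inside that gate.
#' @param outcome \code{"remission"}, \code{"no-remission"} or
#'   \code{"unknown"}.
#' @return object of class \code{sample_profile}.
#' @examples
#' sample_profile("LPZ6", "AML", "M4", engraft_prob = 0.9, foci_mean = 20,
#'                aldh_bright_frac = 0.256, cd34_frac_within = 0.511,
#'                outcome = "no-remission")
#' @export
sample_profile <- function(sample_id,
                           lineage = c("AML", "ALL", "non-leukemic", "cell-line"),
                           fab_subtype = "",
                           engraft_prob = 0.8,
                           foci_mean = 20,
                           survival_decay = 0.8,
                           dispersion_mode = c("clumped", "random"),
                           tropism_weights = NULL,
                           aldh_bright_frac = 0.05,
                           cd34_frac_within = 0.3,
                           outcome = c("unknown", "remission", "no-remission")) {
  lineage <- match.arg(lineage)
  dispersion_mode <- match.arg(dispersion_mode)
  outcome <- match.arg(outcome)
  for (p in c(engraft_prob, aldh_bright_frac, cd34_frac_within)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]")
    }
  }
  if (foci_mean < 0) stop("foci_mean must be >= 0")
  if (survival_decay < 0) stop("survival_decay must be >= 0")
  if (dispersion_mode == "random") {
    if (!is.null(tropism_weights) &&
        any(abs(tropism_weights - 0.1) > 1e-9)) {
      stop("dispersion_mode = 'random' implies uniform tropism weights")
    }
    tropism_weights <- rep(0.1, 10)
  }
  if (is.null(tropism_weights)) {
    # default clump: CHT-dominated, mirroring the leukemic tropism the
    # behavior module is designed to detect
    tropism_weights <- c(PCS = 0.15, Yolk = 0.05, CHT = 0.40, CF = 0.05,
                         ISV = 0.05, PHBC = 0.05, PCV = 0.15, PMBC = 0.04,
                         DLAV = 0.03, AA1 = 0.03)
  }
  tropism_weights <- as.numeric(tropism_weights)
  if (length(tropism_weights) != 10L) {
    stop("tropism_weights must have length 10")
  }
  s <- sum(tropism_weights)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("tropism_weights must sum to 1 (got %.12g)", s))
  }
  if (any(tropism_weights < 0)) stop("tropism_weights must be non-negative")
  structure(
    list(sample_id = as.character(sample_id), lineage = lineage,
         fab_subtype = fab_subtype, engraft_prob = engraft_prob,
         foci_mean = foci_mean, survival_decay = survival_decay,
         dispersion_mode = dispersion_mode,
         tropism_weights = setNames(tropism_weights, .atlas_regions),
         aldh_bright_frac = aldh_bright_frac,
         cd34_frac_within = cd34_frac_within, outcome = outcome),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s (%s %s), outcome: %s\n",
              x$sample_id, x$lineage, x$fab_subtype, x$outcome))
  cat(sprintf("  engraft_prob %.2f, foci_mean %.1f, decay %.2f, %s dispersion\n",
              x$engraft_prob, x$foci_mean, x$survival_decay, x$dispersion_mode))
  cat(sprintf("  ALDH-bright %.1f%%, CD34+ within %.1f%%\n",
              100 * x$aldh_bright_frac, 100 * x$cd34_frac_within))
  invisible(x)
}

#' Study-level configuration for the synthetic generator
#'
#' @param profiles list of \code{\link{sample_profile}} objects with unique
#'   sample ids.
#' @param n_embryos_per_sample embryos injected per sample (default 24).
#' @param n_embryos_scored embryos scored for survival and migration
#'   (default 6); must not exceed \code{n_embryos_per_sample}.
#' @param n_flow_events events acquired per flow tube (default 50000).
#' @param seed integer RNG seed; a fixed seed makes \code{\link{gen_study}}
#'   byte-identical across runs.
#' @param jitter_sd Gaussian jitter (micrometres) added to focus coordinates
#'   (default 10).
#' @param doublet_frac expected doublet fraction among flow events
#'   (default 0.02).
#' @param debris_frac expected debris fraction among flow events
#'   (default 0.05).
#' @param nb_size optional negative-binomial size parameter for overdispersed
#'   foci counts; \code{NULL} (default) keeps counts Poisson.
#' @return object of class \code{study_config}.
#' @export
study_config <- function(profiles,
                         n_embryos_per_sample = 24L,
                         n_embryos_scored = 6L,
                         n_flow_events = 50000L,
                         seed = 1L,
                         jitter_sd = 10,
                         doublet_frac = 0.02,
                         debris_frac = 0.05,
                         nb_size = NULL) {
  if (inherits(profiles, "sample_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "sample_profile")))
  ids <- vapply(profiles, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (n_embryos_scored > n_embryos_per_sample) {
    stop("n_embryos_scored must be <= n_embryos_per_sample")
  }
  if (doublet_frac + debris_frac >= 1) stop("doublet + debris fraction >= 1")
  structure(
    list(profiles = setNames(profiles, ids),
         n_embryos_per_sample = as.integer(n_embryos_per_sample),
         n_embryos_scored = as.integer(n_embryos_scored),
         n_flow_events = as.integer(n_flow_events),
         seed = as.integer(seed), jitter_sd = jitter_sd,
         doublet_frac = doublet_frac, debris_frac = debris_frac,
         nb_size = nb_size),
    class = "study_config"
  )
}

#' Profiles mirroring the reference acute-leukemia cohort
#'
#' Seven \code{\link{sample_profile}} objects whose identifiers, lineages,
#' outcome labels and gate fractions follow the published reference cohort
#' (see \code{\link{lsc_reference}} and \code{\link{clinical_reference}}).
#' Behavioral parameters (engraftment, foci burden, tropism) are synthetic
#' stand-ins consistent with the qualitative description of each sample:
#' random-dispersion samples carry uniform tropism, clumped samples a
#' CHT-weighted clump.
#'
#' @return named list of 7 profiles.
#' @export
reference_profiles <- function() {
  clin <- clinical_reference()
  lsc <- lsc_reference()
  clumped_w <- c(PCS = 0.10, Yolk = 0.04, CHT = 0.40, CF = 0.03, ISV = 0.04,
                 PHBC = 0.05, PCV = 0.22, PMBC = 0.05, DLAV = 0.03, AA1 = 0.04)
  profs <- lapply(seq_len(nrow(clin)), function(i) {
    id <- clin$sample_id[i]
    j <- match(id, lsc$sample_id)
    mode <- if (is.na(clin$dispersion[i])) "clumped" else clin$dispersion[i]
    sample_profile(
      sample_id = id,
      lineage = if (grepl("ALL", clin$subtype[i])) "ALL" else "AML",
      fab_subtype = clin$subtype[i],
      engraft_prob = if (grepl("ALL", clin$subtype[i])) 0.725 else 0.878,
      foci_mean = 18 + 0.15 * clin$pct_blasts[i],
      survival_decay = 0.75,
      dispersion_mode = mode,
      tropism_weights = if (mode == "random") NULL else clumped_w,
      aldh_bright_frac = if (is.na(j)) 0.05 else lsc$pct_aldh_bright_ssclow[j] / 100,
      cd34_frac_within = if (is.na(j)) 0.30 else lsc$pct_cd34_within[j] / 100,
      outcome = switch(clin$remission[i], yes = "remission",
                       no = "no-remission", "unknown")
    )
  })
  setNames(profs, clin$sample_id)
}

#' Profiles for an outcome-driver recovery study
#'
#' Generates \code{2 * n_per_class} sample profiles in which the remission
#' outcome is driven by exactly two features: the combined LSC fraction
#' (ALDH-bright x CD34-within, about 4-fold higher in non-remission samples)
#' and the CHT tropism probability (high in remission samples). The two gate
#' factors receive anticorrelated log-normal noise so that neither factor
#' alone separates the classes as cleanly as their product, and the remaining
#' tropism mass is perturbed with Dirichlet noise so no other region carries a
#' comparable signal. All other generative parameters are drawn identically
#' for both classes. Uses the current RNG stream.
#'
#' @param n_per_class samples per outcome class (default 10).
#' @param factor_noise_sd standard deviation of the shared anticorrelated
#'   log-scale noise on the two gate fractions (default 0.45).
#' @param tropism_concentration Dirichlet concentration of the per-sample
#'   tropism weights around the class template (default 25).
#' @return named list of \code{sample_profile} objects; the intended top
#'   discriminant features are recorded in attribute \code{"drivers"}
#'   (\code{c("pct_lsc_combined", "prob_CHT")}).
#' @export
outcome_profiles <- function(n_per_class = 10,
                             factor_noise_sd = 0.45,
                             tropism_concentration = 25) {
  # the two templates differ strongly only in CHT; the displaced mass is
  # spread over four distance-matched regions (Yolk/ISV/PCV/CF) so the mean
  # migration distance and every single nuisance region carry much weaker
  # class signal than CHT itself
  templ <- list(
    remission = c(PCS = 0.24, Yolk = 0.0325, CHT = 0.50, CF = 0.0325,
                  ISV = 0.0325, PHBC = 0.0325, PCV = 0.0325, PMBC = 0.0325,
                  DLAV = 0.0325, AA1 = 0.0325),
    `no-remission` = c(PCS = 0.24, Yolk = 0.1375, CHT = 0.08, CF = 0.1375,
                       ISV = 0.1375, PHBC = 0.0325, PCV = 0.1375,
                       PMBC = 0.0325, DLAV = 0.0325, AA1 = 0.0325)
  )
  mu <- list(remission = c(a = log(0.14), c = log(0.20)),
             `no-remission` = c(a = log(0.26), c = log(0.42)))
  profs <- list()
  for (cls in names(templ)) {
    for (i in seq_len(n_per_class)) {
      u <- rnorm(1, 0, factor_noise_sd)
      a <- min(0.75, max(0.01, exp(mu[[cls]]["a"] + u)))
      cc <- min(0.97, max(0.02, exp(mu[[cls]]["c"] - u)))
      g <- rgamma(10, shape = tropism_concentration * templ[[cls]])
      w <- g / sum(g)
      w <- w / sum(w)  # renormalize exactly
      profs[[length(profs) + 1L]] <- sample_profile(
        sample_id = sprintf("S%s%02d", if (cls == "remission") "R" else "N", i),
        lineage = "AML", fab_subtype = "synthetic",
        engraft_prob = runif(1, 0.6, 0.9),
        foci_mean = runif(1, 15, 30),
        survival_decay = runif(1, 0.5, 0.9),
        dispersion_mode = "clumped",
        tropism_weights = w,
        aldh_bright_frac = a, cd34_frac_within = cc,
        outcome = cls
      )
    }
  }
  ids <- vapply(profs, `[[`, "", "sample_id")
  structure(setNames(profs, ids), drivers = c("pct_lsc_combined", "prob_CHT"))
}
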