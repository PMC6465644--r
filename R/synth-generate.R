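# Synthetic study generation: embryo cohorts, paired flow tubes, clinical
# records. All draws come from the current RNG stream; gen_study() seeds it
# once from the study_config so a fixed seed gives byte-identical output.

#' Generate an embryo cohort for one sample
#'
#' For each injected embryo, engraftment is Bernoulli(\code{engraft_prob});
#' engrafted embryos receive Poisson(\code{foci_mean}) foci at 1 dpi and
#' Poisson(\code{foci_mean * survival_decay}) at 2 dpi (negative binomial if
#' \code{nb_size} is set in the config). A random subset of
#' \code{n_embryos_scored} embryos is scored: each of their foci is assigned a
#' region from \code{tropism_weights}, placed uniformly inside that region's
#' rectangle, and jittered with Gaussian noise (sd \code{jitter_sd} um), which
#' can carry it across a region border.
#'
#' @param profile a \code{\link{sample_profile}}.
#' @param config a \code{\link{study_config}}.
#' @param atlas region atlas supplying the rectangle extents.
#' @return object of class \code{embryo_cohort}: list with \code{sample_id},
#'   \code{n_injected}, \code{embryos} (per-embryo table with engrafted flag
#'   and foci counts at both dpi) and \code{foci} (per-focus coordinate table
#'   for scored embryos, with the generative \code{region_true} label).
#' @export
gen_embryo_cohort <- function(profile, config, atlas = region_atlas()) {
  stopifnot(inherits(profile, "sample_profile"),
            inherits(config, "study_config"))
  w <- profile$tropism_weights
  s <- sum(w)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("tropism_weights must sum to 1 (got %.12g)", s))
  }
  atlas <- validate_atlas(atlas)
  n <- config$n_embryos_per_sample
  draw_counts <- function(mu, k) {
    if (is.null(config$nb_size)) rpois(k, mu)
    else rnbinom(k, size = config$nb_size, mu = mu)
  }
  engrafted <- runif(n) < profile$engraft_prob
  n1 <- ifelse(engrafted, draw_counts(profile$foci_mean, n), 0L)
  n2 <- ifelse(engrafted,
               draw_counts(profile$foci_mean * profile$survival_decay, n), 0L)
  embryo_id <- sprintf("%s_e%02d", profile$sample_id, seq_len(n))
  # embryos scored for survival/migration are drawn among engrafted embryos
  # when enough are available (scoring empty embryos carries no information)
  eng_idx <- which(engrafted)
  ns <- config$n_embryos_scored
  scored <- if (length(eng_idx) >= ns) {
    eng_idx[sample.int(length(eng_idx), ns)]
  } else {
    rest <- setdiff(seq_len(n), eng_idx)
    c(eng_idx, rest[sample.int(length(rest), ns - length(eng_idx))])
  }
  scored <- sort(scored)
  embryos <- data.frame(embryo_id = embryo_id, engrafted = engrafted,
                        n_foci_1dpi = as.integer(n1),
                        n_foci_2dpi = as.integer(n2),
                        scored = seq_len(n) %in% scored,
                        stringsAsFactors = FALSE)
  foci <- list()
  for (i in scored) {
    for (dpi in 1:2) {
      k <- if (dpi == 1) n1[i] else n2[i]
      if (k == 0) next
      ridx <- sample.int(10L, k, replace = TRUE, prob = w)
      x <- runif(k, atlas$x0[ridx], atlas$x1[ridx]) +
        rnorm(k, 0, config$jitter_sd)
      y <- runif(k, atlas$y0[ridx], atlas$y1[ridx]) +
        rnorm(k, 0, config$jitter_sd)
      foci[[length(foci) + 1L]] <- data.frame(
        embryo_id = embryo_id[i], sample_id = profile$sample_id,
        dpi = dpi, x_um = x, y_um = y,
        region_true = atlas$region[ridx], stringsAsFactors = FALSE)
    }
  }
  foci <- if (length(foci)) do.call(rbind, foci) else
    data.frame(embryo_id = character(), sample_id = character(),
               dpi = integer(), x_um = numeric(), y_um = numeric(),
               region_true = character(), stringsAsFactors = FALSE)
  structure(list(sample_id = profile$sample_id, n_injected = n,
                 embryos = embryos, foci = foci),
            class = "embryo_cohort")
}

#' @export
print.embryo_cohort <- function(x, ...) {
  cat(sprintf("<embryo_cohort> %s: %d injected, %d engrafted, %d scored, %d foci records\n",
              x$sample_id, x$n_injected, sum(x$embryos$engrafted),
              sum(x$embryos$scored), nrow(x$foci)))
  invisible(x)
}

# channel-level event draws for one mixture component
.flow_component <- function(k, kind, cd34_pos_frac = 0.2) {
  if (k == 0) {
    return(data.frame(fsc_a = numeric(), fsc_h = numeric(), ssc_a = numeric(),
                      fitc_a = numeric(), cd34_a = numeric()))
  }
  fitc_bg <- function(k) rlnorm(k, log(100), 0.5)
  cd34 <- function(k, frac) {
    pos <- runif(k) < frac
    ifelse(pos, rlnorm(k, log(2000), 0.4), rlnorm(k, log(50), 0.4))
  }
  switch(kind,
    dim = {
      fsc <- rlnorm(k, log(60000), 0.18)
      data.frame(fsc_a = fsc, fsc_h = fsc * rnorm(k, 1, 0.015),
                 ssc_a = rlnorm(k, log(30000), 0.35),
                 fitc_a = fitc_bg(k), cd34_a = cd34(k, cd34_pos_frac))
    },
    bright_pos = ,
    bright_neg = {
      fsc <- rlnorm(k, log(60000), 0.18)
      data.frame(fsc_a = fsc, fsc_h = fsc * rnorm(k, 1, 0.015),
                 ssc_a = rlnorm(k, log(9000), 0.30),
                 fitc_a = rlnorm(k, log(100) + 4, 0.5),
                 cd34_a = cd34(k, if (kind == "bright_pos") 1 else 0))
    },
    doublet = {
      fsc <- rlnorm(k, log(120000), 0.18)
      data.frame(fsc_a = fsc, fsc_h = 0.5 * fsc * rnorm(k, 1, 0.03),
                 ssc_a = rlnorm(k, log(60000), 0.35),
                 fitc_a = fitc_bg(k), cd34_a = cd34(k, cd34_pos_frac))
    },
    debris = {
      fsc <- rlnorm(k, log(4000), 0.5)
      data.frame(fsc_a = fsc, fsc_h = fsc * rnorm(k, 1, 0.05),
                 ssc_a = rlnorm(k, log(8000), 0.6),
                 fitc_a = fitc_bg(k), cd34_a = cd34(k, 0.05))
    })
}

#' Generate a paired DEAB+/DEAB- flow sample
#'
#' Events are drawn from a mixture of intact singlets (log-normal FSC/SSC),
#' doublets (FSC-H about half of FSC-A) and low-FSC debris. In the DEAB- test
#' tube an ALDH-bright/SSC-low subpopulation of expected fraction
#' \code{aldh_bright_frac} (of intact singlets) carries FITC intensities well
#' above background and a CD34+ fraction of \code{cd34_frac_within}; in the
#' DEAB+ control tube ALDH is fully inhibited, so every event draws its FITC
#' intensity from the background distribution.
#'
#' @inheritParams gen_embryo_cohort
#' @return list with elements \code{test} and \code{control}, each a
#'   \code{\link{flow_sample}}.
#' @export
gen_flow_events <- function(profile, config) {
  stopifnot(inherits(profile, "sample_profile"),
            inherits(config, "study_config"))
  n <- config$n_flow_events
  if (n < 1000) {
    warning("fewer than 1000 flow events; gate fractions will be unstable")
  }
  clean <- 1 - config$debris_frac - config$doublet_frac
  a <- profile$aldh_bright_frac
  c34 <- profile$cd34_frac_within
  draw_tube <- function(bright) {
    p <- if (bright) {
      c(debris = config$debris_frac, doublet = config$doublet_frac,
        dim = clean * (1 - a), bright_pos = clean * a * c34,
        bright_neg = clean * a * (1 - c34))
    } else {
      c(debris = config$debris_frac, doublet = config$doublet_frac,
        dim = clean, bright_pos = 0, bright_neg = 0)
    }
    k <- as.vector(rmultinom(1, n, p))
    ev <- do.call(rbind, lapply(seq_along(k), function(i) {
      .flow_component(k[i], names(p)[i])
    }))
    ev[sample.int(nrow(ev)), , drop = FALSE]
  }
  list(
    test = flow_sample(draw_tube(TRUE), tube = "DEAB-",
                       sample_id = profile$sample_id),
    control = flow_sample(draw_tube(FALSE), tube = "DEAB+",
                          sample_id = profile$sample_id)
  )
}

#' Generate clinical records for a set of profiles
#'
#' One record per profile with the standard diagnostic fields (age band,
#' subtype, blast percentage, platelet and leukocyte counts, cytogenetics,
#' risk stratification, remission). For identifiers present in the reference
#' cohort the published values are used; otherwise plausible values are drawn.
#' The remission column is copied from the profile outcome.
#'
#' @param profiles list of \code{\link{sample_profile}} objects.
#' @return data frame of clinical records (possibly zero rows).
#' @export
gen_clinical_table <- function(profiles) {
  if (inherits(profiles, "sample_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) {
    return(data.frame(sample_id = character(), age_band = character(),
                      subtype = character(), pct_blasts = numeric(),
                      platelets_k_ul = numeric(), leukocytes_k_ul = numeric(),
                      cytogenetics = character(), risk = character(),
                      remission = character(), stringsAsFactors = FALSE))
  }
  ids <- vapply(profiles, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ref <- clinical_reference()
  bands <- c("18-25", "26-30", "30-35", "36-39", "40-45", "46-50",
             "51-60", "61-75", "76-80")
  rows <- lapply(profiles, function(p) {
    j <- match(p$sample_id, ref$sample_id)
    if (!is.na(j)) {
      r <- ref[j, setdiff(names(ref), "dispersion"), drop = FALSE]
    } else {
      r <- data.frame(
        sample_id = p$sample_id, age_band = sample(bands, 1),
        subtype = if (nzchar(p$fab_subtype)) p$fab_subtype else p$lineage,
        pct_blasts = round(runif(1, 2, 95), 1),
        platelets_k_ul = round(runif(1, 20, 300)),
        leukocytes_k_ul = round(runif(1, 2, 110), 1),
        cytogenetics = sample(c("Normal", "Complex", "t(9;22)", "t(15;17)"), 1),
        risk = sample(c("favorable/standard", "intermediate", "adverse"), 1),
        remission = NA_character_, stringsAsFactors = FALSE)
    }
    r$remission <- switch(p$outcome, remission = "yes",
                          `no-remission` = "no", NA_character_)
    r
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic study
#'
#' Seeds the RNG from \code{config$seed}, then generates an embryo cohort and
#' a paired flow sample per profile plus the clinical table, and records every
#' generative parameter in a ground-truth sidecar for recovery tests. With a
#' fixed seed the result (and the files written by \code{\link{write_study}})
#' is identical across runs.
#'
#' @param config a \code{\link{study_config}}.
#' @param atlas region atlas used for foci placement.
#' @return object of class \code{synthetic_study}: list with \code{config},
#'   \code{cohorts}, \code{flow}, \code{clinical} and \code{ground_truth}.
#' @export
gen_study <- function(config, atlas = region_atlas()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  cohorts <- lapply(config$profiles, gen_embryo_cohort, config = config,
                    atlas = atlas)
  flow <- lapply(config$profiles, gen_flow_events, config = config)
  clinical <- gen_clinical_table(config$profiles)
  gt <- list(
    seed = config$seed,
    n_embryos_per_sample = config$n_embryos_per_sample,
    n_embryos_scored = config$n_embryos_scored,
    n_flow_events = config$n_flow_events,
    jitter_sd = config$jitter_sd,
    doublet_frac = config$doublet_frac,
    debris_frac = config$debris_frac,
    profiles = lapply(config$profiles, unclass)
  )
  structure(list(config = config, cohorts = cohorts, flow = flow,
                 clinical = clinical, ground_truth = gt),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d samples, %d embryos/sample, %d flow events/tube, seed %d\n",
              length(x$cohorts), x$config$n_embryos_per_sample,
              x$config$n_flow_events, x$config$seed))
  invisible(x)
}

#' Write or read a synthetic study as plain-text files
#'
#' Writes \code{foci.csv} (schema: embryo_id, sample_id, dpi, x_um, y_um, plus
#' the generative region_true column), \code{embryos.csv} (per-embryo counts),
#' one flow CSV per sample and tube (\code{flow_<id>_<test|control>.csv} with
#' the cytometer channel names), \code{clinical.csv} and the ground-truth
#' sidecar \code{ground_truth.json}.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if missing).
#' @return \code{write_study} returns \code{dir} invisibly; \code{read_study}
#'   returns a list with \code{foci}, \code{embryos}, \code{flow},
#'   \code{clinical} and (if present) \code{ground_truth}.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  foci <- do.call(rbind, lapply(study$cohorts, `[[`, "foci"))
  write_foci_csv(foci, file.path(dir, "foci.csv"))
  embryos <- do.call(rbind, lapply(study$cohorts, function(co) {
    cbind(sample_id = co$sample_id, co$embryos, n_injected = co$n_injected,
          stringsAsFactors = FALSE)
  }))
  write.csv(embryos, file.path(dir, "embryos.csv"), row.names = FALSE)
  for (id in names(study$flow)) {
    write_flow_csv(study$flow[[id]]$test,
                   file.path(dir, sprintf("flow_%s_test.csv", id)))
    write_flow_csv(study$flow[[id]]$control,
                   file.path(dir, sprintf("flow_%s_control.csv", id)))
  }
  write.csv(study$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(study$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) stop("study directory not found: ", dir)
  foci <- read_foci_csv(file.path(dir, "foci.csv"))
  embryos <- read.csv(file.path(dir, "embryos.csv"), stringsAsFactors = FALSE)
  clinical <- read_clinical_csv(file.path(dir, "clinical.csv"))
  ids <- unique(embryos$sample_id)
  flow <- setNames(lapply(ids, function(id) {
    list(test = read_flow_csv(file.path(dir, sprintf("flow_%s_test.csv", id)),
                              tube = "DEAB-", sample_id = id),
         control = read_flow_csv(file.path(dir, sprintf("flow_%s_control.csv", id)),
                                 tube = "DEAB+", sample_id = id))
  }), ids)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE)
  cohorts <- setNames(lapply(ids, function(id) {
    e <- embryos[embryos$sample_id == id, , drop = FALSE]
    structure(list(sample_id = id, n_injected = e$n_injected[1],
                   embryos = e[, c("embryo_id", "engrafted", "n_foci_1dpi",
                                   "n_foci_2dpi", "scored")],
                   foci = foci[foci$sample_id == id, , drop = FALSE]),
              class = "embryo_cohort")
  }), ids)
  list(foci = foci, embryos = embryos, cohorts = cohorts, flow = flow,
       clinical = clinical, ground_truth = gt)
}
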