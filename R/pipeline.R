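# End-to-end orchestration: simulate (or load) -> gate -> behavior ->
# integrate -> report, with a serializable configuration and a manifest of
# seeds and input hashes.

#' Pipeline configuration
#'
#' Either a \code{\link{study_config}} (simulation requested) or a directory
#' of input tables written in the package's formats (see
#' \code{\link{write_study}}).
#'
#' @param study_config a \code{study_config} for simulation, or \code{NULL}.
#' @param input_dir directory with \code{foci.csv}, \code{embryos.csv}, flow
#'   CSVs and \code{clinical.csv}; ignored when \code{study_config} is given.
#' @param atlas region atlas object or path to an atlas YAML/JSON file.
#' @param bootstrap_reps bootstrap resamples for behavior CIs (default 9999).
#' @param seed analysis seed for the bootstrap stages (default 1).
#' @param gamma_prior length-2 \code{c(a0, b0)} survival prior.
#' @param dirichlet_prior length-10 tropism prior.
#' @param deab_quantile,min_fsc,band_halfwidth,threshold_numerous gating
#'   parameters (see \code{\link{gate_sample}}).
#' @param ncomp PLS components for the integration stage (default 2).
#' @return object of class \code{pipeline_config} (a fully serializable
#'   list).
#' @export
pipeline_config <- function(study_config = NULL, input_dir = NULL,
                            atlas = region_atlas(), bootstrap_reps = 9999,
                            seed = 1L, gamma_prior = c(1, 1),
                            dirichlet_prior = rep(1, 10),
                            deab_quantile = 0.999, min_fsc = 20000,
                            band_halfwidth = 0.15, threshold_numerous = 1.9,
                            ncomp = 2) {
  if (is.null(study_config) && is.null(input_dir)) {
    stop("provide either a study_config (simulation) or an input_dir")
  }
  if (is.character(atlas)) atlas <- read_atlas(atlas)
  structure(
    list(study_config = study_config, input_dir = input_dir,
         atlas = validate_atlas(atlas), bootstrap_reps = bootstrap_reps,
         seed = as.integer(seed), gamma_prior = gamma_prior,
         dirichlet_prior = dirichlet_prior, deab_quantile = deab_quantile,
         min_fsc = min_fsc, band_halfwidth = band_halfwidth,
         threshold_numerous = threshold_numerous, ncomp = ncomp),
    class = "pipeline_config"
  )
}

.stage <- function(stage, sample_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed for sample '%s': %s",
                 stage, sample_id, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> gate -> behavior -> integrate and collects
#' the results in a study report: per-sample gate results and behavior
#' summaries, the tropism probability table (the tabular analog of a
#' per-region heat map), the product-identity audit warnings, and the PLS-DA
#' integration summary over the outcome-labeled patients. Stage errors abort
#' with the stage name and offending sample id; analytic warnings (product
#' mismatch, separation) are collected, never fatal.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{study_report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  atlas <- config$atlas
  if (!is.null(config$study_config)) {
    study <- gen_study(config$study_config, atlas = atlas)
    cohorts <- study$cohorts
    flow <- study$flow
    clinical <- study$clinical
  } else {
    loaded <- .stage("load", "*", read_study(config$input_dir))
    cohorts <- loaded$cohorts
    flow <- loaded$flow
    clinical <- loaded$clinical
  }
  set.seed(config$seed)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  gates <- lapply(names(flow), function(id) {
    .stage("gate", id, gate_sample(
      flow[[id]]$test, flow[[id]]$control, min_fsc = config$min_fsc,
      band_halfwidth = config$band_halfwidth,
      deab_quantile = config$deab_quantile,
      threshold_numerous = config$threshold_numerous))
  })
  names(gates) <- names(flow)

  behaviors <- lapply(names(cohorts), function(id) {
    .stage("behavior", id, behavior_summary(
      cohorts[[id]], atlas = atlas, B = config$bootstrap_reps,
      a0 = config$gamma_prior[1], b0 = config$gamma_prior[2],
      dirichlet_prior = config$dirichlet_prior))
  })
  names(behaviors) <- names(cohorts)

  gate_table <- do.call(rbind, lapply(gates, as.data.frame))
  rownames(gate_table) <- NULL
  tropism_table <- do.call(rbind, lapply(behaviors, function(b) {
    if (is.null(b$tropism)) rep(NA_real_, 10) else b$tropism$prob_mean
  }))

  integration <- withCallingHandlers(
    tryCatch({
      fm <- build_feature_matrix(clinical, gates, behaviors)
      fit <- pls_da(fm, ncomp = config$ncomp)
      list(feature_matrix = fm, fit = fit,
           variable_weights = variable_weights(fit),
           resubstitution_accuracy = mean(predict(fit) == fm$y))
    }, error = function(e) {
      note("integration skipped: %s", conditionMessage(e))
      NULL
    }),
    warning = function(w) {
      note("integration: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  structure(
    list(config = config, gate_results = gates, gate_table = gate_table,
         behavior_summaries = behaviors, tropism_table = tropism_table,
         integration = integration, clinical = clinical,
         warnings = warnings_log,
         manifest = list(seed = config$seed,
                         simulation_seed = if (!is.null(config$study_config))
                           config$study_config$seed,
                         bootstrap_reps = config$bootstrap_reps,
                         input_dir = config$input_dir)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d samples\n", length(x$gate_results)))
  print(x$gate_table)
  cat("\nTropism probabilities (posterior means):\n")
  print(round(x$tropism_table, 3))
  if (!is.null(x$integration)) {
    cat("\n")
    print(x$integration$fit)
    cat(sprintf("  resubstitution accuracy %.1f%%\n",
                100 * x$integration$resubstitution_accuracy))
  }
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Serialize a study report
#'
#' Writes \code{report.json} (gate table, tropism table, behavior scalars,
#' integration weights and explained variance, warnings, manifest) plus tidy
#' CSVs (\code{gates.csv}, \code{tropism.csv}, \code{behavior.csv}) and a
#' manifest with the seeds used and MD5 hashes of any file inputs. Output is
#' deterministic for a fixed configuration.
#'
#' @param report a \code{\link{run_pipeline}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  behavior_tab <- do.call(rbind, lapply(report$behavior_summaries, function(b) {
    data.frame(sample_id = b$sample_id,
               engraftment_pct = b$engraftment_pct,
               survival_mean_1dpi = b$survival_1dpi$mean,
               survival_lo = b$survival_1dpi$hdi95[1],
               survival_hi = b$survival_1dpi$hdi95[2],
               survival_mean_2dpi = b$survival_2dpi$mean,
               mean_ap = if (is.null(b$migration)) NA else b$migration$mean_ap,
               mean_dv = if (is.null(b$migration)) NA else b$migration$mean_dv,
               ellipse_area = if (is.null(b$ellipse)) NA else b$ellipse$area,
               dispersion = if (is.null(b$dispersion)) NA else b$dispersion,
               preferred = paste(b$preferred, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(behavior_tab) <- NULL
  write.csv(report$gate_table, file.path(dir, "gates.csv"), row.names = FALSE)
  write.csv(cbind(sample_id = rownames(report$tropism_table),
                  as.data.frame(report$tropism_table)),
            file.path(dir, "tropism.csv"), row.names = FALSE)
  write.csv(behavior_tab, file.path(dir, "behavior.csv"), row.names = FALSE)
  manifest <- report$manifest
  if (!is.null(manifest$input_dir) && dir.exists(manifest$input_dir)) {
    files <- list.files(manifest$input_dir, full.names = TRUE)
    manifest$input_md5 <- as.list(tools::md5sum(files))
  }
  out <- list(
    gate_table = report$gate_table,
    tropism_table = cbind(sample_id = rownames(report$tropism_table),
                          as.data.frame(report$tropism_table)),
    behavior = behavior_tab,
    integration = if (!is.null(report$integration)) list(
      variable_weights = report$integration$variable_weights,
      explained_y_variance = report$integration$fit$explained_y_variance,
      resubstitution_accuracy = report$integration$resubstitution_accuracy),
    warnings = report$warnings,
    manifest = manifest
  )
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
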