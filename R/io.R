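# Plain-text I/O: foci tables, flow-event tables (CSV with cytometer channel
# names), clinical records, and the published reference tables shipped with
# the package. CSV dialect: UTF-8, comma separator, '.' decimal, header
# required.

.foci_cols <- c("embryo_id", "sample_id", "dpi", "x_um", "y_um")

.default_channel_map <- c(fsc_a = "FSC-A", fsc_h = "FSC-H", ssc_a = "SSC-A",
                          fitc_a = "FITC-A", cd34_a = "PerCP-Cy5.5-A")

.norm_channel <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read and write foci tables
#'
#' Foci CSVs carry one detected fluorescent focus per row with columns
#' \code{embryo_id, sample_id, dpi, x_um, y_um} (extra columns are
#' preserved). Coordinates are micrometre offsets from the injection site.
#' Malformed numeric fields are reported with their file line number.
#'
#' @param path CSV file path.
#' @return \code{read_foci_csv} returns the foci data frame.
#' @export
read_foci_csv <- function(path) {
  if (!file.exists(path)) stop("foci file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(.foci_cols %in% names(df))) {
    stop("foci table must have columns: ", paste(.foci_cols, collapse = ", "))
  }
  for (col in c("dpi", "x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at line %d of %s ('%s')",
                   col, bad[1] + 1L, path, df[[col]][bad[1]]))
    }
    if (anyNA(v) && nrow(df) > 0) {
      stop(sprintf("missing %s at line %d of %s", col,
                   which(is.na(v))[1] + 1L, path))
    }
    df[[col]] <- if (col == "dpi") as.integer(v) else v
  }
  df
}

#' @rdname read_foci_csv
#' @param foci foci data frame to write.
#' @export
write_foci_csv <- function(foci, path) {
  stopifnot(all(.foci_cols %in% names(foci)))
  ord <- c(.foci_cols, setdiff(names(foci), .foci_cols))
  write.csv(foci[, ord, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read and write flow-event tables
#'
#' The CSV fallback for cytometry data: one event per row, columns named by
#' the cytometer channels (default \code{FSC-A, FSC-H, SSC-A, FITC-A,
#' PerCP-Cy5.5-A}). Channel names are matched case-insensitively ignoring
#' punctuation, and the mapping is configurable for other panels.
#'
#' @param path CSV file path.
#' @param tube \code{"DEAB-"} or \code{"DEAB+"}.
#' @param sample_id sample identifier.
#' @param channel_map named character vector mapping canonical channels
#'   (\code{fsc_a, fsc_h, ssc_a, fitc_a, cd34_a}) to file column names.
#' @return \code{read_flow_csv} returns a \code{\link{flow_sample}}.
#' @export
read_flow_csv <- function(path, tube = "DEAB-", sample_id = "",
                          channel_map = NULL) {
  if (!file.exists(path)) stop("flow file not found: ", path)
  if (is.null(channel_map)) channel_map <- .default_channel_map
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  have <- .norm_channel(names(df))
  ev <- list()
  for (canon in names(channel_map)) {
    j <- match(.norm_channel(channel_map[[canon]]), have)
    if (is.na(j)) {
      stop("channel ", channel_map[[canon]], " not found in ", path)
    }
    ev[[canon]] <- as.numeric(df[[j]])
  }
  flow_sample(as.data.frame(ev), tube = tube, sample_id = sample_id)
}

#' @rdname read_flow_csv
#' @param sample \code{\link{flow_sample}} to write.
#' @export
write_flow_csv <- function(sample, path, channel_map = NULL) {
  stopifnot(inherits(sample, "flow_sample"))
  if (is.null(channel_map)) channel_map <- .default_channel_map
  out <- sample$events
  names(out) <- unname(channel_map[names(out)])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write clinical record tables
#'
#' @param path CSV file path with columns \code{sample_id, age_band, subtype,
#'   pct_blasts, platelets_k_ul, leukocytes_k_ul, cytogenetics, risk,
#'   remission}.
#' @return \code{read_clinical_csv} returns the clinical data frame.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_band", "subtype", "pct_blasts",
            "platelets_k_ul", "leukocytes_k_ul", "cytogenetics", "risk",
            "remission")
  if (!all(need %in% names(df))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  df$remission <- tolower(as.character(df$remission))
  df$remission[df$remission %in% c("na", "")] <- NA_character_
  df
}

#' @rdname read_clinical_csv
#' @param clinical clinical data frame to write.
#' @export
write_clinical_csv <- function(clinical, path) {
  write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' Published reference tables of the study cohort
#'
#' \code{lsc_reference} returns the published per-sample gating percentages
#' (ALDH-bright/SSC-low percentage, CD34+ percentage within the gate, the
#' reported combined LSC percentage and the ALDH pattern call) for the six
#' primary samples and two cell lines of the reference cohort.
#' \code{clinical_reference} returns the diagnostic records of the seven
#' patients (age band, subtype, blasts, counts, cytogenetics, risk,
#' remission) plus the reported in-vivo dispersion class.
#'
#' @return data frame.
#' @export
lsc_reference <- function() {
  read.csv(system.file("extdata", "lsc_gating_reference.csv",
                       package = "zfpdx"), stringsAsFactors = FALSE)
}

#' @rdname lsc_reference
#' @export
clinical_reference <- function() {
  path <- system.file("extdata", "clinical_reference.csv", package = "zfpdx")
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$remission[df$remission %in% c("NA", "")] <- NA_character_
  df$dispersion[df$dispersion %in% c("NA", "")] <- NA_character_
  df
}
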