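# Sequential gating chain quantifying the LSC compartment
# (ALDH-bright / SSC-low / CD34+), with the DEAB+ tube defining background
# FITC fluorescence.

.flow_channels <- c("fsc_a", "fsc_h", "ssc_a", "fitc_a", "cd34_a")

#' Flow cytometry sample
#'
#' Container for raw cytometry events of one tube. Channels are stored under
#' canonical names: \code{fsc_a}, \code{fsc_h}, \code{ssc_a}, \code{fitc_a}
#' (ALDH/ALDEFLUOR), \code{cd34_a} (CD34 PerCP-Cy5.5). All channels must be
#' the same length, finite and non-negative.
#'
#' @param events data frame holding the five channels (canonical names).
#' @param tube \code{"DEAB+"} (ALDH-inhibited control) or \code{"DEAB-"}
#'   (test).
#' @param sample_id sample identifier.
#' @return object of class \code{flow_sample}.
#' @export
flow_sample <- function(events, tube = c("DEAB-", "DEAB+"), sample_id = "") {
  tube <- match.arg(tube)
  if (!all(.flow_channels %in% names(events))) {
    stop("events must contain channels: ",
         paste(.flow_channels, collapse = ", "))
  }
  events <- as.data.frame(events)[, .flow_channels]
  if (nrow(events) == 0) stop("flow sample has no events")
  for (ch in .flow_channels) {
    v <- events[[ch]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("channel ", ch, " must be finite, non-negative and complete")
    }
  }
  rownames(events) <- NULL
  structure(list(events = events, tube = tube,
                 sample_id = as.character(sample_id)),
            class = "flow_sample")
}

#' @export
print.flow_sample <- function(x, ...) {
  cat(sprintf("<flow_sample> %s tube %s: %d events\n",
              x$sample_id, x$tube, nrow(x$events)))
  invisible(x)
}

#' Viability gate
#'
#' Removes debris and non-viable events by an FSC-A floor (the package's
#' numeric reduction of the usual FSC-A vs SSC-A polygon gate).
#'
#' @param sample a \code{\link{flow_sample}} or plain event data frame.
#' @param min_fsc FSC-A threshold below which events are discarded
#'   (default 20000 arbitrary units, matched to the generator's scale).
#' @return list with \code{events} (retained subset) and \code{pct_retained}.
#' @export
gate_viable <- function(sample, min_fsc = 20000) {
  ev <- if (inherits(sample, "flow_sample")) sample$events else sample
  if (nrow(ev) == 0) stop("no events to gate")
  keep <- ev$fsc_a >= min_fsc
  if (!any(keep)) {
    stop(sprintf("viability gate at FSC-A >= %g removed every event", min_fsc))
  }
  list(events = ev[keep, , drop = FALSE], pct_retained = 100 * mean(keep))
}

#' Doublet exclusion gate
#'
#' Keeps events whose FSC-H / FSC-A ratio lies within \code{band_halfwidth}
#' of the median ratio of the gated population; doublets sit near half the
#' singlet ratio and are excluded.
#'
#' @param events event data frame after the viability gate.
#' @param band_halfwidth half-width of the accepted ratio band (default 0.15;
#'   \code{Inf} retains everything).
#' @return list with \code{events} and \code{pct_retained}.
#' @export
gate_singlets <- function(events, band_halfwidth = 0.15) {
  if (nrow(events) == 0) stop("no events to gate")
  r <- events$fsc_h / events$fsc_a
  keep <- abs(r - median(r)) <= band_halfwidth
  list(events = events[keep, , drop = FALSE], pct_retained = 100 * mean(keep))
}

#' FITC cutoff from the DEAB+ control tube
#'
#' The ALDH-bright gate is placed at a high quantile of the control tube's
#' FITC distribution after viability and singlet gating; DEAB inhibits ALDH,
#' so the control carries background fluorescence only.
#'
#' @param control a \code{\link{flow_sample}} with \code{tube == "DEAB+"}.
#' @param q control quantile defining the cutoff (default 0.999, i.e. a 0.1
#'   percent false-positive allowance).
#' @param min_fsc,band_halfwidth upstream gate parameters.
#' @return FITC-A cutoff (scalar).
#' @export
aldh_threshold_from_deab <- function(control, q = 0.999, min_fsc = 20000,
                                     band_halfwidth = 0.15) {
  stopifnot(inherits(control, "flow_sample"))
  if (control$tube != "DEAB+") {
    stop("control tube must be DEAB+ (got ", control$tube, ")")
  }
  stopifnot(q > 0, q <= 1)
  v <- gate_viable(control, min_fsc)
  s <- gate_singlets(v$events, band_halfwidth)
  unname(quantile(s$events$fitc_a, q))
}

#' ALDH-bright / SSC-low gate
#'
#' @param events singlet events of the DEAB- test tube.
#' @param fitc_cutoff FITC-A cutoff, normally from
#'   \code{\link{aldh_threshold_from_deab}}.
#' @param ssc_cutoff SSC-A cutoff; default is the median SSC-A of the singlet
#'   events.
#' @return list with \code{events} (gated subset), \code{pct} (percentage of
#'   singlets in the gate) and the cutoffs used.
#' @export
gate_aldh_bright_ssclow <- function(events, fitc_cutoff, ssc_cutoff = NULL) {
  if (nrow(events) == 0) stop("no events to gate")
  if (is.null(ssc_cutoff)) ssc_cutoff <- median(events$ssc_a)
  sel <- events$fitc_a > fitc_cutoff & events$ssc_a < ssc_cutoff
  list(events = events[sel, , drop = FALSE], pct = 100 * mean(sel),
       fitc_cutoff = fitc_cutoff, ssc_cutoff = ssc_cutoff)
}

#' CD34+ fraction within a gate
#'
#' @param events gated events.
#' @param cd34_cutoff intensity above which an event is CD34+; \code{NULL}
#'   (default) estimates the valley of the bimodal CD34 density on the log
#'   scale.
#' @return list with \code{pct} (percentage CD34+; \code{NA} on an empty
#'   gate), \code{undefined} flag and \code{cd34_cutoff}.
#' @export
cd34_fraction <- function(events, cd34_cutoff = NULL) {
  if (nrow(events) == 0) {
    return(list(pct = NA_real_, undefined = TRUE, cd34_cutoff = cd34_cutoff))
  }
  if (is.null(cd34_cutoff)) cd34_cutoff <- .cd34_valley(events$cd34_a)
  list(pct = 100 * mean(events$cd34_a > cd34_cutoff), undefined = FALSE,
       cd34_cutoff = cd34_cutoff)
}

# valley of a bimodal intensity distribution on the log scale; falls back to
# the geometric mid-range when the density has a single mode
.cd34_valley <- function(x) {
  lx <- log(pmax(x, .Machine$double.eps))
  if (length(unique(lx)) < 10) return(exp(mean(range(lx))))
  d <- density(lx)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] > 0.05 * max(y)]
  if (length(peaks) < 2) return(exp(mean(range(lx))))
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- seq(top2[1], top2[2])[which.min(y[top2[1]:top2[2]])]
  exp(d$x[valley])
}

#' Combined LSC percentage
#'
#' The combined ALDH-bright/SSC-low CD34+ percentage is the product of the
#' two sequential gate percentages, reported to two decimals:
#' \code{pct_aldh * pct_cd34_within / 100}.
#'
#' @param pct_aldh ALDH-bright/SSC-low percentage of singlets, in [0, 100].
#' @param pct_cd34_within CD34+ percentage within that gate, in [0, 100].
#' @return combined percentage rounded to 2 decimals.
#' @examples
#' combined_lsc_fraction(25.6, 51.1)  # 13.08
#' @export
combined_lsc_fraction <- function(pct_aldh, pct_cd34_within) {
  if (any(!is.finite(c(pct_aldh, pct_cd34_within))) ||
      any(c(pct_aldh, pct_cd34_within) < 0) ||
      any(c(pct_aldh, pct_cd34_within) > 100)) {
    stop("gate percentages must lie in [0, 100]")
  }
  round(pct_aldh * pct_cd34_within / 100, 2)
}

#' ALDH pattern call
#'
#' A sample is ALDH-numerous when strictly more than \code{threshold} percent
#' of its singlet events fall in the ALDH-bright/SSC-low gate, ALDH-rare
#' otherwise (the boundary itself maps to rare since neither published bound
#' covers equality).
#'
#' @param pct_aldh_bright_ssclow percentage in [0, 100].
#' @param threshold pattern boundary (default 1.9).
#' @return \code{"numerous"} or \code{"rare"}.
#' @examples
#' classify_aldh_pattern(25.6)  # numerous
#' @export
classify_aldh_pattern <- function(pct_aldh_bright_ssclow, threshold = 1.9) {
  stopifnot(is.finite(pct_aldh_bright_ssclow),
            pct_aldh_bright_ssclow >= 0, pct_aldh_bright_ssclow <= 100)
  if (pct_aldh_bright_ssclow > threshold) "numerous" else "rare"
}

#' Run the full gating chain on a paired sample
#'
#' Applies viability and singlet gating to both tubes, places the FITC cutoff
#' from the DEAB+ control, gates ALDH-bright/SSC-low on the test tube,
#' quantifies CD34+ within the gate, and reports the combined LSC percentage
#' and the ALDH pattern call. All reported gate percentages other than
#' viability and singlet retention are percentages of singlet events.
#'
#' @param test \code{\link{flow_sample}} of the DEAB- tube.
#' @param control \code{\link{flow_sample}} of the DEAB+ tube.
#' @param min_fsc,band_halfwidth,deab_quantile,ssc_cutoff,cd34_cutoff gate
#'   parameters (see the individual gate functions).
#' @param threshold_numerous ALDH pattern boundary (default 1.9).
#' @return object of class \code{gate_result}.
#' @export
gate_sample <- function(test, control, min_fsc = 20000, band_halfwidth = 0.15,
                        deab_quantile = 0.999, ssc_cutoff = NULL,
                        cd34_cutoff = NULL, threshold_numerous = 1.9) {
  stopifnot(inherits(test, "flow_sample"))
  if (test$tube != "DEAB-") stop("test tube must be DEAB- (got ", test$tube, ")")
  fitc_cutoff <- aldh_threshold_from_deab(control, q = deab_quantile,
                                          min_fsc = min_fsc,
                                          band_halfwidth = band_halfwidth)
  v <- gate_viable(test, min_fsc)
  s <- gate_singlets(v$events, band_halfwidth)
  g <- gate_aldh_bright_ssclow(s$events, fitc_cutoff, ssc_cutoff)
  c34 <- cd34_fraction(g$events, cd34_cutoff)
  combined <- if (c34$undefined) NA_real_ else
    combined_lsc_fraction(g$pct, c34$pct)
  structure(
    list(sample_id = test$sample_id,
         pct_viable = v$pct_retained,
         pct_singlet = s$pct_retained,
         pct_aldh_bright_ssclow = g$pct,
         pct_cd34_within = c34$pct,
         pct_lsc_combined = combined,
         pattern = classify_aldh_pattern(g$pct, threshold_numerous),
         cd34_undefined = c34$undefined,
         cutoffs = list(min_fsc = min_fsc, band_halfwidth = band_halfwidth,
                        fitc = fitc_cutoff, ssc = g$ssc_cutoff,
                        cd34 = c34$cd34_cutoff,
                        threshold_numerous = threshold_numerous)),
    class = "gate_result"
  )
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> %s\n", x$sample_id))
  cat(sprintf("  viable %.1f%%, singlets %.1f%% of viable\n",
              x$pct_viable, x$pct_singlet))
  cat(sprintf("  ALDH-bright/SSC-low %.2f%% of singlets (%s pattern)\n",
              x$pct_aldh_bright_ssclow, x$pattern))
  if (x$cd34_undefined) {
    cat("  CD34+ within gate: undefined (empty gate)\n")
  } else {
    cat(sprintf("  CD34+ within gate %.1f%%, combined LSC %.2f%%\n",
                x$pct_cd34_within, x$pct_lsc_combined))
  }
  invisible(x)
}

#' @export
as.data.frame.gate_result <- function(x, ...) {
  data.frame(sample_id = x$sample_id, pct_viable = x$pct_viable,
             pct_singlet = x$pct_singlet,
             pct_aldh_bright_ssclow = x$pct_aldh_bright_ssclow,
             pct_cd34_within = x$pct_cd34_within,
             pct_lsc_combined = x$pct_lsc_combined,
             pattern = x$pattern, stringsAsFactors = FALSE)
}

#' Audit the product identity of reported gate percentages
#'
#' Recomputes the combined LSC percentage from the two gate percentages of a
#' reported table and flags rows whose printed combined value disagrees with
#' the product beyond \code{tol}.
#'
#' @param tab data frame with \code{pct_aldh_bright_ssclow},
#'   \code{pct_cd34_within} and \code{pct_lsc_combined_reported}.
#' @param tol absolute tolerance on the 2-decimal product (default 0.005,
#'   i.e. printed-precision agreement).
#' @return \code{tab} with columns \code{pct_lsc_combined_product} and logical
#'   \code{product_mismatch}.
#' @export
audit_product_identity <- function(tab, tol = 0.005) {
  prod2 <- mapply(combined_lsc_fraction, tab$pct_aldh_bright_ssclow,
                  tab$pct_cd34_within)
  tab$pct_lsc_combined_product <- prod2
  tab$product_mismatch <- abs(prod2 - tab$pct_lsc_combined_reported) > tol
  if (any(tab$product_mismatch)) {
    warning("combined LSC %% differs from the gate-percentage product for: ",
            paste(tab$sample_id[tab$product_mismatch], collapse = ", "))
  }
  tab
}
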