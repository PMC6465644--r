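# Integration layer: patient-by-feature matrix and the association tests
# (exact Wilcoxon rank-sum, Yates-corrected chi-square, univariate logistic).

.code_risk <- c("favorable/standard" = 0, favorable = 0, standard = 0,
                intermediate = 1, adverse = 2)
.code_pattern <- c(rare = 0, numerous = 1)
.code_dispersion <- c(random = 0, clumped = 1)

.age_midpoint <- function(band) {
  m <- regmatches(band, gregexpr("[0-9]+", band))
  vapply(m, function(v) mean(as.numeric(v)), numeric(1))
}

#' Build the standardized patient-by-feature matrix
#'
#' Assembles one row per outcome-labeled patient from the three evidence
#' layers: clinical (age band midpoint, blast percentage, platelet and
#' leukocyte counts, risk code), LSC gating (the two gate percentages, their
#' combined product and the ALDH-pattern code) and in-vivo behavior
#' (engraftment percentage, posterior-mean survival, the ten region
#' probabilities, dispersion class code, ellipse area, mean AP and DV
#' migration). Categorical codes: risk favorable/standard=0, intermediate=1,
#' adverse=2; pattern rare=0, numerous=1; dispersion random=0, clumped=1.
#' Patients with unknown remission are dropped; columns are standardized to
#' mean 0 and unit variance, and constant columns are dropped with a warning.
#'
#' @param clinical clinical records data frame (see
#'   \code{\link{gen_clinical_table}}).
#' @param gates named list of \code{\link{gate_sample}} results (names =
#'   sample ids).
#' @param behaviors named list of \code{\link{behavior_summary}} results.
#' @return object of class \code{feature_matrix}: list with standardized
#'   matrix \code{X}, response \code{y} (1 = remission, 0 = no remission),
#'   \code{center}, \code{scale} and \code{dropped} column names.
#' @export
build_feature_matrix <- function(clinical, gates, behaviors) {
  ids <- clinical$sample_id
  orphans <- c(setdiff(ids, names(gates)), setdiff(ids, names(behaviors)))
  extra <- c(setdiff(names(gates), ids), setdiff(names(behaviors), ids))
  if (length(orphans) || length(extra)) {
    stop("sample ids do not align across sources; missing or extra: ",
         paste(unique(c(orphans, extra)), collapse = ", "))
  }
  keep <- !is.na(clinical$remission) & clinical$remission %in% c("yes", "no")
  clinical <- clinical[keep, , drop = FALSE]
  if (nrow(clinical) == 0) stop("no outcome-labeled patients")
  rows <- lapply(clinical$sample_id, function(id) {
    g <- gates[[id]]
    b <- behaviors[[id]]
    cl <- clinical[clinical$sample_id == id, ]
    pm <- if (is.null(b$tropism)) {
      setNames(rep(NA_real_, 10), .atlas_regions)
    } else {
      b$tropism$prob_mean
    }
    c(age_mid = .age_midpoint(cl$age_band),
      pct_blasts = cl$pct_blasts,
      platelets = cl$platelets_k_ul,
      leukocytes = cl$leukocytes_k_ul,
      risk_code = unname(.code_risk[cl$risk]),
      pct_aldh_bright_ssclow = g$pct_aldh_bright_ssclow,
      pct_cd34_within = g$pct_cd34_within,
      pct_lsc_combined = g$pct_lsc_combined,
      pattern_code = unname(.code_pattern[g$pattern]),
      engraftment_pct = b$engraftment_pct,
      survival_mean = b$survival_1dpi$mean,
      setNames(as.numeric(pm), paste0("prob_", names(pm))),
      dispersion_code = if (is.null(b$dispersion)) NA_real_ else
        unname(.code_dispersion[b$dispersion]),
      ellipse_area = if (is.null(b$ellipse)) NA_real_ else b$ellipse$area,
      mean_ap = if (is.null(b$migration)) NA_real_ else b$migration$mean_ap,
      mean_dv = if (is.null(b$migration)) NA_real_ else b$migration$mean_dv)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- clinical$sample_id
  if (anyNA(X)) {
    bad <- rownames(X)[apply(X, 1, anyNA)]
    stop("missing features for: ", paste(bad, collapse = ", "))
  }
  y <- as.integer(clinical$remission == "yes")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  const <- scl < 1e-12
  if (all(const)) stop("all features are constant; nothing to standardize")
  if (any(const)) {
    warning("dropping constant feature columns: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  X <- X[, !const, drop = FALSE]
  ctr <- ctr[!const]
  scl <- scl[!const]
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  structure(list(X = Xs, y = y, center = ctr, scale = scl,
                 dropped = names(const)[const]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d standardized features (%d remission, %d no-remission)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  if (length(x$dropped)) {
    cat("  dropped constant columns:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Enumerates rank assignments of group A among all \code{choose(nA+nB, nA)}
#' arrangements and reports the two-sided p-value by the doubling rule,
#' \code{min(1, 2 * min(P(W <= w), P(W >= w)))} where \code{W} is the group-A
#' rank sum. Ties are handled by midranks with enumeration over
#' distinguishable arrangements (a warning is emitted). For large tie-free
#' samples where enumeration is infeasible the exact null distribution of
#' the Mann-Whitney statistic is used instead.
#'
#' @param a,b numeric observations of the two groups.
#' @param enumeration_limit largest number of arrangements enumerated
#'   directly (default 2e6).
#' @return object of class \code{htest} with the rank-sum statistic and
#'   exact p-value.
#' @examples
#' wilcoxon_exact(c(1, 2), c(3, 4, 5, 6))  # p = 2/15 = 0.1333
#' @export
wilcoxon_exact <- function(a, b, enumeration_limit = 2e6) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ties <- anyDuplicated(c(a, b)) > 0
  if (ties) warning("ties present; using midranks with exact enumeration")
  w <- sum(r[seq_len(na)])
  n_arr <- choose(n, na)
  if (n_arr <= enumeration_limit) {
    sums <- combn(r, na, sum)
    p_low <- mean(sums <= w + 1e-9)
    p_high <- mean(sums >= w - 1e-9)
  } else if (!ties) {
    u <- w - na * (na + 1) / 2
    p_low <- pwilcox(u, na, nb)
    p_high <- 1 - pwilcox(u - 1, na, nb)
  } else {
    stop("too many arrangements to enumerate with ties present")
  }
  p <- min(1, 2 * min(p_low, p_high))
  structure(list(statistic = c(W = w), p.value = p,
                 method = "Exact Wilcoxon rank-sum test (two-sided)",
                 data.name = sprintf("groups of size %d and %d", na, nb),
                 ties = ties),
            class = "htest")
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Continuity-corrected chi-square statistic
#' \code{n * (max(|ad - bc| - n/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))} with the
#' p-value from the chi-square distribution on 1 degree of freedom. The
#' uncorrected statistic is reported alongside. A zero marginal makes the
#' statistic undefined and is flagged rather than returned as 0.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return object of class \code{yates_test}: statistic, p_value, their
#'   uncorrected counterparts, and an \code{undefined} flag.
#' @examples
#' chisq_yates(matrix(c(0, 2, 3, 1), 2))  # statistic 0.75, p = 0.3865
#' @export
chisq_yates <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("table must be a 2x2 matrix of non-negative integer counts")
  }
  n <- sum(tab)
  if (n < 1) stop("table must contain at least one observation")
  marg <- c(rowSums(tab), colSums(tab))
  if (any(marg == 0)) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          statistic_uncorrected = NA_real_,
                          p_uncorrected = NA_real_,
                          undefined = TRUE, table = tab),
                     class = "yates_test"))
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  denom <- prod(marg)
  stat <- n * max(abs(a * d - b * c) - n / 2, 0)^2 / denom
  stat_u <- n * (a * d - b * c)^2 / denom
  structure(list(statistic = stat,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 statistic_uncorrected = stat_u,
                 p_uncorrected = pchisq(stat_u, df = 1, lower.tail = FALSE),
                 undefined = FALSE, table = tab),
            class = "yates_test")
}

#' @export
print.yates_test <- function(x, ...) {
  if (x$undefined) {
    cat("<yates_test> undefined (zero marginal)\n")
  } else {
    cat(sprintf("<yates_test> Yates chi-square = %.4f, p = %.4f (uncorrected %.4f, p = %.4f)\n",
                x$statistic, x$p_value, x$statistic_uncorrected,
                x$p_uncorrected))
  }
  invisible(x)
}

#' Univariate logistic regression of a binary outcome
#'
#' Maximum-likelihood logistic fit (IRLS via \code{stats::glm}) of a binary
#' response on a single predictor, reporting the coefficients, McFadden /
#' Cox-Snell / Nagelkerke pseudo-R-squared and the likelihood-ratio p-value.
#' Quasi-complete separation is detected (fitted probabilities numerically 0
#' or 1 on a perfectly classified fit) and flagged; coefficients are still
#' reported with a warning.
#'
#' @param x numeric predictor.
#' @param y binary response (0/1) containing both classes.
#' @param ... passed to \code{stats::glm}.
#' @return object of class \code{logistic_fit}.
#' @export
logistic_fit <- function(x, y, ...) {
  stopifnot(length(x) == length(y), length(y) >= 3)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial(), control = list(epsilon = 1e-10,
                                                   maxit = 100), ...),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  p_hat <- fitted(fit)
  separated <- sep_warn &&
    all((p_hat > 0.5) == (y == 1) | abs(p_hat - 0.5) < 1e-8)
  ll <- as.numeric(logLik(fit))
  fit0 <- glm(y ~ 1, family = binomial())
  ll0 <- as.numeric(logLik(fit0))
  n <- length(y)
  r2_cs <- 1 - exp(2 * (ll0 - ll) / n)
  out <- structure(
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         r2_mcfadden = 1 - ll / ll0,
         r2_coxsnell = r2_cs,
         r2_nagelkerke = r2_cs / (1 - exp(2 * ll0 / n)),
         p_lr = pchisq(2 * (ll - ll0), df = 1, lower.tail = FALSE),
         separation = separated, converged = fit$converged, n = n),
    class = "logistic_fit")
  if (separated) {
    warning("quasi-complete separation detected; coefficients are unstable")
  }
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d: logit(p) = %.3f + %.3f x\n",
              x$n, x$intercept, x$slope))
  cat(sprintf("  pseudo-R2: McFadden %.3f, Cox-Snell %.3f, Nagelkerke %.3f; LR p = %.4f\n",
              x$r2_mcfadden, x$r2_coxsnell, x$r2_nagelkerke, x$p_lr))
  if (x$separation) cat("  warning: quasi-complete separation\n")
  invisible(x)
}
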