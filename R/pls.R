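#' Partial least squares discriminant analysis (NIPALS PLS1)
#'
#' Fits a univariate-response PLS model by the NIPALS algorithm to a binary
#' class label, the construction underlying PLS-DA: per component the weight
#' vector is \code{w = X'y / ||X'y||}, scores \code{t = Xw}, X-loading
#' \code{p = X't / t't}, y-loading \code{q = y't / t't}, followed by
#' deflation \code{X <- X - t p'} and \code{y <- y - t q}. The explained
#' Y-variance after k components is \code{1 - SS(y_k) / SS(y_0)} on the
#' (centered) working response. Scores of successive components are
#' orthogonal by construction.
#'
#' @param x numeric matrix of predictors (rows = patients), or a
#'   \code{\link{build_feature_matrix}} result (in which case \code{y},
#'   \code{center} and \code{scale} are taken from it).
#' @param y binary response coded 0/1 (1 = successful remission).
#' @param ncomp number of latent components (default 2); must not exceed the
#'   rank of the centered predictor matrix.
#' @param center,scale standardize the columns of \code{x} before fitting
#'   (defaults \code{TRUE}; ignored for a pre-standardized feature matrix).
#' @return object of class \code{pls_da}: weights \code{W}, loadings
#'   \code{P}, y-loadings \code{q}, scores \code{T}, per-component and
#'   cumulative \code{explained_y_variance}, VIP scores, class centroids on
#'   component 1, and the centering/scaling used.
#' @seealso \code{\link{variable_weights}}, \code{\link{predict.pls_da}}
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 6, 10)
#' y <- rep(c(0, 1), each = 3)
#' fit <- pls_da(X, y)
#' fit$explained_y_variance
#' @export
pls_da <- function(x, y = NULL, ncomp = 2, center = TRUE, scale = TRUE) {
  if (inherits(x, "feature_matrix")) {
    fm <- x
    X <- fm$X
    y <- fm$y
    ctr <- fm$center
    scl <- fm$scale
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop("y is required when x is a plain matrix")
    ctr <- if (center) colMeans(X) else rep(0, ncol(X))
    scl <- if (scale) {
      s <- apply(X, 2, sd)
      if (any(s < 1e-12)) stop("constant columns cannot be scaled; drop them first")
      s
    } else rep(1, ncol(X))
    X <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  feat <- colnames(X)
  ybar <- if (center) mean(y) else 0
  yw <- y - ybar
  ss_y0 <- sum(yw^2)
  r <- qr(X)$rank
  if (ncomp > r) {
    stop(sprintf("ncomp = %d exceeds rank(X) = %d", ncomp, r))
  }
  n <- nrow(X); pvar <- ncol(X)
  W <- P <- matrix(0, pvar, ncomp, dimnames = list(feat, NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  q <- tt <- expl <- numeric(ncomp)
  Xd <- X; yd <- yw
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("response residual is orthogonal to X; reduce ncomp")
    w <- w / nw
    t_k <- drop(Xd %*% w)
    tt[k] <- sum(t_k^2)
    p_k <- drop(crossprod(Xd, t_k)) / tt[k]
    q[k] <- sum(yd * t_k) / tt[k]
    Xd <- Xd - tcrossprod(t_k, p_k)
    yd <- yd - t_k * q[k]
    W[, k] <- w
    P[, k] <- p_k
    Tm[, k] <- t_k
    expl[k] <- 1 - sum(yd^2) / ss_y0
  }
  # VIP over the fitted components
  ssq <- q^2 * tt
  vip <- sqrt(pvar * drop(W^2 %*% ssq) / sum(ssq))
  names(vip) <- feat
  centroids <- c(`0` = mean(Tm[y == 0, 1]), `1` = mean(Tm[y == 1, 1]))
  structure(
    list(W = W, P = P, q = q, T = Tm, tt = tt,
         explained_y_variance = expl,
         explained_per_component = diff(c(0, expl)),
         vip = vip, centroids = centroids,
         ncomp = ncomp, y = y, ybar = ybar,
         center = ctr, scale = scl, features = feat,
         call = match.call()),
    class = "pls_da"
  )
}

#' @export
print.pls_da <- function(x, ...) {
  cat(sprintf("<pls_da> NIPALS PLS1, %d component(s), %d patients x %d features\n",
              x$ncomp, nrow(x$T), length(x$features)))
  cat("  cumulative explained Y-variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_y_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.pls_da <- function(object, ...) {
  vw <- variable_weights(object)
  acc <- mean(predict(object) == object$y)
  structure(list(fit = object, variable_weights = vw,
                 resubstitution_accuracy = acc),
            class = "summary.pls_da")
}

#' @export
print.summary.pls_da <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  resubstitution accuracy: %.1f%%\n",
              100 * x$resubstitution_accuracy))
  cat("  top variables by |component-1 weight|:\n")
  print(head(x$variable_weights, 8), row.names = FALSE)
  invisible(x)
}

#' @export
coef.pls_da <- function(object, ...) {
  # regression coefficients on the standardized scale: B = W (P'W)^-1 q
  drop(object$W %*% solve(crossprod(object$P, object$W), object$q))
}

#' Ranked variable weights and VIP scores
#'
#' Features ranked by the magnitude of their component-1 weight; the VIP
#' (variable importance in projection) score for feature j over K components
#' is \code{sqrt(p * sum_k(q_k^2 t_k't_k w_jk^2) / sum_k(q_k^2 t_k't_k))}.
#'
#' @param model a fitted \code{\link{pls_da}} model.
#' @return data frame with columns \code{feature}, \code{w1} (signed
#'   component-1 weight), \code{abs_w1} and \code{vip}, sorted by
#'   \code{abs_w1} descending.
#' @export
variable_weights <- function(model) {
  stopifnot(inherits(model, "pls_da"))
  w1 <- model$W[, 1]
  out <- data.frame(feature = model$features, w1 = unname(w1),
                    abs_w1 = unname(abs(w1)), vip = unname(model$vip),
                    stringsAsFactors = FALSE)
  out[order(out$abs_w1, decreasing = TRUE), , drop = FALSE]
}

#' Predict class, scores or response from a PLS-DA fit
#'
#' Classes are assigned by the nearest class centroid along the component-1
#' scores (component 1 carries the bulk of the outcome discrimination); a
#' score exactly midway between centroids is broken toward class 0.
#'
#' @param object fitted \code{\link{pls_da}}.
#' @param newdata matrix of predictors on the original (unstandardized)
#'   scale; omitted = training data.
#' @param type \code{"class"} (default), \code{"score"} (matrix of component
#'   scores) or \code{"response"} (continuous PLS prediction of y).
#' @param ... unused.
#' @return according to \code{type}.
#' @export
predict.pls_da <- function(object, newdata = NULL, type = c("class", "score",
                                                            "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Tm <- object$T
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object$features)) {
      stop("newdata must have ", length(object$features), " columns")
    }
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
    Tm <- matrix(0, nrow(X), object$ncomp)
    Xd <- X
    for (k in seq_len(object$ncomp)) {
      Tm[, k] <- drop(Xd %*% object$W[, k])
      Xd <- Xd - tcrossprod(Tm[, k], object$P[, k])
    }
  }
  if (type == "score") return(Tm)
  if (type == "response") {
    return(drop(Tm %*% object$q) + object$ybar)
  }
  d0 <- abs(Tm[, 1] - object$centroids["0"])
  d1 <- abs(Tm[, 1] - object$centroids["1"])
  as.integer(d1 < d0)  # ties (d1 == d0) go to class 0
}

#' @export
fitted.pls_da <- function(object, ...) predict(object, type = "response")

#' @export
residuals.pls_da <- function(object, ...) object$y - fitted(object)

#' Score plot of a PLS-DA fit
#'
#' Component-1 vs component-2 scores (or component 1 vs patient index for a
#' one-component fit), colored by observed class.
#'
#' @param x fitted \code{\link{pls_da}}.
#' @param ... passed to \code{plot}.
#' @export
plot.pls_da <- function(x, ...) {
  cls <- factor(x$y, levels = c(0, 1),
                labels = c("no remission", "remission"))
  col <- c("firebrick", "forestgreen")[as.integer(cls)]
  if (x$ncomp >= 2) {
    plot(x$T[, 1], x$T[, 2], col = col, pch = 19,
         xlab = "component 1 score", ylab = "component 2 score", ...)
  } else {
    plot(seq_len(nrow(x$T)), x$T[, 1], col = col, pch = 19,
         xlab = "patient", ylab = "component 1 score", ...)
  }
  abline(v = mean(x$centroids), lty = 2, col = "grey50")
  legend("topleft", legend = levels(cls), col = c("firebrick", "forestgreen"),
         pch = 19, bty = "n")
  invisible(x)
}
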