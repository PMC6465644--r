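test_that("NIPALS recovers an exactly representable response", {
  X <- diag(6)[, 1:4]  # orthonormal columns
  y <- X[, 1]
  fit <- pls_da(X, y, ncomp = 1, center = FALSE, scale = FALSE)
  expect_equal(unname(fit$W[, 1]), c(1, 0, 0, 0))
  expect_equal(fit$explained_y_variance[1], 1)
})

test_that("NIPALS scores are orthogonal and explained variance is monotone", {
  set.seed(83)
  for (i in 1:10) {
    X <- matrix(rnorm(6 * 10), 6, 10)
    y <- rep(c(0, 1), each = 3)
    fit <- pls_da(X, y, ncomp = 3)
    expect_lt(abs(crossprod(fit$T[, 1], fit$T[, 2])), 1e-8)
    expect_lt(abs(crossprod(fit$T[, 2], fit$T[, 3])), 1e-8)
    expect_true(all(diff(fit$explained_y_variance) >= -1e-12))
    expect_lte(fit$explained_y_variance[3], 1 + 1e-12)
  }
})

test_that("NIPALS matches the SVD-deflation oracle on random matrices", {
  set.seed(89)
  for (i in 1:25) {
    n <- sample(6:12, 1); p <- sample(4:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y <- rep(c(0, 1), length.out = n)
    fit <- pls_da(X, y, ncomp = 2, center = TRUE, scale = FALSE)
    ora <- svd_pls1_oracle(X, y, ncomp = 2)
    for (k in 1:2) {
      s <- sign(sum(fit$W[, k] * ora$W[, k]))
      expect_lt(max(abs(fit$W[, k] - s * ora$W[, k])), 1e-6)
      expect_lt(max(abs(fit$T[, k] - s * ora$T[, k])), 1e-6)
      expect_lt(abs(fit$q[k] - s * ora$q[k]), 1e-6)
    }
  }
})

test_that("NIPALS agrees with the mixOmics PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(97)
  X <- matrix(rnorm(8 * 6), 8, 6)
  y <- rep(c(0, 1), 4)
  fit <- pls_da(X, y, ncomp = 2)
  mo <- mixOmics::pls(X, y, ncomp = 2, mode = "regression", scale = TRUE)
  for (k in 1:2) {
    w_mo <- mo$loadings$X[, k]
    s <- sign(sum(fit$W[, k] * w_mo))
    expect_lt(max(abs(fit$W[, k] - s * w_mo)), 1e-6)
    expect_lt(max(abs(fit$T[, k] - s * mo$variates$X[, k])), 1e-5)
  }
})

test_that("duplicate features receive equal weights; rank bound is enforced", {
  set.seed(101)
  X <- matrix(rnorm(8 * 3), 8, 3)
  Xd <- cbind(X, X[, 1])
  y <- rep(c(0, 1), 4)
  fit <- pls_da(Xd, y, ncomp = 2)
  expect_lt(abs(abs(fit$W[1, 1]) - abs(fit$W[4, 1])), 1e-8)
  expect_error(pls_da(Xd, y, ncomp = 4), "rank")
})

test_that("explained Y-variance reaches 1 when y lies in the column span", {
  set.seed(103)
  X <- matrix(rnorm(10 * 10), 10, 10)
  y <- rep(c(0, 1), 5)
  fit <- pls_da(X, y, ncomp = 9, center = TRUE, scale = FALSE)
  expect_equal(fit$explained_y_variance[9], 1, tolerance = 1e-8)
})

test_that("prediction is nearest-centroid on component 1 with ties to class 0", {
  set.seed(107)
  X <- rbind(matrix(rnorm(40, -3), 8, 5), matrix(rnorm(40, 3), 8, 5))
  y <- rep(c(0, 1), each = 8)
  fit <- pls_da(X, y)
  expect_equal(mean(predict(fit) == y), 1)  # separable by construction
  # antisymmetric design: centroids are exact mirror images, so a row at the
  # predictor center scores exactly midway -- the tie must go to class 0
  X1 <- matrix(rnorm(40), 8, 5)
  fit_sym <- pls_da(rbind(X1, -X1), rep(c(0, 1), each = 8))
  expect_equal(mean(fit_sym$centroids), 0)
  expect_equal(predict(fit_sym, matrix(0, 1, 5)), 0L)
})

test_that("accuracy against permuted labels is at chance", {
  set.seed(109)
  accs <- replicate(100, {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rep(c(0, 1), 10)
    fit <- pls_da(X, y, ncomp = 1)
    mean(predict(fit) == sample(y))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("an informative feature dominates the component-1 ranking", {
  set.seed(113)
  hits <- replicate(200, {
    y <- rep(c(0, 1), each = 15)
    X <- matrix(rnorm(30 * 8), 30, 8)
    X[, 3] <- X[, 3] + 3 * y  # 3-SD class shift on one feature
    fit <- pls_da(X, y, ncomp = 1)
    variable_weights(fit)$feature[1] == "x3"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("null VIP scores rarely exceed 2 for any given feature", {
  set.seed(127)
  p <- 10
  vips <- replicate(150, {
    X <- matrix(rnorm(20 * p), 20, p)
    y <- rep(c(0, 1), 10)
    pls_da(X, y, ncomp = 2)$vip
  })
  per_feature_rate <- rowMeans(vips > 2)
  expect_true(all(per_feature_rate <= 0.10))
})

test_that("model methods are coherent: coef, fitted, residuals, summary", {
  set.seed(131)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- rep(c(0, 1), 6)
  fit <- pls_da(X, y)
  expect_length(coef(fit), 5)
  expect_equal(fitted(fit) + residuals(fit), y)
  # regression coefficients reproduce the fitted response
  Xs <- scale(X)
  expect_equal(drop(Xs %*% coef(fit)) + fit$ybar, fitted(fit),
               tolerance = 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.pls_da")
  expect_true(is.numeric(s$resubstitution_accuracy))
})
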