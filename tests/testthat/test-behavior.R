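test_that("engraftment efficiency is simple arithmetic with guarded input", {
  emb <- data.frame(n_foci_1dpi = c(rep(2, 21), rep(0, 3)))
  expect_equal(engraftment_efficiency(emb), 87.5)
  expect_equal(engraftment_efficiency(data.frame(n_foci_1dpi = rep(0, 24))), 0)
  expect_error(engraftment_efficiency(emb, n_injected = 0), "positive")
})

test_that("survival posterior follows the conjugate Gamma-Poisson update", {
  s <- survival_posterior(c(5, 5, 5, 5))
  expect_equal(s$shape, 21)
  expect_equal(s$rate, 5)
  expect_equal(s$mean, 4.2)
  z <- survival_posterior(rep(0, 4))
  expect_equal(z$shape, 1)
  expect_equal(z$rate, 5)
  expect_equal(unname(z$hdi95[1]), 0)  # mode at zero
  expect_error(survival_posterior(integer(0)), "non-empty")
  expect_error(survival_posterior(c(1, -2)), "non-negative")
})

test_that("HDI comparison of survival posteriors is symmetric", {
  set.seed(3)
  for (i in 1:20) {
    a <- survival_posterior(rpois(6, 5))$hdi95
    b <- survival_posterior(rpois(6, sample(c(2, 5, 15), 1)))$hdi95
    expect_equal(compare_hdi(a, b), compare_hdi(b, a))
  }
})

test_that("mean migration distances are exact in degenerate configurations", {
  one <- mean_migration(data.frame(x_um = 0, y_um = 0), B = 0)
  expect_equal(c(one$mean_ap, one$mean_dv), c(0, 0))
  sym <- mean_migration(data.frame(x_um = c(-3, 3), y_um = c(0, 0)), B = 0)
  expect_equal(c(sym$mean_ap, sym$mean_dv), c(3, 0))
})

test_that("migration bootstrap CIs reach nominal coverage", {
  set.seed(19)
  true_mean <- sqrt(2 / pi) * 100  # E|X| for X ~ N(0, 100)
  hits <- replicate(300, {
    f <- data.frame(x_um = rnorm(50, 0, 100), y_um = rnorm(50, 0, 100))
    ci <- mean_migration(f, B = 399)$ci_ap
    ci[1] <= true_mean && true_mean <= ci[2]
  })
  expect_gt(mean(hits), 0.88)
  expect_lt(mean(hits), 0.99)
})

test_that("deviational ellipse recovers symmetric and collinear geometry", {
  circ <- deviational_ellipse(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1)))
  expect_equal(circ$center, c(x = 0, y = 0))
  expect_equal(circ$semi_major, circ$semi_minor)
  line <- deviational_ellipse(cbind(c(-2, -1, 0, 1, 2), rep(0, 5)))
  expect_equal(line$theta, 0)
  expect_equal(line$semi_minor, 0)
  expect_error(deviational_ellipse(cbind(1, 1)), "at least 2")
})

test_that("ellipse is equivariant under rotation and rigid motions", {
  set.seed(23)
  xy <- cbind(rnorm(40, sd = 3), rnorm(40))
  e0 <- deviational_ellipse(xy)
  e30 <- deviational_ellipse(rotate_xy(xy, pi / 6))
  expect_equal((e0$theta + pi / 6) %% pi, e30$theta, tolerance = 1e-8)
  expect_equal(e0$semi_major, e30$semi_major, tolerance = 1e-8)
  expect_equal(e0$semi_minor, e30$semi_minor, tolerance = 1e-8)
  for (i in 1:10) {
    ang <- runif(1, 0, 2 * pi)
    shift <- matrix(runif(2, -50, 50), nrow(xy), 2, byrow = TRUE)
    et <- deviational_ellipse(rotate_xy(xy, ang) + shift)
    expect_equal(et$area, e0$area, tolerance = 1e-8)
  }
})

test_that("ellipse bootstrap is deterministic under a seed and degenerates cleanly", {
  pts <- cbind(rep(1.5, 8), rep(-2, 8))
  ci <- bootstrap_ellipse(pts, B = 99)
  for (nm in names(ci$ci)) expect_equal(diff(ci$ci[[nm]]), 0)
  set.seed(31)
  xy <- cbind(rnorm(30), rnorm(30))
  set.seed(5); c1 <- bootstrap_ellipse(xy, B = 199)
  set.seed(5); c2 <- bootstrap_ellipse(xy, B = 199)
  expect_equal(c1, c2)
})

test_that("semi-major bootstrap CI coverage is near nominal", {
  set.seed(37)
  # population semi-major axis for isotropic N(0, sigma^2 I) is sigma*sqrt(2)
  sigma <- 40
  true_a <- sigma * sqrt(2)
  hits <- replicate(200, {
    xy <- cbind(rnorm(40, 0, sigma), rnorm(40, 0, sigma))
    ci <- bootstrap_ellipse(xy, B = 299)$ci$semi_major
    ci[1] <= true_a && true_a <= ci[2]
  })
  expect_gt(mean(hits), 0.85)
})

test_that("dispersion comparison separates distant clusters, not identical sets", {
  set.seed(41)
  xy <- cbind(rnorm(50, 0, 30), rnorm(50, 0, 30))
  expect_equal(compare_dispersion(xy, xy, B = 199), "not-different")
  far <- cbind(rnorm(50, 1000, 30), rnorm(50, 0, 30))
  expect_equal(compare_dispersion(xy, far, B = 199), "different")
  expect_equal(compare_dispersion(xy, far, B = 199, method = "permutation"),
               "different")
})

test_that("dispersion comparison rarely separates draws of one distribution", {
  set.seed(43)
  same <- replicate(100, {
    a <- cbind(rnorm(40, 0, 50), rnorm(40, 0, 50))
    b <- cbind(rnorm(40, 0, 50), rnorm(40, 0, 50))
    compare_dispersion(a, b, B = 199) == "not-different"
  })
  expect_gte(mean(same), 0.9)
})

test_that("behavior summary integrates all per-sample quantities", {
  set.seed(47)
  p <- sample_profile("S1", "AML", engraft_prob = 0.9, foci_mean = 25)
  cfg <- study_config(p, seed = 47)
  co <- gen_embryo_cohort(p, cfg)
  b <- behavior_summary(co, B = 99)
  expect_s3_class(b, "behavior_summary")
  expect_true(b$engraftment_pct > 50)
  expect_s3_class(b$survival_1dpi, "survival_summary")
  expect_s3_class(b$survival_2dpi, "survival_summary")
  expect_true(b$survival_2dpi$hdi95[1] <= b$survival_2dpi$mean)
  expect_s3_class(b$ellipse, "deviational_ellipse")
  expect_s3_class(b$tropism, "tropism_profile")
  expect_true(b$dispersion %in% c("random", "clumped"))
})
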