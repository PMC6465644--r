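test_that("exact Wilcoxon reproduces hand-enumerable configurations", {
  # group of 2 entirely below a group of 4: 2/15 two-sided
  r <- wilcoxon_exact(c(62, 65), c(70, 74, 78, 81))
  expect_equal(r$p.value, 2 / 15, tolerance = 1e-12)
  expect_equal(round(r$p.value, 4), 0.1333)
  expect_equal(wilcoxon_exact(c(1, 2), c(3, 4))$p.value, 1 / 3)
  # interleaved groups: doubling rule caps at 1
  expect_equal(wilcoxon_exact(c(1, 4), c(2, 3))$p.value, 1)
  expect_error(wilcoxon_exact(numeric(0), 1:3), "non-empty")
})

test_that("exact Wilcoxon equals enumeration and wilcox.test for all n <= 10", {
  set.seed(59)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      for (rep in 1:2) {
        x <- sample(100, na + nb)  # distinct values, no ties
        a <- x[seq_len(na)]; b <- x[-seq_len(na)]
        p <- wilcoxon_exact(a, b)$p.value
        expect_equal(p, enum_wilcoxon_oracle(a, b), tolerance = 1e-12)
        expect_equal(p, wilcox.test(a, b, exact = TRUE)$p.value,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("exact Wilcoxon handles ties by midranks and large n by pwilcox", {
  expect_warning(p_tie <- wilcoxon_exact(c(1, 2, 2), c(2, 3, 4))$p.value,
                 "ties")
  expect_true(p_tie > 0 && p_tie <= 1)
  set.seed(61)
  a <- rnorm(30); b <- rnorm(30, 1)
  p_big <- wilcoxon_exact(a, b)$p.value  # falls back to the exact pwilcox path
  expect_equal(p_big, wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Yates chi-square matches the closed form and stats::chisq.test", {
  r <- chisq_yates(matrix(c(0, 2, 3, 1), 2))
  expect_equal(r$statistic, 0.75)
  expect_equal(round(r$p_value, 4), 0.3865)
  flat <- chisq_yates(matrix(5, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # continuity term floored at zero when |ad - bc| < n/2
  small <- chisq_yates(matrix(c(3, 2, 2, 3), 2))
  expect_equal(small$statistic, 0)
  # zero marginal is undefined, not zero
  undef <- chisq_yates(matrix(c(0, 0, 3, 4), 2))
  expect_true(undef$undefined)
  set.seed(67)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    mine <- chisq_yates(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    ref_u <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic_uncorrected, unname(ref_u$statistic),
                 tolerance = 1e-12)
  }
})

test_that("logistic fit matches an independent Newton solver", {
  set.seed(71)
  for (i in 1:5) {
    x <- rnorm(50)
    y <- rbinom(50, 1, plogis(0.5 + 0.8 * x))
    fit <- logistic_fit(x, y)
    want <- newton_logistic_oracle(x, y)
    expect_equal(fit$intercept, unname(want["intercept"]), tolerance = 1e-6)
    expect_equal(fit$slope, unname(want["slope"]), tolerance = 1e-6)
  }
})

test_that("logistic fit flags no-signal and separated data appropriately", {
  set.seed(73)
  x <- rnorm(200)
  y <- rbinom(200, 1, 0.5)
  fit <- logistic_fit(x, y)
  expect_lt(abs(fit$slope), 0.3)
  expect_lt(fit$r2_mcfadden, 0.02)
  expect_gt(fit$p_lr, 0.05)
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_warning(sep <- logistic_fit(xs, ys), "separation")
  expect_true(sep$separation)
})

test_that("feature matrix drops unlabeled patients and validates alignment", {
  study <- make_small_study(seed = 79)
  an <- suppressWarnings(analyse_study(study))
  fm <- suppressWarnings(
    build_feature_matrix(an$clinical, an$gates, an$behaviors))
  expect_equal(nrow(fm$X), 6)  # the remission-NA patient is excluded
  expect_false("LPZ10" %in% rownames(fm$X))
  expect_equal(unname(colMeans(fm$X)), rep(0, ncol(fm$X)), tolerance = 1e-10)
  expect_equal(unname(apply(fm$X, 2, sd)), rep(1, ncol(fm$X)),
               tolerance = 1e-10)
  # orphan ids are reported by name
  expect_error(build_feature_matrix(an$clinical, an$gates[-1], an$behaviors),
               "LPZ6")
})

test_that("an all-constant feature matrix is rejected", {
  clin <- clinical_reference()[c(1, 4), ]
  gate_stub <- list(sample_id = "x", pct_aldh_bright_ssclow = 10,
                    pct_cd34_within = 50, pct_lsc_combined = 5,
                    pattern = "numerous")
  beh_stub <- list(engraftment_pct = 80,
                   survival_1dpi = list(mean = 10),
                   tropism = list(prob_mean = setNames(rep(0.1, 10),
                                                       region_atlas()$region)),
                   dispersion = "clumped",
                   ellipse = list(area = 100),
                   migration = list(mean_ap = 5, mean_dv = 5))
  clin$age_band <- "40-45"; clin$pct_blasts <- 10
  clin$platelets_k_ul <- 50; clin$leukocytes_k_ul <- 10
  clin$risk <- "adverse"
  gates <- setNames(list(gate_stub, gate_stub), clin$sample_id)
  behs <- setNames(list(beh_stub, beh_stub), clin$sample_id)
  expect_error(suppressWarnings(build_feature_matrix(clin, gates, behs)),
               "constant")
})
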