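test_that("degenerate cohort parameters behave exactly", {
  p1 <- sample_profile("A", "AML", engraft_prob = 1, foci_mean = 0)
  cfg <- study_config(p1, seed = 3)
  set.seed(3)
  co <- gen_embryo_cohort(p1, cfg)
  expect_true(all(co$embryos$engrafted))
  expect_true(all(co$embryos$n_foci_1dpi == 0))
  expect_equal(engraftment_efficiency(co), 0)

  p0 <- sample_profile("B", "AML", engraft_prob = 0, foci_mean = 10)
  co0 <- gen_embryo_cohort(p0, cfg)
  expect_equal(engraftment_efficiency(co0), 0)
})

test_that("engraftment fraction recovers the generative probability", {
  p <- sample_profile("A", "AML", engraft_prob = 0.9, foci_mean = 10)
  cfg <- study_config(p, n_embryos_per_sample = 500, n_embryos_scored = 6,
                      seed = 5)
  set.seed(5)
  co <- gen_embryo_cohort(p, cfg)
  obs <- engraftment_efficiency(co) / 100
  expect_lt(abs(obs - 0.9), 3 * sqrt(0.9 * 0.1 / 500))
})

test_that("non-normalized tropism weights are rejected with the sum named", {
  expect_error(sample_profile("A", "AML", tropism_weights = rep(0.2, 10)),
               "sum to 1.*2")
  p <- sample_profile("A", "AML")
  p$tropism_weights[1] <- p$tropism_weights[1] + 0.5
  expect_error(gen_embryo_cohort(p, study_config(sample_profile("B", "AML"))),
               "sum to 1")
})

test_that("foci moments recover the generative mean over replicate cohorts", {
  set.seed(17)
  p <- sample_profile("A", "AML", engraft_prob = 0.8, foci_mean = 5)
  cfg <- study_config(p, seed = 17)
  means <- replicate(200, {
    co <- gen_embryo_cohort(p, cfg)
    eng <- co$embryos$engrafted
    mean(co$embryos$n_foci_1dpi[eng])
  })
  # Poisson(5) over ~19 engrafted embryos per cohort, 200 cohorts
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 5), 3 * se)
})

test_that("empirical region frequencies converge to the tropism weights", {
  set.seed(29)
  p <- sample_profile("A", "AML", engraft_prob = 1, foci_mean = 450)
  cfg <- study_config(p, n_embryos_per_sample = 24, n_embryos_scored = 24)
  co <- gen_embryo_cohort(p, cfg)
  f1 <- co$foci[co$foci$dpi == 1, ]
  expect_gt(nrow(f1), 10000)
  freq <- table(factor(f1$region_true, levels = names(p$tropism_weights)))
  tv <- sum(abs(freq / sum(freq) - p$tropism_weights)) / 2
  expect_lt(tv, 0.02)
})

test_that("DEAB tubes are indistinguishable when no bright population exists", {
  set.seed(41)
  p <- sample_profile("A", "AML", aldh_bright_frac = 0)
  cfg <- study_config(p, n_flow_events = 10000)
  fp <- gen_flow_events(p, cfg)
  ks <- suppressWarnings(
    ks.test(fp$test$events$fitc_a, fp$control$events$fitc_a))
  expect_gt(ks$p.value, 0.01)
})

test_that("all gated events are CD34+ when the generative fraction is 1", {
  set.seed(43)
  p <- sample_profile("A", "AML", aldh_bright_frac = 0.2, cd34_frac_within = 1)
  cfg <- study_config(p, n_flow_events = 20000)
  fp <- gen_flow_events(p, cfg)
  g <- gate_sample(fp$test, fp$control)
  # the 0.999-quantile bright gate admits ~0.1% background singlets and the
  # CD34+ intensity component has its own extreme lower tail, so the measured
  # fraction sits within a fraction of a point of 100
  expect_gte(g$pct_cd34_within, 99.5)
})

test_that("too few flow events triggers an instability warning", {
  p <- sample_profile("A", "AML")
  cfg <- study_config(p, n_flow_events = 500)
  set.seed(1)
  expect_warning(gen_flow_events(p, cfg), "unstable")
})

test_that("clinical table generation mirrors the reference cohort", {
  profs <- reference_profiles()
  tab <- gen_clinical_table(profs)
  expect_equal(nrow(tab), 7)
  expect_equal(sum(tab$remission == "yes", na.rm = TRUE), 2)
  expect_equal(sum(tab$remission == "no", na.rm = TRUE), 4)
  expect_equal(sum(is.na(tab$remission)), 1)
  expect_equal(nrow(gen_clinical_table(list())), 0)
  expect_error(gen_clinical_table(c(profs, profs[1])), "duplicate")
})

test_that("a fixed seed makes the study byte-identical; seeds differ otherwise", {
  profs <- reference_profiles()[1:2]
  cfg <- study_config(profs, n_flow_events = 2000, seed = 99)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_study(gen_study(cfg), d1)
  write_study(gen_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  cfg2 <- study_config(profs, n_flow_events = 2000, seed = 100)
  s3 <- gen_study(cfg2)
  s1 <- gen_study(cfg)
  expect_false(identical(s1$cohorts[[1]]$foci, s3$cohorts[[1]]$foci))
})
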