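make_events <- function(n, fsc = 60000, fitc = 100, ssc = 30000, cd34 = 50) {
  data.frame(fsc_a = rep(fsc, n), fsc_h = rep(fsc, n), ssc_a = rep(ssc, n),
             fitc_a = rep(fitc, n), cd34_a = rep(cd34, n))
}

test_that("viability gate removes debris and errors when empty", {
  set.seed(7)
  p <- sample_profile("A", "AML")
  cfg <- study_config(p, n_flow_events = 50000)
  fp <- gen_flow_events(p, cfg)
  v <- gate_viable(fp$test)
  expect_lt(abs(v$pct_retained - 95), 1)  # 5% debris injected by default
  all_above <- gate_viable(flow_sample(make_events(100), "DEAB-"))
  expect_equal(all_above$pct_retained, 100)
  expect_error(gate_viable(fp$test, min_fsc = max(fp$test$events$fsc_a) + 1),
               "removed every event")
})

test_that("singlet gate excludes the injected doublet fraction", {
  set.seed(7)
  p <- sample_profile("A", "AML")
  fp0 <- gen_flow_events(p, study_config(p, n_flow_events = 30000,
                                         doublet_frac = 0))
  v0 <- gate_viable(fp0$test)
  expect_gte(gate_singlets(v0$events)$pct_retained, 99)
  fp2 <- gen_flow_events(p, study_config(p, n_flow_events = 30000,
                                         doublet_frac = 0.02))
  v2 <- gate_viable(fp2$test)
  s2 <- gate_singlets(v2$events)
  expect_lt(abs(s2$pct_retained - 98), 0.5)
  expect_equal(gate_singlets(v2$events, Inf)$pct_retained, 100)
})

test_that("DEAB threshold is the control quantile, matching closed forms", {
  set.seed(9)
  ev <- make_events(100000)
  ev$fitc_a <- runif(nrow(ev))
  ctrl <- flow_sample(ev, tube = "DEAB+")
  expect_equal(aldh_threshold_from_deab(ctrl), 0.999, tolerance = 1e-3)
  expect_equal(aldh_threshold_from_deab(ctrl, q = 1), max(ev$fitc_a))
  # log-normal background: cutoff matches the analytic quantile
  ev$fitc_a <- rlnorm(nrow(ev), log(100), 0.5)
  ctrl2 <- flow_sample(ev, tube = "DEAB+")
  expect_equal(aldh_threshold_from_deab(ctrl2),
               qlnorm(0.999, log(100), 0.5), tolerance = 0.08)
  expect_error(aldh_threshold_from_deab(flow_sample(ev, tube = "DEAB-")),
               "DEAB\\+")
})

test_that("ALDH-bright gate bounds false positives and saturates correctly", {
  set.seed(11)
  p0 <- sample_profile("A", "AML", aldh_bright_frac = 0)
  fp <- gen_flow_events(p0, study_config(p0, n_flow_events = 50000))
  g <- gate_sample(fp$test, fp$control)
  expect_lte(g$pct_aldh_bright_ssclow, 0.2)  # q = 0.999 false-positive bound
  ev <- make_events(1000, fitc = 1e5, ssc = 10)
  bright <- gate_aldh_bright_ssclow(ev, fitc_cutoff = 500, ssc_cutoff = 100)
  expect_equal(bright$pct, 100)
})

test_that("gating recovers generative fractions at moderate event counts", {
  set.seed(13)
  p <- sample_profile("A", "AML", aldh_bright_frac = 0.256,
                      cd34_frac_within = 0.511)
  fp <- gen_flow_events(p, study_config(p, n_flow_events = 30000))
  g <- gate_sample(fp$test, fp$control)
  expect_lt(abs(g$pct_aldh_bright_ssclow - 25.6), 1.5)
  expect_lt(abs(g$pct_cd34_within - 51.1), 2)
})

test_that("CD34 fraction flags an empty gate as undefined, not zero", {
  r <- cd34_fraction(make_events(0))
  expect_true(r$undefined)
  expect_true(is.na(r$pct))
  full <- cd34_fraction(make_events(50, cd34 = 1e4), cd34_cutoff = 100)
  expect_equal(full$pct, 100)
})

test_that("combined LSC percentage is the two-decimal product identity", {
  expect_equal(combined_lsc_fraction(25.6, 51.1), 13.08)
  expect_equal(combined_lsc_fraction(1.74, 68), 1.18)
  expect_equal(combined_lsc_fraction(0, 77.3), 0)
  expect_error(combined_lsc_fraction(101, 10), "0, 100")
  expect_error(combined_lsc_fraction(10, -1), "0, 100")
})

test_that("ALDH pattern call uses the strict 1.9 boundary", {
  expect_equal(classify_aldh_pattern(25.6), "numerous")
  expect_equal(classify_aldh_pattern(1.58), "rare")
  expect_equal(classify_aldh_pattern(1.9), "rare")  # boundary maps to rare
  expect_equal(classify_aldh_pattern(1.9000001), "numerous")
})

test_that("each successive gate is a subset of its predecessor", {
  set.seed(15)
  p <- sample_profile("A", "AML", aldh_bright_frac = 0.2)
  fp <- gen_flow_events(p, study_config(p, n_flow_events = 20000))
  v <- gate_viable(fp$test)
  s <- gate_singlets(v$events)
  cut <- aldh_threshold_from_deab(fp$control)
  g <- gate_aldh_bright_ssclow(s$events, cut)
  expect_lte(nrow(v$events), nrow(fp$test$events))
  expect_lte(nrow(s$events), nrow(v$events))
  expect_lte(nrow(g$events), nrow(s$events))
  key <- function(d) do.call(paste, d)
  expect_true(all(key(v$events) %in% key(fp$test$events)))
  expect_true(all(key(s$events) %in% key(v$events)))
  expect_true(all(key(g$events) %in% key(s$events)))
})

test_that("the product-identity audit flags inconsistent reported rows", {
  ref <- lsc_reference()
  expect_warning(audited <- audit_product_identity(ref), "LPZ21")
  expect_true(audited$product_mismatch[audited$sample_id == "LPZ21"])
  expect_false(any(audited$product_mismatch[audited$sample_id != "LPZ21"]))
})
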