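test_that("kernel sum: centered shot gives rate * time, distant reference gives 0", {
  lib <- flat_library()
  plan <- single_shot_plan(pos = c(0, 30, 0), time_s = 120)
  res <- dose_ref_no_volume(plan, c(0, 30, 0), lib)
  expect_equal(res$dose_no_volume, 2, tolerance = 1e-12)
  expect_equal(sum(res$contributions), res$dose_no_volume)
  # reference far outside every kernel
  far <- dose_ref_no_volume(plan, c(0, 30, 45), lib)
  expect_equal(far$dose_no_volume, 0)
})

test_that("kernel sum equals an independent per-point re-summation", {
  lib <- test_library()
  set.seed(21)
  cup <- cup_geometry("medium", 5)
  n <- 10
  cps <- control_points(runif(n, -10, 10), runif(n, 30, 50), runif(n, -10, 10),
                        sample(c(15, 25), n, TRUE), runif(n, 10, 120))
  plan <- gp_plan("ten", cup, cps)
  ref <- c(2, 40, -1)
  res <- dose_ref_no_volume(plan, ref, lib)

  jig <- to_jig_coordinates(ref)
  acc <- 0
  for (i in seq_len(n)) {
    r_i <- sqrt(cps$x_mm[i]^2 + cps$z_mm[i]^2)
    acc <- acc + dose_rate_lookup(lib, cps$collimator_mm[i], cup, cps$y_mm[i], r_i) *
      (cps$time_s[i] / 60) *
      ocr_lookup(lib, cps$collimator_mm[i], cup,
                 cps$y_mm[i] - jig[["y"]], r_i - jig[["r"]])
  }
  expect_equal(res$dose_no_volume, acc, tolerance = 1e-12)
  expect_true(all(res$contributions >= 0))
})

test_that("Vf evaluation: identity, preset coefficients, and endpoints", {
  expect_equal(vf_eval(vf_identity(), 123), 1)
  expect_equal(vf_eval(vf_preset(), 66.9), 4.5732)
  expect_equal(vf_eval(vf_preset(), 0), 2.7)
})

test_that("volume correction conventions apply as documented", {
  lib <- flat_library()
  plan <- single_shot_plan(pos = c(0, 30, 0), time_s = 120)
  base <- dose_ref(plan, c(0, 30, 0), lib, vf_identity())
  expect_equal(base$dose_corrected, base$dose_no_volume)

  m <- vf_model(0, 1.02)
  mult <- dose_ref(plan, c(0, 30, 0), lib, m, convention = "multiplier")
  expect_equal(mult$dose_corrected, mult$dose_no_volume * 1.02)
  pct <- dose_ref(plan, c(0, 30, 0), lib, m, convention = "percent_offset")
  expect_equal(pct$dose_corrected, pct$dose_no_volume * (1 + 1.02 / 100))
  div <- dose_ref(plan, c(0, 30, 0), lib, m, convention = "divisor")
  expect_equal(div$dose_corrected, div$dose_no_volume / 1.02)

  # non-identity model demands a target volume
  bare <- gp_plan("bare", plan$cup, plan$control_points)
  expect_error(dose_ref(bare, c(0, 30, 0), lib, m), "target volume")
})

test_that("dwell-time scaling scales both uncorrected and corrected doses", {
  lib <- test_library()
  plan <- generate_synthetic_plan(seed = 31)
  ref <- plan_target(plan, "GTV")$centroid_mm
  k <- 2.5
  scaled <- plan
  scaled$control_points$time_s <- scaled$control_points$time_s * k
  m <- vf_model(0.001, 1.05)
  r1 <- dose_ref(plan, ref, lib, m)
  r2 <- dose_ref(scaled, ref, lib, m)
  expect_equal(r2$dose_no_volume, k * r1$dose_no_volume, tolerance = 1e-12)
  expect_equal(r2$dose_corrected, k * r1$dose_corrected, tolerance = 1e-12)
})

test_that("Vf calibration recovers exact and degenerate inputs", {
  v <- c(5, 20, 40, 80, 120)
  m <- calibrate_vf(v, 0.028 * v + 2.7)
  expect_equal(m$slope, 0.028, tolerance = 1e-9)
  expect_equal(m$intercept, 2.7, tolerance = 1e-9)
  expect_equal(m$provenance, "calibrated")

  flat <- calibrate_vf(v, rep(1, 5))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 1, tolerance = 1e-12)

  expect_error(calibrate_vf(c(10, 10, 10), c(1, 1.1, 0.9)), "degenerate")
  expect_error(calibrate_vf(c(10, 20), c(1, 1.1)), "at least 3")
})

test_that("Vf calibration recovers noisy coefficients within 3 standard errors", {
  set.seed(77)
  v <- runif(50, 5, 150)
  ratios <- 0.028 * v + 2.7 + rnorm(50, 0, 0.01)
  m <- calibrate_vf(v, ratios)
  fit <- summary(lm(ratios ~ v))
  expect_lt(abs(m$slope - 0.028), 3 * fit$coefficients["v", "Std. Error"])
  expect_lt(abs(m$intercept - 2.7),
            3 * fit$coefficients["(Intercept)", "Std. Error"])
  expect_lt(m$residual_sd, 0.015)
})

test_that("percent difference follows the calc-minus-reference convention", {
  expect_equal(percent_difference(1, 1), 0)
  expect_equal(percent_difference(0.987, 1), -1.3)
  expect_equal(percent_difference(1.02, 1), 2)
  expect_error(percent_difference(1, 0), "positive")
})

test_that("kernel sum equals the forward engine exactly for undistorted on-axis plans", {
  lib <- test_library(alpha = 0)
  plan <- generate_synthetic_plan(seed = 13)  # on-axis target centroid
  ref <- plan_target(plan, "GTV")$centroid_mm
  ref[c(1, 3)] <- 0  # reference exactly on the cup axis
  eq1 <- dose_ref_no_volume(plan, ref, lib)$dose_no_volume
  engine <- forward_point_dose(plan, lib, ref)
  expect_equal(eq1, engine, tolerance = 1e-12)
})

test_that("with distortion the kernel-sum error grows with target volume", {
  lib <- test_library(alpha = 0.15)
  res <- t(vapply(1:30, function(i) {
    plan <- generate_synthetic_plan(seed = 1000 + i)
    ref <- plan_target(plan, "GTV")$centroid_mm
    e <- forward_point_dose(plan, lib, ref)
    s <- dose_ref_no_volume(plan, ref, lib)$dose_no_volume
    c(plan_target(plan, "PTV")$volume_cc, abs(e / s - 1))
  }, numeric(2)))
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.8)
})

test_that("calibrated correction transfers to held-out plans within 3 residual SD", {
  lib <- test_library(alpha = 0.15)
  pairs <- t(vapply(1:40, function(i) {
    plan <- generate_synthetic_plan(seed = 2000 + i)
    ref <- plan_target(plan, "GTV")$centroid_mm
    c(v = plan_target(plan, "PTV")$volume_cc,
      ratio = forward_point_dose(plan, lib, ref) /
        dose_ref_no_volume(plan, ref, lib)$dose_no_volume)
  }, numeric(2)))
  m <- calibrate_vf(pairs[1:20, 1], pairs[1:20, 2])
  pred <- vf_eval(m, pairs[21:40, 1])
  expect_lt(max(abs(pred - pairs[21:40, 2])), 3 * m$residual_sd)
  expect_gt(m$slope, 0)
})
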