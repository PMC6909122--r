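test_that("identical planes give gamma 0 everywhere and a 100% pass rate", {
  p <- tophat_plane()
  g <- gamma_map(p, p, gamma_params(normalization = "max"))
  expect_equal(max(g$gamma), 0)
  expect_equal(g$pass_rate, 100)
})

test_that("uniform planes offset by 4% fail everywhere at 3%/1 mm", {
  ref <- dose_plane(matrix(1, 21, 21))
  ev <- dose_plane(matrix(1.04, 21, 21))
  g <- gamma_map(ref, ev, gamma_params(normalization = "explicit", norm_value = 1))
  expect_equal(g$pass_rate, 0)
  # the dose term is 4/3 everywhere; no spatial search can compensate
  expect_equal(min(g$gamma), 4 / 3, tolerance = 1e-6)
})

test_that("a 0.5 mm rigid shift passes 3%/1 mm everywhere", {
  p <- tophat_plane()
  shifted <- dose_plane(p$values, spacing = p$spacing,
                        origin = p$origin + c(0.5, 0))
  g <- gamma_map(p, shifted, gamma_params(normalization = "max"))
  expect_equal(g$pass_rate, 100)
  expect_true(all(g$gamma[g$evaluated_mask] <= 0.51))
})

test_that("gamma map matches a brute-force per-pixel evaluation", {
  set.seed(5)
  ref <- tophat_plane(n = 21, width = 14, sigma = 2)
  ev <- dose_plane(ref$values * (1 + rnorm(441, 0, 0.015)),
                   spacing = ref$spacing, origin = ref$origin + c(0.4, -0.3))
  params <- gamma_params(normalization = "max")
  g <- gamma_map(ref, ev, params)

  d_norm <- max(ref$values)
  crit <- params$dose_criterion / 100 * d_norm
  off <- seq(-params$search_radius_mm, params$search_radius_mm,
             by = params$fine_step_mm)
  og <- expand.grid(du = off, dv = off)
  og <- og[og$du^2 + og$dv^2 <= params$search_radius_mm^2, ]
  ax <- plane_axes(ref)
  brute <- matrix(NA_real_, 21, 21)
  for (i in 1:21) for (j in 1:21) {
    ev_off <- oracle_bilinear(ev, ax$u[i] + og$du, ax$v[j] + og$dv)
    g2 <- (og$du^2 + og$dv^2) / params$dta_mm^2 +
      (ev_off - ref$values[i, j])^2 / crit^2
    brute[i, j] <- sqrt(min(g2, na.rm = TRUE))
  }
  expect_equal(g$gamma, brute, tolerance = 1e-9)
})

test_that("pass rate is monotone non-increasing as criteria tighten", {
  set.seed(6)
  ref <- tophat_plane()
  ev <- dose_plane(ref$values * (1 + rnorm(length(ref$values), 0, 0.02)),
                   spacing = ref$spacing, origin = ref$origin + c(0.6, 0.2))
  ladder <- list(c(4, 2), c(3, 1), c(2, 1), c(2, 0.5), c(1, 0.5))
  rates <- vapply(ladder, function(cr)
    gamma_map(ref, ev, gamma_params(dose_criterion = cr[1], dta_mm = cr[2],
                                    normalization = "max"))$pass_rate, 0)
  expect_true(all(diff(rates) <= 1e-9))
})

test_that("gamma is invariant under a joint rigid transformation of both planes", {
  set.seed(7)
  ref <- tophat_plane(center = c(3, -2))
  ev <- dose_plane(ref$values * (1 + rnorm(length(ref$values), 0, 0.02)),
                   spacing = ref$spacing, origin = ref$origin)
  params <- gamma_params(normalization = "max")
  rot <- function(p) dose_plane(t(p$values[nrow(p$values):1, ]),
                                spacing = rev(p$spacing), origin = p$origin)
  g0 <- gamma_map(ref, ev, params)
  g90 <- gamma_map(rot(ref), rot(ev), params)
  expect_equal(g90$pass_rate, g0$pass_rate)
  expect_equal(sort(as.vector(g90$gamma)), sort(as.vector(g0$gamma)),
               tolerance = 1e-9)
})

test_that("plateau normalization restores the region mean and validates the region", {
  p <- tophat_plane()
  region <- list(center = c(0, 0), radius = 4)
  n1 <- normalize_to_plateau(p, region)
  # already normalized: renormalizing is the identity
  expect_equal(normalize_to_plateau(n1, region)$values, n1$values,
               tolerance = 1e-12)

  doubled <- dose_plane(p$values * 2, spacing = p$spacing, origin = p$origin)
  n2 <- normalize_to_plateau(doubled, region)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)

  # a steep region is rejected
  expect_error(normalize_to_plateau(p, list(center = c(15, 0), radius = 3)),
               "not a plateau")
})

test_that("profile extraction reproduces a linear field along an oblique line", {
  u <- 0:20
  plane <- dose_plane(outer(2 + 0.3 * u, rep(1, 21)))
  prof <- extract_profile(plane, c(0, 5), c(20, 15), step = 0.5)
  # value depends only on u = s * cos(angle)
  cosang <- 20 / sqrt(20^2 + 10^2)
  expect_equal(prof$value, 2 + 0.3 * prof$s * cosang, tolerance = 1e-9)
})

test_that("area sensitivity: closed form, zero case, and quadrature oracle", {
  expect_equal(area_sensitivity(22, 0.2), 100 * 0.2 / 22)
  expect_equal(round(area_sensitivity(22, 0.2)), 1)
  expect_equal(area_sensitivity(30, 0), 0)

  tophat <- function(x, w, s = 2.5)
    0.5 * ((2 * pnorm((w / 2 - x) / s) - 1) + (2 * pnorm((w / 2 + x) / s) - 1))
  for (w in c(15, 22, 30, 40)) for (dl in c(0.2, 0.5, 1)) {
    a0 <- integrate(tophat, -80, 80, w = w)$value
    a1 <- integrate(tophat, -80, 80, w = w + dl)$value
    expect_lt(abs(100 * (a1 - a0) / a0 - area_sensitivity(w, dl)), 0.05)
  }
})

test_that("error-band analysis matches the normal model", {
  eb <- error_band_analysis(1.4, 2.7)
  expect_equal(round(eb$threshold, 1), 3.8)
  expect_lt(eb$two_sided_tail, 0.01)
  expect_equal(eb$two_sided_tail, 2 * (1 - pnorm(2.7)))

  zero <- error_band_analysis(1, 0)
  expect_equal(zero$threshold, 0)
  expect_equal(zero$two_sided_tail, 1)
  expect_equal(error_band_analysis(1, 1.96)$two_sided_tail, 0.05,
               tolerance = 1e-3)
})

test_that("QA outcome classification matches its definitions and a brute-force loop", {
  all_good <- classify_qa_outcomes(c(0.5, -0.8, 1), c(0.2, -0.5, 0.9), 3)
  expect_equal(all_good$type_I, 0)
  expect_equal(all_good$type_II, 0)
  expect_equal(all_good$true_pass, 3)

  one_false_pass <- classify_qa_outcomes(2.5, 3.5, 3)
  expect_equal(one_false_pass$type_II, 1)

  set.seed(8)
  calc <- rnorm(200, 0, 2); meas <- calc + rnorm(200, 0, 1.5)
  res <- classify_qa_outcomes(calc, meas, 3)
  counts <- c(tp = 0, tf = 0, t1 = 0, t2 = 0)
  for (i in 1:200) {
    cp <- abs(calc[i]) <= 3; mp <- abs(meas[i]) <= 3
    if (cp && mp) counts["tp"] <- counts["tp"] + 1
    else if (!cp && !mp) counts["tf"] <- counts["tf"] + 1
    else if (!cp && mp) counts["t1"] <- counts["t1"] + 1
    else counts["t2"] <- counts["t2"] + 1
  }
  expect_equal(res$true_pass, unname(counts["tp"]))
  expect_equal(res$true_fail, unname(counts["tf"]))
  expect_equal(res$type_I, unname(counts["t1"]))
  expect_equal(res$type_II, unname(counts["t2"]))
  expect_equal(res$true_pass + res$true_fail + res$type_I + res$type_II, 200)
  expect_error(classify_qa_outcomes(numeric(0), numeric(0), 3), "empty")
})
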