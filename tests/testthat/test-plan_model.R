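test_that("jig cylindrical coordinates follow the stated conventions", {
  expect_equal(unname(to_jig_coordinates(c(0, 50, 0))), c(0, 0, 50))
  expect_equal(unname(to_jig_coordinates(c(10, 0, 0))), c(10, 0, 0))
  expect_equal(unname(to_jig_coordinates(c(0, 0, 10))), c(10, 90, 0))
})

test_that("jig transform round-trips on random points within 1e-9 mm", {
  set.seed(11)
  pts <- matrix(rnorm(3e4, sd = 40), ncol = 3)
  back <- from_jig_coordinates(to_jig_coordinates(pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("plan JSON round-trip is lossless", {
  p <- generate_synthetic_plan(seed = 42)
  f <- withr::local_tempfile(fileext = ".json")
  write_plan(p, f)
  q <- read_plan(f)
  expect_equal(q$plan_id, p$plan_id)
  expect_equal(q$cup, p$cup)
  expect_equal(q$control_points, p$control_points, tolerance = 1e-12)
  expect_equal(q$prescription_Gy, p$prescription_Gy)
  expect_equal(length(q$targets), length(p$targets))
  for (k in seq_along(p$targets)) {
    expect_equal(q$targets[[k]]$label, p$targets[[k]]$label)
    expect_equal(q$targets[[k]]$volume_cc, p$targets[[k]]$volume_cc,
                 tolerance = 1e-12)
    expect_equal(q$targets[[k]]$centroid_mm, p$targets[[k]]$centroid_mm,
                 tolerance = 1e-12)
  }
})

test_that("plan reader accepts a minimal plan and rejects schema violations", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '{"plan_id":"m","cup":{"size_class":"small","inner_index":2},',
    '"prescription_Gy":8,"control_points":',
    '[{"x_mm":0,"y_mm":30,"z_mm":0,"collimator_mm":15,"time_s":60}]}'), f)
  p <- read_plan(f)
  expect_s3_class(p, "gp_plan")
  expect_equal(nrow(p$control_points), 1L)

  writeLines(paste0(
    '{"plan_id":"m","cup":{"size_class":"small","inner_index":2},',
    '"prescription_Gy":8,"control_points":',
    '[{"x_mm":0,"y_mm":30,"z_mm":0,"collimator_mm":20,"time_s":60}]}'), f)
  expect_error(read_plan(f), "collimator")

  writeLines('{"cup":{"size_class":"small","inner_index":2}}', f)
  expect_error(read_plan(f), "plan_id")
})

test_that("QA plan shifts every control point by chamber - centroid", {
  cup <- cup_geometry("medium", 5)
  p <- gp_plan("p", cup, control_points(c(5, 12), c(38, 44), c(-3, 2), 15, 60),
               targets = list(target_structure("GTV", 8, c(10, 40, -1)),
                              target_structure("PTV", 30, c(11, 41, 0))))
  qa <- make_qa_plan(p, c(0, 30, 0), "GTV")
  shift <- c(0, 30, 0) - c(10, 40, -1)
  expect_equal(qa$control_points$x_mm, p$control_points$x_mm + shift[1])
  expect_equal(qa$control_points$y_mm, p$control_points$y_mm + shift[2])
  expect_equal(qa$control_points$z_mm, p$control_points$z_mm + shift[3])
  expect_equal(qa$control_points$time_s, p$control_points$time_s)
  expect_equal(qa$control_points$collimator_mm, p$control_points$collimator_mm)
  expect_true(qa$qa$is_qa_plan)
  expect_equal(qa$qa$centroid_of, "GTV")
  # recomputed centroid of the shifted target equals the chamber position
  expect_equal(plan_target(qa, "GTV")$centroid_mm, c(0, 30, 0))
  # PTV-anchored variant and identity case
  qap <- make_qa_plan(p, c(0, 30, 0), "PTV")
  expect_equal(plan_target(qap, "PTV")$centroid_mm, c(0, 30, 0))
  same <- make_qa_plan(p, c(10, 40, -1), "GTV")
  expect_equal(same$control_points, p$control_points)
})

test_that("QA plan shift preserves pairwise inter-control-point distances", {
  p <- generate_synthetic_plan(seed = 5)
  qa <- make_qa_plan(p, c(2, 40, -2), "GTV")
  d0 <- dist(p$control_points[, c("x_mm", "y_mm", "z_mm")])
  d1 <- dist(qa$control_points[, c("x_mm", "y_mm", "z_mm")])
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
})

test_that("QA plan requires the requested target", {
  cup <- cup_geometry("small", 3)
  p <- gp_plan("p", cup, control_points(0, 30, 0, 15, 60))
  expect_error(make_qa_plan(p, c(0, 30, 0)), "no target")
})

test_that("low-gradient search returns the centroid voxel in a uniform field", {
  g <- grid_around(c(0, 30, 0), 10, 1)
  g$values[] <- 5
  tg <- target_structure("GTV", 4, c(0, 30, 0))
  rp <- find_low_gradient_point(g, tg)
  expect_equal(rp$position, c(0, 30, 0))
  expect_equal(rp$averaging, "cube_5x5x5")
})

test_that("low-gradient search errors when no voxel qualifies", {
  g <- grid_around(c(0, 30, 0), 10, 1)
  ax <- grid_axes(g)
  # 2%/mm relative gradient everywhere
  g$values[] <- outer(outer(1 + 0.02 * (ax$x - 0), rep(1, 21)), rep(1, 21))
  tg <- target_structure("GTV", 4, c(0, 30, 0))
  expect_error(find_low_gradient_point(g, tg), "no low-gradient point")
})

test_that("low-gradient search agrees with an exhaustive voxel scan", {
  lib <- flat_library()
  plan <- single_shot_plan(pos = c(0, 30, 0))
  g <- compute_dose_grid(plan, lib, grid_around(c(0, 30, 0), 12, 1))
  tg <- target_structure("GTV", 15, c(3, 32, 1))
  rp <- find_low_gradient_point(g, tg)

  # oracle: explicit loop over every structure voxel
  idx <- rasterize_sphere(g, tg$centroid_mm, tg$volume_cc)
  best <- NULL
  for (m in seq_len(nrow(idx))) {
    i <- idx[m, 1]; j <- idx[m, 2]; k <- idx[m, 3]
    if (i <= 1 || j <= 1 || k <= 1 || i >= dim(g$values)[1] ||
        j >= dim(g$values)[2] || k >= dim(g$values)[3]) next
    d0 <- g$values[i, j, k]
    gx <- abs(g$values[i + 1, j, k] - g$values[i - 1, j, k]) / 2 / d0
    gy <- abs(g$values[i, j + 1, k] - g$values[i, j - 1, k]) / 2 / d0
    gz <- abs(g$values[i, j, k + 1] - g$values[i, j, k - 1]) / 2 / d0
    if (max(gx, gy, gz) >= 0.005 || d0 <= 0) next
    pos <- g$origin + (c(i, j, k) - 1) * g$spacing
    cand <- list(dose = d0, pos = pos,
                 dist = sqrt(sum((pos - tg$centroid_mm)^2)))
    if (is.null(best) || cand$dose > best$dose ||
        (cand$dose == best$dose && cand$dist < best$dist)) best <- cand
  }
  expect_false(is.null(best))
  expect_equal(rp$position, unname(best$pos))
})

test_that("synthetic plans are reproducible and respect the cohort envelopes", {
  p1 <- generate_synthetic_plan(seed = 9)
  p2 <- generate_synthetic_plan(seed = 9)
  expect_identical(p1$control_points, p2$control_points)
  expect_identical(p1$cup, p2$cup)

  env <- plan_attribute_envelopes()
  for (s in 1:200) {
    p <- generate_synthetic_plan(seed = 3000 + s)
    expect_gte(plan_target(p, "GTV")$volume_cc, env$gtv_cc[["min"]])
    expect_lte(plan_target(p, "GTV")$volume_cc, env$gtv_cc[["max"]])
    expect_gte(plan_target(p, "PTV")$volume_cc, env$ptv_cc[["min"]])
    expect_lte(plan_target(p, "PTV")$volume_cc, env$ptv_cc[["max"]])
    expect_gte(plan_target(p, "normal_breast")$volume_cc, env$breast_cc[["min"]])
    expect_lte(plan_target(p, "normal_breast")$volume_cc, env$breast_cc[["max"]])
    expect_gte(nrow(p$control_points), env$control_points[["min"]])
    expect_lte(nrow(p$control_points), env$control_points[["max"]])
  }
})

test_that("all synthetic control points lie inside the cup", {
  for (s in 1:20) {
    p <- generate_synthetic_plan(seed = 500 + s)
    cp <- p$control_points
    expect_true(all(point_in_cup(p$cup, cp$x_mm, cp$y_mm, cp$z_mm)))
  }
})

test_that("synthetic attribute means approach the configured distribution means", {
  n <- 300
  gtv <- vapply(seq_len(n), function(s)
    plan_target(generate_synthetic_plan(seed = 7000 + s), "GTV")$volume_cc, 0)
  # oracle: Monte-Carlo mean of the configured scaled-Beta distribution
  env <- plan_attribute_envelopes()$gtv_cc
  frac <- (env[["mean"]] - env[["min"]]) / (env[["max"]] - env[["min"]])
  set.seed(1)
  draws <- env[["min"]] + (env[["max"]] - env[["min"]]) *
    rbeta(5e4, 4 * frac, 4 - 4 * frac)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(gtv) - mean(draws)), 4 * se)
})
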