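# Shared fixtures: compact kernel libraries and simple plans built in code.

small_cups <- function() list(cup_geometry("small", 3), cup_geometry("medium", 5))

# coarse lattice for speed; physics identical to the full-size library
test_library <- function(alpha = 0, cups = default_cup_set(), ...) {
  make_synthetic_library(
    library_params(alpha = alpha, lattice_step = 1, lattice_half_width = 40,
                   rate_step = 5, ...),
    cups = cups)
}

# unit dose rate everywhere: 1 Gy/min, no depth attenuation
flat_library <- function(alpha = 0) {
  test_library(alpha = alpha, rate_apex_15 = 1, rate_apex_25 = 1, mu_mm = 0)
}

single_shot_plan <- function(cup = cup_geometry("small", 3),
                             pos = c(0, 30, 0), collimator = 15,
                             time_s = 120, volume_cc = 10) {
  gp_plan("shot", cup, control_points(pos[1], pos[2], pos[3], collimator, time_s),
          targets = list(target_structure("GTV", volume_cc, pos),
                         target_structure("PTV", volume_cc * 4, pos)))
}

# independent bilinear sampler for oracle implementations (kept separate from
# the package's interpolation path)
oracle_bilinear <- function(plane, uq, vq) {
  ax <- plane_axes(plane)
  out <- numeric(length(uq))
  for (m in seq_along(uq)) {
    u <- uq[m]; v <- vq[m]
    if (u < ax$u[1] || u > ax$u[length(ax$u)] ||
        v < ax$v[1] || v > ax$v[length(ax$v)]) { out[m] <- NA; next }
    i <- min(max(findInterval(u, ax$u), 1), length(ax$u) - 1)
    j <- min(max(findInterval(v, ax$v), 1), length(ax$v) - 1)
    fu <- (u - ax$u[i]) / (ax$u[i + 1] - ax$u[i])
    fv <- (v - ax$v[j]) / (ax$v[j + 1] - ax$v[j])
    out[m] <- plane$values[i, j] * (1 - fu) * (1 - fv) +
      plane$values[i + 1, j] * fu * (1 - fv) +
      plane$values[i, j + 1] * (1 - fu) * fv +
      plane$values[i + 1, j + 1] * fu * fv
  }
  out
}

# smoothed top-hat test field (flat plateau, erf penumbra)
tophat_plane <- function(n = 41, spacing = 1, width = 30, sigma = 2.5,
                         amplitude = 1, center = c(0, 0)) {
  u <- (seq_len(n) - (n + 1) / 2) * spacing
  prof <- function(d) 0.5 * ((2 * pnorm((width / 2 - d) / sigma) - 1) +
                               (2 * pnorm((width / 2 + d) / sigma) - 1))
  r <- sqrt(outer((u - center[1])^2, (u - center[2])^2, `+`))
  dose_plane(amplitude * prof(r) / prof(0), spacing = spacing,
             origin = c(u[1], u[1]))
}
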