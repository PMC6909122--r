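## Forward dose engine: kernel superposition of all control points onto a 3-D
## grid (or a single point), with optional in-transit dose and a
## kernel-broadening distortion away from the cup axis. Serves as the
## ground-truth oracle for the independent point-dose check.

#' Construct a 3-D dose grid
#'
#' @param origin `(x, y, z)` mm of the first voxel center.
#' @param spacing voxel spacing per axis, mm (scalar recycled).
#' @param dim integer voxel counts per axis.
#' @param values optional array of doses (Gy); defaults to zeros.
#' @return object of class `dose_grid` with fields `origin`, `spacing`,
#'   `values` (3-D array), `frame = "stereotactic"`, `units = "Gy"`.
#' @export
dose_grid <- function(origin, spacing, dim, values = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3)
  dim <- as.integer(rep_len(dim, 3))
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (is.null(values)) values <- array(0, dim)
  stopifnot(all(base::dim(values) == dim))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 values = values, frame = "stereotactic", units = "Gy"),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose grid %s voxels @ %s mm, origin (%.1f, %.1f, %.1f), max %.3f Gy>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              x$origin[1], x$origin[2], x$origin[3], max(x$values)))
  invisible(x)
}

#' Axis coordinate vectors of a grid
#' @param grid a `dose_grid`.
#' @return list with components `x`, `y`, `z` (voxel-center coordinates, mm).
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

#' Voxel-center coordinates for index triplets
#' @param grid a `dose_grid`.
#' @param idx integer matrix (n x 3) of voxel indices.
#' @return numeric matrix (n x 3) of positions, mm.
#' @export
voxel_centers <- function(grid, idx) {
  sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Rasterize a sphere onto a grid
#'
#' Utility for building structure masks: returns indices of voxels whose
#' centers lie within the sphere of the given volume around `center`.
#'
#' @param grid a `dose_grid`.
#' @param center `(x, y, z)` mm.
#' @param volume_cc sphere volume, cc.
#' @return integer matrix (n x 3) of voxel indices.
#' @export
rasterize_sphere <- function(grid, center, volume_cc) {
  rad <- .sphere_radius_mm(volume_cc)
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  dx2 <- (ax$x - center[1])^2
  dy2 <- (ax$y - center[2])^2
  dz2 <- (ax$z - center[3])^2
  ok <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rad^2
  which(ok, arr.ind = TRUE)
}

#' Convenience grid specification centered on a point
#'
#' @param center `(x, y, z)` mm.
#' @param half_extent half-size of the cube, mm (scalar or per-axis).
#' @param spacing voxel spacing, mm (default 1 mm, i.e. 0.001 cc voxels).
#' @return an empty `dose_grid` whose central voxel sits exactly on `center`.
#' @export
grid_around <- function(center, half_extent = 20, spacing = 1) {
  spacing <- rep_len(spacing, 3)
  half_extent <- rep_len(half_extent, 3)
  n_half <- ceiling(half_extent / spacing)
  dim <- 2L * as.integer(n_half) + 1L
  origin <- as.numeric(center) - n_half * spacing
  dose_grid(origin, spacing, dim)
}

## ---- kernel evaluation ------------------------------------------------------

## dose contribution of one control point at arbitrary points (Gy).
## The kernel is a function of the displacement from the focal spot: axial
## offset y - y_i and true transverse distance rho = |(x,z) - (x_i,z_i)|.
## (The point-dose approximation instead collapses rho to the off-axis
## difference r_i - r_ref; the engine does not.) Distortion: a control point
## at off-axis distance r_off has its kernel stretched by
## b = 1 + alpha * r_off / R (width and penumbra scale together; b = 1 on
## the axis or when alpha = 0).
.cp_contribution <- function(lib, cup, cp, X, Y, Z, distorted = TRUE) {
  r_i <- sqrt(cp$x_mm^2 + cp$z_mm^2)
  b <- 1
  if (distorted && lib$distortion$alpha > 0)
    b <- 1 + lib$distortion$alpha * r_i / lib$distortion$R
  rate <- dose_rate_lookup(lib, cp$collimator_mm, cup, cp$y_mm, r_i)
  rho <- sqrt((X - cp$x_mm)^2 + (Z - cp$z_mm)^2)
  ocr <- ocr_lookup(lib, cp$collimator_mm, cup,
                    (Y - cp$y_mm) / b, rho / b)
  rate * (cp$time_s / 60) * ocr
}

#' Forward-compute a 3-D dose grid from a plan
#'
#' Superposes the kernel of every control point:
#' `dose(p) = sum_i rate(C_i, cup, y_i, r_i) * t_i * K_i(p)`, where `K_i` is
#' the library OCR kernel broadened according to the control point's off-axis
#' distance (the distortion model). With `transit = TRUE`, dose delivered
#' while the table moves between consecutive control points is added by
#' trapezoidal integration along the straight connecting segment at
#' `table_speed_mm_s`, subdivided at steps of at most 0.5 mm.
#'
#' @param plan a `gp_plan`.
#' @param lib a `kernel_library` covering the plan's cup and collimators.
#' @param grid a `dose_grid` (its values are ignored and replaced).
#' @param transit include in-transit dose (default off, matching the
#'   instantaneous-move assumption of the point-dose formula).
#' @param table_speed_mm_s table speed used for transit integration.
#' @return the `dose_grid` with computed values.
#' @export
compute_dose_grid <- function(plan, lib, grid, transit = FALSE,
                              table_speed_mm_s = 5) {
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  X <- array(rep(ax$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
  Z <- array(rep(ax$z, each = d[1] * d[2]), d)
  grid$values[] <- .accumulate_dose(plan, lib, as.vector(X), as.vector(Y),
                                    as.vector(Z), transit, table_speed_mm_s)
  grid
}

.accumulate_dose <- function(plan, lib, X, Y, Z, transit, table_speed_mm_s) {
  cup <- plan$cup
  cps <- plan$control_points
  dose <- numeric(length(X))
  for (i in seq_len(nrow(cps)))
    dose <- dose + .cp_contribution(lib, cup, cps[i, ], X, Y, Z)
  if (transit && nrow(cps) > 1L) {
    for (i in seq_len(nrow(cps) - 1L)) {
      a <- cps[i, ]; bpt <- cps[i + 1L, ]
      seg <- c(bpt$x_mm - a$x_mm, bpt$y_mm - a$y_mm, bpt$z_mm - a$z_mm)
      L <- sqrt(sum(seg^2))
      if (L == 0) next
      t_total <- L / table_speed_mm_s          # seconds in transit
      nstep <- max(2L, ceiling(L / 0.5) + 1L)  # <= 0.5 mm subdivisions
      f <- seq(0, 1, length.out = nstep)
      w <- rep(t_total / (nstep - 1L), nstep)  # trapezoid weights (s)
      w[c(1L, nstep)] <- w[c(1L, nstep)] / 2
      for (k in seq_len(nstep)) {
        cp_k <- a
        cp_k$x_mm <- a$x_mm + f[k] * seg[1]
        cp_k$y_mm <- a$y_mm + f[k] * seg[2]
        cp_k$z_mm <- a$z_mm + f[k] * seg[3]
        cp_k$time_s <- w[k]
        dose <- dose + .cp_contribution(lib, cup, cp_k, X, Y, Z)
      }
    }
  }
  dose
}

#' Forward point dose without a grid
#'
#' Evaluates the engine's superposition directly at one or more points —
#' identical physics to [compute_dose_grid()] but with no voxelization or
#' interpolation error.
#'
#' @inheritParams compute_dose_grid
#' @param points numeric `(x, y, z)` or an n x 3 matrix.
#' @return dose(s), Gy.
#' @export
forward_point_dose <- function(plan, lib, points, transit = FALSE,
                               table_speed_mm_s = 5) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  .accumulate_dose(plan, lib, p[, 1], p[, 2], p[, 3], transit,
                   table_speed_mm_s)
}

## ---- grid sampling ----------------------------------------------------------

#' Trilinear point dose and 5x5x5 neighborhood mean
#'
#' `point_dose` interpolates trilinearly at the point. `neighborhood_mean`
#' averages the 5x5x5 voxel block centered on the voxel containing the point
#' (0.125 cc on a 1 mm grid — close to a small thimble chamber's sensitive
#' volume, versus 0.001 cc for a single voxel).
#'
#' @param grid a `dose_grid`.
#' @param point `(x, y, z)` mm; must lie inside the grid (and, for the
#'   neighborhood mean, far enough from the edge for the full block).
#' @return dose, Gy.
#' @export
point_dose <- function(grid, point) {
  ax <- grid_axes(grid)
  p <- as.numeric(point)
  if (p[1] < ax$x[1] || p[1] > ax$x[length(ax$x)] ||
      p[2] < ax$y[1] || p[2] > ax$y[length(ax$y)] ||
      p[3] < ax$z[1] || p[3] > ax$z[length(ax$z)])
    stop("point lies outside the dose grid", call. = FALSE)
  ii <- function(axis, v) min(max(findInterval(v, axis), 1L), length(axis) - 1L)
  i <- ii(ax$x, p[1]); j <- ii(ax$y, p[2]); k <- ii(ax$z, p[3])
  fx <- (p[1] - ax$x[i]) / (ax$x[i + 1] - ax$x[i])
  fy <- (p[2] - ax$y[j]) / (ax$y[j + 1] - ax$y[j])
  fz <- (p[3] - ax$z[k]) / (ax$z[k + 1] - ax$z[k])
  V <- grid$values
  c00 <- V[i, j, k] * (1 - fx) + V[i + 1, j, k] * fx
  c10 <- V[i, j + 1, k] * (1 - fx) + V[i + 1, j + 1, k] * fx
  c01 <- V[i, j, k + 1] * (1 - fx) + V[i + 1, j, k + 1] * fx
  c11 <- V[i, j + 1, k + 1] * (1 - fx) + V[i + 1, j + 1, k + 1] * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' @rdname point_dose
#' @export
neighborhood_mean <- function(grid, point) {
  d <- dim(grid$values)
  idx <- round((as.numeric(point) - grid$origin) / grid$spacing) + 1
  if (any(idx < 3) || any(idx > d - 2))
    stop("5x5x5 neighborhood extends outside the dose grid", call. = FALSE)
  blk <- grid$values[(idx[1] - 2):(idx[1] + 2),
                     (idx[2] - 2):(idx[2] + 2),
                     (idx[3] - 2):(idx[3] + 2)]
  mean(blk)
}

#' Apply the medium (density) correction
#'
#' Cross-medium comparisons (water measurement vs. breast-tissue calculation)
#' use a small multiplicative density correction, 1.6% by default. The
#' direction depends on which side of the comparison is being corrected, so
#' the sign is an explicit configuration and is recorded, with the factor, in
#' the result's `medium_correction` attribute.
#'
#' @param dose dose value(s), Gy.
#' @param factor fractional correction (default 0.016).
#' @param sign `+1` or `-1`.
#' @return corrected dose with attribute `medium_correction = list(factor, sign)`.
#' @export
apply_medium_correction <- function(dose, factor = 0.016, sign = 1) {
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1", call. = FALSE)
  structure(dose * (1 + sign * factor),
            medium_correction = list(factor = factor, sign = sign))
}

## ---- portable file format ---------------------------------------------------

#' Write / read a dose grid as a portable JSON container
#'
#' Attributes `{origin_mm, spacing_mm, dim, frame, units}` plus the flattened
#' voxel values (column-major). Intended for small grids and interchange;
#' metadata round-trips exactly.
#'
#' @param grid a `dose_grid`.
#' @param path file path.
#' @return `write_dose_grid` returns `path` invisibly; `read_dose_grid` a
#'   `dose_grid`.
#' @export
write_dose_grid <- function(grid, path) {
  doc <- list(format = "gammapodqa-grid-1",
              origin_mm = grid$origin, spacing_mm = grid$spacing,
              dim = dim(grid$values), frame = grid$frame, units = grid$units,
              values = as.vector(grid$values))
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dose_grid(doc$origin_mm, doc$spacing_mm, doc$dim,
            array(doc$values, doc$dim))
}
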