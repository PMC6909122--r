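## Plan model: cups, control points, targets, reference points, the JSON plan
## format, QA-plan generation and the synthetic plan generator.

.CUP_BASE_DIAMETER <- c(small = 93.7, medium = 121.7, large = 153.7)
.CUP_APEX_OFFSET   <- c(small = 0, medium = 10, large = 20)
.COLLIMATORS <- c(15, 25)

#' Breast-cup geometry
#'
#' The immobilization cup defines the stereotactic frame: the chest wall is
#' the plane `y = 0`, the cup apex sits on the axis at `y = apex_y`. The cup
#' wall is modelled as a hemi-ellipsoid of revolution: at axial position `y`
#' the wall radius is `R_base * sqrt(1 - (y/apex_y)^2)`.
#'
#' @param size_class one of `"small"`, `"medium"`, `"large"`; fixes the base
#'   diameter (93.7, 121.7 or 153.7 mm).
#' @param inner_index integer 1..10, the chest-to-apex depth class of the
#'   inner cup; deeper cups have larger `apex_y`.
#' @return an object of class `cup_geometry` with fields `size_class`,
#'   `base_diameter` (mm), `inner_index`, `apex_y` (mm) and `cup_id`.
#' @export
cup_geometry <- function(size_class = c("small", "medium", "large"),
                         inner_index = 5L) {
  size_class <- match.arg(size_class)
  inner_index <- as.integer(inner_index)
  if (is.na(inner_index) || inner_index < 1L || inner_index > 10L)
    stop("inner_index must be an integer in 1..10", call. = FALSE)
  apex_y <- 40 + 5 * inner_index + .CUP_APEX_OFFSET[[size_class]]
  structure(
    list(size_class = size_class,
         base_diameter = .CUP_BASE_DIAMETER[[size_class]],
         inner_index = inner_index,
         apex_y = apex_y,
         cup_id = sprintf("%s-%02d", size_class, inner_index)),
    class = "cup_geometry")
}

#' @export
print.cup_geometry <- function(x, ...) {
  cat(sprintf("<cup %s: base %.1f mm, apex at y = %.0f mm>\n",
              x$cup_id, x$base_diameter, x$apex_y))
  invisible(x)
}

#' Cup wall radius at an axial position
#'
#' @param cup a [cup_geometry()] object.
#' @param y axial position(s), mm (chest wall at 0).
#' @return wall radius in mm (0 outside `[0, apex_y]`).
#' @export
cup_radius_at <- function(cup, y) {
  R <- cup$base_diameter / 2
  ifelse(y < 0 | y > cup$apex_y, 0,
         R * sqrt(pmax(0, 1 - (y / cup$apex_y)^2)))
}

#' Test whether points lie inside the cup volume
#'
#' @inheritParams cup_radius_at
#' @param x,z transverse coordinates, mm.
#' @return logical vector.
#' @export
point_in_cup <- function(cup, x, y, z) {
  y >= 0 & y <= cup$apex_y & sqrt(x^2 + z^2) <= cup_radius_at(cup, y)
}

#' Build a control-point table
#'
#' A control point is one delivery state: table position `(x, y, z)` in mm,
#' collimator size (15 or 25 mm) and dwell time in seconds.
#'
#' @param x,y,z coordinates, mm (recycled to a common length).
#' @param collimator_mm 15 or 25.
#' @param time_s dwell time, seconds, non-negative.
#' @return a `data.frame` with columns `x_mm, y_mm, z_mm, collimator_mm, time_s`.
#' @export
control_points <- function(x, y, z, collimator_mm = 15, time_s = 1) {
  cp <- data.frame(x_mm = x, y_mm = y, z_mm = z,
                   collimator_mm = collimator_mm, time_s = time_s)
  .validate_control_points(cp)
  cp
}

.validate_control_points <- function(cp) {
  problems <- character()
  need <- c("x_mm", "y_mm", "z_mm", "collimator_mm", "time_s")
  miss <- setdiff(need, names(cp))
  if (length(miss))
    stop("control points missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(cp$collimator_mm %in% .COLLIMATORS))
    problems <- c(problems, sprintf(
      "collimator_mm must be one of {%s}; found %s",
      paste(.COLLIMATORS, collapse = ", "),
      paste(unique(setdiff(cp$collimator_mm, .COLLIMATORS)), collapse = ", ")))
  if (any(cp$time_s < 0))
    problems <- c(problems, "time_s must be >= 0")
  if (length(problems))
    stop("invalid control points:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(cp)
}

#' Define a target structure
#'
#' @param label one of `"GTV"`, `"PTV"`, `"normal_breast"`.
#' @param volume_cc structure volume in cc, positive.
#' @param centroid_mm numeric length-3 `(x, y, z)` centroid, mm.
#' @param mask optional integer matrix (n x 3) of voxel indices on a named
#'   dose grid; when present its centroid must match `centroid_mm` within
#'   half a voxel.
#' @param grid_id identifier of the grid the mask indices refer to.
#' @return object of class `target_structure`.
#' @export
target_structure <- function(label = c("GTV", "PTV", "normal_breast"),
                             volume_cc, centroid_mm, mask = NULL,
                             grid_id = NULL) {
  label <- match.arg(label)
  if (!is.numeric(volume_cc) || length(volume_cc) != 1L || volume_cc <= 0)
    stop("volume_cc must be a single positive number", call. = FALSE)
  if (length(centroid_mm) != 3L)
    stop("centroid_mm must have length 3", call. = FALSE)
  structure(list(label = label, volume_cc = volume_cc,
                 centroid_mm = as.numeric(centroid_mm),
                 mask = mask, grid_id = grid_id),
            class = "target_structure")
}

#' Assemble a treatment plan
#'
#' @param plan_id character identifier.
#' @param cup a [cup_geometry()].
#' @param cps control-point table from [control_points()]; at least one row.
#' @param targets list of [target_structure()] objects.
#' @param prescription_Gy prescription dose, Gy.
#' @param qa optional QA metadata list (set by [make_qa_plan()]).
#' @return object of class `gp_plan`.
#' @export
gp_plan <- function(plan_id, cup, cps, targets = list(),
                    prescription_Gy = 8, qa = NULL) {
  stopifnot(inherits(cup, "cup_geometry"))
  .validate_control_points(cps)
  if (nrow(cps) < 1L) stop("a plan needs at least one control point",
                           call. = FALSE)
  structure(list(plan_id = as.character(plan_id), cup = cup,
                 control_points = cps, targets = targets,
                 prescription_Gy = prescription_Gy, qa = qa),
            class = "gp_plan")
}

#' @export
print.gp_plan <- function(x, ...) {
  cat(sprintf("<plan %s: %d control points, cup %s%s>\n", x$plan_id,
              nrow(x$control_points), x$cup$cup_id,
              if (!is.null(x$qa) && isTRUE(x$qa$is_qa_plan)) ", QA plan" else ""))
  for (tg in x$targets)
    cat(sprintf("  %s: %.1f cc at (%.1f, %.1f, %.1f) mm\n", tg$label,
                tg$volume_cc, tg$centroid_mm[1], tg$centroid_mm[2],
                tg$centroid_mm[3]))
  invisible(x)
}

#' Fetch a target structure from a plan
#'
#' @param plan a `gp_plan`.
#' @param label target label to look up.
#' @return the matching [target_structure()]; error if absent.
#' @export
plan_target <- function(plan, label) {
  for (tg in plan$targets) if (tg$label == label) return(tg)
  stop(sprintf("plan '%s' has no target labelled '%s'", plan$plan_id, label),
       call. = FALSE)
}

## ---- plan file format (JSON) ------------------------------------------------

#' Write / read the JSON plan format
#'
#' Plans are stored as a single JSON document:
#' `{format, units, plan_id, cup:{size_class, inner_index}, prescription_Gy,`
#' `control_points:[{x_mm,y_mm,z_mm,collimator_mm,time_s}],`
#' `targets:[{label, volume_cc, centroid_mm, mask?, grid_id?}], qa?}`.
#' The round trip `read_plan(write_plan(p))` is lossless field for field.
#'
#' @param plan a `gp_plan`.
#' @param path file path.
#' @return `write_plan` returns `path` invisibly; `read_plan` returns a
#'   validated `gp_plan`.
#' @export
write_plan <- function(plan, path) {
  doc <- list(
    format = "gammapodqa-plan-1",
    units = list(length = "mm", time = "s", dose = "Gy"),
    plan_id = plan$plan_id,
    cup = list(size_class = plan$cup$size_class,
               inner_index = plan$cup$inner_index),
    prescription_Gy = plan$prescription_Gy,
    control_points = plan$control_points,
    targets = lapply(plan$targets, function(tg) {
      out <- list(label = tg$label, volume_cc = tg$volume_cc,
                  centroid_mm = tg$centroid_mm)
      if (!is.null(tg$mask)) out$mask <- unclass(tg$mask)
      if (!is.null(tg$grid_id)) out$grid_id <- tg$grid_id
      out
    }))
  if (!is.null(plan$qa)) doc$qa <- plan$qa
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  problems <- character()
  for (f in c("plan_id", "cup", "control_points"))
    if (is.null(doc[[f]])) problems <- c(problems, paste("missing field:", f))
  if (length(problems))
    stop("invalid plan file:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  cup <- cup_geometry(doc$cup$size_class, doc$cup$inner_index)
  cps <- as.data.frame(doc$control_points)
  .validate_control_points(cps)
  targets <- list()
  tg_doc <- doc$targets
  if (!is.null(tg_doc)) {
    ## jsonlite may simplify a homogeneous target list to a data.frame
    if (is.data.frame(tg_doc)) tg_doc <- split(tg_doc, seq_len(nrow(tg_doc)))
    targets <- lapply(tg_doc, function(tg) {
      tg <- as.list(tg)
      mask <- tg$mask
      if (!is.null(mask)) mask <- matrix(as.integer(unlist(mask)), ncol = 3)
      centroid <- unlist(tg$centroid_mm)
      target_structure(tg$label, tg$volume_cc, centroid, mask = mask,
                       grid_id = tg$grid_id)
    })
    names(targets) <- NULL
  }
  qa <- doc$qa
  if (!is.null(qa)) {
    for (f in c("chamber_position_mm", "shift_mm"))
      if (!is.null(qa[[f]])) qa[[f]] <- as.numeric(unlist(qa[[f]]))
  }
  gp_plan(doc$plan_id, cup, cps, targets,
          prescription_Gy = doc$prescription_Gy, qa = qa)
}

## ---- QA plan ----------------------------------------------------------------

#' Generate a QA plan by shifting the target centroid to the chamber
#'
#' The measurement phantom accepts its ion chamber only at a fixed position,
#' so the delivery is rigidly translated: every control point is shifted by
#' `chamber_position - target centroid`. Dwell times and collimator sizes are
#' untouched; target centroids are shifted with the plan so that the moved
#' target centroid coincides with the chamber. Structure masks are dropped
#' (they are bound to the original dose grid).
#'
#' @param plan a `gp_plan` containing the requested target.
#' @param chamber_position numeric `(x, y, z)` mm of the chamber's sensitive
#'   volume in the phantom.
#' @param centroid_of which target centroid to move onto the chamber:
#'   `"GTV"` (default) or `"PTV"`. Recorded in the QA metadata.
#' @return a new `gp_plan` flagged as a QA plan (`plan$qa$is_qa_plan`).
#' @export
make_qa_plan <- function(plan, chamber_position, centroid_of = c("GTV", "PTV")) {
  centroid_of <- match.arg(centroid_of)
  stopifnot(length(chamber_position) == 3L)
  tg <- plan_target(plan, centroid_of)
  shift <- as.numeric(chamber_position) - tg$centroid_mm
  cps <- plan$control_points
  cps$x_mm <- cps$x_mm + shift[1]
  cps$y_mm <- cps$y_mm + shift[2]
  cps$z_mm <- cps$z_mm + shift[3]
  targets <- lapply(plan$targets, function(t2) {
    t2$centroid_mm <- t2$centroid_mm + shift
    t2$mask <- NULL
    t2$grid_id <- NULL
    t2
  })
  gp_plan(paste0(plan$plan_id, "-qa"), plan$cup, cps, targets,
          prescription_Gy = plan$prescription_Gy,
          qa = list(is_qa_plan = TRUE, centroid_of = centroid_of,
                    chamber_position_mm = as.numeric(chamber_position),
                    shift_mm = shift, source_plan_id = plan$plan_id))
}

## ---- reference points -------------------------------------------------------

#' Reference point for point-dose comparison
#'
#' @param position numeric `(x, y, z)` mm.
#' @param averaging `"cube_5x5x5"` (mean over the 5x5x5 voxel block, 0.125 cc
#'   on a 1 mm grid, close to a small-volume thimble chamber) or
#'   `"single_voxel"`.
#' @return object of class `reference_point`.
#' @export
reference_point <- function(position,
                            averaging = c("cube_5x5x5", "single_voxel")) {
  averaging <- match.arg(averaging)
  stopifnot(length(position) == 3L)
  structure(list(position = as.numeric(position), averaging = averaging),
            class = "reference_point")
}

#' Locate a low-gradient reference point inside a structure
#'
#' Scans the structure's voxels for points where the relative dose change
#' over a 1 mm step (central differences along each axis, normalized by the
#' local dose) stays below `max_gradient`. Among qualifying voxels the one
#' with the largest dose is returned; ties are broken by distance to the
#' structure centroid.
#'
#' @param grid a [dose_grid()].
#' @param structure a [target_structure()]; if it has no mask, a spherical
#'   mask of the structure's volume around its centroid is rasterized on the
#'   grid.
#' @param max_gradient maximum relative change per mm (default 0.005,
#'   i.e. 0.5% over 1 mm).
#' @return a [reference_point()] at the qualifying voxel center.
#' @export
find_low_gradient_point <- function(grid, structure, max_gradient = 0.005) {
  stopifnot(inherits(grid, "dose_grid"))
  idx <- structure$mask
  if (is.null(idx))
    idx <- rasterize_sphere(grid, structure$centroid_mm, structure$volume_cc)
  if (is.null(idx) || nrow(idx) == 0L)
    stop("structure mask is empty on this grid", call. = FALSE)
  dims <- dim(grid$values)
  ## interior voxels only: central differences need both neighbours
  interior <- idx[, 1] > 1L & idx[, 1] < dims[1] &
    idx[, 2] > 1L & idx[, 2] < dims[2] &
    idx[, 3] > 1L & idx[, 3] < dims[3]
  idx <- idx[interior, , drop = FALSE]
  if (nrow(idx) == 0L)
    stop("no low-gradient point: structure has no interior voxels on the grid",
         call. = FALSE)
  V <- grid$values
  d0 <- V[idx]
  rel_step <- function(axis) {
    up <- idx; up[, axis] <- up[, axis] + 1L
    dn <- idx; dn[, axis] <- dn[, axis] - 1L
    abs(V[up] - V[dn]) / (2 * grid$spacing[axis]) / pmax(d0, .Machine$double.eps)
  }
  g <- pmax(rel_step(1), rel_step(2), rel_step(3))
  ok <- g < max_gradient & d0 > 0
  if (!any(ok))
    stop("no low-gradient point: no voxel satisfies the gradient criterion",
         call. = FALSE)
  idx <- idx[ok, , drop = FALSE]
  d0 <- d0[ok]
  pos <- voxel_centers(grid, idx)
  dc <- sqrt(rowSums(sweep(pos, 2, structure$centroid_mm)^2))
  best <- order(-d0, dc)[1]
  reference_point(pos[best, ])
}

## ---- jig coordinates --------------------------------------------------------

#' Convert between stereotactic and jig cylindrical coordinates
#'
#' The measurement jig addresses points as `(r, theta, y)`:
#' `r = sqrt(x^2 + z^2)`, `theta = atan2(z, x)` in degrees on `[0, 360)`
#' (defined as 0 on the axis), `y` unchanged.
#'
#' @param point numeric `(x, y, z)` mm, or a matrix with three columns.
#' @return `to_jig_coordinates`: `(r, theta, y)`; `from_jig_coordinates`:
#'   `(x, y, z)`. Matrix in, matrix out.
#' @export
to_jig_coordinates <- function(point) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  r <- sqrt(p[, 1]^2 + p[, 3]^2)
  theta <- ifelse(r == 0, 0, (atan2(p[, 3], p[, 1]) * 180 / pi) %% 360)
  out <- cbind(r = r, theta = theta, y = p[, 2])
  if (is.matrix(point)) out else drop(out)
}

#' @rdname to_jig_coordinates
#' @param jig numeric `(r, theta, y)` or a three-column matrix.
#' @export
from_jig_coordinates <- function(jig) {
  p <- if (is.matrix(jig)) jig else matrix(jig, ncol = 3)
  th <- p[, 2] * pi / 180
  out <- cbind(x = p[, 1] * cos(th), y = p[, 3], z = p[, 1] * sin(th))
  if (is.matrix(jig)) out else drop(out)
}

## ---- synthetic plan generator ----------------------------------------------

#' Envelopes of the clinical plan attributes
#'
#' Min/max/mean of GTV volume (cc), PTV volume (cc), normal-breast volume
#' (cc) and control-point count across the 15-patient commissioning cohort.
#' These are the default sampling envelopes of [generate_synthetic_plan()].
#'
#' @return a named list of `c(min, max, mean)` vectors.
#' @export
plan_attribute_envelopes <- function() {
  list(gtv_cc = c(min = 2.9, max = 29.1, mean = 11.1),
       ptv_cc = c(min = 21.7, max = 153.9, mean = 66.9),
       breast_cc = c(min = 722, max = 1994, mean = 1264),
       control_points = c(min = 361, max = 813, mean = 491))
}

## scaled Beta draw on [min, max] whose expectation equals `mean`
## (a + b fixed at 4 for a broad but unimodal shape)
.draw_envelope <- function(env, n = 1) {
  frac <- (env[["mean"]] - env[["min"]]) / (env[["max"]] - env[["min"]])
  a <- 4 * frac
  env[["min"]] + (env[["max"]] - env[["min"]]) * rbeta(n, a, 4 - a)
}

## map breast volume onto the 19-cup set: size class from volume band, depth
## index from the position within the band (small 1-6, medium 1-7, large 1-6)
.cup_for_breast <- function(breast_cc) {
  env <- plan_attribute_envelopes()$breast_cc
  bands <- list(small = c(env[["min"]], 1100, 6L),
                medium = c(1100, 1550, 7L),
                large = c(1550, env[["max"]], 6L))
  size <- if (breast_cc < 1100) "small" else if (breast_cc < 1550) "medium" else "large"
  b <- bands[[size]]
  frac <- (breast_cc - b[1]) / (b[2] - b[1])
  idx <- as.integer(pmin(b[3], pmax(1, 1 + floor(frac * b[3]))))
  cup_geometry(size, idx)
}

.sphere_radius_mm <- function(volume_cc) (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)

#' Generate a synthetic treatment plan
#'
#' Draws GTV/PTV/breast volumes and the control-point count from scaled Beta
#' distributions whose support and mean match the clinical cohort envelopes
#' ([plan_attribute_envelopes()]), assigns a cup from the breast volume,
#' places the target centroid off-center inside the cup, and scatters control
#' points uniformly in the PTV sphere around it (clipped to the cup volume).
#' Collimator 25 mm is used with probability increasing in PTV volume; dwell
#' times are uniform on `dwell_range`.
#'
#' @param seed integer; the same seed reproduces the plan exactly.
#' @param envelopes attribute envelopes (see [plan_attribute_envelopes()]).
#' @param dwell_range dwell-time range, seconds.
#' @param prescription_Gy prescription dose.
#' @param max_centroid_offset_mm largest transverse (off-axis) distance of
#'   the target centroid, mm; 0 (default) keeps targets on the cup axis,
#'   the regime in which the independent point-dose approximation's error is
#'   purely volume-driven.
#' @param plan_id optional identifier (default derived from the seed).
#' @return a `gp_plan` with GTV, PTV and normal_breast targets.
#' @export
generate_synthetic_plan <- function(seed = NULL,
                                    envelopes = plan_attribute_envelopes(),
                                    dwell_range = c(0.3, 2.5),
                                    prescription_Gy = 8,
                                    max_centroid_offset_mm = 0,
                                    plan_id = NULL) {
  .with_seed(seed, {
    gtv <- .draw_envelope(envelopes$gtv_cc)
    ## PTV = GTV + margin: draw, then enforce PTV > GTV
    ptv <- max(.draw_envelope(envelopes$ptv_cc), gtv * 1.5)
    ptv <- min(ptv, envelopes$ptv_cc[["max"]])
    breast <- .draw_envelope(envelopes$breast_cc)
    n_cp <- as.integer(round(.draw_envelope(envelopes$control_points)))
    cup <- .cup_for_breast(breast)

    r_ptv <- .sphere_radius_mm(ptv)
    r_gtv <- .sphere_radius_mm(gtv)
    yc <- runif(1, 0.35, 0.6) * cup$apex_y
    yc <- min(max(yc, r_gtv + 5), cup$apex_y - r_gtv - 5)
    ## on-axis centroids by default: the point-dose approximation is exact
    ## for an on-axis reference point and degrades with centroid off-axis
    ## distance (~10%/mm) independently of target size, so axial placement
    ## isolates the position-dependent kernel distortion — which grows with
    ## the control points' spread, i.e. with target volume — as the sole
    ## error source. That is the regime the volume-correction calibration
    ## presumes; off-axis targets are available via max_centroid_offset_mm.
    rc <- runif(1, 0, max_centroid_offset_mm)
    thc <- runif(1, 0, 2 * pi)
    centroid <- c(rc * cos(thc), yc, rc * sin(thc))

    ## uniform in the PTV sphere, clipped to stay inside the cup wall
    u <- matrix(rnorm(3 * n_cp), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- r_ptv * runif(n_cp)^(1 / 3)
    pts <- sweep(u * rad, 2, centroid, `+`)
    pts[, 2] <- pmin(pmax(pts[, 2], 2), cup$apex_y - 2)
    wall <- cup_radius_at(cup, pts[, 2])
    rr <- sqrt(pts[, 1]^2 + pts[, 3]^2)
    scale <- ifelse(rr > 0.95 * wall, 0.95 * wall / pmax(rr, 1e-9), 1)
    pts[, 1] <- pts[, 1] * scale
    pts[, 3] <- pts[, 3] * scale

    p25 <- min(0.5, ptv / 160)
    coll <- ifelse(runif(n_cp) < p25, 25, 15)
    dwell <- runif(n_cp, dwell_range[1], dwell_range[2])

    if (is.null(plan_id))
      plan_id <- sprintf("synth-%s", if (is.null(seed)) "r" else seed)
    gp_plan(plan_id, cup,
            control_points(pts[, 1], pts[, 2], pts[, 3], coll, dwell),
            targets = list(
              target_structure("GTV", gtv, centroid),
              target_structure("PTV", ptv, centroid),
              target_structure("normal_breast", breast,
                               c(0, cup$apex_y / 2, 0))),
            prescription_Gy = prescription_Gy)
  })
}
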