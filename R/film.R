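## Radiochromic-film workflow: calibration-curve fitting (red-channel netOD
## vs dose), rigid four-mark registration, synthetic film generation and the
## film -> dose processing chain.

#' Fit a film calibration curve
#'
#' Fits the monotone response model `netOD = a * D / (b + D) + c * D`
#' (saturating Michaelis-Menten term plus a linear tail) to calibration
#' points by nonlinear least squares. Twelve points spanning 0.01-10 Gy is
#' the usual measurement layout. The inverse map is evaluated numerically;
#' the fit is accepted only if every calibration point round-trips through
#' response -> dose within 1% of its dose.
#'
#' @param dose_gy calibration doses, Gy (at least 4).
#' @param net_od net optical densities (red channel), strictly increasing
#'   with dose after sorting.
#' @return object of class `film_calibration` with coefficients `a`, `b`,
#'   `c`, the calibration points, fit residuals and the calibrated range.
#' @export
fit_calibration <- function(dose_gy, net_od) {
  stopifnot(length(dose_gy) == length(net_od))
  if (length(dose_gy) < 4L)
    stop("need at least 4 calibration points", call. = FALSE)
  o <- order(dose_gy)
  d <- dose_gy[o]; r <- net_od[o]
  if (any(diff(r) <= 0))
    stop("responses are not strictly monotone in dose", call. = FALSE)
  fit <- minpack.lm::nlsLM(
    r ~ a * d / (b + d) + c * d,
    start = list(a = max(r) * 0.8, b = stats::median(d), c = max(r) / max(d) / 10),
    lower = c(a = 0, b = 1e-6, c = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  curve <- structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                          c = unname(cf["c"]),
                          dose_gy = d, net_od = r,
                          residuals = unname(resid(fit)),
                          dose_range = range(d)),
                     class = "film_calibration")
  rt <- response_to_dose(curve, dose_to_response(curve, d))
  bad <- abs(rt - d) > 0.01 * pmax(d, 1e-6)
  if (any(bad))
    stop("calibration fit fails the 1% round-trip check at dose(s) ",
         paste(signif(d[bad], 3), collapse = ", "), " Gy", call. = FALSE)
  curve
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf("<film calibration: netOD = %.4g D/(%.4g + D) + %.4g D on [%.3g, %.3g] Gy>\n",
              x$a, x$b, x$c, x$dose_range[1], x$dose_range[2]))
  invisible(x)
}

#' Evaluate the calibration model (dose -> response)
#'
#' @param curve a `film_calibration`.
#' @param dose_gy dose value(s), Gy.
#' @return net optical density values.
#' @export
dose_to_response <- function(curve, dose_gy) {
  curve$a * dose_gy / (curve$b + dose_gy) + curve$c * dose_gy
}

#' Invert the calibration curve (response -> dose)
#'
#' Solves the strictly monotone calibration model numerically.
#'
#' @param curve a `film_calibration`.
#' @param net_od response value(s).
#' @param clamp if `TRUE`, responses beyond the calibrated range map to the
#'   range endpoints instead of an error (useful for saturated mark pixels).
#' @return dose(s), Gy.
#' @export
response_to_dose <- function(curve, net_od, clamp = FALSE) {
  upper <- curve$dose_range[2] * 1.05
  r_max <- dose_to_response(curve, upper)
  vapply(net_od, function(od) {
    if (is.na(od)) return(NA_real_)
    if (od <= 0) {
      if (od < -1e-9 && !clamp)
        stop("response below the calibrated range", call. = FALSE)
      return(0)
    }
    if (od >= r_max) {
      if (!clamp)
        stop("response above the calibrated range", call. = FALSE)
      return(upper)
    }
    uniroot(function(D) dose_to_response(curve, D) - od,
            lower = 0, upper = upper, tol = 1e-10)$root
  }, numeric(1))
}

#' Read film calibration points from CSV
#'
#' Expects the dialect `dose_gy,net_od`.
#'
#' @param path CSV path.
#' @return a fitted `film_calibration` (via [fit_calibration()]).
#' @export
read_calibration_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("dose_gy", "net_od") %in% names(d)))
    stop("calibration CSV must have columns dose_gy, net_od", call. = FALSE)
  fit_calibration(d$dose_gy, d$net_od)
}

## ---- rigid registration -----------------------------------------------------

#' Least-squares rigid registration of mark sets
#'
#' Estimates the rotation + translation (no scaling or shear; orthogonal
#' Procrustes with the reflection excluded) mapping the film's fiducial
#' marks onto the plan's marks: `plan ~= R %*% film + t`.
#'
#' @param film_marks,plan_marks matrices (n x 2), n >= 4 corresponding,
#'   non-collinear points, mm.
#' @return object of class `rigid_transform` with `rotation_deg`,
#'   `translation` (mm), `rms_residual` (mm) and the 2x2 rotation matrix `R`.
#' @export
register_marks <- function(film_marks, plan_marks) {
  A <- as.matrix(film_marks); B <- as.matrix(plan_marks)
  if (nrow(A) < 4L || nrow(B) < 4L)
    stop("need at least 4 mark pairs", call. = FALSE)
  if (nrow(A) != nrow(B)) stop("mark sets differ in size", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (svd(B0)$d[2] < 1e-8 || svd(A0)$d[2] < 1e-8)
    stop("marks are collinear: registration is degenerate", call. = FALSE)
  s <- svd(crossprod(A0, B0))           # Kabsch: maps film -> plan
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  t_vec <- cb - as.vector(R %*% ca)
  res <- sweep(A %*% t(R), 2, t_vec, `+`) - B
  structure(list(rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
                 translation = t_vec,
                 rms_residual = sqrt(mean(rowSums(res^2))),
                 R = R),
            class = "rigid_transform")
}

#' Build, apply and invert rigid 2-D transforms
#'
#' `rigid_transform()` constructs a transform from a rotation (about the
#' given center) and a translation; `apply_transform()` maps points;
#' `invert_transform()` returns the inverse.
#'
#' @param rotation_deg rotation angle, degrees (counter-clockwise).
#' @param translation `(u, v)` shift, mm.
#' @param center rotation center, mm.
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, translation = c(0, 0),
                            center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ## rotate about `center`, then shift
  t_vec <- as.numeric(center) - as.vector(R %*% as.numeric(center)) +
    as.numeric(translation)
  structure(list(rotation_deg = rotation_deg, translation = t_vec,
                 rms_residual = 0, R = R),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @param points n x 2 matrix (or length-2 vector), mm.
#' @export
apply_transform <- function(transform, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 2)
  out <- sweep(p %*% t(transform$R), 2, transform$translation, `+`)
  if (is.matrix(points)) out else drop(out)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  Rinv <- t(transform$R)
  structure(list(rotation_deg = -transform$rotation_deg,
                 translation = -as.vector(Rinv %*% transform$translation),
                 rms_residual = transform$rms_residual,
                 R = Rinv),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid transform: %.4g deg, t = (%.4g, %.4g) mm, rms residual %.4g mm>\n",
              x$rotation_deg, x$translation[1], x$translation[2],
              x$rms_residual))
  invisible(x)
}

## ---- synthetic film ---------------------------------------------------------

.default_marks <- function(plane, inset = 5) {
  ax <- plane_axes(plane)
  u <- range(ax$u); v <- range(ax$v)
  rbind(c(u[1] + inset, v[1] + inset), c(u[2] - inset, v[1] + inset),
        c(u[2] - inset, v[2] - inset), c(u[1] + inset, v[2] - inset))
}

#' Generate a synthetic film measurement
#'
#' Emulates the physical film chain: the planned dose plane is converted to
#' film response through the calibration curve, optionally misregistered by
#' a rigid transform (the film's frame vs the plan's frame), perturbed by
#' additive Gaussian response noise, and stamped with the four registration
#' marks (3x3 saturated pixel blocks). Deterministic for a fixed seed.
#'
#' @param plane the planned `dose_plane` (plan frame).
#' @param curve a `film_calibration`.
#' @param noise_sd additive response (netOD) noise SD.
#' @param shift_mm `(u, v)` film misregistration shift.
#' @param rotation_deg film misregistration rotation (about the plane
#'   center).
#' @param dose_scale multiplicative dose-calibration error of the film
#'   (1 = none); what plateau normalization is meant to absorb.
#' @param seed RNG seed for the noise.
#' @param marks_plan optional 4 x 2 mark coordinates in the plan frame
#'   (default: 5 mm corner insets).
#' @return list: `image` (response `dose_plane` in the film frame),
#'   `marks_film`, `marks_plan`, `transform` (plan -> film, a
#'   `rigid_transform`), `curve`.
#' @export
synth_film <- function(plane, curve, noise_sd = 0, shift_mm = c(0, 0),
                       rotation_deg = 0, dose_scale = 1, seed = NULL,
                       marks_plan = NULL) {
  if (is.null(marks_plan)) marks_plan <- .default_marks(plane)
  ax <- plane_axes(plane)
  center <- c(mean(range(ax$u)), mean(range(ax$v)))
  fwd <- rigid_transform(rotation_deg, shift_mm, center = center)  # plan -> film
  inv <- invert_transform(fwd)
  U <- matrix(ax$u, length(ax$u), length(ax$v))
  V <- matrix(ax$v, length(ax$u), length(ax$v), byrow = TRUE)
  ## film pixel at (u,v) in the film frame sees the dose at inv(u,v)
  src <- apply_transform(inv, cbind(as.vector(U), as.vector(V)))
  dose <- plane_sample(plane, src[, 1], src[, 2], outside = 0) * dose_scale
  resp <- dose_to_response(curve, dose)
  resp <- .with_seed(seed, resp + if (noise_sd > 0)
    rnorm(length(resp), 0, noise_sd) else 0)
  img <- matrix(resp, nrow(plane$values), ncol(plane$values))
  film <- dose_plane(img, spacing = plane$spacing, origin = plane$origin)
  ## burn the marks: saturated 3x3 blocks at the transformed mark positions
  marks_film <- apply_transform(fwd, marks_plan)
  sat <- dose_to_response(curve, curve$dose_range[2]) * 1.1
  fax <- plane_axes(film)
  for (m in seq_len(nrow(marks_film))) {
    i <- which.min(abs(fax$u - marks_film[m, 1]))
    j <- which.min(abs(fax$v - marks_film[m, 2]))
    ii <- pmax(1, pmin(nrow(img), (i - 1):(i + 1)))
    jj <- pmax(1, pmin(ncol(img), (j - 1):(j + 1)))
    film$values[ii, jj] <- sat
  }
  list(image = film, marks_film = marks_film, marks_plan = marks_plan,
       transform = fwd, curve = curve)
}

#' Process a film into a dose plane in the plan frame
#'
#' The measurement-side chain: register the film's marks onto the plan's
#' marks, resample the film response onto the plan lattice, and convert
#' response to dose through the calibration curve (saturated mark pixels are
#' clamped to the top of the calibrated range).
#'
#' @param film output of [synth_film()] (or a list with `image`,
#'   `marks_film`, `marks_plan`, and optionally `curve`).
#' @param curve a `film_calibration` (defaults to `film$curve`).
#' @param target_plane optional `dose_plane` defining the output lattice
#'   (defaults to the film's own lattice).
#' @return list: `dose` (a `dose_plane` in the plan frame), `transform`
#'   (film -> plan, as estimated from the marks).
#' @export
process_film <- function(film, curve = film$curve, target_plane = NULL) {
  tr <- register_marks(film$marks_film, film$marks_plan)  # film -> plan
  lattice <- if (is.null(target_plane)) film$image else target_plane
  ax <- plane_axes(lattice)
  U <- matrix(ax$u, length(ax$u), length(ax$v))
  V <- matrix(ax$v, length(ax$u), length(ax$v), byrow = TRUE)
  ## plan position (u,v) maps back into the film frame through the inverse
  src <- apply_transform(invert_transform(tr), cbind(as.vector(U), as.vector(V)))
  resp <- plane_sample(film$image, src[, 1], src[, 2], outside = 0)
  dose <- response_to_dose(curve, pmax(resp, 0), clamp = TRUE)
  out <- dose_plane(matrix(dose, length(ax$u), length(ax$v)),
                    spacing = lattice$spacing, origin = lattice$origin)
  list(dose = out, transform = tr)
}
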