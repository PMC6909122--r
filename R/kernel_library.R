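## Kernel library: off-center-ratio (OCR) tables and isocenter dose-rate
## tables per (collimator, cup), a simple position-dependent distortion model
## used only by the forward engine, the synthetic table generator, and the
## CSV + manifest file format.

#' Parameters of the synthetic kernel generator
#'
#' The synthetic tables emulate vendor Monte-Carlo commissioning data.
#' OCR profiles are error-function-smoothed top-hats,
#' `OCR(d) = 0.5 * (erf((w/2 - d)/(s*sqrt(2))) + erf((w/2 + d)/(s*sqrt(2))))`,
#' applied separably along the cup axis and radially, and renormalized so
#' `OCR(0, 0) = 1` exactly. Isocenter dose rates decay exponentially with
#' depth below the cup apex, `rate = R0 * exp(-mu * (apex_y - y))`, with an
#' optional quadratic radial falloff.
#'
#' @param fwhm_15,fwhm_25 top-hat widths (profile FWHM), mm. The 15 mm
#'   collimator measures ~22.0 mm at the focal spot; the 25 mm collimator's
#'   width is a configurable default, not a device datum.
#' @param sigma_15,sigma_25 penumbra smoothing sigmas, mm.
#' @param rate_apex_15,rate_apex_25 dose rate at the cup apex, Gy/min.
#' @param mu_mm effective attenuation coefficient, 1/mm.
#' @param radial_falloff fractional rate reduction at the cup wall
#'   (quadratic in r); 0 disables radial dependence.
#' @param alpha distortion broadening coefficient: the forward engine widens
#'   the kernel by `1 + alpha * r_off / distortion_radius` for a control point
#'   at off-axis distance `r_off`. `alpha = 0` makes the kernel positionally
#'   invariant.
#' @param distortion_radius reference radius of the distortion model, mm.
#' @param lattice_half_width OCR lattice extent, mm (lattice spans ±this).
#' @param lattice_step OCR lattice spacing, mm.
#' @param rate_step dose-rate lattice spacing, mm.
#' @return a named list of generator parameters.
#' @export
library_params <- function(fwhm_15 = 22.0, fwhm_25 = 35.0,
                           sigma_15 = 2.5, sigma_25 = 3.0,
                           rate_apex_15 = 2.0, rate_apex_25 = 2.3,
                           mu_mm = 0.005, radial_falloff = 0,
                           alpha = 0.15, distortion_radius = 50,
                           lattice_half_width = 40, lattice_step = 0.5,
                           rate_step = 2) {
  p <- list(fwhm_15 = fwhm_15, fwhm_25 = fwhm_25, sigma_15 = sigma_15,
            sigma_25 = sigma_25, rate_apex_15 = rate_apex_15,
            rate_apex_25 = rate_apex_25, mu_mm = mu_mm,
            radial_falloff = radial_falloff, alpha = alpha,
            distortion_radius = distortion_radius,
            lattice_half_width = lattice_half_width,
            lattice_step = lattice_step, rate_step = rate_step)
  if (any(unlist(p[c("fwhm_15", "fwhm_25", "sigma_15", "sigma_25",
                     "lattice_half_width", "lattice_step", "rate_step",
                     "distortion_radius")]) <= 0))
    stop("widths, sigmas, lattice parameters and distortion_radius must be positive",
         call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  p
}

#' The default 19-cup set
#'
#' The device ships 19 inner cup sizes; the default set uses small 1-6,
#' medium 1-7 and large 1-6 depth classes.
#'
#' @return list of [cup_geometry()] objects.
#' @export
default_cup_set <- function() {
  c(lapply(1:6, function(i) cup_geometry("small", i)),
    lapply(1:7, function(i) cup_geometry("medium", i)),
    lapply(1:6, function(i) cup_geometry("large", i)))
}

.erf_tophat <- function(d, width, sigma) {
  0.5 * (.erf((width / 2 - d) / (sigma * sqrt(2))) +
           .erf((width / 2 + d) / (sigma * sqrt(2))))
}

.coll_key <- function(collimator, cup_id) paste(collimator, cup_id, sep = "|")

.cup_of <- function(cup) if (inherits(cup, "cup_geometry")) cup$cup_id else as.character(cup)

#' Generate a synthetic kernel library
#'
#' Builds OCR and dose-rate tables for both collimators over a cup set using
#' the model in [library_params()]. Generation is deterministic for fixed
#' parameters; `seed` is recorded in the provenance metadata (and used only
#' if table noise is ever requested).
#'
#' @param params generator parameters from [library_params()].
#' @param cups list of [cup_geometry()] objects (default [default_cup_set()]).
#' @param seed integer recorded in provenance.
#' @return object of class `kernel_library` with elements `ocr`, `rates`
#'   (named lists keyed `"<collimator>|<cup_id>"`), `distortion`, `cups`,
#'   `params`, `provenance`.
#' @export
make_synthetic_library <- function(params = library_params(),
                                   cups = default_cup_set(),
                                   seed = NULL) {
  lat <- seq(-params$lattice_half_width, params$lattice_half_width,
             by = params$lattice_step)
  ocr_for <- function(coll) {
    w <- if (coll == 15) params$fwhm_15 else params$fwhm_25
    s <- if (coll == 15) params$sigma_15 else params$sigma_25
    prof <- .erf_tophat(lat, w, s)
    V <- outer(prof, prof)
    i0 <- which(lat == 0)
    V / V[i0, i0]
  }
  ocr_mats <- list(`15` = ocr_for(15), `25` = ocr_for(25))

  ocr <- list(); rates <- list()
  for (cup in cups) {
    ys <- unique(c(seq(0, cup$apex_y, by = params$rate_step), cup$apex_y))
    rs <- unique(c(seq(0, cup$base_diameter / 2, by = params$rate_step),
                   cup$base_diameter / 2))
    depth_fac <- exp(-params$mu_mm * (cup$apex_y - ys))
    rad_fac <- 1 - params$radial_falloff * (rs / (cup$base_diameter / 2))^2
    for (coll in .COLLIMATORS) {
      key <- .coll_key(coll, cup$cup_id)
      ocr[[key]] <- list(collimator = coll, cup_id = cup$cup_id,
                         dy = lat, dr = lat, values = ocr_mats[[as.character(coll)]])
      R0 <- if (coll == 15) params$rate_apex_15 else params$rate_apex_25
      rates[[key]] <- list(collimator = coll, cup_id = cup$cup_id,
                           y = ys, r = rs,
                           values = R0 * outer(depth_fac, rad_fac))
    }
  }
  structure(list(ocr = ocr, rates = rates,
                 distortion = list(alpha = params$alpha,
                                   R = params$distortion_radius),
                 cups = stats::setNames(cups, vapply(cups, `[[`, "", "cup_id")),
                 params = params,
                 provenance = list(generator = "synthetic", seed = seed)),
            class = "kernel_library")
}

#' @export
print.kernel_library <- function(x, ...) {
  cat(sprintf("<kernel library: %d cups x 2 collimators, alpha = %.3g (%s)>\n",
              length(x$cups), x$distortion$alpha,
              x$provenance$generator))
  invisible(x)
}

.lib_table <- function(lib, kind, collimator, cup) {
  key <- .coll_key(collimator, .cup_of(cup))
  tab <- lib[[kind]][[key]]
  if (is.null(tab))
    stop(sprintf("no %s table for collimator %s mm, cup '%s'",
                 if (kind == "ocr") "OCR" else "dose-rate",
                 collimator, .cup_of(cup)), call. = FALSE)
  tab
}

#' Look up an off-center ratio
#'
#' Bilinear interpolation on the `(delta_y, delta_r)` lattice; exact at
#' lattice nodes, 0 outside the lattice (the beam is fully blocked far
#' off-axis; no extrapolation).
#'
#' @param lib a `kernel_library`.
#' @param collimator 15 or 25.
#' @param cup a [cup_geometry()] or cup id string.
#' @param dy,dr axial and radial displacement from the focal spot, mm
#'   (vectorized).
#' @return dimensionless ratio(s) in `[0, 1]`.
#' @export
ocr_lookup <- function(lib, collimator, cup, dy, dr) {
  tab <- .lib_table(lib, "ocr", collimator, cup)
  .bilinear(tab$dy, tab$dr, tab$values, dy, dr, outside = 0)
}

#' Look up an isocenter dose rate
#'
#' Bilinear interpolation on the `(y, r)` lattice. Queries outside the cup
#' (negative `r`, `r` beyond the base radius, or `y` outside `[0, apex_y]`)
#' are an error: the focal spot cannot be placed there.
#'
#' @inheritParams ocr_lookup
#' @param y axial focal-spot position, mm.
#' @param r off-axis focal-spot distance, mm.
#' @return dose rate(s), Gy/min.
#' @export
dose_rate_lookup <- function(lib, collimator, cup, y, r) {
  tab <- .lib_table(lib, "rates", collimator, cup)
  bad <- y < min(tab$y) | y > max(tab$y) | r < min(tab$r) | r > max(tab$r)
  if (any(bad))
    stop(sprintf(
      "dose-rate query outside cup '%s': y must be in [%.1f, %.1f], r in [%.1f, %.1f]",
      tab$cup_id, min(tab$y), max(tab$y), min(tab$r), max(tab$r)),
      call. = FALSE)
  .bilinear(tab$y, tab$r, tab$values, y, r)
}

#' FWHM of a sampled profile
#'
#' Locates the half-maximum crossings by linear interpolation between
#' samples. The profile must be unimodal (exactly one rising and one falling
#' half-maximum crossing).
#'
#' @param x sample positions, mm (ascending).
#' @param y profile values.
#' @return full width at half maximum, mm.
#' @export
fwhm_of_profile <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  half <- max(y) / 2
  s <- y - half
  n <- length(s)
  cross_x <- x[s == 0]                        # samples exactly at half maximum
  i <- which(s[-n] * s[-1] < 0)               # strict sign changes
  cross_x <- sort(c(cross_x, x[i] - s[i] * (x[i + 1] - x[i]) / (s[i + 1] - s[i])))
  if (length(cross_x) != 2)
    stop("profile is not unimodal: expected exactly two half-maximum crossings, found ",
         length(cross_x), call. = FALSE)
  diff(cross_x)
}

## ---- file format: CSV tables + JSON manifest -------------------------------

#' Write / read a kernel library as CSV tables with a JSON manifest
#'
#' Each table is one CSV in long format (`delta_y_mm,delta_r_mm,ocr` for OCR
#' tables, `y_mm,r_mm,rate_gy_min` for dose-rate tables); `manifest.json`
#' lists the tables, the cup set, the distortion model and the generator
#' parameters.
#'
#' @param lib a `kernel_library`.
#' @param dir directory to write into (created if missing).
#' @return `write_library` returns `dir` invisibly; `read_library` a
#'   `kernel_library`.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (key in names(lib$ocr)) {
    tab <- lib$ocr[[key]]
    file <- sprintf("ocr_%s_%s.csv", tab$collimator, tab$cup_id)
    g <- expand.grid(delta_y_mm = tab$dy, delta_r_mm = tab$dr)
    g$ocr <- as.vector(tab$values)
    write.csv(g, file.path(dir, file), row.names = FALSE)
    entries[[length(entries) + 1L]] <-
      list(kind = "ocr", collimator = tab$collimator, cup_id = tab$cup_id,
           file = file)
  }
  for (key in names(lib$rates)) {
    tab <- lib$rates[[key]]
    file <- sprintf("rate_%s_%s.csv", tab$collimator, tab$cup_id)
    g <- expand.grid(y_mm = tab$y, r_mm = tab$r)
    g$rate_gy_min <- as.vector(tab$values)
    write.csv(g, file.path(dir, file), row.names = FALSE)
    entries[[length(entries) + 1L]] <-
      list(kind = "rate", collimator = tab$collimator, cup_id = tab$cup_id,
           file = file)
  }
  manifest <- list(
    format = "gammapodqa-library-1",
    tables = entries,
    distortion = lib$distortion,
    cups = lapply(unname(lib$cups), function(cup)
      list(size_class = cup$size_class, inner_index = cup$inner_index)),
    params = lib$params,
    provenance = lib$provenance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  cups <- lapply(mf$cups, function(cc) cup_geometry(cc$size_class, cc$inner_index))
  ocr <- list(); rates <- list()
  for (e in mf$tables) {
    d <- read.csv(file.path(dir, e$file))
    if (e$kind == "ocr") {
      dy <- sort(unique(d$delta_y_mm)); dr <- sort(unique(d$delta_r_mm))
      V <- matrix(NA_real_, length(dy), length(dr))
      V[cbind(match(d$delta_y_mm, dy), match(d$delta_r_mm, dr))] <- d$ocr
      ocr[[.coll_key(e$collimator, e$cup_id)]] <-
        list(collimator = e$collimator, cup_id = e$cup_id,
             dy = dy, dr = dr, values = V)
    } else {
      ys <- sort(unique(d$y_mm)); rs <- sort(unique(d$r_mm))
      V <- matrix(NA_real_, length(ys), length(rs))
      V[cbind(match(d$y_mm, ys), match(d$r_mm, rs))] <- d$rate_gy_min
      rates[[.coll_key(e$collimator, e$cup_id)]] <-
        list(collimator = e$collimator, cup_id = e$cup_id,
             y = ys, r = rs, values = V)
    }
  }
  structure(list(ocr = ocr, rates = rates,
                 distortion = lapply(mf$distortion, as.numeric),
                 cups = stats::setNames(cups, vapply(cups, `[[`, "", "cup_id")),
                 params = mf$params,
                 provenance = mf$provenance),
            class = "kernel_library")
}
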