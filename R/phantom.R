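#' @importFrom stats rnorm sd setNames qnorm pt
#' @importFrom utils write.csv read.csv modifyList
NULL

stop_nemaiq <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("nemaiq_", class), "nemaiq_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Isotope description
#'
#' Physical constants of a positron emitter as they matter for image
#' formation: the half-life (for decay correction between fill and scan time)
#' and the mean positron range in water, which sets the isotope's intrinsic
#' resolution loss. Shipped presets: [ga68()] (68-min half-life, 2.9-mm mean
#' range) and [f18()] (109.8-min half-life, 0.6-mm mean range).
#'
#' @param name Display label.
#' @param half_life Half-life in minutes; must be positive.
#' @param mean_positron_range Mean positron range in water, mm.
#' @return An object of class `isotope_spec`.
#' @export
isotope_spec <- function(name, half_life, mean_positron_range) {
  if (!is.numeric(half_life) || length(half_life) != 1 || !is.finite(half_life) ||
      half_life <= 0) {
    stop_nemaiq("invalid_isotope", "half_life must be a positive number")
  }
  if (mean_positron_range < 0) {
    stop_nemaiq("invalid_isotope", "mean_positron_range must be >= 0")
  }
  structure(list(name = name, half_life = half_life,
                 mean_positron_range = mean_positron_range),
            class = "isotope_spec")
}

#' @rdname isotope_spec
#' @export
ga68 <- function() isotope_spec("Ga-68", 68, 2.9)

#' @rdname isotope_spec
#' @export
f18 <- function() isotope_spec("F-18", 109.8, 0.6)

#' @export
print.isotope_spec <- function(x, ...) {
  cat(sprintf("<isotope %s: T1/2 = %g min, mean positron range = %g mm>\n",
              x$name, x$half_life, x$mean_positron_range))
  invisible(x)
}

#' NEMA IEC body phantom geometry
#'
#' Returns the canonical description of the NEMA IEC image-quality phantom
#' used throughout the package: six fillable spheres of inner diameter 37,
#' 28, 22, 17, 13 and 10 mm with centres coplanar on a 114.4-mm-diameter
#' ring at 60 degree spacing (the standard physical layout), a cylindrical
#' low-density lung insert on the axis, and an elliptical-cylinder body
#' outline (300 x 230 mm axes, 180 mm axial length) approximating the torso
#' shell. The phantom frame has its origin at the ring/lung centre, x lateral,
#' y anteroposterior, z axial; the sphere plane is z = 0.
#'
#' @param sphere_diameters Inner sphere diameters in mm, largest first.
#' @param ring_diameter Diameter of the circle the sphere centres sit on (mm).
#' @param body_half_axes Half-axes of the elliptical body cross-section (mm).
#' @param body_length Axial interior length of the phantom (mm).
#' @param lung_radius Radius of the central lung insert (mm); the insert runs
#'   the full axial length and contains zero activity.
#' @return An object of class `nema_phantom` with elements `spheres` (a
#'   data frame with `diameter`, `cx`, `cy`, `cz`), `body`, `lung`.
#' @export
nema_phantom <- function(sphere_diameters = c(37, 28, 22, 17, 13, 10),
                         ring_diameter = 114.4,
                         body_half_axes = c(150, 115),
                         body_length = 180,
                         lung_radius = 25) {
  stopifnot(all(sphere_diameters > 0), ring_diameter > 0,
            all(body_half_axes > 0), body_length > 0, lung_radius > 0)
  d <- sort(sphere_diameters, decreasing = TRUE)
  ang <- (seq_along(d) - 1) * 2 * pi / length(d)
  r <- ring_diameter / 2
  spheres <- data.frame(
    diameter = d,
    cx = round(r * cos(ang), 10),
    cy = round(r * sin(ang), 10),
    cz = 0
  )
  ph <- structure(list(spheres = spheres,
                       body = list(half_axes = body_half_axes, length = body_length),
                       lung = list(radius = lung_radius, length = body_length)),
                  class = "nema_phantom")
  ov <- .sphere_overlaps(ph)
  if (any(ov)) stop_nemaiq("geometry", "sphere volumes overlap each other or the lung insert")
  ph
}

.sphere_overlaps <- function(ph) {
  s <- ph$spheres
  n <- nrow(s)
  bad <- logical(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dd <- sqrt((s$cx[i] - s$cx[j])^2 + (s$cy[i] - s$cy[j])^2 + (s$cz[i] - s$cz[j])^2)
      bad <- c(bad, dd < (s$diameter[i] + s$diameter[j]) / 2)
    }
  }
  ring_r <- sqrt(s$cx^2 + s$cy^2)
  bad <- c(bad, ring_r - s$diameter / 2 < ph$lung$radius)
  bad
}

#' @export
print.nema_phantom <- function(x, ...) {
  cat("<NEMA IEC body phantom>\n")
  cat(sprintf("  spheres (mm): %s on a %.1f-mm ring\n",
              paste(x$spheres$diameter, collapse = ", "),
              2 * sqrt(x$spheres$cx[1]^2 + x$spheres$cy[1]^2)))
  cat(sprintf("  body: %g x %g mm half-axes, %g mm long; lung insert r = %g mm\n",
              x$body$half_axes[1], x$body$half_axes[2], x$body$length, x$lung$radius))
  invisible(x)
}

#' Phantom fill description
#'
#' Activity concentrations at fill time for the hot spheres and the warm
#' background, the fill and scan times (minutes, any common clock), the
#' isotope, and an optional residual-activity correction factor applied
#' multiplicatively when concentrations are decay-corrected to scan time.
#'
#' @param sphere_kBq_ml Sphere activity concentration at fill time (kBq/ml).
#' @param background_kBq_ml Background concentration at fill time (kBq/ml).
#' @param fill_time,scan_time Times in minutes on a common clock.
#' @param isotope An [isotope_spec()]; defaults to Gallium-68.
#' @param residual_factor Multiplicative residual-activity correction
#'   (default 1, i.e. no residual).
#' @return An object of class `fill_spec`.
#' @export
fill_spec <- function(sphere_kBq_ml, background_kBq_ml,
                      fill_time = 0, scan_time = 0,
                      isotope = ga68(), residual_factor = 1) {
  if (sphere_kBq_ml < 0 || background_kBq_ml < 0) {
    stop_nemaiq("invalid_fill", "concentrations must be >= 0")
  }
  if (sphere_kBq_ml > 0 && sphere_kBq_ml < background_kBq_ml) {
    stop_nemaiq("invalid_fill",
                "sphere concentration must be >= background for hot-sphere studies")
  }
  structure(list(sphere = sphere_kBq_ml, background = background_kBq_ml,
                 fill_time = fill_time, scan_time = scan_time,
                 isotope = isotope, residual_factor = residual_factor),
            class = "fill_spec")
}

#' @export
print.fill_spec <- function(x, ...) {
  cat(sprintf("<fill: spheres %g kBq/ml, background %g kBq/ml (%s), ratio %s>\n",
              x$sphere, x$background, x$isotope$name,
              if (x$background > 0) sprintf("%.2f:1", x$sphere / x$background) else "undefined"))
  invisible(x)
}

#' Decay-correct an activity concentration
#'
#' Applies radioactive decay over `elapsed` minutes:
#' `concentration * 2^(-elapsed / half_life)`. Negative `elapsed` back-corrects.
#'
#' @param concentration Activity concentration (kBq/ml); vectorised.
#' @param elapsed Elapsed time in minutes.
#' @param isotope An [isotope_spec()].
#' @return Decay-corrected concentration, kBq/ml.
#' @examples
#' decay_correct(10, 68, ga68())  # one Ga-68 half-life -> 5
#' @export
decay_correct <- function(concentration, elapsed, isotope) {
  if (!inherits(isotope, "isotope_spec") || isotope$half_life <= 0) {
    stop_nemaiq("invalid_isotope", "isotope must be an isotope_spec with positive half-life")
  }
  concentration * 2^(-elapsed / isotope$half_life)
}

#' Sphere-to-background fill ratio
#'
#' The ratio of sphere to background activity concentration. Decay cancels
#' because both compartments hold the same isotope.
#'
#' @param fill A [fill_spec()].
#' @return Unitless ratio.
#' @export
fill_ratio <- function(fill) {
  if (fill$background <= 0) stop_nemaiq("undefined_ratio", "background concentration is zero")
  fill$sphere / fill$background
}

#' Concentrations decay-corrected to scan time
#'
#' True sphere and background concentrations at scan time, including the
#' residual-activity factor; these are the `C_dc` / `C_bkg.dc` references of
#' the recovery metrics.
#'
#' @param fill A [fill_spec()].
#' @return Named list with `sphere` and `background` (kBq/ml).
#' @export
fill_at_scan <- function(fill) {
  el <- fill$scan_time - fill$fill_time
  list(sphere = decay_correct(fill$sphere, el, fill$isotope) * fill$residual_factor,
       background = decay_correct(fill$background, el, fill$isotope) * fill$residual_factor)
}

#' Reconstruction variant description
#'
#' Labels one reconstruction of an acquisition. `family` is one of
#' `"conventional"` (OSEM/OSEM+TOF), `"psf"` (PSF-modelling reconstruction)
#' or `"bpl"` (Bayesian penalised likelihood, beta-regularised). The Gaussian
#' post-filter width `gaussian_fwhm` applies to conventional and psf;
#' the penalisation factor `beta` applies to bpl only.
#'
#' @param family `"conventional"`, `"psf"` or `"bpl"`.
#' @param gaussian_fwhm Post-reconstruction Gaussian filter FWHM, mm (>= 0).
#' @param beta Penalisation factor (bpl only), >= 0.
#' @param label Display label; derived from the parameters if omitted.
#' @return An object of class `recon_config`.
#' @examples
#' recon_config("psf", gaussian_fwhm = 6.4)
#' recon_config("bpl", beta = 800)
#' @export
recon_config <- function(family = c("conventional", "psf", "bpl"),
                         gaussian_fwhm = NULL, beta = NULL, label = NULL) {
  family <- match.arg(family)
  if (family == "bpl") {
    if (is.null(beta) || beta < 0) stop_nemaiq("invalid_recon", "bpl requires beta >= 0")
    if (!is.null(gaussian_fwhm)) {
      stop_nemaiq("invalid_recon", "gaussian_fwhm is not used for the bpl family")
    }
    if (is.null(label)) label <- sprintf("BPL_%g", beta)
  } else {
    if (!is.null(beta)) stop_nemaiq("invalid_recon", "beta is only used for the bpl family")
    if (is.null(gaussian_fwhm)) gaussian_fwhm <- 0
    if (gaussian_fwhm < 0) stop_nemaiq("invalid_recon", "gaussian_fwhm must be >= 0")
    if (is.null(label)) {
      label <- sprintf("%s_%g", if (family == "psf") "PSF" else "OSEM", gaussian_fwhm)
    }
  }
  structure(list(family = family, gaussian_fwhm = gaussian_fwhm,
                 beta = beta, label = label),
            class = "recon_config")
}

#' @export
print.recon_config <- function(x, ...) {
  cat(sprintf("<recon %s (family %s)>\n", x$label, x$family))
  invisible(x)
}

#' Default reconstruction grids
#'
#' The parameter grids explored for the advanced reconstructions: Gaussian
#' post-filter widths 2, 4, 5 and 6.4 mm for PSF and penalisation factors
#' 200-1200 for BPL.
#'
#' @return A list of [recon_config()] objects.
#' @export
default_recon_grid <- function() {
  c(lapply(c(2, 4, 5, 6.4), function(w) recon_config("psf", gaussian_fwhm = w)),
    lapply(seq(200, 1200, by = 200), function(b) recon_config("bpl", beta = b)))
}
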