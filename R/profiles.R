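#' Axial slice with the largest mask cross-section
#'
#' Returns the index of the axial slice on which the sphere mask has the
#' largest in-plane area; ties go to the slice nearest the mask centroid.
#'
#' @param mask A [segment_sphere()] mask.
#' @return Integer slice index (third array dimension).
#' @export
largest_slice <- function(mask) {
  areas <- apply(mask$mask, 3, sum)
  if (!any(areas > 0)) stop_nemaiq("invalid_parameter", "mask is empty")
  idx <- which(mask$mask, arr.ind = TRUE)
  zc <- mean(idx[, 3])
  best <- which(areas == max(areas))
  best[which.min(abs(best - zc))]
}

# Bilinear interpolation of a 2D matrix at fractional indices (i, j).
bilinear <- function(m, i, j) {
  i0 <- pmin(pmax(floor(i), 1), nrow(m) - 1)
  j0 <- pmin(pmax(floor(j), 1), ncol(m) - 1)
  fi <- i - i0; fj <- j - j0
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) + m[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j0 + 1)] * (1 - fi) * fj + m[cbind(i0 + 1, j0 + 1)] * fi * fj
}

#' Extract 1D profiles across a sphere
#'
#' Draws `n_profiles` straight lines through the centroid of the mask
#' footprint on the largest-area axial slice, at uniformly spaced angles
#' `k * 180 / n` degrees, sampled by bilinear interpolation every `step` mm
#' and extending one footprint radius beyond the footprint on each side
#' (far enough to catch edge overshoot without crossing the neighbouring
#' ring spheres).
#' Each sample carries an `in_region` flag: whether the voxel containing the
#' sample belongs to the mask footprint.
#'
#' @param img A [pet_image()].
#' @param mask A [segment_sphere()] mask.
#' @param n_profiles Number of profiles (default 6).
#' @param step Sampling step along the line, mm.
#' @param angle_offset Rotation of the whole profile fan, degrees.
#' @return List of `pet_profile` objects, each with `position` (signed mm
#'   from the centroid), `value` (kBq/ml) and `in_region`.
#' @section Errors: if the footprint is under 2 voxels wide across any
#'   profile direction the spatial sampling cannot support a profile and a
#'   `nemaiq_profiles_unavailable` error is raised.
#' @export
extract_profiles <- function(img, mask, n_profiles = 6, step = 0.5,
                             angle_offset = 0) {
  k <- largest_slice(mask)
  foot <- mask$mask[, , k]
  if (sum(foot) < 4) {
    stop_nemaiq("profiles_unavailable",
                "mask footprint too small (%d voxels) for profile extraction", sum(foot))
  }
  plane <- img$voxels[, , k]
  idx <- which(foot, arr.ind = TRUE)
  ci <- mean(idx[, 1]); cj <- mean(idx[, 2])
  sp <- img$spacing[1:2]
  # footprint radius estimate from its area, for the sampling extent
  r_fp <- sqrt(sum(foot) * prod(sp) / pi)
  # one footprint radius beyond the footprint each side: far enough to catch
  # edge overshoot, short enough not to cross neighbouring ring spheres
  extent <- 2 * r_fp
  pos <- seq(-extent, extent, by = step)
  angles <- (seq_len(n_profiles) - 1) * pi / n_profiles + angle_offset * pi / 180
  profiles <- lapply(angles, function(a) {
    di <- cos(a) / sp[1]; dj <- sin(a) / sp[2]
    ii <- ci + pos * di; jj <- cj + pos * dj
    ok <- ii >= 1 & ii <= nrow(plane) & jj >= 1 & jj <= ncol(plane)
    v <- bilinear(plane, ii[ok], jj[ok])
    inr <- foot[cbind(pmin(pmax(round(ii[ok]), 1), nrow(plane)),
                      pmin(pmax(round(jj[ok]), 1), ncol(plane)))]
    structure(list(position = pos[ok], value = v, in_region = inr,
                   angle_deg = a * 180 / pi, slice = k),
              class = "pet_profile")
  })
  widths <- vapply(profiles, function(p) {
    if (!any(p$in_region)) return(0)
    diff(range(p$position[p$in_region]))
  }, numeric(1))
  if (any(widths < 2 * max(sp)) ||
      any(vapply(profiles, function(p) sum(p$in_region), numeric(1)) < 5)) {
    stop_nemaiq("profiles_unavailable",
                "limited spatial resolution: footprint under 2 voxels wide across a profile")
  }
  profiles
}

#' @export
print.pet_profile <- function(x, ...) {
  cat(sprintf("<profile at %.0f deg: %d samples (%d in-region), range [%.3g, %.3g]>\n",
              x$angle_deg, length(x$value), sum(x$in_region),
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.pet_profile <- function(x, ...) {
  graphics::plot(x$position, x$value, type = "l", xlab = "position (mm)",
                 ylab = "kBq/ml", ...)
  graphics::abline(v = range(x$position[x$in_region]), lty = 3)
  invisible(x)
}

# Signed per-side footprint extents of a profile and the valley-region
# selector. The valley (and the flat/concave statistics) are taken over the
# central `valley_frac` of the footprint radius on each side, excluding the
# resolution-driven falloff band near the 50% contour.
valley_samples <- function(profile, valley_frac) {
  inr <- profile$in_region
  if (!any(inr)) return(logical(length(inr)))
  p <- profile$position
  r_neg <- -min(p[inr]); r_pos <- max(p[inr])
  p >= -valley_frac * max(r_neg, 0) & p <= valley_frac * max(r_pos, 0)
}

#' Peak-to-valley ratio of one profile
#'
#' `PTV = max(all samples) / min(valley samples)`, where the valley region is
#' the central `valley_frac` of the in-region footprint (the band near the
#' 50% contour is excluded so resolution falloff is not mistaken for a
#' valley). PTV >= 1 whenever defined; values above 1 indicate edge
#' overshoot.
#'
#' @param profile A `pet_profile` from [extract_profiles()].
#' @param valley_frac Fraction of the footprint radius forming the valley
#'   region (default 0.3).
#' @return Unitless PTV.
#' @export
peak_to_valley <- function(profile, valley_frac = 0.3) {
  if (sum(profile$in_region) < 5) {
    stop_nemaiq("profiles_unavailable", "need at least 5 in-region samples")
  }
  vs <- valley_samples(profile, valley_frac)
  valley <- min(profile$value[vs])
  if (valley <= 0) stop_nemaiq("undefined_ptv", "valley is non-positive")
  max(profile$value) / valley
}

#' Classify the cross-sphere surface shape
#'
#' Classifies a sphere's profile set as `"flat"` (no structure in the valley
#' region: max/min ratio below `flat_tol`), `"concave"` (the profile peaks
#' near the footprint edge with a lower interior valley, i.e. genuine edge
#' overshoot), `"conical"` (a partial-volume dome peaking centrally, for
#' which a PTV is not meaningful) or `"undefined"`. Majority vote over the
#' profiles; flat is tested first so that heavily smoothed, artifact-free
#' spheres (whose maximum sits anywhere on the plateau) are not mistaken for
#' domes.
#'
#' @param profiles List of `pet_profile`s for one sphere.
#' @param valley_frac See [peak_to_valley()].
#' @param flat_tol Peak-to-valley ratio below which a profile is flat
#'   (default 1.02).
#' @param edge_band Fraction of the footprint radius adjoining the edge
#'   within which the global maximum must fall for a concave call
#'   (default 0.5).
#' @param central_frac Central footprint fraction in which the maximum of a
#'   conical profile falls (default 0.3).
#' @return Character scalar: `"flat"`, `"concave"`, `"conical"` or
#'   `"undefined"`.
#' @export
classify_shape <- function(profiles, valley_frac = 0.3, flat_tol = 1.02,
                           edge_band = 0.5, central_frac = 0.3) {
  votes <- vapply(profiles, function(p) {
    vs <- valley_samples(p, valley_frac)
    if (!any(vs)) return("undefined")
    valley <- min(p$value[vs])
    if (valley <= 0) return("undefined")
    inr <- p$in_region
    r_fp <- max(abs(p$position[inr]))
    imax <- which.max(p$value)
    rel_max <- abs(p$position[imax]) / r_fp
    if (max(p$value) / valley < flat_tol) return("flat")
    if (rel_max >= 1 - edge_band) return("concave")
    if (rel_max <= central_frac) return("conical")
    "undefined"
  }, character(1))
  tab <- sort(table(votes), decreasing = TRUE)
  if (tab[1] > length(profiles) / 2) names(tab)[1] else "undefined"
}

#' Mean peak-to-valley ratio over a sphere's profiles
#'
#' Classifies the shape first; a numeric PTV (mean and SD over the profiles)
#' is reported only for concave and flat shapes. For conical or undefined
#' shapes the PTV is flagged not measurable, mirroring how small spheres
#' behave under partial volume.
#'
#' @param profiles List of `pet_profile`s for one sphere.
#' @param valley_frac,flat_tol,edge_band,central_frac See [classify_shape()].
#' @return Object of class `ptv_result` with `mean`, `sd`, `per_profile`,
#'   `shape` and `measurable`.
#' @export
mean_ptv <- function(profiles, valley_frac = 0.3, flat_tol = 1.02,
                     edge_band = 0.5, central_frac = 0.3) {
  shape <- classify_shape(profiles, valley_frac, flat_tol, edge_band, central_frac)
  if (!shape %in% c("concave", "flat")) {
    return(structure(list(mean = NA_real_, sd = NA_real_, per_profile = NULL,
                          shape = shape, measurable = FALSE),
                     class = "ptv_result"))
  }
  ptvs <- vapply(profiles, peak_to_valley, numeric(1), valley_frac = valley_frac)
  structure(list(mean = mean(ptvs), sd = sd(ptvs), per_profile = ptvs,
                 shape = shape, measurable = TRUE),
            class = "ptv_result")
}

#' @export
print.ptv_result <- function(x, ...) {
  if (x$measurable) {
    cat(sprintf("<ptv_result: %.3f +/- %.3f (%s)>\n", x$mean, x$sd, x$shape))
  } else {
    cat(sprintf("<ptv_result: not measurable (%s surface)>\n", x$shape))
  }
  invisible(x)
}

#' Surface-plot height field for one sphere
#'
#' The in-plane value grid over the mask footprint's bounding box (plus a
#' one-voxel margin) on the given slice, for surface plots and reports.
#'
#' @param img A [pet_image()].
#' @param mask A [segment_sphere()] mask.
#' @param slice Axial slice index; defaults to [largest_slice()].
#' @return Numeric matrix with `x_mm`/`y_mm` attributes.
#' @export
surface_data <- function(img, mask, slice = NULL) {
  if (is.null(slice)) slice <- largest_slice(mask)
  foot <- mask$mask[, , slice]
  idx <- which(foot, arr.ind = TRUE)
  if (!nrow(idx)) stop_nemaiq("invalid_parameter", "mask footprint empty on that slice")
  lo <- pmax(apply(idx, 2, min) - 1, 1)
  hi <- pmin(apply(idx, 2, max) + 1, dim(foot))
  m <- img$voxels[lo[1]:hi[1], lo[2]:hi[2], slice]
  attr(m, "x_mm") <- voxel_coords(img, 1)[lo[1]:hi[1]]
  attr(m, "y_mm") <- voxel_coords(img, 2)[lo[2]:hi[2]]
  m
}
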