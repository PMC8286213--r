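#' Recovery coefficient
#'
#' `RC = C_m / C_dc`: measured over true activity concentration.
#'
#' @param c_m Measured concentration (kBq/ml).
#' @param c_dc True (decay/residual-corrected) concentration (kBq/ml), > 0.
#' @return Unitless RC; vectorised over `c_m`.
#' @export
recovery_coefficient <- function(c_m, c_dc) {
  if (any(c_dc <= 0)) stop_nemaiq("invalid_reference", "C_dc must be > 0")
  c_m / c_dc
}

#' Contrast recovery coefficient
#'
#' `CRC = (C_m - C_bkg.m) / (C_dc - C_bkg.dc)`: measured contrast normalised
#' by true contrast, which makes acquisitions with different
#' sphere-to-background ratios comparable.
#'
#' @param c_m,c_bkg_m Measured sphere and background concentrations.
#' @param c_dc,c_bkg_dc True sphere and background concentrations.
#' @return Unitless CRC.
#' @export
contrast_recovery_coefficient <- function(c_m, c_bkg_m, c_dc, c_bkg_dc) {
  if (any(c_dc == c_bkg_dc)) {
    stop_nemaiq("invalid_reference", "true contrast C_dc - C_bkg.dc is zero")
  }
  (c_m - c_bkg_m) / (c_dc - c_bkg_dc)
}

#' Background variability
#'
#' The coefficient of variation of the K background-ROI means of one nominal
#' size: `BV_r = sd(C_{r,k}) / mean(C_{r,k})` with the sample (K - 1)
#' denominator. An inter-region noise measure.
#'
#' @param battery A [place_background_battery()] result, or a numeric vector
#'   of ROI means.
#' @param diameter Nominal ROI size in mm (ignored when `battery` is numeric).
#' @return Unitless BV.
#' @export
background_variability <- function(battery, diameter = NULL) {
  means <- if (is.numeric(battery)) battery else battery_means(battery, diameter)
  if (length(means) < 2) stop_nemaiq("insufficient_regions", "need at least 2 ROIs")
  m <- mean(means)
  if (m <= 0) stop_nemaiq("invalid_reference", "grand mean must be > 0")
  sd(means) / m
}

#' Image roughness
#'
#' The within-ROI voxel coefficient of variation
#' `IR_{r,k} = sd(C_{i,r}) / C_{r,k}` (sample I - 1 denominator), reported as
#' the mean over the K ROIs of the size (the per-ROI values and their SD are
#' returned as attributes for diagnostics). An intra-region, pixel-level
#' noise measure.
#'
#' @param battery A [place_background_battery()] result, or a list of per-ROI
#'   voxel-value vectors.
#' @param diameter Nominal ROI size in mm (ignored when `battery` is a list).
#' @return Mean IR over the ROIs, with attributes `per_roi` and `sd`.
#' @export
image_roughness <- function(battery, diameter = NULL) {
  vals <- if (inherits(battery, "region_battery")) {
    battery_values(battery, diameter)
  } else battery
  per <- vapply(vals, function(v) {
    if (length(v) < 2) stop_nemaiq("insufficient_voxels", "ROI has fewer than 2 voxels")
    m <- mean(v)
    if (m <= 0) stop_nemaiq("invalid_reference", "ROI mean must be > 0")
    sd(v) / m
  }, numeric(1))
  structure(mean(per), per_roi = per, sd = sd(per))
}

#' Assemble the image-quality result for one acquisition
#'
#' Computes per-sphere RC and CRC in max/mean/peak flavours and per-size BV
#' and IR from already-segmented inputs. The true references `C_dc` and
#' `C_bkg.dc` are the fill concentrations decay-corrected to scan time; the
#' measured background `C_bkg.m` for CRC is the grand mean of the 37-mm
#' battery ROIs (the largest, most stable size).
#'
#' @param img A [pet_image()].
#' @param masks Sphere masks from [segment_spheres()].
#' @param battery A [place_background_battery()] result, or `NULL` to skip
#'   the background-dependent metrics (CRC, BV, IR).
#' @param fill The [fill_spec()] used.
#' @param peaks Optional list of [find_peak_roi()] results (computed from the
#'   masks if omitted).
#' @return An object of class `iq_result` with data frames `recovery`
#'   (per sphere) and `noise` (per ROI size), plus `meta`.
#' @export
measure_iq <- function(img, masks, battery, fill, peaks = NULL) {
  conc <- fill_at_scan(fill)
  c_dc <- conc$sphere; c_bkg_dc <- conc$background
  if (c_dc <= 0) stop_nemaiq("invalid_reference", "true sphere concentration must be > 0")
  if (is.null(peaks)) peaks <- lapply(masks, function(m) find_peak_roi(img, m))
  has_bkg <- !is.null(battery)
  c_bkg_m <- if (has_bkg) mean(battery_means(battery, max(battery$rois$diameter))) else NA_real_

  rec <- do.call(rbind, lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    v <- img$voxels[m$mask]
    c_max <- max(v); c_mean <- mean(v); c_peak <- peaks[[i]]$mean
    data.frame(
      diameter = m$diameter,
      RC_max = recovery_coefficient(c_max, c_dc),
      RC_mean = recovery_coefficient(c_mean, c_dc),
      RC_peak = recovery_coefficient(c_peak, c_dc),
      CRC_max = if (has_bkg) contrast_recovery_coefficient(c_max, c_bkg_m, c_dc, c_bkg_dc) else NA_real_,
      CRC_mean = if (has_bkg) contrast_recovery_coefficient(c_mean, c_bkg_m, c_dc, c_bkg_dc) else NA_real_,
      CRC_peak = if (has_bkg) contrast_recovery_coefficient(c_peak, c_bkg_m, c_dc, c_bkg_dc) else NA_real_
    )
  }))

  noise <- if (has_bkg) {
    do.call(rbind, lapply(sort(unique(battery$rois$diameter), decreasing = TRUE), function(d) {
      ir <- image_roughness(battery, d)
      data.frame(diameter = d, BV = background_variability(battery, d),
                 IR = as.numeric(ir), IR_sd = attr(ir, "sd"))
    }))
  } else NULL

  structure(list(recovery = rec, noise = noise,
                 meta = list(label = img$meta$label, scanner = img$meta$scanner,
                             seed = img$meta$seed, isotope = fill$isotope$name,
                             c_dc = c_dc, c_bkg_dc = c_bkg_dc, c_bkg_m = c_bkg_m,
                             ir_aggregation = "mean over ROIs")),
            class = "iq_result")
}

#' @export
print.iq_result <- function(x, digits = 3, ...) {
  cat(sprintf("<iq_result%s>\n",
              if (!is.null(x$meta$label)) paste0(" [", x$meta$label, "]") else ""))
  print(cbind(x$recovery[1], round(x$recovery[-1], digits)), row.names = FALSE)
  if (!is.null(x$noise)) {
    cat("noise:\n")
    print(cbind(x$noise[1], round(x$noise[-1], digits)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.iq_result <- function(x, ...) {
  df <- x$recovery
  if (!is.null(x$noise)) df <- merge(df, x$noise, by = "diameter", all.x = TRUE)
  df <- df[order(-df$diameter), ]
  df$label <- x$meta$label %||% NA_character_
  df$scanner <- x$meta$scanner %||% NA_character_
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment, place the battery and measure in one call
#'
#' Convenience wrapper running [segment_spheres()],
#' [place_background_battery()], [find_peak_roi()] and [measure_iq()].
#'
#' @param img A [pet_image()].
#' @param spec A [nema_phantom()].
#' @param fill The [fill_spec()] used.
#' @param battery Logical; set `FALSE` to skip the background battery (and
#'   with it CRC, BV and IR) when only recovery coefficients are needed.
#' @return An `iq_result`.
#' @export
analyse_iq <- function(img, spec, fill, battery = TRUE) {
  masks <- segment_spheres(img, spec)
  bat <- if (battery) place_background_battery(img, spec, masks) else NULL
  measure_iq(img, masks, bat, fill)
}
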