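# 26-connected component of `candidate` (logical array) containing `start`
# (linear index). Frontier-based flood fill, vectorised over the frontier.
connected_component <- function(candidate, start) {
  d <- dim(candidate)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- array(FALSE, d)
  visited[start] <- TRUE
  frontier <- matrix(arrayInd(start, d), ncol = 3)
  while (nrow(frontier) > 0) {
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o) {
      sweep(frontier, 2, offs[o, ], "+")
    }))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    if (!nrow(nb)) break
    lin <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
    keep <- candidate[lin] & !visited[lin]
    lin <- unique(lin[keep])
    if (!length(lin)) break
    visited[lin] <- TRUE
    frontier <- matrix(arrayInd(lin, d), ncol = 3)
  }
  visited
}

#' Segment one sphere with a 50%-of-maximum 3D isocontour
#'
#' Finds the maximum voxel inside a search region around the sphere's nominal
#' position (the nominal sphere dilated to radius `min(3r, r + 18)` mm, which
#' tolerates mis-positioning while keeping the region clear of neighbouring
#' spheres), thresholds at 50% of that maximum, and keeps the 26-connected
#' component of supra-threshold voxels containing the maximum, intersected
#' with the search region.
#'
#' @param img A [pet_image()].
#' @param spec A [nema_phantom()].
#' @param sphere Row index of the sphere in `spec$spheres` (1 = largest).
#' @return An object of class `sphere_mask`: list with `mask` (logical
#'   array), `diameter`, `threshold`, `max_value`, `max_index`, `volume_mm3`.
#' @section Errors: if the mask volume exceeds 8 times the nominal sphere
#'   volume (the contour has merged with the background, as happens at low
#'   sphere-to-background ratios), a `nemaiq_segmentation_failure` error is
#'   raised.
#' @export
segment_sphere <- function(img, spec, sphere) {
  s <- spec$spheres[sphere, ]
  r <- s$diameter / 2
  search_r <- min(3 * r, r + 18)
  xs <- voxel_coords(img, 1); ys <- voxel_coords(img, 2); zs <- voxel_coords(img, 3)
  ix <- which(abs(xs - s$cx) <= search_r)
  iy <- which(abs(ys - s$cy) <= search_r)
  iz <- which(abs(zs - s$cz) <= search_r)
  if (!length(ix) || !length(iy) || !length(iz)) {
    stop_nemaiq("geometry_clipped", "sphere search region lies outside the image grid")
  }
  sub <- img$voxels[ix, iy, iz, drop = FALSE]
  d2 <- outer(outer((xs[ix] - s$cx)^2, (ys[iy] - s$cy)^2, "+"), (zs[iz] - s$cz)^2, "+")
  in_search <- d2 <= search_r^2
  vals <- ifelse(in_search, sub, -Inf)
  mx <- max(vals)
  thr <- 0.5 * mx
  candidate <- in_search & sub >= thr
  # a 50% level set only exists if some active voxel in the region falls
  # below it (the cold lung insert does not count as contrast)
  active <- in_search & sub > 0
  if (all(sub[active] >= thr) || mx <= 0) {
    stop_nemaiq("segmentation_failure",
                "no 50%% level set: the search region has no contrast")
  }
  start <- which.max(ifelse(in_search, sub, -Inf))
  comp <- connected_component(candidate, start)
  vol <- sum(comp) * prod(img$spacing)
  nominal <- 4 / 3 * pi * r^3
  if (vol > 8 * nominal) {
    stop_nemaiq("segmentation_failure",
                "mask volume %.0f mm3 exceeds 8x the nominal sphere volume %.0f mm3 (contrast too low)",
                vol, nominal)
  }
  mask <- array(FALSE, dim(img$voxels))
  mask[ix, iy, iz] <- comp
  mi <- arrayInd(which.max(ifelse(mask, img$voxels, -Inf)), dim(img$voxels))
  structure(list(mask = mask, diameter = s$diameter, centre = c(s$cx, s$cy, s$cz),
                 threshold = thr, max_value = mx, max_index = as.integer(mi),
                 volume_mm3 = vol, spacing = img$spacing),
            class = "sphere_mask")
}

#' @export
print.sphere_mask <- function(x, ...) {
  cat(sprintf("<sphere_mask %g mm: %d voxels, %.0f mm3 (nominal %.0f), max %.3g>\n",
              x$diameter, sum(x$mask), x$volume_mm3,
              4 / 3 * pi * (x$diameter / 2)^3, x$max_value))
  invisible(x)
}

#' Segment all spheres of the phantom
#'
#' @param img A [pet_image()].
#' @param spec A [nema_phantom()].
#' @return Named list of [segment_sphere()] masks (names are diameters).
#' @export
segment_spheres <- function(img, spec) {
  out <- lapply(seq_len(nrow(spec$spheres)), function(i) segment_sphere(img, spec, i))
  names(out) <- as.character(spec$spheres$diameter)
  out
}

#' Place the 360-region background battery
#'
#' Draws six concentric circular background ROIs (diameters equal to the six
#' nominal sphere diameters) at 12 angular positions (30 degree spacing) on
#' each of five axial slices (the sphere plane and +/-10 and +/-20 mm),
#' giving 60 ROIs per size, 360 in total. Each position's centre is placed on
#' a ring of radius 75 mm; if the largest circle there would intersect a
#' sphere mask, the lung insert, or leave the body outline, the radius is
#' shifted deterministically through 85, 65, 95 and 55 mm until it fits.
#'
#' @param img A [pet_image()].
#' @param spec A [nema_phantom()].
#' @param masks List of sphere masks from [segment_spheres()] (used for
#'   collision avoidance); may be `NULL`, in which case nominal spheres
#'   dilated by 2 mm are avoided instead.
#' @param slice_offsets Axial offsets of the five slices, mm.
#' @param ring_radius Primary ring radius, mm.
#' @return An object of class `region_battery`: a data frame `rois` with one
#'   row per ROI (`diameter`, `slice`, `z_mm`, `cx`, `cy`, `mean`, `n_voxels`)
#'   and the per-ROI voxel values in `values`.
#' @export
place_background_battery <- function(img, spec, masks = NULL,
                                     slice_offsets = c(0, -10, 10, -20, 20),
                                     ring_radius = 75) {
  a <- spec$body$half_axes[1]; b <- spec$body$half_axes[2]
  dmax <- max(spec$spheres$diameter)
  xs <- voxel_coords(img, 1); ys <- voxel_coords(img, 2); zs <- voxel_coords(img, 3)
  slices <- vapply(slice_offsets, function(z) which.min(abs(zs - z)), integer(1))
  if (anyDuplicated(slices)) {
    stop_nemaiq("battery_placement", "axial spacing too coarse for five distinct slices")
  }
  angles <- (0:11) * 30 * pi / 180
  radii <- c(ring_radius, ring_radius + 10, ring_radius - 10,
             ring_radius + 20, ring_radius + 30, ring_radius - 20)
  theta <- seq(0, 2 * pi, length.out = 37)[-37]

  # per-slice obstacles: the in-plane cross-section of each sphere's
  # partial-volume shell (nominal radius + half a voxel diagonal), plus the
  # voxel centres of the supplied sphere masks
  half_diag <- sqrt(sum((img$spacing / 2)^2))
  slice_circles <- lapply(slices, function(k) {
    z <- zs[k]
    s <- spec$spheres
    r_shell <- s$diameter / 2 + half_diag + 0.5
    keep <- abs(z - s$cz) < r_shell
    if (!any(keep)) return(NULL)
    cbind(s$cx[keep], s$cy[keep],
          sqrt(r_shell[keep]^2 - (z - s$cz[keep])^2))
  })
  slice_points <- lapply(slices, function(k) {
    if (is.null(masks)) return(NULL)
    pts <- lapply(masks, function(m) {
      sl <- m$mask[, , k]
      if (!any(sl)) return(NULL)
      idx <- which(sl, arr.ind = TRUE)
      cbind(xs[idx[, 1]], ys[idx[, 2]])
    })
    do.call(rbind, pts)
  })

  fits <- function(cx, cy, circles, points) {
    rr <- dmax / 2
    bx <- cx + rr * cos(theta); by <- cy + rr * sin(theta)
    if (any(bx^2 / a^2 + by^2 / b^2 > 1)) return(FALSE)
    if (sqrt(cx^2 + cy^2) - rr < spec$lung$radius) return(FALSE)
    if (!is.null(circles)) {
      dd <- sqrt((circles[, 1] - cx)^2 + (circles[, 2] - cy)^2)
      if (any(dd < rr + circles[, 3])) return(FALSE)
    }
    if (!is.null(points)) {
      dd2 <- (points[, 1] - cx)^2 + (points[, 2] - cy)^2
      if (any(dd2 < (rr + max(img$spacing[1:2]) / 2)^2)) return(FALSE)
    }
    TRUE
  }

  rois <- list(); values <- list(); rn <- 0
  for (si in seq_along(slices)) {
    k <- slices[si]
    plane <- img$voxels[, , k]
    for (ang in angles) {
      placed <- FALSE
      for (R in radii) {
        cx <- R * cos(ang); cy <- R * sin(ang)
        if (fits(cx, cy, slice_circles[[si]], slice_points[[si]])) { placed <- TRUE; break }
      }
      if (!placed) {
        stop_nemaiq("battery_placement",
                    "no collision-free position at angle %.0f deg, slice %d",
                    ang * 180 / pi, k)
      }
      for (d in spec$spheres$diameter) {
        sel <- which(outer((xs - cx)^2, (ys - cy)^2, "+") <= (d / 2)^2)
        v <- plane[sel]
        rn <- rn + 1
        rois[[rn]] <- data.frame(diameter = d, slice = k, z_mm = zs[k],
                                 cx = cx, cy = cy, mean = mean(v),
                                 n_voxels = length(v))
        values[[rn]] <- v
      }
    }
  }
  rois <- do.call(rbind, rois)
  structure(list(rois = rois, values = values, spacing = img$spacing),
            class = "region_battery")
}

#' @export
print.region_battery <- function(x, ...) {
  tab <- table(x$rois$diameter)
  cat(sprintf("<region_battery: %d ROIs (%s per size), grand mean %.3g kBq/ml>\n",
              nrow(x$rois), paste(unique(tab), collapse = "/"), mean(x$rois$mean)))
  invisible(x)
}

#' Battery ROI means or voxel values for one size
#'
#' @param battery A [place_background_battery()] result.
#' @param diameter Nominal ROI diameter, mm.
#' @return `battery_means`: numeric vector of the K ROI means.
#'   `battery_values`: list of per-ROI voxel-value vectors.
#' @export
battery_means <- function(battery, diameter) {
  battery$rois$mean[battery$rois$diameter == diameter]
}

#' @rdname battery_means
#' @export
battery_values <- function(battery, diameter) {
  battery$values[battery$rois$diameter == diameter]
}

#' Locate the floating 1-cm3 peak sphere
#'
#' Among candidate centres (all voxel centres within the sphere mask dilated
#' by one voxel), returns the 1-cm3 spherical neighbourhood (radius about
#' 6.2 mm, snapped to the voxel grid so the enclosed voxel volume is as close
#' as possible to 1000 mm3) with the highest mean value. The peak sphere may
#' extend outside the segmented mask. Ties are broken by the lowest (z, y, x)
#' candidate index.
#'
#' @param img A [pet_image()].
#' @param mask A [segment_sphere()] mask.
#' @return List of class `peak_roi` with `centre` (mm), `radius`, `mean`,
#'   `volume_mm3`.
#' @export
find_peak_roi <- function(img, mask) {
  if (!any(mask$mask)) stop_nemaiq("invalid_parameter", "mask is empty")
  sp <- img$spacing
  vv <- prod(sp)
  # kernel: voxel offsets within radius; pick radius so volume is closest to 1 cm3
  rad_grid <- seq(5.4, 7.4, by = 0.02)
  best <- NULL
  off_r <- ceiling(7.4 / sp)
  og <- expand.grid(dx = -off_r[1]:off_r[1], dy = -off_r[2]:off_r[2], dz = -off_r[3]:off_r[3])
  od2 <- (og$dx * sp[1])^2 + (og$dy * sp[2])^2 + (og$dz * sp[3])^2
  cnts <- vapply(rad_grid, function(r) sum(od2 <= r^2), numeric(1))
  ibest <- which.min(abs(cnts * vv - 1000))
  radius <- rad_grid[ibest]
  keep <- od2 <= radius^2
  offs <- as.matrix(og[keep, ])
  n_in <- sum(keep)

  d <- dim(img$voxels)
  idx <- which(mask$mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1 - off_r, 1)
  hi <- pmin(apply(idx, 2, max) + 1 + off_r, d)
  sub <- img$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  acc <- array(0, ds)
  cov <- array(0, ds)
  for (o in seq_len(nrow(offs))) {
    sx <- offs[o, 1]; sy <- offs[o, 2]; sz <- offs[o, 3]
    tx <- max(1, 1 - sx):min(ds[1], ds[1] - sx)
    ty <- max(1, 1 - sy):min(ds[2], ds[2] - sy)
    tz <- max(1, 1 - sz):min(ds[3], ds[3] - sz)
    acc[tx, ty, tz] <- acc[tx, ty, tz] + sub[tx + sx, ty + sy, tz + sz]
    cov[tx, ty, tz] <- cov[tx, ty, tz] + 1
  }
  means <- ifelse(cov == n_in, acc / n_in, -Inf) # only fully covered centres

  # candidates: mask dilated by one voxel, shifted into sub coordinates
  cand <- array(FALSE, ds)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    ii <- cbind(idx[, 1] + dx - lo[1] + 1, idx[, 2] + dy - lo[2] + 1,
                idx[, 3] + dz - lo[3] + 1)
    ok <- ii[, 1] >= 1 & ii[, 1] <= ds[1] & ii[, 2] >= 1 & ii[, 2] <= ds[2] &
      ii[, 3] >= 1 & ii[, 3] <= ds[3]
    cand[ii[ok, , drop = FALSE]] <- TRUE
  }
  ci <- which(cand, arr.ind = TRUE)
  ord <- order(ci[, 3], ci[, 2], ci[, 1]) # lowest (z, y, x) wins residual ties
  ci <- ci[ord, , drop = FALSE]
  cm <- means[ci]
  tied <- which(cm >= max(cm) - 1e-12 * abs(max(cm)))
  # among exactly tied means prefer the hottest centre voxel, then (z, y, x)
  best <- tied[which.max(sub[ci[tied, , drop = FALSE]])]
  ctr_idx <- unname(ci[best, ]) + lo - 1
  centre <- unname(img$origin + (ctr_idx - 1) * sp)
  structure(list(centre = centre, radius = radius, mean = cm[best],
                 volume_mm3 = n_in * vv),
            class = "peak_roi")
}

#' @export
print.peak_roi <- function(x, ...) {
  cat(sprintf("<peak_roi: mean %.3g kBq/ml, r = %.2f mm (%.0f mm3) at (%.1f, %.1f, %.1f)>\n",
              x$mean, x$radius, x$volume_mm3, x$centre[1], x$centre[2], x$centre[3]))
  invisible(x)
}
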