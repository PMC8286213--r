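# Shared lazily-built fixtures, cached across test files. Everything is
# generated in code at test time; the cache only avoids recomputing the same
# deterministic image chains.
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, force(expr), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

fx_phantom <- function() fx("phantom", nema_phantom())
fx_fill <- function() fx("fill", fill_spec(19.9, 2.4))

# noiseless partial-volume rasterisation at 2-mm voxels
fx_raster2 <- function() {
  fx("raster2", rasterize_phantom(fx_phantom(), fx_fill(), spacing = c(2, 2, 2)))
}

# rasterised + resolution-blurred (Ga-68 positron range + 4.5-mm PSF)
fx_base2 <- function() {
  fx("base2", resolution_blur(fx_raster2(), ga68(), 4.5))
}

fx_masks_raster2 <- function() {
  fx("masks_raster2", segment_spheres(fx_raster2(), fx_phantom()))
}

fx_battery_raster2 <- function() {
  fx("battery_raster2",
     place_background_battery(fx_raster2(), fx_phantom(), fx_masks_raster2()))
}

# noiseless edge-enhanced PSF-family image at a given post-filter width,
# default simulator edge settings
fx_psf_img <- function(w) {
  fx(paste0("psf_w", w),
     post_filter(edge_enhance(fx_base2(), 0.85, 10), w))
}

fx_bpl_img <- function(beta) {
  fx(paste0("bpl_b", beta),
     post_filter(edge_enhance(fx_base2(), nemaiq:::bpl_alpha(0.85, beta)),
                 nemaiq:::bpl_smoothing(beta)))
}

# a synthetic radially symmetric slice image (hot disc in warm background),
# used for profile symmetry/rotation properties
fx_radial_image <- function() {
  fx("radial", {
    n <- 81
    xs <- seq(-40, 40, length.out = n)
    r2 <- outer(xs^2, xs^2, "+")
    plane <- 2.4 + 17.5 / (1 + exp((sqrt(r2) - 15) / 1.5))
    vox <- array(rep(plane, 5), c(n, n, 5))
    pet_image(vox, c(1, 1, 1), origin = c(-40, -40, -2))
  })
}

# independent naive double-loop implementations of the two noise metrics,
# used as oracles against the vectorised package code
naive_bv <- function(roi_means) {
  K <- length(roi_means)
  cbar <- sum(roi_means) / K
  ss <- 0
  for (k in seq_len(K)) ss <- ss + (roi_means[k] - cbar)^2
  sqrt(ss / (K - 1)) / cbar
}

naive_ir <- function(roi_values) {
  irs <- numeric(length(roi_values))
  for (k in seq_along(roi_values)) {
    v <- roi_values[[k]]
    m <- sum(v) / length(v)
    ss <- 0
    for (i in seq_along(v)) ss <- ss + (v[i] - m)^2
    irs[k] <- sqrt(ss / (length(v) - 1)) / m
  }
  mean(irs)
}

# random synthetic ROI battery (list of value vectors) for oracle tests
random_battery_values <- function(K = 60, I = 40) {
  lapply(seq_len(K), function(k) stats::runif(I, 1, 4))
}

# minimal iq_result stand-in for aggregation/compliance tests
fake_iq <- function(rc_mean, diameters = c(37, 28, 22, 17, 13, 10)) {
  structure(list(recovery = data.frame(
    diameter = diameters,
    RC_max = rc_mean + 0.1, RC_mean = rc_mean, RC_peak = rc_mean + 0.05),
    noise = NULL, meta = list()), class = "iq_result")
}

# hand-built profile object: flat top `top` over in-region positions, edge
# samples at `peak` outside the region
make_profile <- function(values, positions, in_region, angle = 0) {
  structure(list(position = positions, value = values, in_region = in_region,
                 angle_deg = angle, slice = 1L),
            class = "pet_profile")
}
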