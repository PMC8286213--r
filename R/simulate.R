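#' Scanner profile
#'
#' Encapsulates the per-scanner properties that drive inter-site variation in
#' a multi-centre ensemble: intrinsic PSF width, reconstruction voxel size,
#' a multiplicative calibration bias, the edge-enhancement amplitude its
#' PSF/BPL reconstructions exhibit before smoothing, and the target noise
#' level (coefficient of variation in the background before post-filtering).
#'
#' @param psf_fwhm Scanner point-spread-function FWHM, mm (> 0).
#' @param voxel_spacing Reconstruction voxel spacing, mm (length 3).
#' @param calibration_bias Multiplicative calibration bias (> 0; 1 = exact).
#' @param edge_strength Difference-of-Gaussians sharpening amplitude applied
#'   by the psf/bpl reconstruction families (>= 0).
#' @param noise_level Target background coefficient of variation before the
#'   post-reconstruction filter (>= 0; 0 = noiseless).
#' @param name Display label.
#' @return An object of class `scanner_profile`.
#' @export
scanner_profile <- function(psf_fwhm = 4.5,
                            voxel_spacing = c(2.7, 2.7, 3.3),
                            calibration_bias = 1,
                            edge_strength = 0.85,
                            noise_level = 0.3,
                            name = "scanner") {
  if (psf_fwhm <= 0) stop_nemaiq("invalid_scanner", "psf_fwhm must be > 0")
  if (calibration_bias <= 0) stop_nemaiq("invalid_scanner", "calibration_bias must be > 0")
  if (noise_level < 0) stop_nemaiq("invalid_scanner", "noise_level must be >= 0")
  if (edge_strength < 0) stop_nemaiq("invalid_scanner", "edge_strength must be >= 0")
  structure(list(psf_fwhm = psf_fwhm, voxel_spacing = as.numeric(voxel_spacing),
                 calibration_bias = calibration_bias, edge_strength = edge_strength,
                 noise_level = noise_level, name = name),
            class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("<scanner %s: PSF %g mm, voxels %s mm, bias %.3f, edge %.2f, noise CV %.2f>\n",
              x$name, x$psf_fwhm, paste(x$voxel_spacing, collapse = "x"),
              x$calibration_bias, x$edge_strength, x$noise_level))
  invisible(x)
}

#' Preset scanner profiles
#'
#' Three profiles spanning the voxel-size range of the clinical systems the
#' package emulates (2.7x2.7x3.3, 4.1x4.1x2.0 and 5.5x5.5x3.3 mm
#' reconstruction grids).
#'
#' @return List of [scanner_profile()] objects.
#' @export
scanner_presets <- function() {
  list(
    scanner_profile(psf_fwhm = 4.5, voxel_spacing = c(2.7, 2.7, 3.3), name = "fine-grid"),
    scanner_profile(psf_fwhm = 4.5, voxel_spacing = c(4.1, 4.1, 2.0), name = "mid-grid"),
    scanner_profile(psf_fwhm = 5.0, voxel_spacing = c(5.5, 5.5, 3.3), name = "coarse-grid")
  )
}

# FWHM (mm) of the Gaussian stand-in for the positron-range kernel. The true
# annihilation-point distribution is cusp-shaped; only the relative Ga-68 vs
# F-18 blur matters here, so a Gaussian with FWHM proportional to the mean
# range is used. The constant is exposed for tuning.
positron_fwhm <- function(isotope, range_to_fwhm = 2 * 0.85) {
  range_to_fwhm * isotope$mean_positron_range
}

#' Voxelise the phantom into a ground-truth image
#'
#' Paints the phantom onto a regular voxel grid: each voxel gets
#' `background + (sphere - background) * f` where `f` is the fraction of the
#' voxel inside a sphere (supersampled 3x3x3 for voxels cut by a sphere
#' surface), lung-insert voxels get 0, and voxels outside the body outline
#' get 0. Body and lung membership use the voxel-centre convention.
#'
#' @param spec A [nema_phantom()].
#' @param fill A [fill_spec()]; concentrations are decay-corrected to the
#'   fill's scan time before painting, so the image represents the scan.
#' @param spacing Voxel spacing, mm (scalar or length 3).
#' @param margin Empty margin beyond the body outline, mm (room for blurring).
#' @param bbox Optional list with `lower` and `upper` world coordinates (mm)
#'   restricting the grid to a sub-volume, e.g. around one sphere.
#' @param supersample Sub-divisions per axis for boundary voxels (default 3).
#' @return A [pet_image()].
#' @export
rasterize_phantom <- function(spec, fill, spacing = c(2.7, 2.7, 3.3),
                              margin = 12, bbox = NULL, supersample = 3) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  conc <- fill_at_scan(fill)
  a <- spec$body$half_axes[1]; b <- spec$body$half_axes[2]
  hl <- spec$body$length / 2
  if (is.null(bbox)) {
    lower <- c(-a - margin, -b - margin, -hl - margin)
    upper <- c(a + margin, b + margin, hl + margin)
  } else {
    lower <- bbox$lower; upper <- bbox$upper
  }
  dims <- pmax(2L, ceiling((upper - lower) / spacing))
  origin <- lower + spacing / 2
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  if (is.null(bbox) && (any(dims < 4))) {
    stop_nemaiq("geometry_clipped", "grid too small to contain the body outline")
  }

  # body membership (centre-in), as a 2D in-plane mask times axial extent
  inxy <- outer(xs^2 / a^2, ys^2 / b^2, "+") <= 1
  inz <- abs(zs) <= hl
  vox <- array(0, dims)
  body_plane <- which(inxy)
  bg <- conc$background
  for (k in which(inz)) vox[, , k][body_plane] <- bg

  # lung insert: zero activity on the axis
  lungxy <- which(outer(xs^2, ys^2, "+") <= spec$lung$radius^2 & inxy)
  for (k in which(inz)) vox[, , k][lungxy] <- 0

  # spheres: exact interior fill plus supersampled partial volumes on the shell
  half_diag <- sqrt(sum((spacing / 2)^2))
  sub <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  offs <- as.matrix(expand.grid(sub * spacing[1], sub * spacing[2], sub * spacing[3]))
  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    r <- s$diameter / 2
    ix <- which(abs(xs - s$cx) <= r + half_diag)
    iy <- which(abs(ys - s$cy) <= r + half_diag)
    iz <- which(abs(zs - s$cz) <= r + half_diag)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - s$cx)^2; dy2 <- (ys[iy] - s$cy)^2; dz2 <- (zs[iz] - s$cz)^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    dist <- sqrt(d2)
    frac <- array(0, dim(d2))
    frac[dist <= r - half_diag] <- 1
    shell <- which(abs(dist - r) < half_diag)
    if (length(shell)) {
      sh_idx <- arrayInd(shell, dim(d2))
      px <- xs[ix][sh_idx[, 1]]; py <- ys[iy][sh_idx[, 2]]; pz <- zs[iz][sh_idx[, 3]]
      cnt <- numeric(length(shell))
      for (o in seq_len(nrow(offs))) {
        cnt <- cnt + ((px + offs[o, 1] - s$cx)^2 +
                      (py + offs[o, 2] - s$cy)^2 +
                      (pz + offs[o, 3] - s$cz)^2 <= r^2)
      }
      frac[shell] <- cnt / nrow(offs)
    }
    block <- vox[ix, iy, iz]
    block <- block + (conc$sphere - bg) * frac * (block > 0 | frac > 0)
    vox[ix, iy, iz] <- block
  }

  pet_image(vox, spacing, origin,
            meta = list(fill = fill, stage = "rasterized",
                        sphere_conc = conc$sphere, background_conc = bg))
}

#' Isotope and scanner resolution loss
#'
#' Gaussian blur with effective FWHM `sqrt(psf_fwhm^2 + positron_fwhm^2)`,
#' where the positron-range FWHM is derived from the isotope's mean positron
#' range in water. Total activity is conserved away from the grid edges.
#'
#' @param img A [pet_image()].
#' @param isotope An [isotope_spec()].
#' @param psf_fwhm Scanner PSF FWHM, mm (>= 0).
#' @return Blurred [pet_image()].
#' @export
resolution_blur <- function(img, isotope = ga68(), psf_fwhm = 4.5) {
  if (psf_fwhm < 0) stop_nemaiq("invalid_parameter", "psf_fwhm must be >= 0")
  eff <- sqrt(psf_fwhm^2 + positron_fwhm(isotope)^2)
  out <- img
  out$voxels <- gauss_blur3(img$voxels, eff, img$spacing)
  out$meta$resolution_fwhm <- eff
  out
}

#' Edge enhancement (Gibbs-type overshoot)
#'
#' Emulates the edge artifact of PSF/BPL reconstruction with an unsharp-mask
#' (difference-of-Gaussians) filter: `out = (1 + alpha) * img - alpha *
#' G_wide(img)`, which overshoots at concentration boundaries. `alpha = 0`
#' is the identity. Negative values created by the sharpening are clipped to
#' zero (concentration images are non-negative).
#'
#' @param img A [pet_image()].
#' @param strength Overshoot amplitude alpha (>= 0).
#' @param wide_fwhm FWHM of the wide (surround) Gaussian, mm (default 10).
#' @return Edge-enhanced [pet_image()].
#' @export
edge_enhance <- function(img, strength, wide_fwhm = 10) {
  if (strength < 0) stop_nemaiq("invalid_parameter", "strength must be >= 0")
  if (strength == 0) return(img)
  out <- img
  wide <- gauss_blur3(img$voxels, wide_fwhm, img$spacing)
  out$voxels <- pmax((1 + strength) * img$voxels - strength * wide, 0)
  out$meta$edge_strength <- strength
  out
}

#' Add spatially correlated noise
#'
#' Adds zero-mean Gaussian noise whose voxel standard deviation is
#' `noise_level * sqrt(local_mean * reference)` (so the background CV equals
#' `noise_level`), spatially smoothed by a Gaussian of FWHM
#' `correlation_fwhm` and renormalised to unit marginal variance before
#' scaling, so inter-voxel correlation can be varied without changing the
#' voxel-level noise magnitude. The result is clipped at zero. Identical
#' `seed` and inputs give identical output.
#'
#' @param img A [pet_image()].
#' @param noise_level Target background coefficient of variation (>= 0).
#' @param correlation_fwhm Correlation length of the noise, mm FWHM.
#' @param seed Integer seed for the noise stream.
#' @param reference Reference concentration (kBq/ml); defaults to the
#'   background concentration recorded in the image metadata, falling back to
#'   the mean positive voxel value.
#' @return Noisy [pet_image()].
#' @export
add_noise <- function(img, noise_level, correlation_fwhm = 4, seed = 1,
                      reference = NULL) {
  if (!is.numeric(noise_level) || noise_level < 0) {
    stop_nemaiq("invalid_parameter", "noise_level must be >= 0")
  }
  if (noise_level == 0) return(img)
  if (is.null(reference)) {
    reference <- img$meta$background_conc
    if (is.null(reference)) reference <- mean(img$voxels[img$voxels > 0])
  }
  out <- img
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max),
           kind = "Mersenne-Twister", normal.kind = "Inversion")
  field <- array(rnorm(length(img$voxels)), dim(img$voxels))
  if (correlation_fwhm > 0) {
    field <- gauss_blur3(field, correlation_fwhm, img$spacing)
    field <- field / sd(field)
  }
  sdmap <- noise_level * sqrt(pmax(img$voxels, 0) * reference)
  out$voxels <- pmax(img$voxels + sdmap * field, 0)
  out$meta$noise_level <- noise_level
  out$meta$noise_seed <- seed
  out
}

#' Post-reconstruction Gaussian filter
#'
#' Gaussian smoothing with the stated FWHM; `fwhm = 0` is the identity.
#'
#' @param img A [pet_image()].
#' @param fwhm Filter FWHM, mm (>= 0).
#' @return Smoothed [pet_image()].
#' @export
post_filter <- function(img, fwhm) {
  if (fwhm < 0) stop_nemaiq("invalid_parameter", "fwhm must be >= 0")
  if (fwhm == 0) return(img)
  out <- img
  out$voxels <- gauss_blur3(img$voxels, fwhm, img$spacing)
  out$meta$post_fwhm <- fwhm
  out
}

# Effective edge-enhancement amplitude and internal smoothing of the BPL
# emulation as functions of the penalisation factor. beta0 = 400 so that
# beta = 200 shows strong overshoot/noise and beta >= 800 suppresses both.
# Simulator knobs, not claims about any vendor algorithm.
bpl_alpha <- function(edge_strength, beta, beta0 = 400) edge_strength * exp(-beta / beta0)
bpl_smoothing <- function(beta, beta0 = 400, s_max = 6.4) s_max * (1 - exp(-beta / beta0))

#' Simulate one phantom acquisition
#'
#' Composes the full image-formation chain: rasterise -> resolution blur
#' (scanner PSF + positron range) -> edge enhancement (psf/bpl families
#' only) -> correlated noise -> post-reconstruction smoothing -> calibration
#' bias. For the bpl family the effective edge amplitude decreases and the
#' effective smoothing increases with the penalisation factor beta.
#' Deterministic under a fixed seed.
#'
#' @param spec A [nema_phantom()].
#' @param fill A [fill_spec()].
#' @param scanner A [scanner_profile()].
#' @param recon A [recon_config()].
#' @param seed Integer master seed.
#' @param base Optional precomputed rasterised+blurred image (internal reuse).
#' @return A [pet_image()] with full provenance in `meta`.
#' @export
simulate_acquisition <- function(spec, fill, scanner = scanner_profile(),
                                 recon = recon_config("conventional", 6.4),
                                 seed = 1, base = NULL) {
  if (is.null(base)) {
    img <- rasterize_phantom(spec, fill, scanner$voxel_spacing)
    img <- resolution_blur(img, fill$isotope, scanner$psf_fwhm)
  } else {
    img <- base
  }
  if (recon$family == "psf") {
    img <- edge_enhance(img, scanner$edge_strength)
  } else if (recon$family == "bpl") {
    img <- edge_enhance(img, bpl_alpha(scanner$edge_strength, recon$beta))
  }
  img <- add_noise(img, scanner$noise_level, correlation_fwhm = 4,
                   seed = (seed + 1000003) %% .Machine$integer.max)
  pf <- if (recon$family == "bpl") bpl_smoothing(recon$beta) else recon$gaussian_fwhm
  img <- post_filter(img, pf)
  img$voxels <- img$voxels * scanner$calibration_bias
  img$meta$label <- recon$label
  img$meta$recon <- recon
  img$meta$scanner <- scanner$name
  img$meta$calibration_bias <- scanner$calibration_bias
  img$meta$seed <- seed
  img
}

#' Simulate a multi-scanner ensemble
#'
#' Draws per-scanner profiles around a base profile (calibration bias jitter,
#' PSF-width jitter, optional per-scanner voxel spacings) and simulates one
#' acquisition per scanner. When the drawn non-bias profile of several
#' scanners is identical and noiseless, the pre-bias image is computed once
#' and reused (the bias enters multiplicatively), which changes nothing in
#' the results.
#'
#' @param n_scanners Number of scanners (>= 2).
#' @param spec,fill Phantom and fill.
#' @param base_profile Base [scanner_profile()].
#' @param jitter List with elements `bias_sd`, `psf_sd` (defaults 0) and
#'   optionally `voxel_choices`, a list of spacings sampled per scanner.
#' @param recon A [recon_config()] applied on every scanner.
#' @param seed Integer master seed.
#' @return List with `images` (list of [pet_image()]) and `profiles` (the
#'   drawn [scanner_profile()]s, ground truth for recovery tests).
#' @export
simulate_ensemble <- function(n_scanners, spec = nema_phantom(),
                              fill = fill_spec(19.9, 2.4),
                              base_profile = scanner_profile(),
                              jitter = list(bias_sd = 0.03, psf_sd = 0),
                              recon = recon_config("conventional", 6.4),
                              seed = 1) {
  if (n_scanners < 2) stop_nemaiq("invalid_parameter", "n_scanners must be >= 2")
  bias_sd <- if (is.null(jitter$bias_sd)) 0 else jitter$bias_sd
  psf_sd <- if (is.null(jitter$psf_sd)) 0 else jitter$psf_sd
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max),
           kind = "Mersenne-Twister", normal.kind = "Inversion")
  profiles <- lapply(seq_len(n_scanners), function(i) {
    p <- base_profile
    p$calibration_bias <- base_profile$calibration_bias * max(0.5, 1 + rnorm(1, 0, bias_sd))
    p$psf_fwhm <- max(2, base_profile$psf_fwhm + rnorm(1, 0, psf_sd))
    if (!is.null(jitter$voxel_choices)) {
      p$voxel_spacing <- jitter$voxel_choices[[sample.int(length(jitter$voxel_choices), 1)]]
    }
    p$name <- sprintf("%s-%02d", base_profile$name, i)
    p
  })
  base_cache <- list()
  images <- vector("list", n_scanners)
  for (i in seq_len(n_scanners)) {
    p <- profiles[[i]]
    base <- NULL
    if (p$noise_level == 0) {
      key <- paste(signif(c(p$psf_fwhm, p$voxel_spacing, p$edge_strength), 12),
                   collapse = "|")
      if (!is.null(base_cache[[key]])) {
        base <- base_cache[[key]]
      } else {
        base <- rasterize_phantom(spec, fill, p$voxel_spacing)
        base <- resolution_blur(base, fill$isotope, p$psf_fwhm)
        base_cache[[key]] <- base
      }
    }
    images[[i]] <- simulate_acquisition(spec, fill, p, recon,
                                        seed = (seed + i * 9973) %% .Machine$integer.max,
                                        base = base)
  }
  list(images = images, profiles = profiles)
}
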