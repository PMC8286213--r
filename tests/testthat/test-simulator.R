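test_that("rasterisation reproduces sphere volumes and fill bounds", {
  ph <- fx_phantom(); f <- fx_fill()
  s <- ph$spheres[1, ]
  sub <- rasterize_phantom(ph, f, spacing = 1,
                           bbox = list(lower = c(s$cx - 30, s$cy - 30, -30),
                                       upper = c(s$cx + 30, s$cy + 30, 30)))
  frac <- (sub$voxels - 2.4) / (19.9 - 2.4)
  vol <- sum(frac[frac > 0]) * prod(sub$spacing)
  expect_equal(vol, 4 / 3 * pi * 18.5^3, tolerance = 0.01)  # analytic oracle

  img <- fx_raster2()
  expect_lte(max(img$voxels), 19.9)
  expect_gte(min(img$voxels), 0)

  # zero contrast: constant inside the body, zero in lung/outside
  flat <- rasterize_phantom(ph, fill_spec(2.4, 2.4), spacing = 4)
  expect_setequal(round(unique(as.numeric(flat$voxels)), 12), c(0, 2.4))
})

test_that("resolution blur conserves activity and widens with positron range", {
  img <- fx_raster2()
  ident <- resolution_blur(img, isotope_spec("none", 68, 0), psf_fwhm = 0)
  expect_identical(ident$voxels, img$voxels)

  b <- fx_base2()
  expect_equal(total_activity(b), total_activity(img), tolerance = 1e-3)

  bf <- resolution_blur(img, f18(), 4.5)
  ph <- fx_phantom()
  for (i in c(1, 4, 6)) {
    s <- ph$spheres[i, ]
    near <- function(im) {
      xs <- abs(nemaiq:::voxel_coords(im, 1) - s$cx) <= s$diameter / 2
      ys <- abs(nemaiq:::voxel_coords(im, 2) - s$cy) <= s$diameter / 2
      zs <- abs(nemaiq:::voxel_coords(im, 3) - s$cz) <= s$diameter / 2
      max(im$voxels[xs, ys, zs])
    }
    expect_lt(near(b), near(bf))  # Ga-68 blurs more than F-18
  }
})

test_that("edge enhancement creates an off-centre overshoot; alpha 0 is identity", {
  b <- fx_base2()
  expect_identical(edge_enhance(b, 0)$voxels, b$voxels)

  e <- fx_psf_img(2)
  ph <- fx_phantom(); s <- ph$spheres[1, ]
  m <- segment_sphere(e, ph, 1)
  k <- largest_slice(m)
  plane <- e$voxels[, , k]
  centre_val <- plane[nemaiq:::world_to_index(e, s$cx, 1),
                      nemaiq:::world_to_index(e, s$cy, 2)]
  expect_gt(max(plane[m$mask[, , k]]), centre_val)  # peak off-centre
})

test_that("post-filtering suppresses both PTV and RC_max monotonically", {
  ph <- fx_phantom()
  img2 <- fx_psf_img(2); img64 <- fx_psf_img(6.4)
  expect_identical(post_filter(img2, 0)$voxels, img2$voxels)
  m2 <- segment_sphere(img2, ph, 1); m64 <- segment_sphere(img64, ph, 1)
  expect_lte(max(img64$voxels[m64$mask]), max(img2$voxels[m2$mask]))
  pv2 <- mean_ptv(extract_profiles(img2, m2))
  pv64 <- mean_ptv(extract_profiles(img64, m64))
  expect_lt(pv64$mean, pv2$mean)
})

test_that("noise injection is seeded, level-controlled and calibrated", {
  b <- fx_base2()
  expect_identical(add_noise(b, 0, seed = 1)$voxels, b$voxels)
  n1 <- add_noise(b, 0.3, correlation_fwhm = 4, seed = 7)
  n2 <- add_noise(b, 0.3, correlation_fwhm = 4, seed = 7)
  expect_identical(n1$voxels, n2$voxels)   # bitwise determinism
  n3 <- add_noise(b, 0.3, correlation_fwhm = 4, seed = 8)
  expect_false(identical(n1$voxels, n3$voxels))
  expect_error(add_noise(b, -0.1, seed = 1), class = "nemaiq_invalid_parameter")

  # the default noise level is calibrated so the background IR of the
  # default scanner's 6.4-mm-filtered image sits near 0.10 (within 20%)
  ph <- fx_phantom(); f <- fx_fill()
  bat_c <- NULL
  irs <- vapply(1:3, function(s) {
    img <- simulate_acquisition(ph, f, scanner_profile(),
                                recon_config("conventional", 6.4), seed = s)
    bat <- place_background_battery(img, ph, segment_spheres(img, ph))
    if (s == 1) bat_c <<- bat
    as.numeric(image_roughness(bat, 37))
  }, numeric(1))
  expect_true(all(abs(irs - 0.10) <= 0.02))

  # the two noise metrics decouple: averaging over a large ROI suppresses
  # inter-region variability well below the pixel-level roughness
  expect_lt(background_variability(bat_c, 37),
            as.numeric(image_roughness(bat_c, 37)))
})

test_that("a full acquisition is a pure function of its seed", {
  ph <- fx_phantom(); f <- fx_fill()
  sc <- scanner_profile(voxel_spacing = c(4, 4, 4))
  rc <- recon_config("bpl", beta = 400)
  a <- simulate_acquisition(ph, f, sc, rc, seed = 11)
  b <- simulate_acquisition(ph, f, sc, rc, seed = 11)
  expect_identical(a$voxels, b$voxels)
  expect_equal(a$meta$label, "BPL_400")

  # conventional reconstruction has no edge-enhancement path: flat surface
  sc0 <- scanner_profile(voxel_spacing = c(2, 2, 2), noise_level = 0)
  img <- simulate_acquisition(ph, f, sc0, recon_config("conventional", 6.4), seed = 1)
  m <- segment_sphere(img, ph, 1)
  pv <- mean_ptv(extract_profiles(img, m))
  expect_identical(pv$shape, "flat")
})

test_that("calibration bias propagates multiplicatively to recovery", {
  ph <- fx_phantom(); f <- fx_fill()
  sc1 <- scanner_profile(voxel_spacing = c(2.7, 2.7, 3.3), noise_level = 0)
  sc2 <- sc1; sc2$calibration_bias <- 1.10
  rc <- recon_config("conventional", 5)
  i1 <- simulate_acquisition(ph, f, sc1, rc, seed = 1)
  i2 <- simulate_acquisition(ph, f, sc2, rc, seed = 1)
  expect_equal(i2$voxels, 1.10 * i1$voxels, tolerance = 1e-12)
  bat <- place_background_battery(i2, ph, segment_spheres(i2, ph))
  expect_equal(mean(battery_means(bat, 37)) / 2.4, 1.10, tolerance = 0.005)
})

test_that("ensembles draw per-scanner profiles and reuse shared bases honestly", {
  ph <- fx_phantom(); f <- fx_fill()
  base <- scanner_profile(voxel_spacing = c(4, 4, 4), noise_level = 0)

  # zero jitter: all scanners identical, derived limit width zero
  ens0 <- simulate_ensemble(3, ph, f, base, jitter = list(bias_sd = 0), seed = 5)
  expect_identical(ens0$images[[1]]$voxels, ens0$images[[2]]$voxels)
  expect_identical(ens0$images[[1]]$voxels, ens0$images[[3]]$voxels)

  # memoised path equals the naive per-scanner computation
  ens <- simulate_ensemble(3, ph, f, base, jitter = list(bias_sd = 0.05), seed = 5)
  for (i in 1:3) {
    direct <- simulate_acquisition(ph, f, ens$profiles[[i]],
                                   recon_config("conventional", 6.4),
                                   seed = (5 + i * 9973) %% .Machine$integer.max)
    expect_equal(ens$images[[i]]$voxels, direct$voxels, tolerance = 1e-12)
  }

  # voxel-size presets mirror the fleet's reconstruction grids
  sp <- lapply(scanner_presets(), function(p) p$voxel_spacing)
  expect_true(any(vapply(sp, function(v) v[1] == 2.7, logical(1))))
  expect_true(any(vapply(sp, function(v) v[1] == 4.1, logical(1))))
  expect_true(any(vapply(sp, function(v) v[1] == 5.5, logical(1))))
  expect_error(simulate_ensemble(1, ph, f, base), class = "nemaiq_invalid_parameter")
})
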