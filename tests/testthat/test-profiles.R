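test_that("largest_slice picks the equatorial plane with centroid tie-break", {
  masks <- fx_masks_raster2()
  m37 <- masks[["37"]]
  k <- largest_slice(m37)
  # sphere plane z = 0 on the 2-mm grid
  expect_lt(abs(nemaiq:::voxel_coords(fx_raster2(), 3)[k]), 2)

  # single-slice mask
  single <- m37; single$mask[, , -k] <- FALSE
  expect_equal(largest_slice(single), k)

  # two equal-area slices: the one nearer the centroid wins
  mk <- m37
  mk$mask[] <- FALSE
  mk$mask[10:12, 10:12, 5] <- TRUE   # area 9
  mk$mask[10:12, 10:12, 9] <- TRUE   # area 9
  mk$mask[11, 11, 7:8] <- TRUE       # drags the centroid toward slice 8
  expect_equal(largest_slice(mk), 9)
})

test_that("profiles fan out at 30-degree spacing through the centroid", {
  img <- fx_raster2()
  prs <- extract_profiles(img, fx_masks_raster2()[["37"]])
  expect_length(prs, 6)
  expect_equal(vapply(prs, function(p) p$angle_deg, numeric(1)),
               c(0, 30, 60, 90, 120, 150))
  for (p in prs) {
    expect_true(all(diff(p$position) > 0))
    expect_gte(sum(p$in_region), 5)
  }
})

test_that("a radially symmetric image yields six identical profiles", {
  img <- fx_radial_image()
  mask <- list(mask = array(rep(img$voxels[, , 3] > 11, 5), dim(img$voxels)),
               diameter = 30, spacing = img$spacing)
  class(mask) <- "sphere_mask"
  prs <- extract_profiles(img, mask)
  ptvs <- vapply(prs, peak_to_valley, numeric(1))
  expect_lt(diff(range(ptvs)) / mean(ptvs), 0.01)

  # rotating the fan by 15 degrees changes the mean PTV by < 1%
  prs2 <- extract_profiles(img, mask, angle_offset = 15)
  ptvs2 <- vapply(prs2, peak_to_valley, numeric(1))
  expect_lt(abs(mean(ptvs2) - mean(ptvs)) / mean(ptvs), 0.01)
})

test_that("peak-to-valley follows its definition on hand-built profiles", {
  # in-region values {5,3,4,3,5}, out-of-region edges at 5: PTV = 5/3
  p <- make_profile(values = c(5, 5, 3, 4, 3, 5, 5),
                    positions = seq(-3, 3),
                    in_region = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(peak_to_valley(p, valley_frac = 1), 5 / 3, tolerance = 1e-9)

  # invariant to global positive rescaling
  p2 <- p; p2$value <- 13 * p$value
  expect_equal(peak_to_valley(p2, valley_frac = 1), 5 / 3, tolerance = 1e-12)

  expect_error(peak_to_valley(make_profile(c(1, 2, 1), -1:1, c(TRUE, TRUE, TRUE))),
               class = "nemaiq_profiles_unavailable")
  neg <- make_profile(c(1, -1, 0, -1, 1), -2:2, rep(TRUE, 5))
  expect_error(peak_to_valley(neg, valley_frac = 1), class = "nemaiq_undefined_ptv")
})

test_that("PTV >= 1 on every measurable simulated sphere", {
  ph <- fx_phantom()
  for (w in c(2, 6.4)) {
    img <- fx_psf_img(w)
    for (i in 1:3) {
      prs <- extract_profiles(img, segment_sphere(img, ph, i))
      expect_true(all(vapply(prs, peak_to_valley, numeric(1)) >= 1))
    }
  }
})

test_that("mean PTV aggregates per-profile values with gating by shape", {
  # six flat-top profiles with edge peaks chosen to give known PTVs
  ptv_targets <- c(1.6, 1.7, 1.8, 1.7, 1.6, 1.8)
  prs <- lapply(ptv_targets, function(pt) {
    make_profile(values = c(pt, rep(1, 11), pt),
                 positions = seq(-6, 6),
                 in_region = c(FALSE, rep(TRUE, 11), FALSE))
  })
  res <- mean_ptv(prs)
  expect_true(res$measurable)
  expect_equal(res$mean, 1.70, tolerance = 1e-9)
  expect_equal(res$sd, 0.08944272, tolerance = 1e-6)

  # six identical flat profiles: mean 1, SD 0
  flat <- lapply(1:6, function(i) {
    make_profile(values = c(0.5, rep(2, 11), 0.5), positions = seq(-6, 6),
                 in_region = c(FALSE, rep(TRUE, 11), FALSE))
  })
  res_flat <- mean_ptv(flat)
  expect_identical(res_flat$shape, "flat")
  expect_equal(res_flat$mean, 1)
  expect_equal(res_flat$sd, 0)

  # a partial-volume dome is conical: flagged, no numeric PTV
  dome <- lapply(1:6, function(i) {
    make_profile(values = 2 + 3 * dnorm(seq(-6, 6), 0, 1.5),
                 positions = seq(-6, 6),
                 in_region = abs(seq(-6, 6)) <= 4)
  })
  res_dome <- mean_ptv(dome)
  expect_identical(res_dome$shape, "conical")
  expect_false(res_dome$measurable)
  expect_true(is.na(res_dome$mean))
})

test_that("simulated shapes classify as the physics dictates", {
  ph <- fx_phantom()
  img2 <- fx_psf_img(2)
  expect_identical(classify_shape(extract_profiles(img2, segment_sphere(img2, ph, 1))),
                   "concave")
  img0 <- post_filter(fx_base2(), 6.4)
  expect_identical(classify_shape(extract_profiles(img0, segment_sphere(img0, ph, 1))),
                   "flat")
  img64 <- fx_psf_img(6.4)
  expect_identical(classify_shape(extract_profiles(img64, segment_sphere(img64, ph, 6))),
                   "conical")
})

test_that("profiles are unavailable when resolution cannot support them", {
  ph <- fx_phantom(); f <- fx_fill()
  img <- rasterize_phantom(ph, f, spacing = c(4.1, 4.1, 4.1))
  m <- segment_sphere(img, ph, 6)  # 10-mm sphere at 4.1-mm voxels
  expect_error(extract_profiles(img, m), class = "nemaiq_profiles_unavailable")
})

test_that("surface data covers the footprint bounding box plus margin", {
  img <- fx_raster2()
  m <- fx_masks_raster2()[["28"]]
  k <- largest_slice(m)
  sd_field <- surface_data(img, m, k)
  idx <- which(m$mask[, , k], arr.ind = TRUE)
  expect_equal(dim(sd_field),
               c(diff(range(idx[, 1])) + 3, diff(range(idx[, 2])) + 3))

  # constant slice stays constant; a hot ring peaks on the annulus
  flat <- img; flat$voxels[, , k] <- 5
  expect_true(all(surface_data(flat, m, k) == 5))
  ring <- img
  xs <- nemaiq:::voxel_coords(img, 1); ys <- nemaiq:::voxel_coords(img, 2)
  s28 <- fx_phantom()$spheres[2, ]
  rr <- sqrt(outer((xs - s28$cx)^2, (ys - s28$cy)^2, "+"))
  ring$voxels[, , k] <- exp(-(rr - 12)^2 / 8)
  fld <- ring$voxels[, , k][m$mask[, , k]]
  rads <- rr[m$mask[, , k]]
  expect_gt(abs(rads[which.max(fld)] - 12), -1)  # max lies near the annulus
  expect_lt(abs(rads[which.max(fld)] - 12), 2)
})
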