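test_that("decay correction follows the half-life law", {
  expect_equal(decay_correct(10, 68, ga68()), 5)        # one Ga-68 half-life
  expect_equal(decay_correct(10, 0, ga68()), 10)        # identity at zero time
  expect_equal(decay_correct(2.4, 136, ga68()), 0.6)    # two half-lives
  expect_equal(decay_correct(5, -68, ga68()), 10)       # back-correction

  # multiplicative in elapsed time
  set.seed(42)
  for (i in 1:20) {
    t1 <- runif(1, -50, 150); t2 <- runif(1, -50, 150)
    expect_equal(decay_correct(decay_correct(7.3, t1, ga68()), t2, ga68()),
                 decay_correct(7.3, t1 + t2, ga68()), tolerance = 1e-12)
  }

  bad <- ga68(); bad$half_life <- -1
  expect_error(decay_correct(10, 5, bad), class = "nemaiq_invalid_isotope")
  expect_error(isotope_spec("X", 0, 1), class = "nemaiq_invalid_isotope")
})

test_that("fill ratio divides the two fill concentrations", {
  expect_equal(fill_ratio(fill_spec(19.9, 2.4)), 8.291667, tolerance = 1e-6)
  expect_equal(fill_ratio(fill_spec(4.8, 1.0)), 4.8)
  expect_equal(fill_ratio(fill_spec(0, 2.4)), 0)
  expect_error(fill_ratio(fill_spec(1, 0)), class = "nemaiq_undefined_ratio")

  # decay cancels: the ratio at scan time equals the fill-time ratio
  f <- fill_spec(19.9, 2.4, fill_time = 0, scan_time = 90)
  at_scan <- fill_at_scan(f)
  expect_equal(at_scan$sphere / at_scan$background, fill_ratio(f), tolerance = 1e-12)
})

test_that("default phantom has the six standard spheres on a coplanar ring", {
  ph <- nema_phantom()
  expect_identical(ph$spheres$diameter, c(37, 28, 22, 17, 13, 10))
  expect_true(all(ph$spheres$cz == 0))
  expect_equal(sqrt(ph$spheres$cx^2 + ph$spheres$cy^2), rep(57.2, 6))
  # stable across calls
  expect_identical(nema_phantom()$spheres, ph$spheres)

  # pairwise non-overlap, and clear of the lung insert
  s <- ph$spheres
  for (i in 1:5) for (j in (i + 1):6) {
    d <- sqrt((s$cx[i] - s$cx[j])^2 + (s$cy[i] - s$cy[j])^2)
    expect_gt(d, (s$diameter[i] + s$diameter[j]) / 2)
  }
  expect_true(all(sqrt(s$cx^2 + s$cy^2) - s$diameter / 2 > ph$lung$radius))
  expect_error(nema_phantom(ring_diameter = 20), class = "nemaiq_geometry")
})

test_that("background region volume is near 9.7 litres", {
  # independent numeric integration of the chosen geometry on a 2-mm grid
  ph <- nema_phantom()
  xs <- seq(-150, 150, by = 2); ys <- seq(-115, 115, by = 2)
  inxy <- outer(xs^2 / 150^2, ys^2 / 115^2, "+") <= 1
  lung <- outer(xs^2, ys^2, "+") <= ph$lung$radius^2
  area <- (sum(inxy) - sum(lung & inxy)) * 4        # mm^2
  vol <- area * 180 - sum(4 / 3 * pi * (ph$spheres$diameter / 2)^3)
  expect_equal(vol / 1e6, 9.7, tolerance = 0.10)    # litres, +/- 10%
})

test_that("reconstruction configs enforce family-specific parameters", {
  expect_equal(recon_config("psf", gaussian_fwhm = 6.4)$label, "PSF_6.4")
  expect_equal(recon_config("bpl", beta = 800)$label, "BPL_800")
  expect_equal(recon_config("conventional", gaussian_fwhm = 5)$label, "OSEM_5")
  expect_error(recon_config("bpl"), class = "nemaiq_invalid_recon")
  expect_error(recon_config("psf", gaussian_fwhm = 2, beta = 400),
               class = "nemaiq_invalid_recon")
  expect_error(recon_config("bpl", beta = 400, gaussian_fwhm = 2),
               class = "nemaiq_invalid_recon")
  grid <- default_recon_grid()
  expect_length(grid, 10)
  expect_setequal(vapply(grid[5:10], function(r) r$beta, numeric(1)),
                  seq(200, 1200, by = 200))
})

test_that("phantom, fill and recon survive a YAML round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  ph <- nema_phantom()
  f <- fill_spec(19.9, 2.4, fill_time = 10, scan_time = 55, residual_factor = 0.98)
  rc <- recon_config("bpl", beta = 600)
  write_phantom_config(ph, path, fill = f, recon = rc)
  back <- read_phantom_config(path)
  expect_equal(back$spec$spheres, ph$spheres)
  expect_equal(back$spec$body$half_axes, ph$body$half_axes)
  expect_equal(back$fill$sphere, 19.9)
  expect_equal(back$fill$isotope$half_life, 68)
  expect_equal(back$fill$residual_factor, 0.98)
  expect_equal(back$recon$label, "BPL_600")
  expect_equal(back$recon$beta, 600)
})
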