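## Minimal cube construction for controlled pixel values.
two_band_cube <- function(red, nir, extra = NULL) {
  ## wavelengths inside the red / NIR windows plus optional extra bands
  wl <- c(670, 830)
  refl <- cbind(red, nir)
  if (!is.null(extra)) {
    wl <- c(wl, seq(1000, 1000 + 10 * (ncol(extra) - 1), by = 10))
    refl <- cbind(refl, extra)
  }
  n <- nrow(refl)
  plot_cube(refl, wl, nrow = n, ncol = 1)
}

test_that("band filtering removes exactly the prescribed wavelengths", {
  wl <- seq(384, 2512, by = 5)            # 426 bands
  cube <- plot_cube(matrix(0.3, 4, length(wl)), wl, nrow = 2, ncol = 2)
  filtered <- filter_bands(cube)

  ## independent per-rule count
  keep_count <- 0
  for (w in wl) {
    bad <- (w >= 1340 && w <= 1445) || (w >= 1790 && w <= 1955) ||
      w <= 400 || w >= 2450
    if (!bad) keep_count <- keep_count + 1
  }
  expect_length(filtered$wavelength, keep_count)
  expect_false(1340 %in% filtered$wavelength)   # closed interval boundary
  expect_false(1445 %in% filtered$wavelength)
  expect_false(400 %in% filtered$wavelength)
  expect_true(all(diff(filtered$wavelength) > 0))

  ## untouched grid passes through
  wl2 <- seq(500, 900, by = 10)
  cube2 <- plot_cube(matrix(0.3, 4, length(wl2)), wl2, nrow = 2, ncol = 2)
  expect_equal(filter_bands(cube2)$wavelength, wl2)

  wl3 <- seq(1340, 1440, by = 10)
  cube3 <- plot_cube(matrix(0.3, 4, length(wl3)), wl3, nrow = 2, ncol = 2)
  expect_error(filter_bands(cube3), "no bands remain")
})

test_that("NDVI masking applies class thresholds with boundary kept", {
  ## pixels: NDVI = 0.8, 0.0, exactly 0.5, 0.3 (binary-exact values)
  red <- c(0.05, 0.2, 0.125, 0.07)
  nir <- c(0.45, 0.2, 0.375, 0.13)
  cube <- two_band_cube(red, nir)
  expect_equal(cube_ndvi(cube), c(0.8, 0, 0.5, 0.3), tolerance = 1e-12)

  high <- ndvi_mask(cube, "high")
  expect_identical(high$mask, c(TRUE, FALSE, TRUE, FALSE))
  low <- ndvi_mask(cube, "low")
  expect_identical(low$mask, c(TRUE, FALSE, TRUE, TRUE))

  ## idempotent
  expect_identical(ndvi_mask(high, "high")$mask, high$mask)

  cube_nored <- plot_cube(matrix(0.3, 2, 3), c(900, 1000, 1100),
                          nrow = 2, ncol = 1)
  expect_error(cube_ndvi(cube_nored), "window missing")
})

test_that("brightness mask follows Tukey fences and is idempotent", {
  vals <- c(rep(0.30, 10), 0.02)
  cube <- plot_cube(matrix(vals, 11, 5), seq(500, 540, 10),
                    nrow = 11, ncol = 1)
  masked <- brightness_mask(cube)
  expect_identical(which(!masked$mask), 11L)

  ## all equal: IQR = 0, fences collapse, nothing masked
  cube_eq <- plot_cube(matrix(0.25, 8, 5), seq(500, 540, 10),
                       nrow = 8, ncol = 1)
  expect_true(all(brightness_mask(cube_eq)$mask))

  ## symmetric spread within fences: nothing masked
  spread <- seq(0.2, 0.3, length.out = 9)
  q <- quantile(spread, c(0.25, 0.75))
  stopifnot(min(spread) > q[1] - 1.5 * diff(q))
  cube_sp <- plot_cube(matrix(spread, 9, 5), seq(500, 540, 10),
                       nrow = 9, ncol = 1)
  expect_true(all(brightness_mask(cube_sp)$mask))

  ## idempotence through the provenance log
  twice <- brightness_mask(masked)
  expect_identical(twice$mask, masked$mask)
  expect_identical(twice$log, masked$log)

  small <- plot_cube(matrix(c(0.1, 0.5, 0.6), 3, 2), c(500, 510),
                     nrow = 3, ncol = 1, mask = c(TRUE, TRUE, FALSE))
  expect_warning(brightness_mask(small), "fewer than 4")
})

test_that("vector normalization yields unit norms and scale invariance", {
  cube <- plot_cube(rbind(c(3, 4), c(6, 8), c(1, 0)), c(500, 510),
                    nrow = 3, ncol = 1)
  vn <- vector_normalize(cube)
  expect_equal(vn$reflectance[1, ], c(0.6, 0.8))
  expect_equal(vn$reflectance[2, ], c(0.6, 0.8))  # scalar multiple collapses
  expect_equal(sqrt(rowSums(vn$reflectance^2)), rep(1, 3), tolerance = 1e-9)

  zero <- plot_cube(rbind(c(1, 1), c(0, 0)), c(500, 510), nrow = 2, ncol = 1)
  expect_warning(z <- vector_normalize(zero), "zero-norm")
  expect_identical(z$mask, c(TRUE, FALSE))
})

test_that("cleaning pipeline rejects bare plots and keeps vegetated ones", {
  ## all-soil plot: every pixel below any NDVI threshold
  soil <- make_test_cube(n_species = 2, grid = 8, soil_fraction = 0,
                         noise = 0)
  wl <- soil$cube$wavelength
  soil_cube <- plot_cube(matrix(rep(specdiv:::soil_template(wl), each = 64),
                                64), wl, nrow = 8, ncol = 8)
  r <- suppressWarnings(clean_plot_pipeline(soil_cube))
  expect_s3_class(r, "plot_rejection")

  ## clean vegetation plot: no soil, no noise, no shading variation
  veg <- make_test_cube(n_species = 3, grid = 8, soil_fraction = 0, noise = 0,
                        brightness_sd = 0)
  cv <- clean_plot_pipeline(veg$cube)
  expect_s3_class(cv, "plot_cube")
  expect_true(all(cv$mask))
  expect_equal(sqrt(rowSums(valid_pixels(cv)^2)),
               rep(1, sum(cv$mask)), tolerance = 1e-9)
  expect_length(cv$log, 4)   # provenance: every applied filter

  ## 30% soil: soil pixels masked, plot retained
  mixed <- make_test_cube(n_species = 3, grid = 10, soil_fraction = 0.3,
                          noise = 0, seed = 7)
  cm <- clean_plot_pipeline(mixed$cube)
  expect_s3_class(cm, "plot_cube")
  soil_idx <- which(mixed$truth$soil)
  expect_true(all(!cm$mask[soil_idx]))
  expect_gt(mean(cm$mask), 0.5)

  ## masks only ever shrink through the pipeline
  expect_true(all(which(cm$mask) %in% which(mixed$cube$mask)))
})
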