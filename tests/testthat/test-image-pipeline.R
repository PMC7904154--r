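# DN calibration, segmentation, cluster identification, angle mask and
# plot aggregation.

make_test_scene <- function(noise_sd = 0, seed = NULL, rows = 18, cols = 36,
                            f761 = 1.6e-3) {
  wl <- camera_grid()
  mats <- default_materials(wl, f761 = f761)
  lay <- default_scene_layout(rows, cols)
  sc <- make_scene(mats, lay, make_irradiance(), noise_sd = noise_sd,
                   seed = seed)
  list(scene = sc, layout = lay, materials = mats)
}

test_that("calibrate_dn inverts the scene encoding at zero noise", {
  ts <- make_test_scene()
  rc <- calibrate_dn(ts$scene)
  # spot-check: DN=0 -> offset; linear map
  arr <- array(0, dim = c(2, 2, 3))
  rc2 <- calibrate_dn(arr, gain = 0.001, offset = 0.5, wavelength = 1:3)
  expect_equal(rc2$data[1, 1, ], rep(0.5, 3))
  arr[1, 1, ] <- 1000
  rc3 <- calibrate_dn(arr, gain = 0.001, offset = 0, wavelength = 1:3)
  expect_equal(rc3$data[1, 1, ], rep(1, 3))
  expect_error(calibrate_dn(arr, gain = 0, wavelength = 1:3), "positive")
  # round trip against the forward model
  e_cam <- resample_spectrum(make_irradiance(), ts$scene$wavelength)
  px <- which(ts$layout == "shaded_leaf", arr.ind = TRUE)[1, ]
  m <- ts$materials$shaded_leaf
  expect_equal(rc$data[px[1], px[2], ],
               m$illumination * m$reflectance$value * e_cam$value / pi +
                 m$fluorescence$value,
               tolerance = 1e-12)
})

test_that("saturated pixels are flagged, excluded from clustering and aggregation", {
  ts <- make_test_scene()
  sc <- ts$scene
  # force one sunlit pixel to the ceiling in every band
  px <- which(ts$layout == "sunlit_leaf", arr.ind = TRUE)[1, ]
  sc$dn[px[1], px[2], ] <- 4095
  sc$saturated[px[1], px[2]] <- TRUE
  rc <- calibrate_dn(sc)
  cm <- cluster_image(rc, k = 6, seed = 1)
  expect_true(cm$saturated[px[1], px[2]])
  expect_equal(sum(cm$sizes), prod(dim(ts$layout)) - 1)
})

test_that("k-means recovers a noiseless 6-material layout up to permutation", {
  ts <- make_test_scene()
  rc <- calibrate_dn(ts$scene)
  cm <- cluster_image(rc, k = 6, seed = 1)
  expect_equal(label_agreement(ts$layout, cm$labels), 1)
  # two different seeds: identical partition up to label permutation
  cm2 <- cluster_image(rc, k = 6, seed = 99)
  perm_tab <- table(cm$labels, cm2$labels)
  expect_true(all(rowSums(perm_tab > 0) == 1))
  expect_error(cluster_image(rc, k = 7), "distinct")
})

test_that("moderate noise still yields >= 99% pixel agreement", {
  ts <- make_test_scene(noise_sd = 5, seed = 7)
  rc <- calibrate_dn(ts$scene)
  cm <- cluster_image(rc, k = 6, seed = 2)
  expect_gte(label_agreement(ts$layout, cm$labels), 0.99)
})

test_that("white panel is identified by highest mean radiance, size-independent", {
  ts <- make_test_scene()
  rc <- calibrate_dn(ts$scene)
  cm <- cluster_image(rc, k = 6, seed = 1)
  wid <- identify_white_panel(cm)
  px <- which(ts$layout == "white_panel", arr.ind = TRUE)[1, ]
  expect_equal(cm$labels[px[1], px[2]], wid)
  # panel occupies a small fraction of the scene
  expect_lt(mean(ts$layout == "white_panel"), 0.1)
  # tie detection
  cm_tie <- cm
  cm_tie$mean_radiance <- rep(1, 6)
  expect_error(identify_white_panel(cm_tie), "ambiguous")
})

test_that("sunlit-leaf identification applies the NDVI rule and brightness", {
  ts <- make_test_scene()
  rc <- calibrate_dn(ts$scene)
  cm <- cluster_image(rc, k = 6, seed = 1)
  wid <- identify_white_panel(cm)
  refl <- cluster_reflectance(cm, wid, 0.99)
  sid <- identify_sunlit_leaves(cm, refl, wid)
  px <- which(ts$layout == "sunlit_leaf", arr.ind = TRUE)[1, ]
  expect_equal(cm$labels[px[1], px[2]], as.integer(sid))
  # exactly the two leaf clusters pass NDVI > 0.1 (soil ~0.06 is excluded)
  veg <- attr(sid, "vegetation")
  expect_length(veg, 2)
  veg_materials <- vapply(veg, function(j) {
    px <- which(cm$labels == j, arr.ind = TRUE)[1, ]
    ts$layout[px[1], px[2]]
  }, character(1))
  expect_setequal(veg_materials, c("sunlit_leaf", "shaded_leaf"))
  # soil NDVI really is below the threshold
  soil_ndvi <- ndvi(refl[[setdiff(seq_len(6), c(wid, veg))[1]]])
  expect_lt(soil_ndvi, 0.1)
  # three vegetation clusters: strict errors, relaxed takes the brightest
  expect_error(identify_sunlit_leaves(cm, refl, wid, ndvi_threshold = -2),
               "expected exactly 2")
  expect_silent(sid2 <- suppressMessages(
    identify_sunlit_leaves(cm, refl, wid, ndvi_threshold = -2, strict = FALSE)))
  expect_equal(as.integer(sid2), wid_brightest <- order(cm$mean_radiance,
    decreasing = TRUE)[2])  # brightest non-panel cluster
})

test_that("angle mask matches brute-force evaluation of the linear angle map", {
  m <- angle_mask(640, 46.1, 15)
  # independent brute force over all columns
  brute <- vapply(0:639, function(i) {
    ang <- -46.1 + i * (2 * 46.1 / 639)
    abs(ang) <= 15
  }, logical(1))
  expect_equal(m$kept, brute)
  expect_equal(range(m$columns - 1L), c(216L, 423L))  # 0-based indices
  expect_length(m$columns, 208L)
  # symmetry about the center
  expect_equal(m$kept, rev(m$kept))
  # boundary cases
  expect_length(angle_mask(640, 46.1, 46.1)$columns, 640L)
  # keep = 0 keeps only the exact-nadir column (odd channel count has one)
  expect_equal(angle_mask(641, 46.1, 0)$columns, 321L)
  expect_error(angle_mask(640, 46.1, 50), "exceeds")
})

test_that("shrinking the kept half-angle never adds columns", {
  kept_prev <- angle_mask(640, 46.1, 40)$columns
  for (keep in c(30, 20, 15, 8, 2)) {
    cols <- angle_mask(640, 46.1, keep)$columns
    expect_true(all(cols %in% kept_prev))
    kept_prev <- cols
  }
})

test_that("plot mean spectra equal the generating material on noiseless scenes", {
  ts <- make_test_scene()
  rc <- calibrate_dn(ts$scene)
  cm <- cluster_image(rc, k = 6, seed = 1)
  wid <- identify_white_panel(cm)
  refl <- cluster_reflectance(cm, wid, 0.99)
  sid <- identify_sunlit_leaves(cm, refl, wid)
  mask <- angle_mask(n_channels = ncol(ts$layout), half_fov = 46.1,
                     keep_half_angle = 15)
  pm <- plot_mean_spectra(rc, cm, sid, mask, wid, 0.99)
  m <- ts$materials$sunlit_leaf
  e_cam <- resample_spectrum(make_irradiance(), ts$scene$wavelength)
  expect_equal(pm$radiance$value,
               m$reflectance$value * e_cam$value / pi + m$fluorescence$value,
               tolerance = 1e-12)
  # mean reflectance = material reflectance + fluorescence infilling term
  apparent <- m$reflectance$value + pi * m$fluorescence$value / e_cam$value
  expect_equal(pm$reflectance$value, apparent, tolerance = 1e-10)
  expect_equal(pm$ndvi, ndvi(make_spectrum(ts$scene$wavelength, apparent,
                                           "reflectance")),
               tolerance = 1e-10)
  # mismatched mask size errors
  expect_error(plot_mean_spectra(rc, cm, sid, angle_mask(640, 46.1, 15),
                                 wid, 0.99), "columns")
})

test_that("ENVI BIL cubes round-trip", {
  ts <- make_test_scene(rows = 8, cols = 12)
  base <- file.path(tempdir(), "cube_test")
  write_envi(ts$scene, base)
  back <- read_envi(base)
  expect_equal(back$data, ts$scene$dn)
  expect_equal(back$wavelength, ts$scene$wavelength, tolerance = 1e-9)
  unlink(paste0(base, c(".bil", ".hdr")))
})
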