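# FLD / iFLD retrieval, correction-factor estimation and SIF yield.

test_that("plain FLD recovers constant-R, constant-F forward models exactly", {
  # hand example: r/pi = 0.06 sr-1, F = 0.02, E_out = 1.0, E_in = 0.3
  b <- forward_bands(0.06, 0.06, 0.02, 0.02, e_in = 0.3, e_out = 1.0)
  expect_equal(b$l_in, 0.038)
  expect_equal(b$l_out, 0.08)
  expect_equal(fld(b), 0.02, tolerance = 1e-15)
  # no fluorescence -> 0
  b0 <- forward_bands(0.06, 0.06, 0, 0, 0.3, 1.0)
  expect_equal(fld(b0), 0)
  # homogeneity of degree 1 in (E, L)
  bc <- fld_bands(e_in = 0.3 * 3, e_out = 3, l_in = 0.038 * 3, l_out = 0.24)
  expect_equal(fld(bc), 3 * 0.02, tolerance = 1e-12)
  # no contrast
  expect_error(fld(fld_bands(0.5, 0.5 + 1e-12, 0.1, 0.1)), "contrast")
})

test_that("fld_bands enforces its invariants", {
  expect_error(fld_bands(1.0, 0.3, 0.1, 0.1), "exceed")
  expect_error(fld_bands(-0.1, 0.3, 0.1, 0.1), "nonnegative")
})

test_that("iFLD hand example is exact and reduces to FLD at unit factors", {
  # r_in/pi = 0.06, r_out/pi = 0.063 (aR = 1.05), F_in = 0.02,
  # F_out = 0.0204 (aF = 1.02), E_in = 0.3, E_out = 1.0
  b <- forward_bands(0.06, 0.063, 0.02, 0.0204, 0.3, 1.0)
  expect_equal(b$l_in, 0.038)
  expect_equal(b$l_out, 0.0834)
  sif <- ifld(b, correction_factors(1.05, 1.02))
  expect_equal(sif, 0.01488 / 0.744, tolerance = 1e-12)
  expect_equal(sif, 0.02, tolerance = 1e-12)
  # unit factors = plain FLD
  expect_equal(ifld(b, correction_factors(1, 1)), fld(b), tolerance = 1e-15)
  # near-zero denominator carries the value
  expect_error(ifld(b, correction_factors(0.3, 1.0)), "denominator")
  expect_error(correction_factors(-1, 1), "positive")
})

test_that("iFLD with true shape factors is algebraically exact (randomized)", {
  set.seed(314)
  for (i in 1:200) {
    r_in <- runif(1, 0.05, 0.6); r_out <- r_in * runif(1, 0.9, 1.1)
    f_in <- runif(1, 0.001, 0.05); f_out <- f_in * runif(1, 0.9, 1.2)
    e_out <- runif(1, 0.5, 1.5); e_in <- e_out * runif(1, 0.2, 0.6)
    b <- forward_bands(r_in / pi, r_out / pi, f_in, f_out, e_in, e_out)
    cf <- correction_factors(r_out / r_in, f_out / f_in)
    expect_lt(abs(ifld(b, cf) - f_in) / f_in, 1e-10)
  }
})

test_that("estimate_alphas: flat reflectance gives alpha_R = 1", {
  grid <- camera_grid()
  irr <- make_irradiance()
  e_cam <- resample_spectrum(irr, grid)
  # F = 0, flat true reflectance: apparent reflectance is flat
  l <- make_spectrum(grid, 0.5 * e_cam$value / pi, "radiance")
  ret <- retrieve_sif(l, irr)
  expect_equal(ret$alphas$alpha_R, 1, tolerance = 1e-6)
  expect_equal(ret$sif, 0, tolerance = 1e-9)
})

test_that("estimate_alphas: sloping reflectance within 1% of the analytic ratio", {
  grid <- camera_grid()
  irr <- make_irradiance()
  e_cam <- resample_spectrum(irr, grid)
  b_in <- which.min(abs(grid - 761)); b_out <- which.min(abs(grid - 754))
  for (slope in c(-0.004, -0.001, 0.002, 0.004)) {  # per nm
    r <- 0.4 + slope * (grid - 761)
    l <- make_spectrum(grid, r * e_cam$value / pi, "radiance")
    ret <- retrieve_sif(l, irr)
    analytic <- r[b_out] / r[b_in]
    expect_lt(abs(ret$alphas$alpha_R - analytic) / analytic, 0.01)
  }
})

test_that("estimate_alphas rejects misconfigured windows and thin shoulders", {
  grid <- camera_grid()
  irr <- make_irradiance()
  e_cam <- resample_spectrum(irr, grid)
  l <- make_spectrum(grid, 0.5 * e_cam$value / pi, "radiance")
  b <- extract_fld_bands(l, irr)
  app <- make_spectrum(grid, pi * l$value / e_cam$value, "reflectance")
  expect_error(estimate_alphas(app, band_window(750, 768), b), "lambda_out")
  expect_error(estimate_alphas(app, band_window(762, 768), b), "lambda_in")
  # truncated grid: too few shoulder bands on the left
  short <- grid[grid > 756]
  app2 <- make_spectrum(short, rep(0.5, length(short)), "reflectance")
  expect_error(estimate_alphas(app2, band_window(756.1, 768), b), "shoulder")
})

test_that("explicit fluorescence shape sets alpha_F from the shape ratio", {
  grid <- camera_grid()
  irr <- make_irradiance()
  shape <- fluorescence_shape_spectrum(grid)
  e_cam <- resample_spectrum(irr, grid)
  l <- make_spectrum(grid, 0.5 * e_cam$value / pi + 1.6e-3 * shape$value,
                     "radiance")
  ret <- retrieve_sif(l, irr, fluorescence_shape = shape)
  b <- ret$bands
  fs <- resample_spectrum(shape, sort(c(b$lambda_out, b$lambda_in)))
  expect_equal(ret$alphas$alpha_F, fs$value[1] / fs$value[2], tolerance = 1e-12)
  expect_gt(ret$alphas$alpha_F, 1)  # emission declines past its 740 nm peak
})

test_that("when R varies and F is constant, iFLD beats FLD given good alphas", {
  grid <- camera_grid()
  irr <- make_irradiance()
  e_cam <- resample_spectrum(irr, grid)
  flat_shape <- flat_spectrum(1, "radiance")  # constant F: alpha_F = 1
  f0 <- 1.6e-3
  for (slope in c(-0.004, 0.002, 0.004)) {
    r <- 0.4 + slope * (grid - 761)
    l <- make_spectrum(grid, r * e_cam$value / pi + f0, "radiance")
    ret_i <- retrieve_sif(l, irr, fluorescence_shape = flat_shape)
    ret_f <- retrieve_sif(l, irr, method = "fld")
    expect_lte(abs(ret_i$sif - f0), abs(ret_f$sif - f0))
  }
})

test_that("sif_yield follows APAR = PAR * NDVI and its hand example", {
  y <- sif_yield(2.0, 400, 0.8)
  expect_equal(y$apar, 320)
  expect_equal(y$sif_yield, 0.00625)
  expect_equal(sif_yield(0, 400, 0.8)$sif_yield, 0)
  # clipping
  expect_equal(sif_yield(1, 100, 1.3)$fapar, 1)
  expect_error(sif_yield(1, 0, 0.8), "PAR")
  expect_error(sif_yield(1, 100, 0), "APAR")
  # invariants: SIF_yield * APAR = SIF, APAR = PAR * fAPAR
  set.seed(2)
  for (i in 1:20) {
    sif <- runif(1, 0, 0.01); par <- runif(1, 100, 500); nd <- runif(1, 0.2, 0.95)
    y <- sif_yield(sif, par, nd)
    expect_equal(y$sif_yield * y$apar, sif, tolerance = 1e-12)
    expect_equal(y$apar, par * y$fapar, tolerance = 1e-12)
  }
})

test_that("joint rescaling of E and L scales SIF and leaves SIF yield unchanged", {
  grid <- camera_grid()
  irr <- make_irradiance()
  fw <- sifyield:::plot_forward_spectra(6e-6, 0.8, irr, grid)
  base <- retrieve_sif(fw$radiance, irr)
  nd <- ndvi(base$apparent)
  y0 <- sif_yield(base$sif, fw$par, nd)
  for (c0 in c(0.5, 2, 10)) {
    irr_c <- make_spectrum(irr$wavelength, c0 * irr$value, "irradiance")
    l_c <- make_spectrum(grid, c0 * fw$radiance$value, "radiance")
    ret <- retrieve_sif(l_c, irr_c)
    expect_equal(ret$sif, c0 * base$sif, tolerance = 1e-9)
    nd_c <- ndvi(ret$apparent)
    expect_equal(nd_c, nd, tolerance = 1e-12)
    y <- sif_yield(ret$sif, c0 * fw$par, nd_c)
    expect_equal(y$sif_yield, y0$sif_yield, tolerance = 1e-9)
  }
})
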