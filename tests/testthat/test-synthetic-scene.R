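# Synthetic irradiance, scenes, trait links and A/Ci datasets.

test_that("make_irradiance matches its analytic trough", {
  flat <- make_irradiance(line_depth = 0)
  expect_equal(flat$value, rep(1, length(flat$wavelength)))
  # grid chosen to contain the trough center exactly
  irr <- make_irradiance(seq(700, 800, by = 0.5), continuum_level = 1.0,
                         line_depth = 0.7)
  expect_equal(irr$value[which(irr$wavelength == 761)], 0.30, tolerance = 1e-12)
  narrow <- make_irradiance(line_depth = 0.7, line_width = 1)
  i754 <- which.min(abs(narrow$wavelength - 754))
  expect_gte(narrow$value[i754], 0.999)
  # analytic check across the whole support
  expect_equal(narrow$value,
               1 - 0.7 * exp(-(narrow$wavelength - 761)^2 / 2),
               tolerance = 1e-12)
  expect_error(make_irradiance(line_width = 0), "line_width")
  expect_error(make_irradiance(line_depth = 1), "line_depth")
})

test_that("material_spec enforces panel and vegetation invariants", {
  wl <- camera_grid()
  expect_error(material_spec("white_panel",
                             leaf_reflectance_spectrum(wl)), "flat")
  expect_error(
    material_spec("white_panel", flat_spectrum(0.99),
                  fluorescence_shape_spectrum(wl)), "fluoresce")
  expect_error(material_spec("x", flat_spectrum(0.5), illumination = 0),
               "illumination")
  m <- material_spec("shaded_leaf", leaf_reflectance_spectrum(wl),
                     illumination = 0.4)
  expect_equal(sum(m$fluorescence$value), 0)
})

test_that("scene encoding is linear and round-trips at zero noise", {
  wl <- camera_grid()
  mats <- default_materials(wl)
  lay <- default_scene_layout(12, 18)
  irr <- make_irradiance()
  sc <- make_scene(mats, lay, irr, gain = 0.001, offset = 0, noise_sd = 0)
  rc <- calibrate_dn(sc)
  # decode(encode(L)) = L to machine precision
  e_cam <- resample_spectrum(irr, wl)
  for (m in c("white_panel", "sunlit_leaf", "soil")) {
    px <- which(lay == m, arr.ind = TRUE)[1, ]
    spec <- mats[[m]]
    l_expected <- spec$illumination * spec$reflectance$value * e_cam$value / pi +
      spec$fluorescence$value
    expect_equal(rc$data[px[1], px[2], ], l_expected, tolerance = 1e-12)
  }
  # white panel radiance = R_white * E / pi
  px <- which(lay == "white_panel", arr.ind = TRUE)[1, ]
  expect_equal(rc$data[px[1], px[2], ], 0.99 * e_cam$value / pi,
               tolerance = 1e-12)
})

test_that("forward model identity: E = pi gives panel radiance R_white", {
  wl <- camera_grid()
  mats <- default_materials(wl)
  lay <- default_scene_layout(12, 18)
  irr <- make_spectrum(wl, rep(pi, length(wl)), "irradiance")
  sc <- make_scene(mats, lay, irr, gain = 0.001, noise_sd = 0)
  rc <- calibrate_dn(sc)
  px <- which(lay == "white_panel", arr.ind = TRUE)[1, ]
  expect_equal(rc$data[px[1], px[2], ], rep(0.99, length(wl)), tolerance = 1e-12)
})

test_that("DN encoding example: L=1, gain=0.001, offset=0 -> DN=1000", {
  wl <- camera_grid()
  # single material whose radiance is exactly 1 everywhere: r/pi * E = 1
  mats <- list(
    white_panel = material_spec("white_panel", flat_spectrum(0.99)),
    unit = material_spec("unit", flat_spectrum(1 / 2)))
  lay <- matrix(c("white_panel", "unit"), 4, 12)
  irr <- make_spectrum(wl, rep(2 * pi, length(wl)), "irradiance")
  sc <- make_scene(mats, lay, irr, gain = 0.001, offset = 0, noise_sd = 0)
  px <- which(lay == "unit", arr.ind = TRUE)[1, ]
  expect_equal(sc$dn[px[1], px[2], ], rep(1000, length(wl)), tolerance = 1e-9)
})

test_that("fluorescence injection is additive in DN space", {
  wl <- camera_grid()
  irr <- make_irradiance()
  lay <- default_scene_layout(12, 18)
  mats1 <- default_materials(wl, f761 = 1.6e-3)
  mats0 <- default_materials(wl, f761 = 0)
  g <- 9e-5
  s1 <- make_scene(mats1, lay, irr, gain = g, noise_sd = 0)
  s0 <- make_scene(mats0, lay, irr, gain = g, noise_sd = 0)
  diff_dn <- s1$dn - s0$dn
  px <- which(lay == "sunlit_leaf", arr.ind = TRUE)[1, ]
  expect_equal(diff_dn[px[1], px[2], ],
               mats1$sunlit_leaf$fluorescence$value / g, tolerance = 1e-9)
  px0 <- which(lay == "soil", arr.ind = TRUE)[1, ]
  expect_equal(diff_dn[px0[1], px0[2], ], rep(0, length(wl)))
})

test_that("scene errors: unknown material, missing white panel", {
  wl <- camera_grid()
  mats <- default_materials(wl)
  irr <- make_irradiance()
  expect_error(make_scene(mats, matrix("mystery", 4, 12), irr), "unknown")
  expect_error(make_scene(mats, matrix("soil", 4, 12), irr), "white-panel")
})

test_that("the white panel is the brightest material in mean radiance", {
  wl <- camera_grid()
  for (seed in 1:5) {
    irr <- make_irradiance(continuum_level = runif(1, 0.8, 1.2))
    mats <- default_materials(wl, ndvi_leaf = runif(1, 0.6, 0.9))
    e_cam <- resample_spectrum(irr, wl)
    mean_rad <- vapply(mats, function(m)
      mean(m$illumination * m$reflectance$value * e_cam$value / pi +
             m$fluorescence$value), numeric(1))
    expect_identical(names(which.max(mean_rad)), "white_panel")
  }
})

test_that("make_plot_truth respects ranges and the group scheme", {
  tr <- make_plot_truth(seed = 21)
  expect_equal(nrow(tr), 27)
  expect_equal(as.vector(table(tr$group)[c("group1", "group2", "group3")]),
               c(11L, 8L, 8L))
  expect_true(all(tr$Vcmax_true >= 15.98 & tr$Vcmax_true <= 318.96))
  expect_true(all(tr$Jmax_true >= 118.85 & tr$Jmax_true <= 338.70))
  expect_true(all(tr$date[tr$group == "group3"] %in%
                    c("2018-07-24", "2018-07-25")))
})

test_that("make_trait_link: monotone negative link, null link, positivity", {
  tr <- make_plot_truth(seed = 8)
  # negative link: within-group sample correlation negative at every seed
  for (seed in 1:8) {
    tl <- make_trait_link(tr, seed = seed)
    for (g in unique(tl$group)) {
      i <- tl$group == g
      expect_lt(pearson_cc(tl$phiF[i], tl$Jmax_true[i]), 0)
    }
  }
  # zero slope + zero noise: one shared yield per group
  tl0 <- make_trait_link(tr, phiF_model = list(phi0 = c(group1 = 5e-6,
                                                        group2 = 5e-6,
                                                        group3 = 5e-6),
                                               slope = 0, noise_sd = 0,
                                               link = "log"), seed = 1)
  expect_equal(sd(tl0$phiF), 0)
  # two plots, Jmax 120 vs 300, noiseless negative slope: strict order
  tr2 <- data.frame(plot_id = c("a", "b"), group = "group1",
                    date = "2017-07-06", Vcmax_true = c(100, 250),
                    Jmax_true = c(120, 300), Rd_true = 1.2)
  tl2 <- make_trait_link(tr2, phiF_model = list(phi0 = 5e-6, slope = -0.006,
                                                noise_sd = 0, link = "log"),
                         seed = 1)
  expect_gt(tl2$phiF[1], tl2$phiF[2])
  # a linear model driven negative is refused
  expect_error(
    make_trait_link(tr2, phiF_model = list(phi0 = 1e-7, slope = -5e-8,
                                           noise_sd = 0, link = "linear"),
                    seed = 1),
    "non-positive fluorescence")
  # positive slope contradicts the encoded hypothesis
  expect_error(make_trait_link(tr, phiF_model = list(phi0 = 5e-6, slope = 1e-3,
                                                     noise_sd = 0, link = "log")),
               "slope")
})

test_that("zero-noise A/Ci curves reproduce the forward model exactly", {
  tr <- data.frame(plot_id = "p1", Vcmax_true = 120, Jmax_true = 180,
                   Rd_true = 1.2)
  cur <- make_aci_dataset(tr, noise_sd = 0, leaves_per_plot = 1,
                          leaf_jitter_cv = 0, seed = 3)[[1]]
  k <- kinetic_constants()
  gm <- gm_at_temperature(0.3, 0.04, 25)
  # self-consistency: A = FvCB(Ci - A/gm) at every setpoint
  for (i in seq_along(cur$ci)) {
    cc <- cur$ci[i] - cur$a[i] / gm
    expect_equal(cur$a[i], fvcb_assimilation(cc, 120, 180, 1.2, k)$a,
                 tolerance = 1e-8)
  }
  expect_false(cur$no_j_limited)
})

test_that("a curve that is never electron-transport limited is flagged", {
  tr <- data.frame(plot_id = "ssud", Vcmax_true = 40, Jmax_true = 400,
                   Rd_true = 1.0)
  cur <- make_aci_dataset(tr, noise_sd = 0, leaves_per_plot = 1,
                          leaf_jitter_cv = 0, seed = 3)[[1]]
  expect_true(cur$no_j_limited)
})

test_that("make_aci_dataset rejects nonpositive Ci", {
  tr <- data.frame(plot_id = "p1", Vcmax_true = 120, Jmax_true = 180,
                   Rd_true = 1.2)
  expect_error(make_aci_dataset(tr, ci_setpoints = c(-50, 400)), "positive")
})

test_that("simulate-then-refit recovers parameters within 5%", {
  tr <- data.frame(plot_id = "p1", Vcmax_true = 120, Jmax_true = 180,
                   Rd_true = 1.2)
  cur <- make_aci_dataset(tr, noise_sd = 0.3, leaves_per_plot = 1,
                          leaf_jitter_cv = 0, seed = 42)[[1]]
  f <- fit_aci(cur)
  expect_lt(abs(f$vcmax - 120) / 120, 0.05)
  expect_lt(abs(f$jmax - 180) / 180, 0.05)
})
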