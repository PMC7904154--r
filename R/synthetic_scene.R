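# Synthetic inputs with full ground truth: irradiance with an O2-A style
# absorption trough, hyperspectral scenes with known materials and injected
# chlorophyll fluorescence, and A/Ci curves from known FvCB parameters.
#
# Forward-model convention used throughout (Lambertian):
#   L(lambda) = illumination * r(lambda) * E(lambda) / pi + F(lambda)
# with r a reflectance factor, E downwelling irradiance and F fluorescence
# radiance. With F == 0 the apparent reflectance pi * L / E equals r exactly.

#' Default camera wavelength grid
#'
#' 240 bands spanning 400-900 nm, ~2.1 nm sampling (push-broom VNIR camera).
#' @param n_bands number of bands.
#' @param lo,hi grid limits in nm.
#' @export
camera_grid <- function(n_bands = 240, lo = 400, hi = 900)
  seq(lo, hi, length.out = n_bands)

#' Downwelling irradiance with a Fraunhofer-style absorption trough
#'
#' A flat continuum with a Gaussian absorption line, by default the O2-A
#' feature at 761 nm with fractional depth 0.7. At the trough center
#' `E = continuum_level * (1 - line_depth)` exactly.
#'
#' @param wavelengths nm grid; default is the spectrometer grid,
#'   350-1000 nm at 0.35 nm.
#' @param continuum_level continuum irradiance, W m-2 nm-1.
#' @param line_center trough center, nm.
#' @param line_depth fractional depth in \[0, 1).
#' @param line_width Gaussian standard deviation of the trough, nm (> 0).
#' @param noise_sd relative (multiplicative) measurement noise; 0 = none.
#' @param seed RNG seed for the noise term.
#' @return an irradiance spectrum.
#' @export
make_irradiance <- function(wavelengths = seq(350, 1000, by = 0.35),
                            continuum_level = 1.0,
                            line_center = 761, line_depth = 0.7,
                            line_width = 1.5, noise_sd = 0, seed = NULL) {
  if (line_width <= 0) stopf("line_width must be > 0 (got %g)", line_width)
  if (line_depth < 0 || line_depth >= 1)
    stopf("line_depth must lie in [0, 1) (got %g)", line_depth)
  e <- continuum_level *
    (1 - line_depth * exp(-(wavelengths - line_center)^2 / (2 * line_width^2)))
  if (noise_sd > 0)
    e <- with_seed(seed, e * (1 + stats::rnorm(length(e), 0, noise_sd)))
  make_spectrum(wavelengths, pmax(e, 0), "irradiance")
}

#' Scene material specification
#'
#' One scene constituent: reflectance, fluorescence radiance (zero for
#' non-vegetation) and a dimming factor for shaded variants. The white
#' reference panel must be flat, non-fluorescent and fully illuminated.
#'
#' @param name material label, e.g. `"white_panel"`, `"sunlit_leaf"`.
#' @param reflectance reflectance spectrum (values in \[0, 1\]).
#' @param fluorescence fluorescence radiance spectrum on the same grid,
#'   or `NULL` for none.
#' @param illumination scalar in (0, 1\]; fraction of full sun the material
#'   receives (shaded leaves < 1).
#' @export
material_spec <- function(name, reflectance, fluorescence = NULL,
                          illumination = 1) {
  stopifnot(inherits(reflectance, "spectrum"),
            reflectance$kind == "reflectance")
  if (any(reflectance$value > 1 + 1e-12))
    stopf("material '%s' reflectance exceeds 1", name)
  if (is.null(fluorescence))
    fluorescence <- make_spectrum(reflectance$wavelength,
                                  rep(0, length(reflectance$wavelength)),
                                  "radiance")
  stopifnot(inherits(fluorescence, "spectrum"))
  if (!isTRUE(all.equal(fluorescence$wavelength, reflectance$wavelength)))
    stopf("material '%s': fluorescence and reflectance grids differ", name)
  if (any(fluorescence$value < 0))
    stopf("material '%s' has negative fluorescence", name)
  if (illumination <= 0 || illumination > 1)
    stopf("illumination must lie in (0, 1] (got %g)", illumination)
  if (identical(name, "white_panel")) {
    if (any(fluorescence$value != 0))
      stopf("white panel must not fluoresce")
    if (diff(range(reflectance$value)) > 1e-9)
      stopf("white panel reflectance must be spectrally flat")
    if (illumination != 1)
      stopf("white panel is mounted in full sun; illumination must be 1")
  }
  structure(list(name = name, reflectance = reflectance,
                 fluorescence = fluorescence, illumination = illumination),
            class = "material_spec")
}

#' Vegetation-like reflectance with a red edge
#'
#' Low visible reflectance rising through a logistic red edge to a NIR
#' plateau chosen so the analytic NDVI of the plateau/floor pair equals
#' `ndvi_target` (the realized band-window NDVI is within ~1% of it).
#'
#' @param wavelengths nm grid.
#' @param ndvi_target target NDVI in (0, 1).
#' @param r_vis visible (red) reflectance floor.
#' @param red_edge inflection wavelength, nm.
#' @param edge_width logistic scale of the red edge, nm.
#' @export
leaf_reflectance_spectrum <- function(wavelengths, ndvi_target = 0.8,
                                      r_vis = 0.05, red_edge = 715,
                                      edge_width = 10) {
  stopifnot(ndvi_target > 0, ndvi_target < 1)
  r_nir <- r_vis * (1 + ndvi_target) / (1 - ndvi_target)
  r <- r_vis + (r_nir - r_vis) * stats::plogis((wavelengths - red_edge) / edge_width)
  make_spectrum(wavelengths, clamp(r, 0, 1), "reflectance")
}

#' Normalized chlorophyll-fluorescence emission shape
#'
#' A single broad Gaussian far-red emission peak, scaled so the value at
#' `anchor` (the O2-A retrieval wavelength) is exactly 1; multiply by the
#' desired fluorescence radiance at 761 nm to obtain F(lambda). Only the
#' 754/761 nm values matter to the retrieval, so the shape is configurable.
#'
#' @param wavelengths nm grid.
#' @param peak emission peak, nm.
#' @param width Gaussian standard deviation, nm.
#' @param anchor wavelength whose value is normalized to 1.
#' @export
fluorescence_shape_spectrum <- function(wavelengths, peak = 740, width = 35,
                                        anchor = 761) {
  g <- exp(-(wavelengths - peak)^2 / (2 * width^2))
  make_spectrum(wavelengths, g / exp(-(anchor - peak)^2 / (2 * width^2)),
                "radiance")
}

#' Default six-material scene content
#'
#' White reference panel, sunlit and shaded leaves, sunlit and shaded soil,
#' and a dark background — six spectrally distinct clusters, matching the
#' default k of the segmentation stage. Soil NDVI is ~0.06, below the 0.1
#' vegetation threshold.
#'
#' @param wavelengths camera grid (nm).
#' @param r_white panel reflectance (flat).
#' @param ndvi_leaf leaf NDVI target.
#' @param f761 sunlit-leaf fluorescence radiance at 761 nm
#'   (W m-2 sr-1 nm-1); shaded-leaf fluorescence scales with its
#'   illumination factor.
#' @param shaded_illumination dimming factor of the shaded leaf.
#' @return named list of [material_spec()] objects.
#' @export
default_materials <- function(wavelengths = camera_grid(),
                              r_white = 0.99, ndvi_leaf = 0.8,
                              f761 = 1.6e-3, shaded_illumination = 0.4) {
  flat <- function(v) make_spectrum(wavelengths, rep(v, length(wavelengths)),
                                    "reflectance")
  leaf <- leaf_reflectance_spectrum(wavelengths, ndvi_target = ndvi_leaf)
  soil <- make_spectrum(wavelengths,
                        0.15 + 0.10 * (wavelengths - 400) / 500, "reflectance")
  shape <- fluorescence_shape_spectrum(wavelengths)
  fluo <- function(scale)
    make_spectrum(wavelengths, scale * shape$value, "radiance")
  list(
    white_panel = material_spec("white_panel", flat(r_white)),
    sunlit_leaf = material_spec("sunlit_leaf", leaf, fluo(f761)),
    shaded_leaf = material_spec("shaded_leaf", leaf,
                                fluo(f761 * shaded_illumination),
                                illumination = shaded_illumination),
    soil        = material_spec("soil", soil),
    shaded_soil = material_spec("shaded_soil", soil, illumination = 0.35),
    background  = material_spec("background", flat(0.04))
  )
}

#' Default scene layout
#'
#' A label image: the white panel occupies a block at the top of the frame
#' (mounted above the canopy, in the field of view); below it the other
#' materials cycle column-wise, so every material is present in any
#' cross-track angle window.
#'
#' @param rows,cols layout size in pixels.
#' @param materials character vector of material names; must contain
#'   `"white_panel"`.
#' @return character matrix of material names.
#' @export
default_scene_layout <- function(rows = 24, cols = 48,
                                 materials = c("white_panel", "sunlit_leaf",
                                               "shaded_leaf", "soil",
                                               "shaded_soil", "background")) {
  stopifnot("white_panel" %in% materials, rows >= 8, cols >= 12)
  lay <- matrix("background", rows, cols)
  others <- setdiff(materials, c("white_panel", "background"))
  panel_rows <- 1:max(3, rows %/% 6)
  body <- (max(panel_rows) + 1):rows
  for (cc in seq_len(cols))
    lay[body, cc] <- others[(cc - 1) %% length(others) + 1]
  pc <- (cols %/% 3):(2 * cols %/% 3)
  lay[panel_rows, pc] <- "white_panel"
  lay
}

#' Generate a hyperspectral scene cube with ground truth
#'
#' Builds per-pixel radiance with the Lambertian forward model
#' `L = illumination * r * E / pi + F`, then encodes digital numbers as
#' `DN = (L - offset) / gain` plus optional Gaussian noise, clipped to the
#' 12-bit range \[0, 4095\] (saturated pixels are flagged). DN values are
#' kept continuous (not rounded) so the zero-noise encode/decode round trip
#' is exact to machine precision.
#'
#' @param materials named list of [material_spec()]; must include a
#'   `white_panel` entry reachable from the layout.
#' @param layout character matrix of material names, one per pixel.
#' @param irradiance downwelling irradiance spectrum; resampled onto the
#'   material grid if needed.
#' @param gain,offset radiometric encoding coefficients, scalar or
#'   per-band vectors (`L = gain * DN + offset`).
#' @param noise_sd Gaussian DN noise standard deviation.
#' @param seed RNG seed for the noise.
#' @return a `"scene_cube"`: list with `dn` (row x col x band array),
#'   `wavelength`, `gain`, `offset`, `saturated` (logical pixel matrix) and
#'   `truth` (label map, per-material SIF at the 761 nm band, materials,
#'   the irradiance on the camera grid).
#' @export
make_scene <- function(materials, layout, irradiance,
                       gain = 9e-5, offset = 0, noise_sd = 0, seed = NULL) {
  stopifnot(is.list(materials), is.matrix(layout), is.character(layout),
            inherits(irradiance, "spectrum"))
  used <- unique(as.vector(layout))
  missing_m <- setdiff(used, names(materials))
  if (length(missing_m))
    stopf("layout references unknown material(s): %s",
          paste(missing_m, collapse = ", "))
  if (!"white_panel" %in% used)
    stopf("layout lacks a white-panel region; reflectance conversion is undefined without it")
  wl <- materials[[used[1]]]$reflectance$wavelength
  for (m in materials[used])
    if (!isTRUE(all.equal(m$reflectance$wavelength, wl)))
      stopf("materials are not on a common wavelength grid")
  e <- if (isTRUE(all.equal(irradiance$wavelength, wl))) irradiance
       else resample_spectrum(irradiance, wl)

  nb <- length(wl)
  gain <- rep_len(as.numeric(gain), nb)
  offset <- rep_len(as.numeric(offset), nb)
  if (any(gain <= 0)) stopf("gain must be positive at every band")

  # per-material radiance rows, then broadcast through the layout
  lmat <- t(vapply(materials[used], function(m)
    m$illumination * m$reflectance$value * e$value / pi + m$fluorescence$value,
    numeric(nb)))
  rownames(lmat) <- used
  idx <- match(as.vector(layout), used)
  npx <- length(idx)
  l_px <- lmat[idx, , drop = FALSE]                     # pixels x bands
  dn <- sweep(sweep(l_px, 2, offset, "-"), 2, gain, "/")
  if (noise_sd > 0)
    dn <- dn + with_seed(seed, matrix(stats::rnorm(npx * nb, 0, noise_sd), npx, nb))
  sat_px <- rowSums(dn > 4095) > 0 | rowSums(dn < 0) > 0
  dn <- clamp(dn, 0, 4095)

  b761 <- nearest_index(wl, 761)
  sif_true <- vapply(materials[used], function(m) m$fluorescence$value[b761],
                     numeric(1))
  structure(list(
    dn = array(dn, dim = c(nrow(layout), ncol(layout), nb)),
    wavelength = wl, gain = gain, offset = offset,
    saturated = matrix(sat_px, nrow(layout), ncol(layout)),
    truth = list(labels = layout, sif_true = sif_true,
                 sif_band_nm = wl[b761], materials = materials[used],
                 irradiance = e)),
    class = "scene_cube")
}

#' @export
print.scene_cube <- function(x, ...) {
  d <- dim(x$dn)
  cat(sprintf("<scene_cube: %d x %d pixels, %d bands, materials: %s>\n",
              d[1], d[2], d[3],
              paste(names(x$truth$sif_true), collapse = ", ")))
  invisible(x)
}

#' Draw a table of plot-level ground truth
#'
#' Photosynthetic capacities for a simulated campaign: per plot a true
#' (Vcmax, Jmax, Rd) triple, a time group and an acquisition date. Jmax is
#' uniform on `jmax_range` and Vcmax is linearly coupled to it with noise
#' (the two capacities are tightly, positively correlated in C3 leaves);
#' both are clipped to the observed tobacco cultivar ranges.
#'
#' @param scheme a [group_scheme()]; dates cycle within each group.
#' @param n_per_group named integer vector of plots per group.
#' @param jmax_range uniform sampling range for Jmax, umol m-2 s-1.
#' @param coupling list with `slope`, `intercept`, `noise_sd` of the
#'   Vcmax ~ Jmax link.
#' @param vcmax_limits,jmax_limits clipping ranges (observed cultivar spread).
#' @param seed RNG seed.
#' @return data.frame with plot_id, group, date, Vcmax_true, Jmax_true,
#'   Rd_true.
#' @export
make_plot_truth <- function(scheme = group_scheme(),
                            n_per_group = c(group1 = 11, group2 = 8, group3 = 8),
                            jmax_range = c(140, 320),
                            coupling = list(slope = 1.1, intercept = -80,
                                            noise_sd = 30),
                            vcmax_limits = c(15.98, 318.96),
                            jmax_limits = c(118.85, 338.70),
                            seed = NULL) {
  stopifnot(all(names(n_per_group) %in% names(scheme)))
  with_seed(seed, {
    rows <- lapply(names(n_per_group), function(g) {
      n <- n_per_group[[g]]
      jm <- clamp(stats::runif(n, jmax_range[1], jmax_range[2]),
                  jmax_limits[1], jmax_limits[2])
      vc <- clamp(coupling$intercept + coupling$slope * jm +
                    stats::rnorm(n, 0, coupling$noise_sd),
                  vcmax_limits[1], vcmax_limits[2])
      data.frame(group = g,
                 date = rep_len(scheme[[g]], n),
                 Vcmax_true = vc, Jmax_true = jm,
                 Rd_true = stats::runif(n, 0.8, 2.0),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$plot_id <- sprintf("p%02d", seq_len(nrow(out)))
    out[c("plot_id", "group", "date", "Vcmax_true", "Jmax_true", "Rd_true")]
  })
}

#' Link fluorescence yield and canopy light capture to capacity
#'
#' Encodes the generating hypotheses of the synthetic campaign: within each
#' time group, fluorescence yield (phiF) decreases with Jmax, and NDVI (the
#' fAPAR proxy, hence APAR) increases with Vcmax. The phiF link is
#' log-linear by default so yield stays structurally positive; noise is
#' calibrated per group so the generating phiF~Jmax R-squared hits
#' `target_r2`. The realized per-group generating R-squared values are
#' recorded so the pipeline's recovered R-squared can be compared.
#'
#' @param truth a [make_plot_truth()] table.
#' @param apar_model list: `ndvi0` (group-mean NDVI), `slope` (per umol
#'   Vcmax), `noise_sd`, `clip` (NDVI bounds).
#' @param phiF_model list: `phi0` (named per-group baseline yield,
#'   sr-1 nm-1), `slope` (<= 0, per umol Jmax, on the log scale for
#'   `link = "log"`), `target_r2` or explicit `noise_sd`, `link`
#'   (`"log"` or `"linear"`).
#' @param seed RNG seed.
#' @return `truth` with `phiF` and `ndvi_target` columns; attributes
#'   `generating` (per-group realized R-squared of both links) and
#'   `fluorescence_shape` (normalized emission shape).
#' @export
make_trait_link <- function(truth,
                            apar_model = list(ndvi0 = 0.78, slope = 9e-4,
                                              noise_sd = 0.035,
                                              clip = c(0.35, 0.93)),
                            phiF_model = list(
                              phi0 = c(group1 = 3.5e-6, group2 = 6e-6,
                                       group3 = 8.5e-6),
                              slope = -0.006, target_r2 = 0.75,
                              noise_sd = NULL, link = "log"),
                            seed = NULL) {
  stopifnot(is.data.frame(truth),
            all(c("group", "Vcmax_true", "Jmax_true") %in% names(truth)))
  if (phiF_model$slope > 0)
    stopf("phiF_model encodes the inverse yield-capacity hypothesis; slope must be <= 0")
  link <- phiF_model$link %||% "log"
  with_seed(seed, {
    truth$phiF <- NA_real_
    truth$ndvi_target <- NA_real_
    gen <- list()
    for (g in unique(truth$group)) {
      i <- truth$group == g
      jm <- truth$Jmax_true[i]; vc <- truth$Vcmax_true[i]
      dj <- jm - mean(jm)
      phi0 <- if (length(phiF_model$phi0) > 1) phiF_model$phi0[[g]]
              else phiF_model$phi0[[1]]
      s <- phiF_model$noise_sd %||%
        (abs(phiF_model$slope) * stats::sd(dj) *
           sqrt(1 / phiF_model$target_r2 - 1))
      if (!is.finite(s)) s <- 0
      eta <- phiF_model$slope * dj + stats::rnorm(length(dj), 0, s)
      phi <- if (link == "log") phi0 * exp(eta) else phi0 + eta
      if (any(phi <= 0))
        stopf("phiF model yields non-positive fluorescence (min %.3g) in %s",
              min(phi), g)
      truth$phiF[i] <- phi
      nd <- apar_model$ndvi0 + apar_model$slope * (vc - mean(vc)) +
        stats::rnorm(length(vc), 0, apar_model$noise_sd)
      truth$ndvi_target[i] <- clamp(nd, apar_model$clip[1], apar_model$clip[2])
      gen[[g]] <- data.frame(
        group = g,
        r2_phiF_jmax = if (stats::sd(phi) > 0 && stats::sd(jm) > 0)
          stats::cor(phi, jm)^2 else 0,
        r2_ndvi_vcmax = if (stats::sd(truth$ndvi_target[i]) > 0)
          stats::cor(truth$ndvi_target[i], vc)^2 else 0)
    }
    attr(truth, "generating") <- do.call(rbind, gen)
    attr(truth, "link_models") <- list(apar = apar_model, phiF = phiF_model)
    attr(truth, "fluorescence_shape") <-
      fluorescence_shape_spectrum(camera_grid())
    truth
  })
}

#' Simulate A/Ci gas-exchange curves from known FvCB parameters
#'
#' For each plot, `leaves_per_plot` leaves are simulated at the plot's true
#' (Vcmax, Jmax, Rd) with optional leaf-to-leaf parameter jitter; net
#' assimilation at each Ci setpoint is obtained by solving the implicit
#' mesophyll-conductance coupling A = FvCB(Ci - A/gm) by fixed-point
#' iteration, then Gaussian measurement noise is added. Curves whose
#' noiseless model is Rubisco-limited at every setpoint are flagged
#' `no_j_limited` (Jmax is unidentifiable from such a curve).
#'
#' @param truth a [make_plot_truth()] table.
#' @param ci_setpoints intercellular CO2 setpoints, umol mol-1; the default
#'   is the standard 12-step sequence with the duplicate 400 retained.
#' @param k [kinetic_constants()].
#' @param noise_sd Gaussian noise on A, umol m-2 s-1.
#' @param leaves_per_plot leaves measured per plot.
#' @param leaf_jitter_cv fractional leaf-to-leaf sd on Vcmax/Jmax/Rd.
#' @param tleaf leaf temperature, degC.
#' @param gm25,gm_slope mesophyll conductance at 25 degC
#'   (mol m-2 s-1 bar-1) and its linear temperature slope (per degC).
#' @param par_chamber chamber light level, umol m-2 s-1 (saturating).
#' @param seed RNG seed.
#' @return list of `"aci_curve"` objects (plot_id, leaf_id, ci, a,
#'   tleaf, par_chamber, truth triple, no_j_limited flag).
#' @export
make_aci_dataset <- function(truth,
                             ci_setpoints = c(400, 200, 50, 100, 300, 400,
                                              600, 900, 1200, 1500, 1800, 2000),
                             k = kinetic_constants(),
                             noise_sd = 0.3, leaves_per_plot = 3,
                             leaf_jitter_cv = 0.05, tleaf = 25,
                             gm25 = 0.3, gm_slope = 0.04,
                             par_chamber = 1800, seed = NULL) {
  if (any(ci_setpoints <= 0))
    stopf("Ci setpoints must be positive (got %g)", min(ci_setpoints))
  with_seed(seed, {
    gm <- gm_at_temperature(gm25, gm_slope, tleaf)
    kt <- kinetics_at_temperature(k, tleaf)
    curves <- list()
    for (p in seq_len(nrow(truth))) {
      for (lf in seq_len(leaves_per_plot)) {
        jit <- function(x) x * (1 + stats::rnorm(1, 0, leaf_jitter_cv))
        vc <- jit(truth$Vcmax_true[p]); jm <- jit(truth$Jmax_true[p])
        rd <- max(jit(truth$Rd_true[p]), 0.05)
        # solve the implicit coupling A = FvCB(Ci - A/gm); the residual is
        # strictly increasing in A, so the root is unique
        a <- vapply(ci_setpoints, function(ci) {
          g <- function(av)
            av - fvcb_assimilation(max(ci - av / gm, 1e-9), vc, jm, rd, kt)$a
          stats::uniroot(g, c(-50, ci * gm - 1e-9), tol = 1e-12)$root
        }, numeric(1))
        cc <- pmax(ci_setpoints - a / gm, 1e-6)
        lim <- fvcb_assimilation(cc, vc, jm, rd, kt)$limitation
        curves[[length(curves) + 1L]] <- structure(list(
          plot_id = truth$plot_id[p], leaf_id = lf,
          ci = ci_setpoints,
          a = a + stats::rnorm(length(a), 0, noise_sd),
          tleaf = tleaf, par_chamber = par_chamber,
          truth = list(vcmax = vc, jmax = jm, rd = rd, gm = gm),
          no_j_limited = !any(lim == "RuBP")),
          class = "aci_curve")
      }
    }
    curves
  })
}
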