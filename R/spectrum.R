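#' Wavelength-indexed spectrum
#'
#' The universal currency of the pipeline: a vector of radiometric samples on
#' a strictly increasing wavelength grid, tagged with its radiometric kind.
#' Irradiance is downwelling flux density (W m-2 nm-1), radiance is
#' directional flux (W m-2 sr-1 nm-1) and reflectance is a unitless factor.
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly increasing.
#' @param value numeric vector of samples, same length as `wavelength`.
#' @param kind one of `"irradiance"`, `"radiance"`, `"reflectance"`.
#' @return an object of class `"spectrum"`: a list with elements
#'   `wavelength`, `value`, `kind`.
#' @examples
#' s <- make_spectrum(400:700, rep(1, 301), "irradiance")
#' integrate_par(s)
#' @export
make_spectrum <- function(wavelength, value,
                          kind = c("radiance", "irradiance", "reflectance")) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stopf("wavelength (%d) and value (%d) lengths differ",
          length(wavelength), length(value))
  if (length(wavelength) < 2L) stopf("a spectrum needs at least 2 samples")
  if (anyNA(wavelength) || anyNA(value) || any(!is.finite(value)))
    stopf("spectrum contains NA or non-finite values")
  if (any(diff(wavelength) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (kind == "reflectance" && any(value < 0))
    stopf("reflectance spectrum has negative values (min %.4g)", min(value))
  structure(list(wavelength = wavelength, value = value, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d bands, %.1f-%.1f nm>\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  units <- switch(x$kind,
                  irradiance  = "W m-2 nm-1",
                  radiance    = "W m-2 sr-1 nm-1",
                  reflectance = "unitless")
  graphics::plot(x$wavelength, x$value, type = "l",
                 xlab = "wavelength (nm)", ylab = sprintf("%s (%s)", x$kind, units),
                 ...)
}

#' Resample a spectrum by cubic-spline interpolation
#'
#' Cubic-spline (Forsythe-Malcolm-Moler end conditions, so polynomials up to
#' degree 3 are reproduced exactly) interpolation onto a new wavelength grid.
#' Extrapolation is refused: every target must lie inside the source support.
#'
#' @param s a [make_spectrum()] object.
#' @param target_wavelengths nm vector, within `range(s$wavelength)`.
#' @return a spectrum of the same kind on the target grid.
#' @export
resample_spectrum <- function(s, target_wavelengths) {
  stopifnot(inherits(s, "spectrum"))
  target_wavelengths <- as.numeric(target_wavelengths)
  rng <- range(s$wavelength)
  eps <- 1e-9 * diff(rng)
  bad <- target_wavelengths < rng[1] - eps | target_wavelengths > rng[2] + eps
  if (any(bad))
    stopf("resampling to %.3f nm would extrapolate outside support [%.3f, %.3f] nm",
          target_wavelengths[which(bad)[1]], rng[1], rng[2])
  f <- stats::splinefun(s$wavelength, s$value, method = "fmm")
  v <- f(target_wavelengths)
  if (s$kind == "reflectance") v <- pmax(v, 0)  # spline undershoot guard
  out <- make_spectrum(target_wavelengths, v, s$kind)
  out
}

#' Spectral band window
#'
#' Closed interval on band centers; membership is `lo <= lambda <= hi`.
#'
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @export
band_window <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stopf("band window needs lo < hi (got [%s, %s])", lo, hi)
  structure(list(lo = lo, hi = hi), class = "band_window")
}

#' Mean of spectrum samples inside a band window
#'
#' @param s a spectrum.
#' @param w a [band_window()], or a length-2 numeric `c(lo, hi)`.
#' @return arithmetic mean of the samples whose band center lies in the
#'   closed window.
#' @export
band_mean <- function(s, w) {
  stopifnot(inherits(s, "spectrum"))
  if (is.numeric(w) && length(w) == 2L) w <- band_window(w[1], w[2])
  stopifnot(inherits(w, "band_window"))
  idx <- s$wavelength >= w$lo & s$wavelength <= w$hi
  if (!any(idx))
    stopf("no spectrum samples inside band window [%g, %g] nm", w$lo, w$hi)
  mean(s$value[idx])
}

#' Normalized difference vegetation index
#'
#' NDVI = (R_nir - R_red) / (R_nir + R_red) on band-window means of a
#' reflectance spectrum; defaults are the 770-780 nm and 650-660 nm windows.
#'
#' @param reflectance a reflectance spectrum.
#' @param nir,red band windows (nm) for the near-infrared and red means.
#' @return NDVI in \[-1, 1\].
#' @export
ndvi <- function(reflectance, nir = band_window(770, 780),
                 red = band_window(650, 660)) {
  stopifnot(inherits(reflectance, "spectrum"))
  a <- band_mean(reflectance, nir)
  b <- band_mean(reflectance, red)
  if (a + b == 0) stopf("NDVI undefined: both band means are zero")
  (a - b) / (a + b)
}

#' Photosynthetically active radiation (energy units)
#'
#' Trapezoidal integral of downwelling irradiance over 400-700 nm, in W m-2.
#' The window endpoints are added by linear interpolation so a flat 1
#' W m-2 nm-1 spectrum integrates to exactly 300 W m-2 on any grid.
#'
#' @param irradiance an irradiance spectrum whose support covers the window.
#' @param window integration bounds in nm.
#' @return PAR in W m-2.
#' @export
integrate_par <- function(irradiance, window = c(400, 700)) {
  stopifnot(inherits(irradiance, "spectrum"))
  if (irradiance$kind != "irradiance")
    stopf("PAR integrates an irradiance spectrum, got kind '%s'", irradiance$kind)
  wl <- irradiance$wavelength; v <- irradiance$value
  if (min(wl) > window[1] + 1e-9 || max(wl) < window[2] - 1e-9)
    stopf("spectrum support [%.2f, %.2f] nm does not cover [%g, %g] nm",
          min(wl), max(wl), window[1], window[2])
  inside <- wl > window[1] & wl < window[2]
  xs <- c(window[1], wl[inside], window[2])
  ys <- c(stats::approx(wl, v, xout = window[1])$y,
          v[inside],
          stats::approx(wl, v, xout = window[2])$y)
  d <- diff(xs)
  d <- d[d > 0]
  if (length(d) > 1 && max(d) > 2 * stats::median(d) * (1 + 1e-8))
    stopf("support gap of %.3f nm inside PAR window exceeds one sampling step (%.3f nm)",
          max(d), stats::median(d))
  trapz(xs, ys)
}

# trapezoidal quadrature
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Convert a PAR integral to quantum units
#'
#' Photon-flux PAR, in umol photons m-2 s-1, from the same irradiance
#' spectrum: the integrand is E(lambda) * lambda / (h c N_A). Provided for
#' comparison with gas-exchange light levels; the SIF-yield definition keeps
#' PAR in energy units.
#'
#' @inheritParams integrate_par
#' @export
par_to_quantum <- function(irradiance, window = c(400, 700)) {
  stopifnot(inherits(irradiance, "spectrum"))
  h <- 6.62607015e-34; c0 <- 2.99792458e8; na <- 6.02214076e23
  # E * lambda[m] / (h c N_A) gives mol photons m-2 s-1 nm-1
  q <- make_spectrum(irradiance$wavelength,
                     irradiance$value * irradiance$wavelength * 1e-9 / (h * c0 * na) * 1e6,
                     "irradiance")
  integrate_par(q, window)
}

#' Radiance-to-reflectance conversion against the white reference panel
#'
#' R = (S_cluster / S_white) * R_white per band, the in-scene white-panel
#' ratio method. All spectra must share one wavelength grid and the panel
#' radiance must be strictly positive at every band.
#'
#' @param s_cluster radiance spectrum of the target cluster.
#' @param s_white radiance spectrum of the white panel.
#' @param r_white the panel's calibrated reflectance: a scalar (flat panel)
#'   or a reflectance spectrum on the same grid.
#' @return a reflectance spectrum.
#' @export
to_reflectance <- function(s_cluster, s_white, r_white = 0.99) {
  stopifnot(inherits(s_cluster, "spectrum"), inherits(s_white, "spectrum"))
  if (!isTRUE(all.equal(s_cluster$wavelength, s_white$wavelength)))
    stopf("cluster and white-panel spectra are on different wavelength grids")
  if (any(s_white$value <= 0)) {
    b <- which(s_white$value <= 0)[1]
    stopf("white-panel radiance is not positive at %.2f nm", s_white$wavelength[b])
  }
  rw <- if (inherits(r_white, "spectrum")) {
    if (!isTRUE(all.equal(r_white$wavelength, s_cluster$wavelength)))
      stopf("r_white spectrum is on a different wavelength grid")
    r_white$value
  } else {
    rep(as.numeric(r_white), length(s_cluster$value))
  }
  make_spectrum(s_cluster$wavelength,
                pmax(s_cluster$value / s_white$value * rw, 0),
                "reflectance")
}

#' Read / write a spectrum as two-column CSV
#'
#' Plain-text interchange format: a `# kind=...` header comment line, then
#' `wavelength_nm,value` rows.
#'
#' @param s a spectrum.
#' @param path file path.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  units <- switch(s$kind,
                  irradiance  = "W m-2 nm-1",
                  radiance    = "W m-2 sr-1 nm-1",
                  reflectance = "unitless")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s units=%s", s$kind, units), con)
  utils::write.csv(data.frame(wavelength_nm = s$wavelength, value = s$value),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- sub(".*kind=(\\w+).*", "\\1", first)
  if (!kind %in% c("irradiance", "radiance", "reflectance"))
    stopf("missing or malformed '# kind=' header line in %s", path)
  d <- utils::read.csv(path, comment.char = "#")
  make_spectrum(d$wavelength_nm, d$value, kind)
}
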