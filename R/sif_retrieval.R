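# Fraunhofer Line Discrimination at the O2-A band: plain FLD, the improved
# variant with reflectance/fluorescence correction factors, and SIF yield.
#
# The in-filling idea: inside a deep solar/atmospheric absorption line the
# reflected signal collapses with the irradiance while the added
# fluorescence does not, so the in-line radiance is fractionally enriched
# in fluorescence. With L = r E / pi + F at two bands (in/out) and
# correction factors alpha_R = r_out / r_in, alpha_F = F_out / F_in, the
# estimator
#   SIF = (alpha_R E_out L_in - E_in L_out) / (alpha_R E_out - alpha_F E_in)
# recovers F_in exactly.

#' FLD band quadruple
#'
#' Irradiance and radiance sampled inside (default 761 nm, O2-A) and
#' outside (754 nm) the absorption line. `e_out > e_in` is required: the
#' out-of-line continuum must exceed the in-line trough.
#'
#' @param e_in,e_out irradiance at the in/out bands, W m-2 nm-1.
#' @param l_in,l_out radiance at the in/out bands, W m-2 sr-1 nm-1.
#' @param lambda_in,lambda_out the band wavelengths, nm.
#' @export
fld_bands <- function(e_in, e_out, l_in, l_out,
                      lambda_in = 761, lambda_out = 754) {
  vals <- c(e_in = e_in, e_out = e_out, l_in = l_in, l_out = l_out)
  if (any(vals < 0)) stopf("FLD bands must be nonnegative")
  if (e_out <= e_in)
    stopf("out-of-line irradiance (%.4g) must exceed in-line irradiance (%.4g)",
          e_out, e_in)
  structure(list(e_in = e_in, e_out = e_out, l_in = l_in, l_out = l_out,
                 lambda_in = lambda_in, lambda_out = lambda_out),
            class = "fld_bands")
}

#' Extract FLD bands from paired spectra
#'
#' Picks the camera band centers nearest the nominal in/out wavelengths and
#' evaluates the (resampled) irradiance at those same wavelengths, so both
#' signals refer to identical band positions.
#'
#' @param radiance radiance spectrum on the camera grid.
#' @param irradiance irradiance spectrum (any grid covering the bands).
#' @param lambda_in,lambda_out nominal wavelengths, nm.
#' @export
extract_fld_bands <- function(radiance, irradiance,
                              lambda_in = 761, lambda_out = 754) {
  stopifnot(inherits(radiance, "spectrum"), inherits(irradiance, "spectrum"))
  wl <- radiance$wavelength
  bi <- nearest_index(wl, lambda_in); bo <- nearest_index(wl, lambda_out)
  if (bi == bo) stopf("in and out wavelengths map to the same camera band")
  targets <- sort(wl[c(bi, bo)])
  e <- resample_spectrum(irradiance, targets)
  ev <- e$value[match(wl[c(bi, bo)], targets)]
  fld_bands(e_in = ev[1], e_out = ev[2],
            l_in = radiance$value[bi], l_out = radiance$value[bo],
            lambda_in = wl[bi], lambda_out = wl[bo])
}

#' Plain Fraunhofer Line Discrimination
#'
#' `SIF = (E_out L_in - E_in L_out) / (E_out - E_in)`: exact when both
#' reflectance and fluorescence are constant across the two bands
#' (equivalently, the improved estimator with both correction factors 1).
#'
#' @param b an [fld_bands()] quadruple.
#' @param tol minimum irradiance contrast.
#' @return SIF at the in-line band, radiance units.
#' @export
fld <- function(b, tol = 1e-9) {
  stopifnot(inherits(b, "fld_bands"))
  if (abs(b$e_out - b$e_in) <= tol)
    stopf("no absorption contrast: |E_out - E_in| = %.3g <= %.3g",
          abs(b$e_out - b$e_in), tol)
  (b$e_out * b$l_in - b$e_in * b$l_out) / (b$e_out - b$e_in)
}

#' Correction factors for the improved FLD
#'
#' @param alpha_R reflectance shape factor r(out)/r(in).
#' @param alpha_F fluorescence shape factor F(out)/F(in).
#' @export
correction_factors <- function(alpha_R, alpha_F = alpha_R) {
  if (!is.finite(alpha_R) || !is.finite(alpha_F) ||
      alpha_R <= 0 || alpha_F <= 0)
    stopf("correction factors must be finite and positive (got alpha_R=%.4g, alpha_F=%.4g)",
          alpha_R, alpha_F)
  structure(list(alpha_R = alpha_R, alpha_F = alpha_F),
            class = "correction_factors")
}

#' Estimate iFLD correction factors from apparent reflectance
#'
#' The apparent reflectance `pi L / E` is spuriously inflated inside the
#' absorption line (the fluorescence in-filling itself). The true
#' reflectance across the line is reconstructed by cubic interpolation from
#' shoulder bands on both sides of an exclusion window containing the
#' in-line band; `alpha_R` is the ratio of the (smoothed) reflectance at
#' the out-band to the interpolated value at the in-band. `alpha_F`
#' defaults to `alpha_R` (the fluorescence spectrum is smooth at this
#' scale); pass a known emission shape to compute it explicitly.
#'
#' @param apparent_reflectance reflectance spectrum `pi L / E` on the
#'   camera grid.
#' @param exclusion_window [band_window()] containing `lambda_in` but not
#'   `lambda_out`.
#' @param b the [fld_bands()] in use (for the actual band wavelengths).
#' @param n_shoulder shoulder bands used on each side (>= 2).
#' @param fluorescence_shape optional emission-shape spectrum for an
#'   explicit `alpha_F`.
#' @return a [correction_factors()] object.
#' @export
estimate_alphas <- function(apparent_reflectance,
                            exclusion_window = band_window(756, 768),
                            b, n_shoulder = 4, fluorescence_shape = NULL) {
  stopifnot(inherits(apparent_reflectance, "spectrum"),
            inherits(b, "fld_bands"))
  if (is.numeric(exclusion_window) && length(exclusion_window) == 2L)
    exclusion_window <- band_window(exclusion_window[1], exclusion_window[2])
  w <- exclusion_window
  if (b$lambda_in < w$lo || b$lambda_in > w$hi)
    stopf("exclusion window [%g, %g] nm does not contain lambda_in (%.2f nm)",
          w$lo, w$hi, b$lambda_in)
  if (b$lambda_out >= w$lo && b$lambda_out <= w$hi)
    stopf("exclusion window [%g, %g] nm must not contain lambda_out (%.2f nm)",
          w$lo, w$hi, b$lambda_out)
  wl <- apparent_reflectance$wavelength; v <- apparent_reflectance$value
  left <- which(wl < w$lo); right <- which(wl > w$hi)
  left <- utils::tail(left, n_shoulder); right <- utils::head(right, n_shoulder)
  if (length(left) < 2 || length(right) < 2)
    stopf("need >= 2 shoulder bands on each side of the exclusion window (have %d left, %d right)",
          length(left), length(right))
  sm <- stats::splinefun(wl[c(left, right)], v[c(left, right)], method = "fmm")
  r_in <- sm(b$lambda_in)
  r_out <- v[nearest_index(wl, b$lambda_out)]
  if (r_in <= 0)
    stopf("interpolated reflectance at the in-band is non-positive (%.4g)", r_in)
  alpha_r <- r_out / r_in
  alpha_f <- if (is.null(fluorescence_shape)) alpha_r else {
    fs <- resample_spectrum(fluorescence_shape, c(b$lambda_out, b$lambda_in))
    fs$value[1] / fs$value[2]
  }
  correction_factors(alpha_r, alpha_f)
}

#' Improved Fraunhofer Line Discrimination
#'
#' `SIF = (alpha_R E_out L_in - E_in L_out) / (alpha_R E_out - alpha_F E_in)`.
#' Reduces to [fld()] when both factors are 1; exact (algebraically) when
#' the true shape factors are supplied.
#'
#' @param b an [fld_bands()] quadruple.
#' @param cf [correction_factors()].
#' @param tol minimum |denominator|.
#' @return SIF at the in-line band, radiance units.
#' @export
ifld <- function(b, cf, tol = 1e-9) {
  stopifnot(inherits(b, "fld_bands"), inherits(cf, "correction_factors"))
  den <- cf$alpha_R * b$e_out - cf$alpha_F * b$e_in
  if (abs(den) <= tol)
    stopf("iFLD denominator %.3g is below tolerance %.3g", den, tol)
  (cf$alpha_R * b$e_out * b$l_in - b$e_in * b$l_out) / den
}

#' SIF yield from SIF, PAR and NDVI
#'
#' `fAPAR = NDVI` (clipped to \[0, 1\]), `APAR = PAR * fAPAR`,
#' `SIF_yield = SIF / APAR`. Valid for vegetation spectra only (the NDVI >
#' 0.1 rule is applied upstream). Because PAR is kept in energy units
#' (W m-2), SIF yield carries units sr-1 nm-1.
#'
#' @param sif retrieved SIF, W m-2 sr-1 nm-1.
#' @param par PAR, W m-2 (> 0).
#' @param ndvi NDVI of the plot's sunlit foliage.
#' @return list with `fapar`, `apar`, `sif_yield`.
#' @export
sif_yield <- function(sif, par, ndvi) {
  if (par <= 0) stopf("PAR must be positive (got %g)", par)
  fapar <- clamp(ndvi, 0, 1)
  apar <- par * fapar
  if (apar <= 0) stopf("APAR = %g <= 0; SIF yield undefined", apar)
  list(fapar = fapar, apar = apar, sif_yield = sif / apar)
}

#' One-call SIF retrieval from paired spectra
#'
#' Resamples the irradiance onto the camera grid, extracts the FLD bands,
#' estimates the correction factors from the apparent reflectance (unless
#' supplied) and applies the requested estimator.
#'
#' @param radiance plot mean radiance spectrum (camera grid).
#' @param irradiance time-matched downwelling irradiance spectrum.
#' @param lambda_in,lambda_out nominal band wavelengths, nm.
#' @param method `"ifld"` (default) or `"fld"`.
#' @param exclusion_window passed to [estimate_alphas()].
#' @param alphas optional precomputed [correction_factors()].
#' @param fluorescence_shape optional emission shape for `alpha_F`.
#' @param n_shoulder shoulder bands per side.
#' @return list with `sif`, `alphas`, `bands`, `apparent` (apparent
#'   reflectance spectrum on the camera grid).
#' @export
retrieve_sif <- function(radiance, irradiance,
                         lambda_in = 761, lambda_out = 754,
                         method = c("ifld", "fld"),
                         exclusion_window = band_window(756, 768),
                         alphas = NULL, fluorescence_shape = NULL,
                         n_shoulder = 4) {
  method <- match.arg(method)
  stopifnot(inherits(radiance, "spectrum"), inherits(irradiance, "spectrum"))
  e_cam <- if (isTRUE(all.equal(irradiance$wavelength, radiance$wavelength)))
    irradiance else resample_spectrum(irradiance, radiance$wavelength)
  if (any(e_cam$value <= 0))
    stopf("irradiance is non-positive on the camera grid at %.2f nm",
          radiance$wavelength[which(e_cam$value <= 0)[1]])
  b <- extract_fld_bands(radiance, irradiance, lambda_in, lambda_out)
  apparent <- make_spectrum(radiance$wavelength,
                            pmax(pi * radiance$value / e_cam$value, 0),
                            "reflectance")
  if (method == "fld")
    return(list(sif = fld(b), alphas = correction_factors(1, 1), bands = b,
                apparent = apparent))
  cf <- alphas %||% estimate_alphas(apparent, exclusion_window, b,
                                    n_shoulder = n_shoulder,
                                    fluorescence_shape = fluorescence_shape)
  list(sif = ifld(b, cf), alphas = cf, bands = b, apparent = apparent)
}
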