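# Farquhar-von Caemmerer-Berry (FvCB) C3 photosynthesis model, A/Ci curve
# fitting for Vcmax/Jmax/Rd, mesophyll-conductance temperature correction
# and leaf-to-plot averaging.

#' Rubisco kinetic constants
#'
#' 25 degC reference values of the tobacco-derived kinetic set commonly used
#' for C3 A/Ci fitting: CO2 compensation point without day respiration
#' (Gamma_star, umol mol-1), Michaelis constants for carboxylation
#' (Kc, umol mol-1) and oxygenation (Ko, mmol mol-1), chloroplast O2
#' (O, mmol mol-1), plus Arrhenius activation energies (J mol-1) for
#' temperature scaling. All overridable.
#'
#' @param Gamma_star,Kc,Ko,O 25 degC values (units above).
#' @param Ea named activation energies for `Gamma_star`, `Kc`, `Ko`.
#' @export
kinetic_constants <- function(Gamma_star = 42.75, Kc = 404.9, Ko = 278.4,
                              O = 210,
                              Ea = c(Gamma_star = 37830, Kc = 79430,
                                     Ko = 36380)) {
  stopifnot(Gamma_star > 0, Kc > 0, Ko > 0, O > 0)
  structure(list(Gamma_star = Gamma_star, Kc = Kc, Ko = Ko, O = O, Ea = Ea),
            class = "kinetic_constants")
}

#' Arrhenius temperature scaling of the kinetic constants
#'
#' @param k a [kinetic_constants()] set (25 degC reference).
#' @param tleaf leaf temperature, degC.
#' @return a [kinetic_constants()] set at `tleaf`.
#' @export
kinetics_at_temperature <- function(k, tleaf) {
  stopifnot(inherits(k, "kinetic_constants"))
  if (abs(tleaf - 25) < 1e-12) return(k)
  r <- 8.314; tk <- tleaf + 273.15
  arr <- function(v25, ea) v25 * exp(ea * (tk - 298.15) / (298.15 * r * tk))
  kinetic_constants(Gamma_star = arr(k$Gamma_star, k$Ea[["Gamma_star"]]),
                    Kc = arr(k$Kc, k$Ea[["Kc"]]),
                    Ko = arr(k$Ko, k$Ea[["Ko"]]),
                    O = k$O, Ea = k$Ea)
}

#' Mesophyll conductance at leaf temperature
#'
#' Linear temperature dependence around the 25 degC reference:
#' `gm = gm25 * (1 + slope * (T - 25))`.
#'
#' @param gm25 conductance at 25 degC, mol m-2 s-1 bar-1.
#' @param slope fractional change per degC.
#' @param tleaf leaf temperature, degC.
#' @export
gm_at_temperature <- function(gm25, slope, tleaf) {
  gm <- gm25 * (1 + slope * (tleaf - 25))
  if (gm <= 0)
    stopf("gm is non-positive (%.3g) at %g degC; check gm25/slope", gm, tleaf)
  gm
}

#' Intercellular to chloroplastic CO2
#'
#' `Cc = Ci - A / gm`. Points whose Cc is non-positive are flagged (and
#' excluded from fitting by [fit_aci()]).
#'
#' @param ci intercellular CO2, umol mol-1.
#' @param a net assimilation, umol m-2 s-1.
#' @param gm mesophyll conductance, mol m-2 s-1 bar-1 (Inf = infinite
#'   conductance, Cc = Ci).
#' @return list with `cc` and logical `flagged` (Cc <= 0).
#' @export
ci_to_cc <- function(ci, a, gm) {
  if (gm <= 0) stopf("gm must be positive (got %g)", gm)
  cc <- if (is.infinite(gm)) ci else ci - a / gm
  list(cc = cc, flagged = cc <= 0)
}

#' FvCB net assimilation
#'
#' Minimum of the Rubisco-limited and RuBP-regeneration-limited rates:
#' `Ac = Vcmax (Cc - G*) / (Cc + Kc (1 + O/Ko)) - Rd`,
#' `Aj = J (Cc - G*) / (4 Cc + 8 G*) - Rd`. Under saturating chamber light
#' `J = Jmax` (the default); pass `j` to use e.g. a light-response value
#' from [electron_transport()]. TPU limitation is not modelled.
#'
#' @param cc chloroplastic CO2, umol mol-1 (vectorized).
#' @param vcmax,jmax,rd FvCB parameters, umol m-2 s-1.
#' @param k [kinetic_constants()] at leaf temperature.
#' @param j electron transport rate; defaults to `jmax`.
#' @return list with `a` (net A), `ac`, `aj`, `limitation`
#'   (`"Rubisco"`/`"RuBP"` per point; ties count as Rubisco).
#' @export
fvcb_assimilation <- function(cc, vcmax, jmax, rd, k = kinetic_constants(),
                              j = NULL) {
  stopifnot(inherits(k, "kinetic_constants"))
  if (any(cc <= 0)) stopf("Cc must be positive (got %g)", min(cc))
  j <- j %||% jmax
  km <- k$Kc * (1 + k$O / k$Ko)
  ac <- vcmax * (cc - k$Gamma_star) / (cc + km) - rd
  aj <- j * (cc - k$Gamma_star) / (4 * cc + 8 * k$Gamma_star) - rd
  list(a = pmin(ac, aj), ac = ac, aj = aj,
       limitation = ifelse(ac <= aj, "Rubisco", "RuBP"))
}

#' Non-rectangular hyperbola electron transport light response
#'
#' `J` as the lower root of `theta J^2 - (alpha Q + Jmax) J + alpha Q Jmax`.
#' Provided behind a flag; the default fitting path assumes saturating
#' chamber light (J = Jmax).
#'
#' @param jmax maximum electron transport rate, umol m-2 s-1.
#' @param par incident PAR, umol m-2 s-1.
#' @param alpha apparent quantum yield of electron transport.
#' @param theta curvature (0, 1\].
#' @export
electron_transport <- function(jmax, par = 1800, alpha = 0.3, theta = 0.9) {
  b <- alpha * par + jmax
  (b - sqrt(b^2 - 4 * theta * alpha * par * jmax)) / (2 * theta)
}

#' Fit an A/Ci curve for Vcmax, Jmax and Rd
#'
#' Nonlinear least squares of the min-rule FvCB model on chloroplastic CO2
#' (`Cc = Ci - A_obs/gm`, with gm and the kinetic constants evaluated at the
#' curve's leaf temperature), multi-start from data-driven initial guesses.
#' Jmax is reported only when the fitted curve has at least two
#' RuBP-limited points *and* the three-parameter model significantly
#' improves on a Rubisco-only fit (F-test, p < 0.05) — a curve that is
#' Rubisco-limited at every setpoint returns `jmax = NA` with a diagnostic
#' instead of a spurious value.
#'
#' @param curve an `"aci_curve"` (list with `ci`, `a`, `tleaf`), e.g. from
#'   [make_aci_dataset()].
#' @param k [kinetic_constants()] (25 degC reference).
#' @param gm25,gm_slope mesophyll conductance model; set `gm25 = Inf` to fit
#'   on Ci directly.
#' @param min_points minimum usable points.
#' @return an `"fvcb_fit"`: `vcmax`, `jmax`, `rd`, `gm`, `sse`, `rmse`,
#'   `limitation` labels, `jmax_available`, `n_rubisco`, `n_rubp`,
#'   `excluded` indices (Cc <= 0), `diagnostic`.
#' @export
fit_aci <- function(curve, k = kinetic_constants(), gm25 = 0.3,
                    gm_slope = 0.04, min_points = 6) {
  ci <- as.numeric(curve$ci); a <- as.numeric(curve$a)
  stopifnot(length(ci) == length(a))
  tleaf <- curve$tleaf %||% 25
  kt <- kinetics_at_temperature(k, tleaf)
  gm <- if (is.infinite(gm25)) Inf else gm_at_temperature(gm25, gm_slope, tleaf)
  conv <- ci_to_cc(ci, a, gm)
  use <- !conv$flagged & conv$cc > kt$Gamma_star * 0.2
  if (sum(use) < min_points)
    stopf("only %d usable points (need >= %d) after Cc screening", sum(use), min_points)
  cc <- conv$cc[use]; ao <- a[use]; n <- length(ao)

  sse3 <- function(th)
    sum((ao - fvcb_assimilation(cc, th[1], th[2], th[3], kt)$a)^2)
  sse2 <- function(th) {
    km <- kt$Kc * (1 + kt$O / kt$Ko)
    sum((ao - (th[1] * (cc - kt$Gamma_star) / (cc + km) - th[2]))^2)
  }

  # data-driven initial guesses: invert Ac at the lowest-Ci points and Aj at
  # the highest-Ci point, assuming Rd ~ 1.5
  km <- kt$Kc * (1 + kt$O / kt$Ko)
  ilow <- order(cc)[seq_len(min(3, n))]
  ihigh <- which.max(cc)
  rd0 <- 1.5
  vc0 <- stats::median((ao[ilow] + rd0) * (cc[ilow] + km) /
                         pmax(cc[ilow] - kt$Gamma_star, 1))
  jm0 <- (ao[ihigh] + rd0) * (4 * cc[ihigh] + 8 * kt$Gamma_star) /
    (cc[ihigh] - kt$Gamma_star)
  vc0 <- clamp(vc0, 10, 500); jm0 <- clamp(jm0, 20, 500)
  starts <- list(c(vc0, jm0, rd0),
                 c(0.6 * vc0, 1.5 * jm0, 0.5),
                 c(1.5 * vc0, 0.8 * jm0, 3))

  lower3 <- c(5, 15, 0.01); upper3 <- c(800, 800, 20)
  best <- NULL
  for (st in starts) {
    f <- tryCatch(stats::optim(clamp(st, lower3, upper3), sse3,
                               method = "L-BFGS-B",
                               lower = lower3, upper = upper3,
                               control = list(maxit = 1000, factr = 1e4)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best))
    stopf("A/Ci fit failed to converge from all starts")
  # polish: the min-rule surface has flat valleys near the limitation switch;
  # a derivative-free pass from the best candidate tightens the optimum
  pol <- tryCatch(stats::optim(best$par, sse3, method = "Nelder-Mead",
                               control = list(maxit = 2000,
                                              reltol = 1e-14)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value &&
      all(pol$par >= lower3 & pol$par <= upper3)) best <- pol

  fr <- NULL
  for (st in list(c(vc0, rd0), c(1.5 * vc0, 3))) {
    f <- tryCatch(stats::optim(clamp(st, c(5, 0.01), c(800, 20)), sse2,
                               method = "L-BFGS-B",
                               lower = c(5, 0.01), upper = c(800, 20),
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(fr) || f$value < fr$value)) fr <- f
  }

  th <- best$par
  lim <- fvcb_assimilation(cc, th[1], th[2], th[3], kt)$limitation
  n_rubp <- sum(lim == "RuBP")
  jmax_ok <- n_rubp >= 2
  diagnostic <- NULL
  if (jmax_ok && !is.null(fr)) {
    # require a significant SSE improvement over the Rubisco-only model
    if (fr$value <= best$value * (1 + 1e-8)) {
      jmax_ok <- FALSE
    } else if (best$value > 1e-12 && n > 3) {
      fstat <- (fr$value - best$value) / (best$value / (n - 3))
      jmax_ok <- stats::pf(fstat, 1, n - 3, lower.tail = FALSE) < 0.05
    }
  }
  if (!jmax_ok) {
    diagnostic <- sprintf(
      "no J-limited points: %d of %d points RuBP-limited; Jmax unidentifiable, Rubisco-only fit reported",
      n_rubp, n)
    th <- c(fr$par[1], NA_real_, fr$par[2])
    sse <- fr$value
    lim <- rep("Rubisco", n)
    n_rubp <- 0L
  } else sse <- best$value

  structure(list(
    vcmax = th[1], jmax = th[2], rd = th[3], gm = gm,
    sse = sse, rmse = sqrt(sse / n),
    limitation = lim, jmax_available = jmax_ok,
    n_rubisco = sum(lim == "Rubisco"), n_rubp = n_rubp,
    n_used = n, excluded = which(!use),
    diagnostic = diagnostic, tleaf = tleaf),
    class = "fvcb_fit")
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat(sprintf("<fvcb_fit: Vcmax=%.1f Jmax=%s Rd=%.2f umol m-2 s-1, rmse=%.3f, %d/%d RuBP-limited>\n",
              x$vcmax, ifelse(is.na(x$jmax), "NA", sprintf("%.1f", x$jmax)),
              x$rd, x$rmse, x$n_rubp, x$n_used))
  if (!is.null(x$diagnostic)) cat(" ", x$diagnostic, "\n")
  invisible(x)
}

#' Average leaf-level fits to plot level
#'
#' Arithmetic mean of Vcmax over all leaves and of Jmax over the leaves
#' where Jmax was identifiable; counts are recorded so a plot with fewer
#' Jmax observations than leaves is visible downstream.
#'
#' @param fits list of [fit_aci()] results (one per leaf).
#' @return list with `vcmax`, `jmax` (NA when no leaf had one), `rd`,
#'   `n_leaves`, `n_jmax`.
#' @export
plot_average <- function(fits) {
  if (!length(fits)) stopf("plot_average: empty leaf list")
  vc <- vapply(fits, function(f) f$vcmax, numeric(1))
  rd <- vapply(fits, function(f) f$rd, numeric(1))
  jm <- vapply(fits, function(f) if (isTRUE(f$jmax_available)) f$jmax
               else NA_real_, numeric(1))
  if (!any(is.finite(vc))) stopf("plot_average: no leaf has a Vcmax estimate")
  list(vcmax = mean(vc[is.finite(vc)]),
       jmax = if (any(is.finite(jm))) mean(jm[is.finite(jm)]) else NA_real_,
       rd = mean(rd[is.finite(rd)]),
       n_leaves = length(fits), n_jmax = sum(is.finite(jm)))
}
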