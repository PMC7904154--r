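# Configuration, timestamp matching, the end-to-end synthetic campaign and
# the full image-based pipeline run.

#' Pipeline configuration
#'
#' All tunable settings in one nested list, with defaults matching the
#' instrument and processing constants used throughout: O2-A bands at
#' 761/754 nm, NDVI windows 770-780 / 650-660 nm and threshold 0.1, 640
#' cross-track channels at +-46.1 degrees keeping +-15 degrees, k-means
#' with k = 6, the standard 12 Ci setpoints, and the three-group date
#' scheme. Round-trips losslessly through [write_config()] /
#' [read_config()].
#'
#' @param ... named top-level sections to override (merged recursively).
#' @return a `"pipeline_config"` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    bands = list(lambda_in = 761, lambda_out = 754,
                 ndvi_nir = c(770, 780), ndvi_red = c(650, 660),
                 ndvi_threshold = 0.1, exclusion_window = c(756, 768),
                 n_shoulder = 4),
    geometry = list(n_channels = 640, half_fov = 46.1, keep_half_angle = 15),
    kmeans = list(k = 6, restarts = 5),
    irradiance = list(continuum_level = 1.0, line_depth = 0.7,
                      line_width = 1.5, level_jitter = 0.08),
    fvcb = list(Gamma_star = 42.75, Kc = 404.9, Ko = 278.4, O = 210,
                gm25 = 0.3, gm_slope = 0.04, chamber_par = 1800,
                ci_setpoints = c(400, 200, 50, 100, 300, 400, 600, 900,
                                 1200, 1500, 1800, 2000)),
    groups = list(group1 = c("2017-07-06", "2017-07-07", "2017-07-12"),
                  group2 = c("2017-07-31", "2017-08-18"),
                  group3 = c("2018-07-24", "2018-07-25")),
    match = list(tolerance_s = 5),
    synthetic = list(
      n_per_group = c(group1 = 11, group2 = 8, group3 = 8),
      jmax_range = c(140, 320),
      phi0 = c(group1 = 3.5e-6, group2 = 6e-6, group3 = 8.5e-6),
      phiF_slope = -0.006, target_r2 = 0.75,
      ndvi0 = 0.78, ndvi_slope = 9e-4, ndvi_noise = 0.035,
      aci_noise_sd = 0.3, leaves_per_plot = 3, leaf_jitter_cv = 0.05,
      scene_rows = 24, scene_cols = 48, scene_noise_sd = 0,
      r_white = 0.99, gain = 9e-5))
  over <- list(...)
  for (i in seq_along(over)) {          # positional: repeated names both apply
    nm <- names(over)[i]
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[i]]))
      utils::modifyList(cfg[[nm]], over[[i]]) else over[[i]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config a `"pipeline_config"`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]]))
      utils::modifyList(cfg[[nm]], raw[[nm]]) else raw[[nm]]
  # yaml drops vector names; restore the named defaults where needed
  for (f in c("n_per_group", "phi0"))
    if (is.null(names(cfg$synthetic[[f]])))
      names(cfg$synthetic[[f]]) <- names(cfg$groups)[seq_along(cfg$synthetic[[f]])]
  cfg
}

#' Match image cubes to irradiance spectra by timestamp
#'
#' Nearest-timestamp match within a tolerance; a cube with no irradiance
#' spectrum inside the tolerance is an error naming the cube.
#'
#' @param cube_timestamps numeric seconds (or POSIXct), time-sorted.
#' @param irradiance_timestamps numeric seconds (or POSIXct), time-sorted.
#' @param tolerance seconds.
#' @return data.frame with `cube_index`, `irradiance_index`, `time_gap`.
#' @export
match_irradiance <- function(cube_timestamps, irradiance_timestamps,
                             tolerance = 5) {
  ct <- as.numeric(cube_timestamps); it <- as.numeric(irradiance_timestamps)
  if (is.unsorted(ct) || is.unsorted(it))
    stopf("timestamp streams must be time-sorted")
  idx <- vapply(ct, function(t) {
    j <- findInterval(t, it)
    cand <- unique(clamp(c(j, j + 1L), 1L, length(it)))
    cand[which.min(abs(it[cand] - t))]
  }, integer(1))
  gap <- abs(it[idx] - ct)
  if (any(gap > tolerance)) {
    i <- which(gap > tolerance)[1]
    stopf("no irradiance spectrum within %g s of cube %d (t = %g; nearest gap %.2f s)",
          tolerance, i, ct[i], gap[i])
  }
  data.frame(cube_index = seq_along(ct), irradiance_index = idx,
             time_gap = gap)
}

# Build the per-plot forward-model spectra for one acquisition:
# leaf reflectance hitting the plot's NDVI target, fluorescence pinned at
# phiF * APAR at the 761 nm band, radiance on the camera grid.
plot_forward_spectra <- function(phiF, ndvi_target, irr_fine, grid) {
  e_cam <- resample_spectrum(irr_fine, grid)
  r_leaf <- leaf_reflectance_spectrum(grid, ndvi_target = ndvi_target)
  par <- integrate_par(irr_fine)
  nd <- ndvi(r_leaf)
  apar <- par * clamp(nd, 0, 1)
  f761 <- phiF * apar
  shape <- fluorescence_shape_spectrum(grid)
  fspec <- make_spectrum(grid, f761 * shape$value, "radiance")
  l <- make_spectrum(grid, r_leaf$value * e_cam$value / pi + fspec$value,
                     "radiance")
  list(radiance = l, reflectance = r_leaf, fluorescence = fspec,
       e_cam = e_cam, par = par, ndvi = nd, apar = apar, sif_true = f761)
}

#' Simulate and analyse a multi-group campaign (spectrum-level)
#'
#' The fast end-to-end experiment: draws plot truth, links fluorescence
#' yield and NDVI to capacity, builds per-plot radiance/irradiance spectra
#' with the forward model, retrieves SIF by iFLD with estimated correction
#' factors, computes SIF yield, obtains plot capacities (by simulating and
#' fitting A/Ci curves, or directly from truth when
#' `fit_gas_exchange = FALSE`), and runs the group-binned regressions.
#' Skipping the image stage keeps a single run in the tens of milliseconds,
#' which is what makes many-seed repetition studies practical; the full
#' image path is exercised by [run_pipeline()].
#'
#' @param config a [pipeline_config()].
#' @param seed master seed; every random draw flows from it.
#' @param fit_gas_exchange simulate + fit A/Ci curves (`TRUE`) or use the
#'   true capacities (`FALSE`).
#' @return list: `records` (per-plot SIF/PAR/NDVI/APAR/SIF-yield table),
#'   `capacity`, `truth`, `generating` (per-group generating R-squared),
#'   `regressions` (all x/y combinations, per group + pooled).
#' @export
simulate_campaign <- function(config = pipeline_config(),
                              seed = config$seed,
                              fit_gas_exchange = TRUE) {
  syn <- config$synthetic
  scheme <- do.call(group_scheme, config$groups)
  with_seed(seed, {
    truth <- make_plot_truth(scheme = scheme,
                             n_per_group = unlist(syn$n_per_group),
                             jmax_range = syn$jmax_range)
    truth <- make_trait_link(
      truth,
      apar_model = list(ndvi0 = syn$ndvi0, slope = syn$ndvi_slope,
                        noise_sd = syn$ndvi_noise, clip = c(0.35, 0.93)),
      phiF_model = list(phi0 = syn$phi0, slope = syn$phiF_slope,
                        target_r2 = syn$target_r2, noise_sd = NULL,
                        link = "log"))
    grid <- camera_grid()
    dates <- unique(truth$date)
    irr_by_date <- lapply(dates, function(d)
      make_irradiance(continuum_level = config$irradiance$continuum_level *
                        stats::runif(1, 1 - config$irradiance$level_jitter,
                                     1 + config$irradiance$level_jitter),
                      line_depth = config$irradiance$line_depth,
                      line_width = config$irradiance$line_width))
    names(irr_by_date) <- dates

    rec <- lapply(seq_len(nrow(truth)), function(i) {
      fw <- plot_forward_spectra(truth$phiF[i], truth$ndvi_target[i],
                                 irr_by_date[[truth$date[i]]], grid)
      ret <- retrieve_sif(fw$radiance, irr_by_date[[truth$date[i]]],
                          lambda_in = config$bands$lambda_in,
                          lambda_out = config$bands$lambda_out,
                          exclusion_window = config$bands$exclusion_window,
                          n_shoulder = config$bands$n_shoulder)
      nd_meas <- ndvi(ret$apparent,
                      nir = band_window(config$bands$ndvi_nir[1],
                                        config$bands$ndvi_nir[2]),
                      red = band_window(config$bands$ndvi_red[1],
                                        config$bands$ndvi_red[2]))
      sy <- sif_yield(ret$sif, fw$par, nd_meas)
      data.frame(plot_id = truth$plot_id[i], group = truth$group[i],
                 date = truth$date[i], SIF = ret$sif, SIF_true = fw$sif_true,
                 PAR = fw$par, NDVI = nd_meas, fAPAR = sy$fapar,
                 APAR = sy$apar, SIF_yield = sy$sif_yield,
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rec)

    k <- kinetic_constants(Gamma_star = config$fvcb$Gamma_star,
                           Kc = config$fvcb$Kc, Ko = config$fvcb$Ko,
                           O = config$fvcb$O)
    capacity <- if (fit_gas_exchange) {
      curves <- make_aci_dataset(truth, ci_setpoints = config$fvcb$ci_setpoints,
                                 k = k, noise_sd = syn$aci_noise_sd,
                                 leaves_per_plot = syn$leaves_per_plot,
                                 leaf_jitter_cv = syn$leaf_jitter_cv,
                                 gm25 = config$fvcb$gm25,
                                 gm_slope = config$fvcb$gm_slope,
                                 par_chamber = config$fvcb$chamber_par)
      by_plot <- split(curves, vapply(curves, `[[`, character(1), "plot_id"))
      rows <- lapply(names(by_plot), function(p) {
        fits <- lapply(by_plot[[p]], fit_aci, k = k,
                       gm25 = config$fvcb$gm25, gm_slope = config$fvcb$gm_slope)
        pa <- plot_average(fits)
        data.frame(plot_id = p, Vcmax = pa$vcmax, Jmax = pa$jmax,
                   n_leaves = pa$n_leaves, n_jmax = pa$n_jmax,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    } else {
      data.frame(plot_id = truth$plot_id, Vcmax = truth$Vcmax_true,
                 Jmax = truth$Jmax_true,
                 n_leaves = NA_integer_, n_jmax = NA_integer_,
                 stringsAsFactors = FALSE)
    }

    merged <- merge(records, capacity, by = "plot_id")
    combos <- expand.grid(x = c("SIF", "SIF_yield", "APAR"),
                          y = c("Vcmax", "Jmax"), stringsAsFactors = FALSE)
    regs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
      grouped_regression(merged, combos$x[i], combos$y[i], scheme)))
    list(records = records, capacity = capacity, truth = truth,
         generating = attr(truth, "generating"),
         regressions = regs, merged = merged, seed = seed)
  })
}

#' Run the full image-based pipeline on synthetic scenes
#'
#' The complete processing chain per plot: scene generation -> DN
#' calibration -> k-means segmentation (k = 6) -> white-panel and
#' sunlit-leaf identification -> NDVI vegetation rule -> scan-angle mask ->
#' plot mean spectra -> timestamp-matched iFLD retrieval -> SIF yield ->
#' A/Ci fitting -> group-binned regression. Writes the SIF-record, capacity
#' and regression tables plus a self-documenting run log when `out_dir` is
#' given. Deterministic: identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed.
#' @param out_dir optional output directory for CSV tables and the run log.
#' @param fit_gas_exchange as in [simulate_campaign()].
#' @return list with `records`, `capacity`, `regressions`, `truth`,
#'   `merged`, `dropped`, `log` (character vector).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = config$seed,
                         out_dir = NULL, fit_gas_exchange = TRUE) {
  syn <- config$synthetic
  scheme <- do.call(group_scheme, config$groups)
  log <- c(sprintf("run_pipeline seed=%d  R %s", seed,
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("k-means k=%d restarts=%d; bands in/out=%g/%g nm; NDVI>%.2f; keep +-%g deg",
                   config$kmeans$k, config$kmeans$restarts,
                   config$bands$lambda_in, config$bands$lambda_out,
                   config$bands$ndvi_threshold,
                   config$geometry$keep_half_angle))
  res <- with_seed(seed, {
    truth <- make_plot_truth(scheme = scheme,
                             n_per_group = unlist(syn$n_per_group),
                             jmax_range = syn$jmax_range)
    truth <- make_trait_link(
      truth,
      apar_model = list(ndvi0 = syn$ndvi0, slope = syn$ndvi_slope,
                        noise_sd = syn$ndvi_noise, clip = c(0.35, 0.93)),
      phiF_model = list(phi0 = syn$phi0, slope = syn$phiF_slope,
                        target_r2 = syn$target_r2, noise_sd = NULL,
                        link = "log"))
    grid <- camera_grid()
    dates <- unique(truth$date)
    irr_by_date <- lapply(dates, function(d)
      make_irradiance(continuum_level = config$irradiance$continuum_level *
                        stats::runif(1, 1 - config$irradiance$level_jitter,
                                     1 + config$irradiance$level_jitter),
                      line_depth = config$irradiance$line_depth,
                      line_width = config$irradiance$line_width))
    names(irr_by_date) <- dates
    mask <- angle_mask(n_channels = syn$scene_cols,
                       half_fov = config$geometry$half_fov,
                       keep_half_angle = config$geometry$keep_half_angle)

    rec <- list()
    for (i in seq_len(nrow(truth))) {
      irr <- irr_by_date[[truth$date[i]]]
      # per-date irradiance stream + this cube's timestamp, matched like the
      # field acquisition
      cube_t <- (i - 1) * 60 + stats::runif(1, -2, 2)
      irr_t <- seq(floor(cube_t) - 10, floor(cube_t) + 10, by = 0.5)
      m <- match_irradiance(cube_t, irr_t, tolerance = config$match$tolerance_s)

      par <- integrate_par(irr)
      nd_t <- truth$ndvi_target[i]
      apar_t <- par * nd_t
      mats <- default_materials(grid, r_white = syn$r_white,
                                ndvi_leaf = nd_t,
                                f761 = truth$phiF[i] * apar_t)
      layout <- default_scene_layout(syn$scene_rows, syn$scene_cols)
      scene <- make_scene(mats, layout, irr, gain = syn$gain,
                          noise_sd = syn$scene_noise_sd)
      rc <- calibrate_dn(scene)
      cm <- cluster_image(rc, k = config$kmeans$k,
                          restarts = config$kmeans$restarts)
      wid <- identify_white_panel(cm)
      refl <- cluster_reflectance(cm, wid, syn$r_white)
      sid <- identify_sunlit_leaves(cm, refl, wid,
                                    ndvi_threshold = config$bands$ndvi_threshold)
      pm <- plot_mean_spectra(rc, cm, sid, mask, wid, syn$r_white)
      ret <- retrieve_sif(pm$radiance, irr,
                          lambda_in = config$bands$lambda_in,
                          lambda_out = config$bands$lambda_out,
                          exclusion_window = config$bands$exclusion_window,
                          n_shoulder = config$bands$n_shoulder)
      sy <- sif_yield(ret$sif, par, pm$ndvi)
      rec[[i]] <- data.frame(plot_id = truth$plot_id[i],
                             group = truth$group[i], date = truth$date[i],
                             timestamp = cube_t, time_gap = m$time_gap,
                             SIF = ret$sif,
                             SIF_true = scene$truth$sif_true[["sunlit_leaf"]],
                             PAR = par, NDVI = pm$ndvi, fAPAR = sy$fapar,
                             APAR = sy$apar, SIF_yield = sy$sif_yield,
                             stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rec)

    k <- kinetic_constants(Gamma_star = config$fvcb$Gamma_star,
                           Kc = config$fvcb$Kc, Ko = config$fvcb$Ko,
                           O = config$fvcb$O)
    capacity <- if (fit_gas_exchange) {
      curves <- make_aci_dataset(truth, ci_setpoints = config$fvcb$ci_setpoints,
                                 k = k, noise_sd = syn$aci_noise_sd,
                                 leaves_per_plot = syn$leaves_per_plot,
                                 leaf_jitter_cv = syn$leaf_jitter_cv,
                                 gm25 = config$fvcb$gm25,
                                 gm_slope = config$fvcb$gm_slope)
      by_plot <- split(curves, vapply(curves, `[[`, character(1), "plot_id"))
      do.call(rbind, lapply(names(by_plot), function(p) {
        fits <- lapply(by_plot[[p]], fit_aci, k = k,
                       gm25 = config$fvcb$gm25, gm_slope = config$fvcb$gm_slope)
        pa <- plot_average(fits)
        data.frame(plot_id = p, Vcmax = pa$vcmax, Jmax = pa$jmax,
                   n_leaves = pa$n_leaves, n_jmax = pa$n_jmax,
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(plot_id = truth$plot_id, Vcmax = truth$Vcmax_true,
                 Jmax = truth$Jmax_true, n_leaves = NA_integer_,
                 n_jmax = NA_integer_, stringsAsFactors = FALSE)
    }
    merged <- merge(records, capacity, by = "plot_id")
    combos <- expand.grid(x = c("SIF", "SIF_yield", "APAR"),
                          y = c("Vcmax", "Jmax"), stringsAsFactors = FALSE)
    regs_l <- lapply(seq_len(nrow(combos)), function(i)
      grouped_regression(merged, combos$x[i], combos$y[i], scheme))
    dropped <- do.call(rbind, lapply(regs_l, attr, "dropped"))
    list(records = records, capacity = capacity, truth = truth,
         merged = merged, regressions = do.call(rbind, regs_l),
         dropped = dropped)
  })
  n_drop <- if (is.null(res$dropped)) 0L else nrow(res$dropped)
  log <- c(log,
           sprintf("plots: %d; records: %d; dropped rows across regressions: %d",
                   nrow(res$truth), nrow(res$records), n_drop),
           if (n_drop > 0)
             sprintf("dropped: %s (%s)", res$dropped$plot_id, res$dropped$reason))
  res$log <- log
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$records, file.path(out_dir, "sif_records.csv"),
                     row.names = FALSE)
    utils::write.csv(res$capacity, file.path(out_dir, "fvcb_params.csv"),
                     row.names = FALSE)
    utils::write.csv(res$regressions, file.path(out_dir, "regressions.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  res
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (spectrum-level campaign), `run-all` (full
#' image pipeline), `regress` (group regressions from a merged CSV).
#' Flags: `--config <yaml>`, `--seed <int>`, `--out <dir>`,
#' `--x <var> --y <var>` (regress), `--in <csv>` (regress). Returns an
#' exit code (0 ok, 2 usage/config error, 1 stage failure) rather than
#' quitting, so it is testable in-session; the installed
#' `inst/scripts/sifyield` wrapper converts it to a process exit status.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: sifyield <simulate|run-all|regress> [--config f.yaml] [--seed n] [--out dir] [--in merged.csv] [--x var] [--y var]\n")
    2L
  }
  if (!length(args)) return(usage())
  cmd <- args[1]
  opt <- list(seed = NULL, config = NULL, out = NULL,
              input = NULL, x = "SIF_yield", y = "Jmax")
  i <- 2L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args)) return(usage())
    val <- args[i + 1L]
    switch(key,
           "--config" = opt$config <- val,
           "--seed" = opt$seed <- as.integer(val),
           "--out" = opt$out <- val,
           "--in" = opt$input <- val,
           "--x" = opt$x <- val,
           "--y" = opt$y <- val,
           return(usage()))
    i <- i + 2L
  }
  cfg <- tryCatch(
    if (is.null(opt$config)) pipeline_config() else read_config(opt$config),
    error = function(e) { message("config error: ", conditionMessage(e)); NULL })
  if (is.null(cfg)) return(2L)
  seed <- opt$seed %||% cfg$seed
  out <- tryCatch(switch(cmd,
    "simulate" = {
      r <- simulate_campaign(cfg, seed = seed)
      if (!is.null(opt$out)) {
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(r$merged, file.path(opt$out, "campaign.csv"),
                         row.names = FALSE)
        utils::write.csv(r$regressions, file.path(opt$out, "regressions.csv"),
                         row.names = FALSE)
      }
      0L
    },
    "run-all" = {
      run_pipeline(cfg, seed = seed, out_dir = opt$out)
      0L
    },
    "regress" = {
      if (is.null(opt$input)) return(usage())
      d <- utils::read.csv(opt$input, stringsAsFactors = FALSE)
      r <- grouped_regression(d, opt$x, opt$y,
                              do.call(group_scheme, cfg$groups))
      if (!is.null(opt$out)) {
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(r, file.path(opt$out, "regressions.csv"),
                         row.names = FALSE)
      } else print(r)
      0L
    },
    usage()),
    error = function(e) { message("stage failure: ", conditionMessage(e)); 1L })
  out
}
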