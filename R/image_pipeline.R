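# DN-to-radiance calibration, k-means segmentation of radiance cubes,
# white-panel and sunlit-leaf cluster identification, the near-nadir scan
# angle mask, and per-plot mean spectra.

#' Calibrate a DN cube to radiance
#'
#' `L = gain * DN + offset` per pixel and band. Saturated pixels (any band
#' at the 12-bit ceiling) are flagged, not silently used.
#'
#' @param cube a `"scene_cube"` from [make_scene()], or a raw
#'   row x col x band DN array (then `gain`/`offset` are required).
#' @param gain,offset per-band calibration coefficients (scalar or vector);
#'   taken from the scene cube when omitted.
#' @param wavelength band centers, nm; taken from the scene cube when omitted.
#' @return a `"radiance_cube"`: list with `data` (row x col x band),
#'   `wavelength`, `saturated` (logical pixel matrix).
#' @export
calibrate_dn <- function(cube, gain = NULL, offset = NULL, wavelength = NULL) {
  if (inherits(cube, "scene_cube")) {
    dn <- cube$dn
    gain <- gain %||% cube$gain
    offset <- offset %||% cube$offset
    wavelength <- wavelength %||% cube$wavelength
    sat <- cube$saturated
  } else {
    dn <- cube
    stopifnot(is.array(dn), length(dim(dn)) == 3L,
              !is.null(gain), !is.null(wavelength))
    offset <- offset %||% 0
    sat <- apply(dn >= 4095, c(1, 2), any)
  }
  nb <- dim(dn)[3]
  gain <- rep_len(as.numeric(gain), nb)
  offset <- rep_len(as.numeric(offset), nb)
  if (any(gain <= 0)) stopf("gain must be positive at every band")
  l <- dn
  for (b in seq_len(nb)) l[, , b] <- gain[b] * dn[, , b] + offset[b]
  structure(list(data = l, wavelength = wavelength, saturated = sat),
            class = "radiance_cube")
}

# pixels x bands matrix view of a radiance cube
cube_matrix <- function(rc) {
  d <- dim(rc$data)
  matrix(rc$data, d[1] * d[2], d[3])
}

#' Segment a radiance cube by k-means
#'
#' Standard k-means on per-pixel radiance spectra (Euclidean distance, no
#' normalization), best of `restarts` k-means++ initializations,
#' deterministic given `seed`. The ++ seeding samples successive centers
#' with probability proportional to squared distance from those already
#' chosen, which both avoids the duplicate-center failure on noiseless
#' scenes (whole regions share one spectrum) and makes poor local optima
#' rare. Saturated pixels are excluded from center estimation and assigned
#' to their nearest center afterwards.
#'
#' @param rc a `"radiance_cube"`.
#' @param k number of clusters (default 6).
#' @param seed RNG seed.
#' @param restarts number of random initializations (the best inertia wins).
#' @return a `"cluster_map"`: `labels` (row x col integer matrix, 1..k),
#'   `k`, `centers`, `mean_radiance` (per-cluster mean over member pixels
#'   and bands), `mean_spectrum` (list of radiance spectra), `sizes`,
#'   `saturated`.
#' @export
cluster_image <- function(rc, k = 6, seed = NULL, restarts = 10) {
  stopifnot(inherits(rc, "radiance_cube"))
  x <- cube_matrix(rc)
  sat <- as.vector(rc$saturated)
  xin <- x[!sat, , drop = FALSE]
  ux <- unique(xin)
  if (nrow(ux) < k)
    stopf("k = %d exceeds the %d distinct pixel spectra", k, nrow(ux))
  kmeanspp_centers <- function(x, k) {
    centers <- x[sample.int(nrow(x), 1), , drop = FALSE]
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      pick <- sample.int(nrow(x), 1, prob = d2 / sum(d2))
      centers <- rbind(centers, x[pick, ])
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[pick, ])^2))
    }
    centers
  }
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      f <- tryCatch(stats::kmeans(xin, centers = kmeanspp_centers(xin, k),
                                  iter.max = 200),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$tot.withinss < best$tot.withinss))
        best <- f
    }
    best
  })
  if (is.null(fit)) stopf("k-means failed for all %d restarts", restarts)
  # assign every pixel (including saturated) to its nearest center
  labels <- integer(nrow(x))
  labels[!sat] <- fit$cluster
  if (any(sat)) {
    d2 <- vapply(seq_len(k), function(j)
      rowSums(sweep(x[sat, , drop = FALSE], 2, fit$centers[j, ])^2),
      numeric(sum(sat)))
    labels[sat] <- max.col(-matrix(d2, nrow = sum(sat)))
  }
  lab_m <- matrix(labels, dim(rc$data)[1], dim(rc$data)[2])
  keep <- !sat
  mean_spec <- lapply(seq_len(k), function(j) {
    idx <- labels == j & keep
    v <- if (any(idx)) colMeans(x[idx, , drop = FALSE]) else fit$centers[j, ]
    make_spectrum(rc$wavelength, pmax(v, 0), "radiance")
  })
  structure(list(labels = lab_m, k = k, centers = fit$centers,
                 mean_radiance = vapply(mean_spec, function(s) mean(s$value),
                                        numeric(1)),
                 mean_spectrum = mean_spec,
                 sizes = tabulate(labels[keep], k),
                 saturated = rc$saturated,
                 wavelength = rc$wavelength),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map: k=%d, sizes: %s>\n", x$k,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Identify the white-panel cluster
#'
#' The cluster with the highest mean radiance (over member pixels and
#' bands). A tie within `tol` (relative) is refused: in-scene panels are
#' far brighter than vegetation, so a tie signals a degenerate scene that
#' needs manual disambiguation.
#'
#' @param cm a [cluster_image()] result.
#' @param tol relative tie tolerance.
#' @return cluster id (integer).
#' @export
identify_white_panel <- function(cm, tol = 1e-6) {
  stopifnot(inherits(cm, "cluster_map"), cm$k >= 2)
  o <- order(cm$mean_radiance, decreasing = TRUE)
  top <- cm$mean_radiance[o[1]]; second <- cm$mean_radiance[o[2]]
  if (top <= 0 || (top - second) / top < tol)
    stopf("white-panel identification ambiguous: top two cluster mean radiances %.6g and %.6g",
          top, second)
  o[1]
}

#' Per-cluster reflectance spectra via the white panel
#'
#' Convenience wrapper: converts every cluster's mean radiance spectrum to
#' reflectance against the identified panel cluster.
#'
#' @param cm a cluster map.
#' @param white_id panel cluster id from [identify_white_panel()].
#' @param r_white panel calibrated reflectance.
#' @return list of reflectance spectra, one per cluster (the panel's is its
#'   own flat `r_white`).
#' @export
cluster_reflectance <- function(cm, white_id, r_white = 0.99) {
  stopifnot(inherits(cm, "cluster_map"))
  sw <- cm$mean_spectrum[[white_id]]
  lapply(cm$mean_spectrum, function(s) to_reflectance(s, sw, r_white))
}

#' Identify the sunlit-leaf cluster
#'
#' Among non-panel clusters whose NDVI exceeds the vegetation threshold,
#' the brighter one (higher mean radiance) is sunlit foliage; the darker is
#' foliage in shadow. By default exactly two vegetation clusters are
#' required; with `strict = FALSE` any number >= 2 is accepted and the
#' brightest wins (a message records the choice). A single vegetation
#' cluster is returned with a warning; none is an error.
#'
#' @param cm a cluster map.
#' @param reflectance_per_cluster list of reflectance spectra, e.g. from
#'   [cluster_reflectance()].
#' @param white_id panel cluster id (excluded from the search).
#' @param ndvi_threshold vegetation NDVI cutoff (default 0.1).
#' @param strict require exactly two vegetation clusters.
#' @return sunlit cluster id; attribute `"vegetation"` lists all vegetation
#'   cluster ids.
#' @export
identify_sunlit_leaves <- function(cm, reflectance_per_cluster, white_id,
                                   ndvi_threshold = 0.1, strict = TRUE) {
  stopifnot(inherits(cm, "cluster_map"))
  ids <- setdiff(seq_len(cm$k), white_id)
  nd <- vapply(ids, function(j) ndvi(reflectance_per_cluster[[j]]), numeric(1))
  veg <- ids[nd > ndvi_threshold]
  if (length(veg) == 0)
    stopf("no vegetation clusters: all NDVI <= %.2f", ndvi_threshold)
  if (length(veg) == 1) {
    warning("only one vegetation cluster found; returning it as sunlit leaves",
            call. = FALSE)
    return(structure(veg, vegetation = veg))
  }
  if (strict && length(veg) != 2)
    stopf("%d vegetation clusters found (expected exactly 2; use strict = FALSE to take the brightest)",
          length(veg))
  if (length(veg) > 2)
    message(sprintf("%d vegetation clusters; taking the brightest as sunlit",
                    length(veg)))
  sunlit <- veg[which.max(cm$mean_radiance[veg])]
  structure(sunlit, vegetation = veg)
}

#' Cross-track scan-angle mask for a push-broom camera
#'
#' Spatial channel i (0-based) maps linearly to the view angle
#' `-half_fov + i * (2 half_fov / (n_channels - 1))`; channels with
#' `|angle| <= keep_half_angle` are kept. The kept set is symmetric about
#' the center column. Defaults select the near-nadir +-15 degrees of a
#' 640-channel, +-46.1 degrees field of view (208 columns, 0-based indices
#' 216-423).
#'
#' @param n_channels number of cross-track channels.
#' @param half_fov half field of view, degrees.
#' @param keep_half_angle kept half-angle, degrees (< `half_fov`).
#' @return an `"angle_mask"`: `kept` (logical per channel), `columns`
#'   (1-based kept indices), `angles`, and the three parameters.
#' @export
angle_mask <- function(n_channels = 640, half_fov = 46.1,
                       keep_half_angle = 15) {
  if (keep_half_angle > half_fov)
    stopf("keep_half_angle (%g) exceeds half_fov (%g)", keep_half_angle, half_fov)
  i <- seq_len(n_channels) - 1
  ang <- -half_fov + i * (2 * half_fov / (n_channels - 1))
  kept <- abs(ang) <= keep_half_angle + 1e-12
  if (!any(kept)) stopf("angle mask keeps no columns")
  structure(list(kept = kept, columns = which(kept), angles = ang,
                 n_channels = n_channels, half_fov = half_fov,
                 keep_half_angle = keep_half_angle),
            class = "angle_mask")
}

#' Per-plot mean sunlit-leaf spectra
#'
#' Arithmetic mean radiance over the unsaturated sunlit pixels inside the
#' angle mask, converted to reflectance against the panel cluster mean (the
#' panel is not angle-masked: it sits above the canopy wherever imaged).
#' NDVI is computed from the mean reflectance spectrum.
#'
#' @param rc radiance cube.
#' @param cm cluster map.
#' @param sunlit_id sunlit cluster id.
#' @param mask an [angle_mask()] whose `n_channels` matches the cube width.
#' @param white_id panel cluster id.
#' @param r_white panel reflectance.
#' @return list with `radiance` and `reflectance` spectra, `ndvi`,
#'   `n_pixels`.
#' @export
plot_mean_spectra <- function(rc, cm, sunlit_id, mask, white_id,
                              r_white = 0.99) {
  stopifnot(inherits(rc, "radiance_cube"), inherits(cm, "cluster_map"),
            inherits(mask, "angle_mask"))
  d <- dim(rc$data)
  if (mask$n_channels != d[2])
    stopf("angle mask has %d channels but cube has %d columns",
          mask$n_channels, d[2])
  colkeep <- matrix(rep(mask$kept, each = d[1]), d[1], d[2])
  sel <- cm$labels == sunlit_id & colkeep & !cm$saturated
  if (!any(sel)) stopf("no sunlit pixels inside the angle mask")
  x <- cube_matrix(rc)
  mean_rad <- make_spectrum(rc$wavelength,
                            pmax(colMeans(x[as.vector(sel), , drop = FALSE]), 0),
                            "radiance")
  refl <- to_reflectance(mean_rad, cm$mean_spectrum[[white_id]], r_white)
  list(radiance = mean_rad, reflectance = refl, ndvi = ndvi(refl),
       n_pixels = sum(sel))
}

#' Write / read an ENVI cube (BIL interleave, double precision)
#'
#' Minimal ENVI support: a binary `.bil` file plus an ASCII `.hdr` carrying
#' dimensions, interleave, data type 5 (64-bit float) and the wavelength
#' list. Enough to round-trip the cubes this pipeline produces.
#'
#' @param data row x col x band array (or a `"radiance_cube"` /
#'   `"scene_cube"`, whose payload is written).
#' @param base_path path without extension; `.bil` and `.hdr` are added.
#' @param wavelength band centers, nm.
#' @export
write_envi <- function(data, base_path, wavelength = NULL) {
  if (inherits(data, "radiance_cube")) {
    wavelength <- wavelength %||% data$wavelength; data <- data$data
  } else if (inherits(data, "scene_cube")) {
    wavelength <- wavelength %||% data$wavelength; data <- data$dn
  }
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (is.null(wavelength)) wavelength <- seq_len(d[3])
  # BIL: lines outer, then bands, then samples
  vec <- as.vector(aperm(data, c(2, 3, 1)))
  con <- file(paste0(base_path, ".bil"), "wb")
  writeBin(as.numeric(vec), con, size = 8, endian = "little")
  close(con)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bil",
           "byte order = 0",
           sprintf("wavelength = { %s }",
                   paste(format(wavelength, digits = 10), collapse = ", ")))
  writeLines(hdr, paste0(base_path, ".hdr"))
  invisible(base_path)
}

#' @rdname write_envi
#' @export
read_envi <- function(base_path) {
  hdr <- readLines(paste0(base_path, ".hdr"))
  val <- function(key) {
    ln <- grep(sprintf("^%s\\s*=", key), hdr, value = TRUE)
    if (!length(ln)) stopf("ENVI header lacks '%s'", key)
    trimws(sub(".*=", "", ln[1]))
  }
  samples <- as.integer(val("samples")); lines <- as.integer(val("lines"))
  bands <- as.integer(val("bands"))
  if (tolower(val("interleave")) != "bil")
    stopf("only BIL interleave is supported (got %s)", val("interleave"))
  dtype <- as.integer(val("data type"))
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stopf("unsupported ENVI data type %d", dtype))
  wl_line <- grep("^wavelength", hdr, value = TRUE)
  wavelength <- if (length(wl_line)) {
    as.numeric(strsplit(gsub(".*\\{|\\}", "", paste(wl_line, collapse = " ")),
                        ",")[[1]])
  } else seq_len(bands)
  con <- file(paste0(base_path, ".bil"), "rb")
  vec <- readBin(con, "double", n = samples * lines * bands, size = size,
                 endian = "little")
  close(con)
  arr <- aperm(array(vec, dim = c(samples, bands, lines)), c(3, 1, 2))
  list(data = arr, wavelength = wavelength)
}
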