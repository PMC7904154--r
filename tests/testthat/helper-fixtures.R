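# Shared in-code fixtures: tiny spectra, forward-model band quadruples and
# a label-agreement score for cluster maps.

flat_spectrum <- function(v, kind = "reflectance", wl = camera_grid()) {
  make_spectrum(wl, rep(v, length(wl)), kind)
}

# Build an fld_bands quadruple from forward-model primitives
# L = r * E / pi + F at each of the two bands.
forward_bands <- function(r_in_over_pi, r_out_over_pi, f_in, f_out,
                          e_in, e_out) {
  fld_bands(e_in = e_in, e_out = e_out,
            l_in = r_in_over_pi * e_in + f_in,
            l_out = r_out_over_pi * e_out + f_out)
}

# Fraction of pixels whose cluster, mapped to its majority truth label,
# matches the truth label map (label-permutation invariant).
label_agreement <- function(truth_labels, cluster_labels) {
  tab <- table(cluster = as.vector(cluster_labels),
               truth = as.vector(truth_labels))
  map <- colnames(tab)[apply(tab, 1, which.max)]
  names(map) <- rownames(tab)
  mean(map[as.character(as.vector(cluster_labels))] ==
         as.vector(truth_labels))
}

# Small campaign config for fast end-to-end tests
small_config <- function(...) {
  pipeline_config(
    synthetic = list(n_per_group = c(group1 = 4, group2 = 4, group3 = 4),
                     scene_rows = 18, scene_cols = 36),
    ...)
}
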