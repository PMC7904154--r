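Package: sifyield
Title: Plot-Level Solar-Induced Fluorescence Yield as a Proxy for
    Photosynthetic Capacity
Version: 0.1.0
Authors@R:
    person("sifyield", "developers", email = "sifyield@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline linking canopy solar-induced chlorophyll
    fluorescence (SIF) to photosynthetic capacity at plot scale: synthetic
    hyperspectral scene and irradiance generation with full ground truth,
    Fraunhofer Line Discrimination retrieval of SIF at the O2-A band
    (plain and improved variants with reflectance/fluorescence correction
    factors), SIF yield via NDVI-proxied absorbed photosynthetically
    active radiation, Farquhar-von Caemmerer-Berry A/Ci curve fitting of
    Vcmax and Jmax with mesophyll-conductance temperature correction, and
    group-binned linear regression of capacity on SIF and SIF yield.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
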