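# sifyield

Plot-level linkage between solar-induced chlorophyll fluorescence (SIF)
yield and photosynthetic capacity, as a tested, fully synthetic-data-backed
R pipeline.

## The problem

High-throughput phenotyping of crop trials needs non-destructive proxies
for the two capacity parameters of C3 photosynthesis — the maximum Rubisco
carboxylation rate *V*cmax and the maximum electron transport rate *J*max.
Absorbed light takes one of three competing de-excitation routes
(photochemistry, non-photochemical quenching, fluorescence), so a canopy's
*apparent fluorescence yield* — SIF normalized by absorbed
photosynthetically active radiation (APAR) — should *decrease* as electron
transport capacity increases. `sifyield` implements the full measurement
chain needed to exercise that hypothesis on plot-scale hyperspectral
imagery, and a ground-truthed synthetic scene generator that stands in for
field data:

1. **Scene generation** — push-broom style cubes (240 bands, 400–900 nm,
   ~2.1 nm sampling) built from a Lambertian forward model
   `L = r·E/π + F`, with a 99% white reference panel, sunlit/shaded
   vegetation and soil, injected fluorescence, 12-bit DN encoding, and
   downwelling irradiance carrying a Gaussian O2-A absorption trough at
   761 nm.
2. **Image processing** — DN→radiance calibration, k-means segmentation
   (k = 6, k-means++ seeding), white-panel identification by highest mean
   radiance, reflectance conversion `R = (S_cluster/S_white)·R_white`,
   NDVI > 0.1 vegetation rule, sunlit/shaded disambiguation by brightness,
   and a ±15° scan-angle mask of the ±46.1° field of view.
3. **SIF retrieval** — Fraunhofer Line Discrimination at the O2-A band
   (761 nm in, 754 nm out), plain and improved:

   SIF = (α_R·E_out·L_in − E_in·L_out) / (α_R·E_out − α_F·E_in)

   with α_R estimated by cubic interpolation of apparent reflectance
   across an exclusion window around the line, and α_F = α_R by default.
4. **SIF yield** — `PAR = ∫₄₀₀⁷⁰⁰ E(λ) dλ`, `fAPAR = NDVI`,
   `APAR = PAR·fAPAR`, `SIFy = SIF/APAR`.
5. **Gas exchange** — Farquhar–von Caemmerer–Berry A/Ci fitting of
   (*V*cmax, *J*max, *R*d) on chloroplastic CO2 (`Cc = Ci − A/gm`, with a
   linear gm temperature dependence), min-rule limitation labelling, and a
   guard that refuses to report *J*max from curves that are never electron
   transport limited.
6. **Statistics** — group-binned OLS of capacity on SIF, SIF yield and
   APAR (slope, R², in-sample RMSE, slope p-value) plus the Pearson
   correlation between *V*cmax and *J*max.

## Worked example

A three-group campaign (11/8/8 plots), generated with a negative
fluorescence-yield–*J*max link, retrieved by iFLD and fitted from
simulated A/Ci curves:

```r
library(sifyield)
r <- simulate_campaign(pipeline_config(), seed = 42)
subset(r$regressions, x_name == "SIF_yield" & y_name == "Jmax")
```

```
    group     slope intercept r_squared rmse p_value_slope  n
17 group1 -36488804       381     0.826 19.7      1.06e-04 11
18 group2 -25774966       423     0.793 22.5      3.01e-03  8
19 group3 -15286941       330     0.757 21.3      4.98e-03  8
20 pooled -14708762       325     0.558 35.3      7.65e-06 27
```

Every within-group slope is negative (higher fluorescence yield, lower
*J*max; slopes are large because SIF yield is of order 10⁻⁶ sr⁻¹ nm⁻¹),
and the pooled fit is visibly weaker than any group — time-binning
matters, because the yield baseline drifts between acquisition periods.
The recovered per-group R² (0.76–0.83) tracks the generating link
strength recorded alongside the data:

```r
r$generating
#>         group r2_phiF_jmax r2_ndvi_vcmax
#> group1 group1        0.777         0.733
#> group2 group2        0.804         0.833
#> group3 group3        0.707         0.248
```

Per-plot records carry the full retrieval context; SIF is of order
10⁻³ W m⁻² sr⁻¹ nm⁻¹ (= order 1 W sr⁻¹ μm⁻¹ m⁻²) and PAR of order
300 W m⁻², so SIF yield lands near 3·10⁻⁶ sr⁻¹ nm⁻¹:

```r
head(r$records[, c("plot_id","group","SIF","PAR","NDVI","APAR","SIF_yield")], 4)
#>   plot_id  group      SIF PAR  NDVI APAR SIF_yield
#> 1     p01 group1 0.000665 304 0.879  267  2.49e-06
#> 2     p02 group1 0.000603 293 0.816  239  2.52e-06
#> 3     p03 group1 0.001296 302 0.785  237  5.46e-06
#> 4     p04 group1 0.000671 304 0.803  244  2.75e-06
```

`run_pipeline()` runs the same experiment through the *image* path —
scene cubes, k-means, panel/sunlit identification, angle masking,
timestamp matching — and writes `sif_records.csv`, `fvcb_params.csv`,
`regressions.csv` and a run log. A small CLI wraps both:

```sh
Rscript inst/scripts/sifyield simulate --seed 3 --out out/
Rscript inst/scripts/sifyield run-all  --config cfg.yaml --out out/
```

## Scope notes

No atmospheric radiative transfer, BRDF, solar geometry, O2-B retrieval,
spectral-fitting retrieval, NPQ quantification or TPU limitation; see the
methods vignette (`vignettes/sifyield-methods.Rmd`) for the model
assumptions and design decisions.
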