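# hncoupling

Grid-scale analysis of human–nature relationships: how human activity
intensity and ecosystem quality co-evolve across a landscape, where they
cooperate or collide, how strongly the two systems are coupled, and what
drives that coupling.

The package is aimed at landscape / urban ecologists working with aligned
raster time series of a **human footprint index (HFI)** and vegetation
indicators, who want a reproducible, tested implementation of a workflow
that is usually assembled ad hoc from GIS tools and scripts:

1. **Ecosystem quality index.**
   `EQI = 100 × (LAI + GPP + FVC) / 3`, with
   `FVC = (EVI − EVI_soil) / (EVI_veg − EVI_soil)` clamped to [0, 1] and
   the 5th/95th EVI percentiles as the bare-soil / full-vegetation
   references. Min–max normalisation (pooled across epochs by default) and
   exact Fisher–Jenks natural-breaks classification for five-level maps.
2. **Improved four-quadrant model.** Per-cell changes (ΔHFI, ΔEQI)
   classified as coordination (+,+), good-for-nature (−,+), degradation
   (−,−) or conflict (+,−); changes smaller than 10% of the change-SD are
   insignificant.
3. **Coupling coordination degree.**
   `C = 2·√(HFI·EQI)/(HFI+EQI)`, `T = a·HFI + b·EQI` (a = b = 0.5),
   `CCD = √(C·T)`, classified into five coordination levels.
4. **Driver screening.** Variance inflation factors (cutoff 6) intersected
   with random-forest permutation importance (%IncMSE, 500 trees) made
   significant against a response-permutation null.
5. **PLS path modeling** (from scratch): Mode A measurement model,
   path-scheme inner weighting, structural OLS, GOF = √(communality·R²),
   direct/indirect/total effect decomposition by path tracing, and
   bootstrap standard errors with star-coded significance.
6. **Pipeline.** One seeded, config-driven run producing rasters
   (plain-text ASCII grids), CSV tables, a JSON report and a log —
   byte-identical for identical config + seed.

A synthetic-data module generates every input with known ground truth
(planted quadrant blocks, known latent path models, requested driver
collinearity), so each stage — and the pipeline end-to-end — is verified
against planted truth rather than against itself.

## Worked example

```r
library(hncoupling)

# synthetic scene with known truth: HFI rising ~35.7 -> 46.1, EQI
# declining ~50.4 -> 47.2 over 2000/2010/2020, four planted quadrant
# blocks, drivers generated from a known latent path model
spec   <- synthetic_raster_spec(shape = c(80, 80), noise_sd = 1,
                                nodata_fraction = 0.02, seed = 11)
bundle <- generate_analysis_bundle(spec)

cfg <- run_config(bundle$hfi, bundle$eqi, bundle$drivers,
                  n_trees = 100, n_permutations = 49, sample_max = 3200,
                  seed = 42)
report <- run_pipeline(cfg)
report
#> <run_report>
#>   epochs: 2000, 2010, 2020
#>   quadrant shares: coordination 25.1%, good_for_nature 24.9%, degradation 25.0%, conflict 25.0%, insignificant 0.0%
#>   region coordination: 814 rows, GOF 0.510 (strong)
#>   region good_for_nature: 799 rows, GOF 0.504 (strong)
#>   region degradation: 798 rows, GOF 0.534 (strong)
#>   region conflict: 789 rows, GOF 0.502 (strong)

report$index_means
#>   epoch hfi_mean eqi_mean
#> 1  2000 35.73444 50.38302
#> 2  2010 40.94786 48.80296
#> 3  2020 46.15556 47.20301
```

The quadrant shares recover the four planted 25% blocks, and the index
means reproduce the planted rising-HFI / declining-EQI trajectory. Inside
the coordination region, screening retains all eleven drivers and the
fitted path model recovers the planted structure (the generating
`Veg -> CCD` coefficient is 0.6; composite-based estimation attenuates it
slightly):

```r
report$regions$coordination$pls$fit
#> <pls_fit> 814 obs, 5 latents, converged in 3 iteration(s)
#>   GOF 0.5100 (strong)
#>   from  to coefficient
#> 1  Ter Hum      -0.372
#> 2  Ter Veg       0.359
#> 3  Ter CCD      -0.300
#> 4  Hum Clm       0.387
#> 5  Hum Veg      -0.205
#> 6  Hum CCD       0.439
#> 7  Clm Veg       0.209
#> 8  Clm CCD       0.295
#> 9  Veg CCD       0.552

subset(report$regions$coordination$pls$effects, to == "CCD")
#>    from  to     direct   indirect      total
#> 4   Ter CCD -0.2998993 0.01797370 -0.2819256
#> 7   Hum CCD  0.4393548 0.04526704  0.4846219
#> 9   Clm CCD  0.2949413 0.11553002  0.4104713
#> 10  Veg CCD  0.5520434 0.00000000  0.5520434
```

Effects are read like any recursive path model: vegetation has the largest
direct effect on the coupling coordination degree, human activity a large
positive total effect (direct plus indirect through climate and
vegetation), terrain a negative one.

Real data enter the same way: load per-epoch layers with
`read_ascii_grid()` (or any route that yields matrices), build
`aligned_stack`s and a named driver list, and call `run_config()` /
`run_pipeline()` — or drive it from a YAML file with `read_run_config()`
and the thin CLI in `inst/scripts/hncoupling-run.R`.

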