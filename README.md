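# ephemNDVI

Remote-sensing phenology of early-spring ephemeral plants in cold arid
deserts.

Ephemeral plants are desert annuals that complete their whole life cycle —
germination on snowmelt, rapid growth, flowering and senescence — within two
to three months of early spring. On a dense (8-day composite) NDVI time
series covering day-of-year 65–225 their signature is unmistakable: a rapid
rise to a spring peak, a rapid collapse to a post-peak minimum, then a slow
secondary rise as xerophytic shrubs green up. `ephemNDVI` turns that
signature into a quantitative analysis chain for ecologists studying
cold-desert vegetation dynamics:

1. **Phenology extraction.** Per pixel-year, three key points on the NDVI
   curve are located: the regreening onset *c*, the peak *a*, and the
   post-peak minimum *b* (with `NDVI = (ρ_NIR − ρ_RED)/(ρ_NIR + ρ_RED)`).
   The ephemeral contribution is the life-cycle increment

   `NDVI_eph = (NDVI_a − NDVI_c) + (NDVI_a − NDVI_b)`

   — rise plus decline around the spring peak. Masking uses the multi-year
   mean of the decline `NDVI_a − NDVI_b` as a threshold, and the masked
   field is classified into Sparse / Less / Medium vigor classes by fixed
   or exact Jenks natural-breaks cutpoints. Occurrence points validate the
   mask per plant family.
2. **Temporal dynamics.** Piecewise linear segmentation of the annual
   regional mean (exhaustive breakpoint search) and ensemble empirical mode
   decomposition (EEMD) with per-mode variance contributions, mean periods,
   and the residual trend.
3. **Spatial dynamics.** Class-to-class transition matrices in km²,
   area-weighted centroid migration (distance and bearing), and per-pixel
   coefficient-of-variation stability maps.
4. **Drivers.** Random-forest Gini importance grouped into snow /
   precipitation / temperature / topography factor categories, Pearson
   correlation matrices, and partial least squares path modeling (PLS-SEM)
   with direct / indirect / total effects and the goodness-of-fit index
   `GoF = sqrt(mean communality × mean R²)`.
5. **Projection.** A small patch-based convolutional regressor (5×5×12
   patches, two 3×3 convolution stages, max-pool, dense head) maps 12
   environmental rasters to `NDVI_eph` under 5-fold cross-validation, then
   projects the distribution under altered climate rasters in which only
   the four substituted climate variables change.

A seeded synthetic-scene generator (`scene_config()`, `gen_ndvi_cube()`,
`gen_env_rasters()`, `gen_occurrences()`) emulates the statistical
structure of a cold-desert study system — south-high/north-low vigor
gradient, snow/precipitation-driven amplitudes, occurrence points
concentrated in high-NDVI cells — so the entire chain runs and is tested
without any satellite downloads.

## Worked example

```r
library(ephemNDVI)

sc   <- scene_config(grid_rows = 32, grid_cols = 32, years = 2001:2022, seed = 1)
env  <- gen_env_rasters(sc)
cube <- gen_ndvi_cube(sc, phenology_preset(), env)

# key points of the regional mean seasonal curve
s <- apply(cube$values, 4, mean)
detect_key_points(s, cube$composite_days)
#> <pheno_keypoints> status: ok
#>   onset  DOYc=81 (NDVI 0.0499)
#>   peak   DOYa=137 (NDVI 0.1628)
#>   trough DOYb=161 (NDVI 0.0503)

eph  <- ephemeral_ndvi_map(cube)
mask <- build_distribution_mask(eph)
mask
#> <dist_mask> 482/1024 pixels in-mask (mode global_mean, threshold 0.1375)

cmap <- classify_ndvi(eph, mask, method = "jenks")
occ  <- gen_occurrences(mask, n_points = 185, inside_prob = 0.8216, seed = 1)
tail(validate_occurrences(mask, occ), 3)
#>            family   n inside outside accuracy_pct
#> 10 Plantaninaceae   5      3       2        60.00
#> 11   Papaveraceae   5      4       1        80.00
#> 12            Sum 189    152      37        80.42

ser <- annual_mean_series(eph, mask)
piecewise_segments(ser, n_breaks = 3)
#> <segmentation> 4 segments, SSE 0.01844
#>  segment start_year end_year       slope  intercept    p_value
#>       P1       2001     2011 0.004387723  -8.501685 0.26608093
#>       P2       2012     2014 0.043897600 -88.054722 0.03744279
#>       P3       2015     2017 0.045816111 -92.015290 0.35868691
#>       P4       2018     2022 0.016600486 -33.157410 0.20608916

eemd(ser$value, ensemble_size = 100, noise_sd_frac = 0.2, seed = 8)
#> <imf_set> 2 IMF(s) + residual, length 22
#>  component period_years variance_pct
#>       IMF1          3.1        51.63
#>       IMF2         11.0        16.08
#>        Res           NA        32.29
```

The peak lands on DOY 137 (mid May) and the post-peak minimum on DOY 161
(mid June) — the calibrated life-cycle window of the spring ephemerals. The
mask threshold (0.1375) is the spatial mean of the per-pixel multi-year
mean decline; 482 of 1024 pixels form the distribution area, validated at
80.4% against 189 synthetic occurrence points. The annual series decomposes
into a dominant ~3-year oscillation plus a slow residual trend.

The whole pipeline — generation through scenario projection, with all
reports on disk — is one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "ephem-run", seed = 1))
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --out-dir ephem-run
--seed 1`.

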