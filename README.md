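# urbanmosaic

Global land-cover maps represent cities as one homogeneous "built" class,
which flattens exactly the heterogeneity — yards, parks, road hierarchies,
building densities — that drives urban wildlife distributions. `urbanmosaic`
rebuilds that heterogeneity from community-mapped geographic features
(polygons and lines with key–value tags in the OpenStreetMap vocabulary) and
carries it through to ecological inference. It is written for spatial and
urban ecologists who need comparable, fine-resolution landscape covariates in
places where no local government product exists.

The pipeline, end to end:

1. **Ingest** tagged features from GeoJSON (projected, meter-unit CRS
   required), unpacking the `"key"=>"value"` packed-tag dialect.
2. **Classify** them into a 27-class framework (human land use, green cover,
   infrastructure) via an editable YAML rule registry; buffer linear features
   into polygons at 6 m per lane, imputing per-type mean lane counts where
   the `lanes` tag is missing.
3. **Rasterize and merge** per-class layers at 30 m under a priority
   structure (land use < green < water < buildings < roads by traffic <
   paths/railways/fences), tiled merging being bit-identical to whole-grid
   merging.
4. **Integrate** with a coarse global land-cover raster: empty cells take
   the reclassified global class, and global "built" becomes class 28,
   *developed unknown*.
5. **Validate**: completeness before backfill, stratified accuracy with
   Cohen's kappa `κ = (p_o − p_e)/(1 − p_e)` and per-class precision
   `TP_c/(TP_c + FP_c)`, and paired building-area regression across cities.
6. **Index**: an urbanization index on the 30 m grid,
   `w_b·P_bld + w_r·(1 − d̂_road) − w_w·(1 − d̂_water) −
   w_v·(3P_forest + 2P_lowveg + P_open)/6`,
   with 900 m / 450 m focal windows and min–max-normalized distances,
   scaled to [0, 100].
7. **Occupancy**: autologistic multi-season models for weekly camera-trap
   detection histories — `ψ_t = logit⁻¹(x'β + θ·z_{t−1})`, weekly detections
   Bernoulli(`p·z_t`) — fit by exact marginal maximum likelihood, compared
   by ΔAIC and Akaike weights, with occupancy ratios between covariate
   extremes from the stationary distribution of the fitted chain.

A seeded synthetic-city generator with an independently computed ground
truth makes every stage testable offline.

## Worked example

```r
library(urbanmosaic)

# a synthetic 6 x 6 km city (200 x 200 cells, ~390 tagged features)
city <- generate_city(city_recipe(seed = 42))
lulc <- build_lulc(city$features, city$grid)          # classify+buffer+merge
mean(lulc$values == city$ground_truth$values)
#> [1] 1

# backfill from a coarse global raster and check completeness
glob      <- generate_global_lulc(city$recipe$extent, 30, seed = 42)
m         <- default_reclass_map()
reclassed <- reclass_global(glob, m$entries, m$developed_codes)
completeness(lulc, reclassed, default_registry())
#> <completeness_report>
#>   overall completeness: 0.9454
#>   urban proportion:     0.44
#>   unknown shares (7/17/28): 0.0066 / 0.0048 / 0
full <- integrate_global(lulc, reclassed)

# urbanization index and site covariates
idx <- urbanization_index(full)
idx
#> <num_raster> 200x200 cells @ 30 m, range [33.331, 66.347]
set.seed(42)
sites <- data.frame(site = 1:30, x = runif(30, 900, 5100),
                    y = runif(30, 900, 5100))
cov <- summarize_covariate(idx, sites)   # 1 km radius, centered and scaled

# simulated camera-trap data at those sites, then model competition
sim <- simulate_detections(occ_sim_recipe(seed = 42, n_sites = 30,
                                          n_seasons = 4, weeks_per_season = 5,
                                          beta = c(-0.3, 0.9), theta = 1,
                                          alpha = 0.4, x = cov$x))
naive_occupancy(sim$history)$average
#> [1] 0.7833333
fit_c <- fit_autologistic(sim$history, cov, "covariate")
fit_n <- fit_autologistic(sim$history, formula = "null")
fit_c
#> <occ_fit> covariate model: logLik -365.063, K 4, AIC 738.126
#>       estimate     se
#> beta0   1.2520 0.3604
#> beta1   0.5947 0.2755
#> theta   0.2688 0.4698
#> alpha   0.5797 0.0984
compare_aic(list(null = fit_n, urbanization = fit_c))
#>         model K logLik   AIC  dAIC weight cum_weight competitive
#>  urbanization 4 -365.1 738.1 0.000 0.8434     0.8434        TRUE
#>          null 3 -367.7 741.5 3.367 0.1566     1.0000       FALSE
occupancy_ratio(fit_c, min(cov$x), max(cov$x))
#> [1] 1.501038
```

Reading the output: the merged raster reproduces the analytically known
ground truth on every cell; ~94.5% of the study area is covered by detailed
features before global backfill; the index summarizes each site's
surroundings within 1 km; with 30 sites the urbanization model beats the
null (ΔAIC 3.4, Akaike weight 0.84), and expected occupancy is about 1.5×
higher at the most urban site than at the least urban one.

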