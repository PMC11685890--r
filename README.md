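# rangebalance

Grassland carrying capacity and grazing–livestock balance assessment for
rangeland systems, at desk scale.

Pastoral regions such as the Mongolian Plateau face a recurring management
question: does the standing forage of a province's grassland support the
livestock actually grazed on it? `rangebalance` implements the full
assessment chain a rangeland analyst runs to answer it — from seasonal
remote-sensing composites and field biomass samples to regional carrying
capacities, a supply/demand index and a four-level load classification —
together with a fully seeded synthetic-data generator, so every stage of the
pipeline can be tested against known ground truth without any satellite
download.

## The model

**Above-ground biomass (AGB).** Field-measured biomass (g/m²) is linked to
three seasonal predictors: the maximum-value composite of NDVI (per-pixel
maximum over the summer time series, suppressing cloud and aerosol dips),
mean summer land-surface temperature (°C), and total summer precipitation
(mm). The default model is ordinary least squares,

    AGB = b0 + b1·NDVI + b2·P + b3·LST + ε,

validated by Pearson correlation and RMSE at the sample points; a random
forest is available behind the same interface. The predicted map is binned
into five productivity classes (< 200, 200–250, 250–300, 300–350,
> 350 g/m²).

**Carrying capacity (GCC).** For region *i* with mean grassland biomass
AGB_i (g/m²) and grassland area A_i (m²),

    GCC_i = AGB_i · A_i · u / (Int · D · 1000)

in standard sheep units (SU), where u = 0.2 is the usable fraction of
standing forage, Int = 1.8 kg/day the daily intake of one SU, D = 180 days
the grazing season, and 1000 converts grams to kilograms. With these
defaults the per-hectare capacity is exactly AGB/162 SU/ha.

**Carrying state (GCSI).** Species headcounts convert to SU with the
national-standard coefficients (cattle 5, horse 6, camel 7, sheep 1,
goat 0.9, merged sheep/goat 0.95, donkey 3, mule 5), and

    GCSI_i = LN_i / GCC_i

compares actual stock LN_i with capacity. Load classes: light load
(< 0.8), normal (0.8–1.0), overload (1.0–1.3), severe overload (> 1.3).

**Land cover.** Grassland area comes from a random-forest land-cover
classification on a 10-band feature stack, assessed by overall accuracy,
Cohen's kappa, and per-class precision/recall on a held-out validation
sample.

The package ships the published 2018–2022 standard-livestock-unit table for
the 16 eastern-plateau provinces and leagues
(`table1_fixture()`), used for regional trend statistics.

## Worked example

```r
library(rangebalance)

scn <- scenario(seed = 1)       # 128 x 128 km synthetic steppe, 8 provinces
res <- run_pipeline(scn)

res$agb$model
#> <agb_model> linear, n = 327
#>  intercept       ndvi        lst     precip
#>  -151.8557   300.4175    -4.9043     1.1985

res$agb$validation
#> $r 0.997   $rmse 4.6   $n 327

subset(res$balance, year == 2022)[, c("region", "gcc_su_per_ha",
                                      "gcsi", "load_class")]
#>    region gcc_su_per_ha  gcsi      load_class
#> 5     R01         1.274 0.564      light load
#> 15    R03         1.730 1.761 severe overload
#> 25    R05         0.901 1.803 severe overload
#> 40    R08         1.490 0.649      light load  (… 8 regions)
```

The fitted coefficients sit within 2% of the generative truth
(−150, 300, 1.2, −5); regional capacities of 0.9–1.9 SU/ha bracket the
1.8 SU/ha plateau-average regime the formula implies at typical steppe
biomass, and the load classes recover the configured stocking state of
every region.

On the published SU table:

```r
tab <- table1_fixture()
growth_rate(tab, "Chifeng", 2018, 2022)   # 1.9  (most stable region)
mean_growth_rate(tab, 2018, 2022)         # 17.9 (regional average, %)
```

A thin CLI wraps the same pipeline
(`Rscript inst/cli/rangebalance.R balance --seed 1 --outdir out/`) with
subcommands `simulate | landcover | agb | capacity | balance | report`.

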