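# dwmlis

Line-intersect sampling (LIS) estimators for downed dead wood (DDW)
inventories, in the data model of the United States national forest
inventory's down woody material (DWM) tables — plus a spatial simulator
that makes every estimator verifiable against analytically known truth
without downloading any data.

## Who this is for

Forest biometricians and ecologists working with transect-sampled downed
wood: coarse woody debris (CWD, pieces >= 7.61 cm diameter), residue
piles, fine woody debris (FWD, three size classes tallied by count), and
the duff and litter forest-floor layers. The package

* reads/writes/validates CSV tables shaped like the FIA Datamart DWM
  exports (`PLOT`, `COND`, `DWM_COARSE_WOODY_DEBRIS`, ... with the
  production column names `PLT_CN`, `TRANSDIA`, `DECAYCD`, `SPCD`,
  `SMALLCT`, `COMP_HT`, ...),
* computes the plot-level LIS estimators for volume, biomass, carbon,
  percent cover and linear length, with domain (species, decay class,
  forest type, condition) indicators,
* combines plots into post-stratified population means, totals and
  standard errors,
* and simulates synthetic stands with closed-form per-hectare truth to
  validate the whole chain by Monte Carlo.

## The estimators

For a plot with total transect length \(L\) (ft; 192 ft = 8 x 24 ft under
the current national design), piece diameters \(DI\) and hollow diameters
\(DH\) (in) at the transect crossing, pile compacted heights \(PH\) and
occupied transect lengths \(PL\) (ft), and a 0/1 domain indicator
\(\delta\):

* CWD volume: \(y = \frac{1}{L}\left[C_1\frac{\pi^2}{8}\sum (DI^2 -
  DH^2)\,\delta + C_2\frac{\pi}{2}\sum PH \cdot PL\,\delta\right]\),
  with \(C_1 = 43560/144\), \(C_2 = 43560\) (ft³/acre) or 21.1659,
  3047.89 (m³/ha).
* CWD biomass/carbon: the same sums weighted by bulk density (specific
  gravity x 62.4 lb/ft³ x decay-class ratio, x carbon ratio for carbon);
  \(C_1 = 0.15125\), \(C_2 = 21.78\) (short tons/acre) or 0.33905,
  48.8233 (Mg/ha).
* Percent cover: \(y = \frac{100\pi}{2L}\left[\sum (DI/12)\,\delta +
  \sum PL\,\delta\right]\).
* Linear length: \(y = C\frac{\pi}{2L}\sum\delta\), \(C = 43560\)
  (ft/acre) or 32808.4 (m/ha).
* FWD volume per size class: \(y = C\frac{\pi^2}{8L}\sum n \cdot
  QMD^2\,\delta\) from per-subplot counts \(n\) and the class quadratic
  mean diameter.
* Duff/litter volume: \(y = C\,\sum y_{jm}\delta / (n_s n_{p,s})\) from
  point depths, \(C = 43560/12\) (ft³/acre) or 253.991 (m³/ha).

Every metric constant is independently re-derived from exact unit
definitions (`derive_metric_constant()`), and estimation always uses the
published values so results match the national database digit for digit.

## Worked example

```r
library(dwmlis)

# One solid 10-inch piece crossed on a standard 192-ft plot:
pieces <- data.frame(PLT_CN = "p1", SUBP = 1L, TRANSECT = 30L, CWDID = 1L,
                     CONDID = 1L, SPCD = 202L, DECAYCD = 3L,
                     TRANSDIA = 10, HOLLOW_DIA = 0)
cwd_volume(pieces)
#> cwd_volume [imperial, domain: all] = 194.3721 ft3/acre
cwd_volume(pieces, units = "metric")
#> cwd_volume [metric, domain: all] = 13.6002 m3/ha
cwd_mass(pieces)  # Douglas-fir, decay class 3, synthetic reference
#> cwd_biomass [imperial, domain: all] = 2.319637 tons/acre

# A synthetic stand with known truth, sampled at 25 random plots:
stand <- generate_stand(stand_params(cwd_per_ha = 200), seed = 42)
stand
#> Synthetic DWM stand: 261 logs, 0 piles over 1.2 ha (seed 42 )
#>   truth: CWD 29.56 m3/ha, 10.21 Mg/ha, 1002 m/ha, cover 1.83%
ds <- make_dataset(stand, n_plots = 25, seed = 42)
est <- estimate_all(ds, attributes = "cwd_volume", units = "metric")
post_stratified_mean(est$VALUE, rep("all", nrow(est)), c(all = 1))
#> Post-stratified estimate: mean 33.5663 (SE 3.3528), n = 25
# 25 plots of 8 short transects each: a noisy but unbiased estimate of
# the 29.56 m3/ha truth (within ~1.2 SE here).

# Design-unbiasedness by Monte Carlo:
run_monte_carlo(stand, n_plots = 2000, seed = 7,
                attributes = c("cwd_volume", "cwd_length"))
#> Monte-Carlo validation over 2000 plots (seed 7 )
#>   attribute      truth    mc_mean      mc_se        z n_plots
#>  cwd_volume   29.55565   30.62765  0.4277331 2.506234    2000
#>  cwd_length 1002.19388 1034.32986 11.3526788 2.830696    2000
# z = (mean - truth)/SE behaves like a standard normal draw; |z| < 3.
```

## Command line

A wrapper script ships at `inst/cli/dwmlis`
(`system.file("cli", "dwmlis", package = "dwmlis")` once installed):

```sh
dwmlis simulate  --out tables --seed 7 --n-plots 50
dwmlis estimate  --tables tables --out est --units both \
                 --domain "DECAYCD in 1,2,3,4" --strata strata.csv
dwmlis validate  --out report --seed 7 --n-plots 2000
dwmlis constants --out consts     # published vs derived constant table
```

## Caveats

The bundled species and forest-type-group reference tables are clearly
labeled synthetic stand-ins (realistic magnitudes, not the published
reference data), and the FWD quadratic mean diameters are placeholders —
supply your own `REF_SPECIES` / `REF_FOREST_TYPE_GROUP` files for
production estimates. See the methods vignette
(`vignettes/dwm-estimation.Rmd`) for the model, its assumptions and the
design decisions.
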