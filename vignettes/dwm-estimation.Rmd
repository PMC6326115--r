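---
title: "Estimating downed dead wood from line-intersect samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating downed dead wood from line-intersect samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwmlis)
```

## The problem

Downed dead wood — fallen stems and branches, plus the duff and litter
layers of the forest floor — is a major pool in forest carbon budgets, a
fuel component in fire-behavior models, and habitat for much of the
dead-wood-dependent biota. National inventories sample it with
line-intersect sampling (LIS): one-dimensional transects are laid across
the forest, and any piece whose centerline crosses a transect joins the
sample. The US inventory's current plot is a cluster of four subplots
(center plus three satellites 36.58 m away at 0°, 120° and 240°), each
anchoring two 24-ft (7.32 m) transects, for 192 ft (58.5 m) of transect
per plot; the 2002–2011 design used three transects per subplot (288 ft,
87.8 m). `dwmlis` implements the plot-level estimators for this design,
the post-stratified population estimators on top of them, and a spatial
simulator that provides ground truth for all of it.

## The estimators and their assumptions

The core LIS identity is that, for a transect of total length $L$ laid
over pieces with **uniformly random orientations**, the probability a
piece is crossed is proportional to $L \times \ell \, \mathbb{E}|\sin
\theta| = 2 L \ell / \pi$ for a piece of length $\ell$. Weighting each
crossing by the piece's cross-sectional area at the crossing point
$\left(\frac{\pi}{4} DI^2\right)$ and inverting the inclusion probability
yields the volume-per-area estimator

$$y_{d} = \frac{1}{L}\left[C_1\frac{\pi^2}{8}\sum_t \left(DI_t^2 -
DH_t^2\right)\delta_t + C_2\frac{\pi}{2}\sum_t PH_t \, PL_t \,
\delta_t\right],$$

whose second term handles residue piles — accumulations too large or
dangerous to measure piece by piece, recorded as a compacted height $PH$
over the transect length $PL$ they occupy. Hollow pieces subtract the
hollow cross-section ($DH$ is the hollow diameter at the crossing; a
missing value is read as 0, i.e. solid — the field protocol only records
it when the piece is hollow). Analogous estimators give biomass and
carbon (density-weighted sums), percent cover, linear length per area,
fine-woody-debris volume from per-subplot counts and a class quadratic
mean diameter, and duff/litter volume from point depths. The estimators
assume:

* piece orientations are uniform (the design's defense is opposing
  transect azimuths per subplot),
* diameters/depths are measured without error at the crossing/point,
* the domain indicator $\delta$ is evaluated from recorded attributes —
  a piece lying exactly on a condition boundary keeps the condition the
  crew recorded; no geometric re-assignment is attempted.

$L$ is the **full protocol length** (192 ft by default) even when part of
the plot is non-forest: condition membership enters only through
$\delta$. Analysts who want the strict-conditional variant can pass
`L_ft = condition_transect_length(segments, condid)`.

Estimation uses the published unit constants verbatim (so outputs match
the national database digit for digit); each metric constant is
independently re-derived from the exact definitions 1 in = 0.0254 m,
1 ft = 0.3048 m, 1 acre = 43560 ft², 1 lb = 0.45359237 kg, and the test
suite requires agreement within $5\times10^{-4}$ relative (the published
values carry about six significant digits; two of them, 3047.89 and
253.991, disagree with exact re-derivation in the fifth digit, and the
published values win).

```{r constants}
constants_table()
```

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `cwd_transect_length_ft` | ft | 24 | protocol transect per azimuth |
| `transects_per_subplot` | — | 2 (2012+), 3 (2002–11) | protocol revision |
| `fwd_sm_md_length_ft` / `fwd_large_length_ft` | ft | 6 / 10 | FWD tally segments per subplot (24 / 40 ft per plot) |
| `dufflitter_points_per_subplot` | — | 2 (2012+), 3 (2002–11) | depth points at transect ends |
| bulk density | lb/ft³ | specific gravity × 62.4 × decay ratio | 62.4 lb/ft³ is the conventional water density in these units |
| FWD QMD | in | 0.15 / 0.62 / 1.85 | **placeholders** inside the class bounds (0–0.24, 0.25–0.9, 1.0–2.9 in); production values come from an external diameter study |
| `denominator` (duff/litter) | — | `"protocol"` | the published estimator keeps the fixed $n_s n_{p,s}$ denominator; `"sampled"` rescales to sampled points (documented deviation) |
| nonresponse $\bar p$ | — | 1 | the plot estimators omit the correction; `apply_nonresponse_adjustment()` applies it per stratum when wanted |

Transect azimuths are not numerically specified by the protocol
documents; the defaults ({30°, 150°}, plus 270° for the three-transect
design) are an opposing-orientation layout, configurable and labeled
non-authoritative.

## Population estimation

Plot estimates combine by post-stratification: $\hat{\bar Y} = \sum_h W_h
\bar y_h$ with known stratum area fractions $W_h$, and

$$\hat V = \frac{1}{n}\left[\sum_h W_h s^2_h + \sum_h (1 - W_h)
\frac{n_h}{n}\frac{s^2_h}{n}\right],$$

the textbook two-term form: the first term is the conditional variance
under proportional allocation, the second the lower-order penalty for the
stratum sample sizes being random. During development we found that a
variant circulating with $W_h n_h s^2_h / n$ as the first term (i.e. an
extra $n_h/n$ factor) underestimates the variance by about half for two
equal strata and drives nominal 95% intervals to roughly 80% coverage in
the package's own Monte-Carlo calibration; the first term must be $W_h
n_h s^2_h / n_h = W_h s^2_h$. The calibration test (1000 replicate
simulated populations of 150 plots, two spatial strata) requires coverage
within 95% ± 2%. The production inventory's exact variance may differ in
finite-population details; plots straddling estimation units are an
error, not prorated.

## What the simulator emulates — and what it does not

`generate_stand()` draws a homogeneous Poisson population of straight,
horizontal logs with uniform azimuths, linear taper between a lognormal
large-end diameter and a tapered small end (both clamped at the 7.61 cm
CWD threshold), species and decay classes from fixed frequency vectors,
occasional hollow centers, optional circular residue piles, per-class FWD
crossing intensities, and smooth periodic duff/litter depth surfaces.
Defaults describe a mesic conifer stand: ~120 logs/ha with ~20 cm
large-end diameters and 4–5 m lengths, i.e. a CWD load on the order of
15–30 m³/ha — mid-range for temperate forests; FWD intensities (2 / 1 /
0.3 crossings per metre for small/medium/large) and duff/litter means
(1.5 / 1.0 in) are likewise typical fuel-inventory magnitudes. These were
chosen once as a realistic stated world and are not tuned to any test.

Truth is closed-form: frustum volumes $\frac{\pi \ell}{12}(D^2 + Dd +
d^2)$, hollow-reduced by $(1-h^2)$, summed per hectare; length and
plan-area (cover) sums; for FWD, whose records are counts with no piece
geometry, the truth is intensity-defined (the estimand of the count
estimator under the exact constants); for piles the truth is the pile
estimator's estimand, $\frac{\pi}{2} PH \times$ plan area per area — the
protocol records no independent pile volume for it to be compared against.
Decay-class-5 logs are generated to already satisfy their stricter
thresholds (≥ 12.7 cm over ≥ 1.52 m), so the class-5 tally filter never
truncates them and the full frustum stays the truth.

Design choices of note: the region is **toroidal** (sampling wraps at the
edges), the standard device for design-unbiasedness experiments — it
removes edge effects that are a real phenomenon in bounded forests;
random streams are split hierarchically from one seed, so adding plots
never perturbs earlier plots; logs are unbranched (the field definition
treats forks as separate pieces, so this loses no generality) and
horizontal (the protocol's horizontal-distance convention makes slope a
separate, out-of-scope correction).

A green Monte-Carlo test therefore establishes design-unbiasedness of the
implementation **under the model's assumptions** — uniform orientations,
exact measurement, single condition. It says nothing about measurement
error, orientation bias after directional windthrow, slope effects, or
condition-mapping subtleties in real data.

```{r mc}
stand <- generate_stand(stand_params(), seed = 7)
run_monte_carlo(stand, n_plots = 1500, seed = 8,
                attributes = c("cwd_volume", "cwd_length", "cwd_cover"))
```

## Numerical and degenerate-input choices

* Estimates are plain sums — no iteration, no tolerances beyond the
  constant-rounding band above. Empty record sets give 0 (empty sums).
* Duff/litter points obstructed by snow or water carry a non-sampled
  reason code and a missing depth: they are dropped from the numerator
  with the protocol denominator kept fixed. A plot whose points are *all*
  missing yields `NA` flagged `undefined` — not 0, which would be a real
  (and wrong) fuel-load claim.
* A domain clause on a column a record type does not carry (decay class
  on FWD tallies, say) gives those records indicator 0; only fields
  unknown to the whole schema are errors.
* Percent cover is not capped at 100: a pile occupying a full transect
  legitimately estimates $100\pi/2 \approx 157\%$, and the cap's absence
  is the estimator's documented behavior.
* `validate_dataset()` returns violations as data rather than raising, so
  a QA workflow can triage; `read_tables()` *does* raise on schema and
  linkage errors, because no estimate is meaningful on unlinked tables.
* QA blind-remeasurement visits (`QASTATCD > 1`) are excluded from
  `estimate_all()` by default and restorable with `include_qa = TRUE`.

## Known limitations

Piece-level length/taper attributes (piece counts, individual volumes)
are not estimable from intersection diameters alone — the current field
protocol dropped those measurements, and the package follows it. The
bundled reference tables are synthetic stand-ins with realistic
magnitudes; production work must supply the published species and
forest-type-group references. Sample-kind and QA codes are treated as
opaque integers. The simulator offers no slope, spatial clustering beyond
homogeneous Poisson, or inhomogeneous intensity (hooks would be natural
extensions), and FWD is simulated as counts only, matching the protocol's
record content.
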