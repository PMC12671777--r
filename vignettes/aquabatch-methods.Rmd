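---
title: "aquabatch: models, file dialect and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aquabatch: models, file dialect and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquabatch)
```

# What the package does

AquaCrop, FAO's crop-water productivity model, writes each simulation's
results to a handful of whitespace-aligned text files. Studies routinely run
hundreds of simulations — factorial combinations of locations, sowing dates,
management practices, emissions scenarios and climate models — so the output
quickly becomes hundreds of files that are awkward to explore by hand.
`aquabatch` is a headless batch workflow for that situation: it discovers and
matches output files into runs, extracts metadata encoded in file names,
assembles everything into three tidy tables (project, seasonal, daily), and
offers the two lightweight analyses such studies typically start with —
time-window summary statistics and grouped simple linear regression — plus
scatter/box plotting with a LOESS smoother.

Because the AquaCrop engine itself is out of scope, the package also ships a
*fixture generator*: a seeded synthetic weather generator and a deliberately
simple ("toy") crop-water simulator that writes syntactically valid output
file sets. Every downstream feature can therefore be exercised, tested and
demonstrated without the engine.

# The toy crop-water model

The toy simulator keeps the canonical structure of a crop-water productivity
model and simplifies everything else.

**Phenology.** Thermal time drives the season:
\[
\mathrm{GDD}_{day} = \max\!\left(0,\ \tfrac{T_{max}+T_{min}}{2} - T_{base}\right),
\]
with the average method and a configurable base temperature (default
10&nbsp;°C). The season ends on the day cumulative GDD reaches
`gdd_maturity`, or at the hard cap `max_cycle_days`. This is the mechanism
behind the package's headline qualitative result: warmer series accumulate
GDD faster, so the crop cycle shortens.

**Canopy.** Green canopy cover ramps linearly from 0 to `cc_max` over
`cc_ramp_days` and then holds. Real canopy dynamics are logistic with
senescence; a fixture only needs plausible structure, not fidelity, and the
linear ramp keeps every downstream number easy to verify by hand.

**Temperature stress.** The optimal range for stomatal function is
`[t_opt_low, t_opt_high]`, 9–30&nbsp;°C by default. The stress coefficient is
binary: $K_s = 0$ on days whose mean temperature falls outside the range,
else 1; such days are counted as stress days and reported as a percentage of
the cycle. A smooth response curve would be more realistic, but the binary
rule makes stress-day counts exactly checkable.

**Water.** Daily transpiration is $Tr = K_s \cdot K_c \cdot CC \cdot ET_o$
and soil evaporation $E = (1 - CC)\cdot 0.5 \cdot ET_o$. The soil is a single
root-zone bucket: rain above a daily infiltration cap (`max_infiltration`,
40&nbsp;mm/day) runs off; infiltrated water tops up storage; storage above
`storage_cap` (150&nbsp;mm) drains; when demand exceeds available water, $Tr$
and $E$ are scaled down pro rata so the bucket never goes negative. The
branch arithmetic is arranged so the balance
\[
\mathrm{rain} = E + Tr + \mathrm{runoff} + \mathrm{drainage} + \Delta\mathrm{storage}
\]
closes exactly (the tests assert closure to $10^{-9}$&nbsp;mm on every day).

**Production.** Biomass and yield use the two defining relations of the
crop-water productivity framework:
\[
B = \Sigma Tr \times WP^{*}, \qquad Y = HI \times B,
\]
with $WP^{*}$ the normalized biomass water productivity (ton/ha per mm) and
$HI$ the harvest index. Note that AquaCrop's own manuals normalize $WP^*$ by
reference evapotranspiration, accumulating $\Sigma (Tr/ET_o)$; this package
implements the simpler unnormalized product shown above, which is the form
its outputs are meant to illustrate, and documents the discrepancy here
rather than hiding it. Both identities hold *exactly* (to the last bit) on
every simulated season, and the tests assert them as identities, not
approximations. Evapotranspiration water productivity is reported as
$Wp_{ET} = 100\, Y / \Sigma ET$ in kg/m³ (yield in ton/ha is 0.1 kg/m²; water
in mm is $10^{-3}$ m).

## The weather generator

Daily minimum and maximum temperature are
`base + seasonal sinusoid + linear warming + noise`, with the seasonal cycle
peaking in mid July and a single daily noise draw shared by `tmin` and
`tmax`, so the diurnal range is preserved exactly. The warming trend (°C per
decade) is applied continuously in time, which gives the closed form used in
the tests: with zero noise and trend $b$, annual means differ by
$b/10 \times \Delta\mathrm{years}$. ETo follows the same seasonal phase with
half relative amplitude; rainfall is seeded wet/dry days (wet probability
0.35) with exponential wet-day amounts whose overall mean is `rain_mean`.

Years are 365 days — there are no leap days anywhere in the package. This
keeps (year, day-of-year) arithmetic exact; dates are carried as
`year`/`doy`/`month`/`day` columns rather than `Date` objects, which would
re-introduce leap-day steps.

The defaults (`base_tmin` 6&nbsp;°C, `base_tmax` 16&nbsp;°C, amplitude
11&nbsp;°C, ETo 3&nbsp;mm/day, mean rain 1.6&nbsp;mm/day, noise SD
1.5&nbsp;°C) sketch the temperate continental climate of the Republic of
Moldova, the setting of the worked example; they were chosen once as
field-plausible values and are not tuned.

## What the fixtures do and do not emulate

The generator reproduces the *statistical structure* a practitioner's
dataset has — multi-decade seasonal series, a warming trend, a factorial
design encoded in file names — and the *syntactic structure* of the output
files. It does not reproduce AquaCrop physics: no logistic canopy, no
water/salinity/fertility stress interactions, no CO₂ response, no irrigation
scheduling. Passing tests therefore demonstrate that the *workflow* (match,
parse, combine, summarise, regress, plot) is correct on dialect-conformant
files, not that any agronomic conclusion transfers to real AquaCrop output.

# The file dialect

The byte layout of real AquaCrop files varies between engine versions and is
not fully specified anywhere this package could rely on, so the package
defines one normative dialect that its writers emit and its readers accept
(see `?"aquabatch-dialect"`): a title line, a blank line, then per block a
variable-name header line, a units line and two-decimal whitespace-aligned
numeric rows. Daily files lead with `Day Month Year DAP Stage`; seasonal
files with `Run Year`; plug-in `day.OUT` files carry one `Run: N` block per
season. Undefined cells (salinity variables, here never simulated) hold the
sentinel `-9.00`, which readers convert to `NA` unconditionally — fixture
sowing windows are warm-season, so a genuine temperature of exactly
−9.00&nbsp;°C does not occur in practice, but the convention is global and
documented. Parsing is header-driven throughout, so files whose column sets
differ (as between engine versions 6 and 7) are absorbed without special
cases.

The seasonal summary carries exactly 41 variable columns after the keys
(`seasonal_schema()` is the canonical catalogue), spanning simulation-period
information, climatic totals, the water balance, salinity placeholders,
average stresses and final production.

Two conventions matter downstream:

* **Matching.** Files are assigned to kinds by *longest registered suffix*
  match, which is what makes a prefix ending in `day` unable to swallow the
  `day.OUT` suffix, and grouped into runs by shared prefix. Partial sets
  warn rather than fail (users may save only some outputs); a prefix mixing
  GUI-only and plug-in-only suffixes is an error.
* **Metadata.** Prefix segments separated by underscores are positional
  metadata (`Maize_Soroca_RCP26` → crop, location, scenario), which is why
  underscores are forbidden inside design level labels.

# Analysis conventions

* **Windows** are anchored at the minimum observed time value and step by
  the user's width; the final window may be partial, visible in its clamped
  `window_end`. SD uses the sample (n−1) denominator. CV = SD/mean is
  reported missing when the mean is 0 or fewer than two values exist —
  never ±Inf. Whether the original interactive tool anchors windows at a
  round calendar value instead is unknown; anchoring at the data minimum is
  this package's documented choice.
* **Regression** is ordinary least squares via `stats::lm()`, reporting
  slope, intercept, R², and the two-sided t-test p-value for the slope
  (df = n−2), with raw (uncorrected) p-values per group. Degenerate groups
  yield `NA` fields: zero-variance x (warned), constant y (R² undefined),
  n &lt; 2, or a perfect zero-residual fit, whose slope SE is 0 and whose t
  statistic — hence p — is undefined rather than 0.
* **LOESS** is tricube-weighted local *linear* regression over the
  `ceiling(span * n)` nearest neighbours, evaluated on a 100-point grid;
  span defaults to 0.75. One tie-break is worth noting: when the window
  covers all points, the weights are made uniform, so the smoother reduces
  to the global OLS line (the textbook tricube weight would zero out the
  farthest point exactly). Quartiles in box-plot sidecars are type-7
  (linear interpolation), with 1.5·IQR whiskers.
* **Plot acceptance surface.** `render_plot()` returns a `plot_data` sidecar
  (panel list, per-series point counts, smoother curves, box summaries);
  tests assert on the sidecar, not on pixels, which are brittle across
  graphics stacks.

# Reproducibility and problem sizes

Every stochastic step flows from one integer seed: the weather generator
seeds its noise, wet-day and amount draws in a fixed order and restores the
caller's RNG state; `generate_study()` derives per-run seeds as
`base seed + run index` in factor-grid order; identical parameters and seed
give byte-identical output files. Runs are processed in prefix-sorted order
so results never depend on scheduling.

The test-suite and acceptance-script study is the full worked-example
factorial (3 × 3 × 2 × 2 × 3 = 108 runs) with six years of zero-noise
weather per run — chosen as the smallest series on which the warming signal
is still visible in every design group; the toy model's unit tests use a
600-GDD crop whose season is about 60 days. These sizes are the package's
own choice of a compact, fully deterministic demonstration; nothing in the
methods depends on them.

# Known limitations

* The dialect is normative for this package, not byte-identical to any
  specific AquaCrop release; real files with the same structural conventions
  parse, but no guarantee is made for arbitrary engine output.
* The toy model has no irrigation, salinity, fertility or CO₂ response; the
  corresponding output columns are constant or sentinel-valued.
* `filter_rows()` supports conjunctions of simple comparisons only;
  disjunctions require two calls and a bind.
* Runs are identified by prefix alone; the same prefix appearing in two
  directories is treated as a duplicate and rejected, not merged.
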