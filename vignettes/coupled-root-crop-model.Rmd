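---
title: "A coupled crop / soil-water / root-architecture model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled crop / soil-water / root-architecture model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizosim)
```

## What the model is

`rhizosim` simulates one growing season of a cereal crop at field scale with
explicit two-way feedback between the shoot, the soil water balance and the
root system:

1. a light-use-efficiency (LINTUL-type) shoot engine turns intercepted
   radiation into daily biomass and partitions it over organs by
   development stage;
2. a multi-layer tipping-bucket water balance turns rainfall, evaporation
   and root water uptake into a daily transpiration reduction factor
   (TRANRF) that scales biomass growth and shifts allocation towards the
   roots under drought;
3. a root model — either a stochastic 3D architectural model or a simple
   1D conceptual model — turns the day's root carbon into new root length,
   with elongation limited *first* by local soil conditions and *then* by
   carbon availability.

The motivating application is mechanical subsoil loosening: the packaged
soil fixtures describe a loess Luvisol field trial in which a 30–60 cm
strip was loosened (treatment "DL"), lowering bulk density in that band
(1.33 vs 1.56 Mg m⁻³ at 30–45 cm) and raising porosity. Whether that pays
off in yield depends on the weather — which is exactly the feedback this
model resolves.

## Soil strength and the stress reduction of root elongation

Penetration resistance is modelled from bulk density γ (Mg m⁻³) and
volumetric water content θ (cm³ cm⁻³) with the Busscher power regression

$$Q_p = a\,\gamma^{b}\,\theta^{c}, \qquad a = 0.00587,\; b = 8.0772,\; c = -4.65,$$

so strength rises steeply with density and falls steeply with wetness.
Mechanical stress reduces relative root elongation exponentially,
$\alpha(Q_p) = e^{x Q_p}$ with $x \le 0$ (the branch for soil without
continuous macropores). The generic default is $x = -0.4325$; with θ taken
as *volumetric* water content the regression produces large $Q_p$ values
(tens of MPa in dry topsoil), and the crop-level calibrations used here are
correspondingly small in magnitude: $x = -0.0025$ for spring barley and
$-0.005$ for winter wheat. These pairings are internally consistent — e.g.
$Q_p = 41.9$ MPa with $x=-0.0025$ still leaves $\alpha \approx 0.90$ — and
we deliberately treat $x$ as the calibration degree of freedom rather than
re-interpreting θ.

Water status enters through a Feddes-type trapezoid on θ, anchored on the
published retention anchors of each horizon: zero at the wilting point
θ~PWP~, rising linearly to 1 at the reduced point θ~red~, flat across the
optimum, and falling to zero over the last `aeration_margin` (default
0.04 cm³ cm⁻³) below saturation θ~S~ (poor aeration). Matric potential is
never computed: the water model is a water-content bucket and the fixtures
publish exactly these θ anchors, so a retention-curve fit would add
invented parameters without adding information. The combined stress
reduction is multiplicative, $srf = \alpha(Q_p)\,\alpha(\theta) \in [0,1]$,
evaluated per numerical soil cell and felt by each root tip at its current
depth.

## Soil water balance

The profile is discretised into 5 cm cells (root length density is
reported separately in 3 cm bins). Each day, in order:

* **Infiltration** fills cells to field capacity top-down; remaining
  excess fills towards saturation; water beyond total capacity runs off.
  The transient store between field capacity and saturation drains
  downward at a first-order rate of 0.5 d⁻¹, the bottom cell's share
  leaving as drainage.
* **Soil evaporation** extracts the canopy-free share of potential ET from
  the top 15 cm, weighted towards the surface (e-folding 7 cm) and
  linearly throttled as the topsoil approaches air-dryness (½·θ~PWP~).
  It can therefore dry the immediate surface below wilting point — which
  is intended, and is what makes a dry spring mechanically hostile.
* **Transpiration** demand (split from PET by Beer's law on yesterday's
  LAI, extinction 0.6) is distributed over cells proportionally to
  FRR(i)·AW(i), where AW is plant-available water above wilting point and
  FRR is the root restriction factor
  $FRR = 1 - e^{-0.3\,\mathrm{RDA4AGE}}$. With the 1D root model RDA4AGE
  up-weights young roots, `max(RLD, RLD·YOUTH/RLAGE)` (YOUTH = 20 d); with
  the 3D model it is RLD alone, because the architectural model already
  resolves where the young tips are. Per-cell uptake is capped at
  FRR·AW, so `TRAN = min(PTRAN, Σ FRR·AW)` and
  `TRANRF = min(1, TRAN/PTRAN)` (defined as 1 when PTRAN = 0).

Mass closure is enforced to better than 10⁻⁹ mm per day and verified in
the tests at 10⁻⁶ mm over 120-day random runs.

The "modified Penman" used by the original modelling framework is not
recoverable from published material, so reference ET is pluggable: the
default is Priestley–Taylor (α = 1.26) on daily radiation and temperature,
with a Hargreaves fallback and verbatim pass-through of an `et0` column
when the weather file provides one. Any defensible closed form works here
because phenology/LUE calibration absorbs level differences.

## Shoot engine

Phenology is thermal time above a 0 °C base: development stage 0→1 from
emergence to anthesis, 1→2 to maturity. Daily growth is
`dW = LUE × 0.5 × radiation × (1 − e^(−k·LAI)) × TRANRF` with LUE = 3 g MJ⁻¹
(PAR). Allocation follows a stage-indexed partitioning table; under
drought the root fraction is multiplied by

$$\mathrm{FRTMOD} = \max\!\left(1, \frac{1}{\mathrm{TRANRF} + 0.5}\right),$$

which is 1 for TRANRF ≥ 0.5 and saturates at 2, with the other fractions
scaled down equally so fractions still sum to 1. The bracketing matters:
the alternative reading `1/TRANRF + 0.5` is unbounded and has no threshold
at 0.5, contradicting both stated properties, so this form is used.
Juvenile LAI grows exponentially with thermal time (0.009 per °C·d) until
LAI 0.75, then with specific leaf area 0.022 m² g⁻¹; after anthesis leaves
die at 0.03 d⁻¹ (dead leaf still counts in above-ground biomass) and roots
turn over at 0.01 d⁻¹. Grain yield is the storage pool × 0.01 (g m⁻² →
t ha⁻¹).

The partitioning table, temperature sums (barley: 90 °C·d to emergence,
900 to anthesis, 1550 to maturity; wheat: 120/1300/2050), SLA and
senescence rates are package defaults in standard LINTUL-2 style; they are
assumptions, not published values, and are exposed in `crop_params()`.
Winter-wheat vernalisation and photoperiod are not modelled; the anthesis
temperature sum absorbs the overwintering delay. Nutrient limitation and
pests are out of scope by design.

A seed reserve (6 g m⁻² over 10 days after sowing) feeds early root
growth, since the radicle and seminal roots grow before the shoot can
export assimilate. Without it the coupling would deadlock at emergence (no
roots → no uptake → TRANRF = 0 → no growth).

## The 3D architectural root model

Each root type follows the negative-exponential growth law
$RL(t) = k\,(1 - e^{-(r/k)t})$ — initial elongation rate $r$, asymptotic
maximum length $k$. The printed form of the exponent is read as $(r/k)t$
so that $RL'(0) = r$ and units close. Per day each tip's potential
elongation is the increment of this law, scaled by `srf` at the tip's
depth cell and by the day's uniform carbon factor; growth is appended as
segments of at most 0.5 cm with the heading renewed per segment by
best-of-n gravitropism (n = 2 trials, angular noise σ = 0.2 rad; the
candidate closest to vertical wins). Tips reflect at the soil surface.
Laterals emerge at spacing `ln` along the parent once the tip is an apical
zone `la` past the branch point; basal (shoot-borne) roots appear at the
plant base every `basal_delay` days up to `maxB`. Defaults: barley = 1
taproot + up to 5 basal axes (2 d apart) + 1 lateral order (ln = 0.85 cm);
wheat = taproot + up to 20 basal axes + laterals (ln = 2 cm); second-order
laterals are supported but off by default. Root geometry is cumulative
(no geometric senescence); root *biomass* turnover is handled in the crop
pools.

Carbon conversion uses a specific root weight of 2·10⁻⁵ g cm⁻¹ for all
types (configurable per type). The per-plant ground area is
10⁴/sowing density cm² (330 plants m⁻² → ≈ 30.3 cm² for barley); there is
no lateral domain confinement, consistent with field-plot averaging, and
root length density uses depth binning only.

## Daily coupling and the order of limitations

The coupling contract is carbon-first and stress-before-carbon. Each day:
phenology; demand split with yesterday's LAI; water step with yesterday's
root length density → TRANRF; biomass growth and FRTMOD partitioning; then
the root side computes *independently* (i) the carbon the shoot offers
(root increment / plants per m²) and (ii) the carbon that stress-limited
potential growth would cost (Σ over tips of srf-limited elongation × SRW).
If supply < cost every root is scaled equally by the ratio; if supply >
cost the surplus returns to the shoot pools in proportion to the day's
non-root fractions. Today's new root length density is recorded for
tomorrow's uptake (explicit one-day lag). Daily closure is enforced:
`dW + seed flux = root carbon spent + surplus + shoot increments` to
10⁻⁹ g m⁻².

## The 1D conceptual root model

The alternative root model advances a seminal rooting front at up to
0.033 m d⁻¹, reduced by a linear soil temperature ramp (0…1 between 0 and
15 °C) and by `srf` in the front's cell, charging 0.033 g m⁻² per cm of
advance (≈ 330 plants × 5 axes × SRW). Remaining carbon becomes lateral
length distributed over rooted cells proportionally to `srf` — the
original's lateral placement rule is not published, and "growth goes where
conditions allow" is the assumption made here. A per-cell root length
density ceiling (5 cm cm⁻³) guards against the conceptual model piling a
blocked season's carbon into a few cells; carbon that cannot be placed
returns to the shoot. Because all tips of the 1D model are summarised by
one front, it reacts to a bulk-density contrast only while the front
traverses the contrasted band — which is why, over a season with a
passable spring, it expresses far less of the loosening treatment effect
than the 3D model. This is the expected and tested behaviour, not a
defect.

## Synthetic weather

The generator emulates a temperate-humid site (annual mean 10.5 °C,
601 mm): a sinusoidal annual temperature cycle (amplitude 8.2 °C, Gaussian
day noise σ = 2 °C, diurnal range 8 ± 1.5 °C), a matching radiation
curve, and two-state Markov rainfall occurrence (stationary wet-day
probability 0.43, wet persistence +0.25) with gamma amounts (shape 0.8)
scaled so the expected annual total matches. `dry_spring = TRUE` multiplies
March–April amounts by 0.15, emulating the observed dry springs (≈ 8 mm
April rainfall) in which subsoil loosening paid off. The generator
reproduces its configured normals in expectation (verified by Monte Carlo
in the tests) and is byte-reproducible under a fixed seed. It does not
emulate multi-day synoptic structure, heat waves coupled to radiation, or
within-month trends; scenario results should be read as weather-class
contrasts (dry spring vs normal), not as reconstructions of specific
years.

## What the tests do and do not show

The test suite verifies: the arithmetic of the packaged observed yield
tables; the drought-allocation threshold at TRANRF = 0.5; water and carbon
conservation; equivalence of the stochastic grower with the closed-form
growth law when tropism noise is off; equivalence of the voxelised root
length density with an independent resampling oracle; bit-reproducibility
of full seasons under a seed; and the qualitative treatment patterns —
higher 30–60 cm root length density and no yield penalty under deep
loosening in a dry spring, no appreciable treatment effect in a wet year,
deeper rooting and no less yield with faster initial tip elongation, and a
weaker treatment contrast with the 1D root model than with the 3D model.
Scenario checks run full barley seasons (~140 days, 5 cm water cells,
0.5 cm segments, one plant) — a single season takes a few seconds — with
two seeds per sweep level for the stochastic architectural comparisons.
These are properties of the model under its synthetic study conditions;
they do not constitute a field validation, and absolute yields depend on
the assumed LINTUL-style parameter defaults.

## Numerical choices and degenerate inputs

* Depths are cm, positive downward; layers are half-open `[z_top, z_bot)`.
* Water cells 5 cm; RLD reporting bins 3 cm; segment cap 0.5 cm.
* `TRANRF = 1` at zero demand (explicit convention, keeps FRTMOD at 1
  before canopy closure).
* θ = 0 is kept out of the strength power law by flooring at 10⁻⁶ — the
  hydric factor is already 0 well before that.
* Segments crossing bin boundaries are split by exact vertical-extent
  clipping; flat (horizontal) segments are assigned to their containing
  bin.
* Reconciliation returns `scale = 1` when required carbon is 0.
* All stochastic components draw from R's RNG under a single per-run seed;
  repeat runs are bit-identical.

## Known limitations

No nitrogen or nutrient limitation; no capillary rise, groundwater or
solute transport; no root hydraulic architecture (uptake is density-based,
without compensation); no macropore/biopore growth paths; no soil
settlement after loosening (single-season scope); no vernalisation
sub-model; fixed root diameters per type ("thinner roots in loose soil"
can emerge only via biomass-per-length bookkeeping, not as a mechanistic
diameter response).
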