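---
title: "Exposure-based hazard screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-based hazard screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazscreen)
```

## The screening problem

Tens of thousands of organic chemicals are in commerce, and only a small
fraction have measured environmental fate data. Screening-level
prioritization ranks large chemical inventories by *exposure-based hazard*
-- the intrinsic potential of a substance to build up in the environment
and reach receptors -- using only physicochemical property estimates.
`hazscreen` scores each chemical against four profiles:

* **POP** (persistent organic pollutant): persistence x bioaccumulation x
  long-range transport with deposition, `Pov * BAF * TE`;
* **vPvB** (very persistent, very bioaccumulative): `Pov * BAF`, no
  transport term;
* **APC** (airborne persistent contaminant): `Pov * CTD_air`;
* **WPC** (waterborne persistent contaminant): `Pov * CTD_water`.

Regulatory language joins criteria with "and" ("persistent *and*
bioaccumulative"), which we treat as a logical AND and hence as a product
of the linear-scale metrics. Raw products are unitless-arbitrary; they
acquire meaning only as *percentile ranks* against a reference set of
well-characterized contaminants, which also makes every ranking invariant
under monotone transformations applied jointly to batch and reference.
Scores deliberately contain no toxicity or emissions term and must not be
read as risk.

## The multimedia fate model

The P and LRT metrics come from an evaluative steady-state model with
three well-mixed compartments (air, surface water, surface soil) covering
a generic continental region. The model is *closed*: the only losses are
first-order degradation with rate `ln 2 / t_half` per compartment, so the
overall persistence

$$P_{ov} = \frac{\sum_i m_i}{\sum_i k_{deg,i} m_i}$$

is a pure degradation residence time, bracketed by the shortest and
longest compartment half-life divided by ln 2. Intermedia transfer
comprises two-film air-water diffusion, rain dissolution, wet and dry
aerosol deposition, air-soil diffusive exchange, soil volatilization and
soil-to-water runoff of water and solids. Partitioning inputs are
log K~OW~ and log K~AW~ only: the aerosol-bound fraction comes from the
K~OA~ = K~OW~/K~AW~ organic-matter absorption model
(`log Kp = log Koa + log f_om - 11.91`, Kp in m^3^/ug), and all sorption
uses `Koc = 0.41 * Kow`. This keeps every metric a function of the two
partition ratios and the three half-lives, the inputs a screening
database can actually supply.

`Pov` is reported as the **maximum over the three single-compartment
emission modes** -- a conservative screening convention, chosen because a
screening rank should not depend on an assumed emission pattern. The
characteristic travel distances use the mode-specific steady state:

$$CTD_{medium} = u_{medium} \cdot \frac{m_{medium}}{\sum m} \cdot \tau_{ov},$$

with `u_air = wind_speed` (4 m/s) and `u_water = water_current`
(0.02 m/s). Transfer efficiency couples two identical regions: region 1
receives the emission to air and loses air by advection at rate
`wind_speed / region_length_scale`; that outflow is the sole input to
region 2, flushed at the same rate. At steady state the net deposition to
the remote surface equals the degradation loss in remote water and soil,
so

$$TE = 100 \cdot \frac{k_{deg,w} m^{(2)}_w + k_{deg,s} m^{(2)}_s}{E}.$$

`region_length_scale` defaults to the square root of the region area
(3162 km for the default 10^7^ km^2^), giving an air residence time of
about nine days.

The environment defaults (6000 m atmosphere, 100 m water, 10 cm soil, 70%
water cover, 30 ug/m^3^ TSP with 10% organic matter, 850 mm/yr rain)
describe a generic evaluative world. Their exact values matter little by
construction: scores are percentiles computed with the *same*
parameterization for screened and reference chemicals, and
`score_table()` enforces this with a parameterization fingerprint carried
by every reference set.

### Numerical choices

The steady state is a direct dense solve of a 3x3 linear system -- no
iteration, no randomness; the mass balance closes to machine precision
(tested against 1e-9). The solution is cross-checked in the test suite
against long-time dynamic integration of the same rate matrix (an
independent `deSolve` oracle, relative tolerance 1e-6) and the two-region
TE construction against a six-state dynamic simulation. Degenerate inputs
are handled with sentinels rather than errors so batch screening
completes: all-infinite half-lives yield `Pov = Inf` with a warning, and
per-record failures in `fate_metrics_table()` are flagged in a
`fate_error` column.

## The bioaccumulation factor

The B metric is a steady-state single-fish mass balance,

$$BAF = \frac{k_1 + k_D \, L_D \, K_{OW}}{k_2 + k_E + k_G + k_M},$$

with gill uptake efficiency `E_W = 1/(1.85 + 155/Kow)`, dietary
assimilation `E_D = 1/(3e-7 Kow + 2)`, allometric ventilation and feeding,
and a diet in lipid equilibrium with the water. A single mid-trophic fish
(184 g, 6.85% lipid) is used rather than a full three-trophic-level food
web: the screening metric needs exactly two sensitivities --
hydrophobicity and biotransformation -- and the single-fish balance
reproduces both while staying transparent. Biotransformation `kM`
defaults to 0 (conservative) and can be supplied per record
(`km_per_day`). Records carrying an external `log_baf` estimate (e.g.
from a dedicated QSAR) bypass the model entirely; the `baf_source` column
records provenance. No bioavailability correction of the dissolved water
concentration is applied; at screening level the ranks are driven by the
K~OW~ ordering.

## Curation

Two rules precede scoring. First, chemicals likely ionized at
environmentally relevant pH (`pKa < 5` or `pKb > 8`, strict inequalities
exactly as stated; a record at `pKa = 5` is kept) are removed, because
neutral-organic partitioning and BAF estimates are unreliable for them.
The `pKb > 8` rule is applied as printed on the base constant; records
lacking both constants are kept and flagged `ionization_unknown`, since a
screening tool must tolerate gaps. Second, partition ratios are clamped
to the property-estimation domain, log K~OW~ to [-4, 10] and log K~AW~ to
[-12, 3] -- the fate model's outputs are insensitive to changes beyond
these bounds, so clipping alters no rank while keeping inputs inside the
training domain of typical property models. Both thresholds and bounds
are arguments with these defaults.

## Percentile benchmarking

With `N_ref = 148` reference chemicals there are exactly 149 attainable
scores per profile: `100 * k / 148` for `k = 0..148`, from 0 (below every
reference chemical) to 100 (above all of them). A raw score tied exactly
with a reference value counts as *not* exceeding it -- the conservative
choice, exposed as the strict `<` count in `percentile_score()`.
Self-benchmarking the reference set therefore yields the uniform grid
`{0, 100/148, ..., 100*147/148}`. Chemicals scoring over 90 (`hi = 90`,
strict) in a profile outrank every reference chemical marking that
profile's top decile; the spatial-coverage classification nests as
near-field (vPvB > 90) before far-field (POP > 90) before global (APC or
WPC > 90), mirroring the scales at which regulatory action for each
profile is most relevant.

## The synthetic generator

The real inputs of a screen of this kind -- a production-volume database
with property estimates, and the curated reference list -- are not
redistributable, so `generate_screening_set()` creates a synthetic table
that emulates their statistical structure, and
`generate_reference_fixture()` a synthetic 148-member reference set; both
are labelled synthetic in their provenance strings and a user-supplied
real reference file is accepted transparently by `read_reference_set()`.

The generator's defaults emulate a commerce-scale inventory: log K~OW~
normal(3, 2.2) and log K~AW~ normal(-4, 3), clipped to the property
domain; log-normal half-lives with medians of about 100 h (air), 900 h
(water) and 1800 h (soil) -- right-skewed, as property-estimated
half-life sets are; 31% of records ionizable (assigned `pKa` < 5 or
`pKb` > 8), matching the removal fraction a commerce inventory shows
under the curation rule; and element compositions with prevalences of
about 13% Cl, 3.8% F, 2.9% Br, 36% N, 82% O, with halogenation-level
distributions peaking at three fluorines and two chlorines. Properties
are sampled *independently*: real databases carry property correlations
(e.g. hydrophobic chemicals tend to be longer-lived in soil) that the
generator deliberately omits because no joint distribution is published.
Passing tests on synthetic data therefore demonstrates correctness of the
computations and the pipeline's invariants, not predictive performance on
any real inventory. The reference fixture draws from the reference
chemical space (log K~AW~ in (-10, 2), log K~OW~ in (-2, 10)) with
longer, more dispersed half-lives (medians 500/3000/8000 h, log-sd 1.5),
biased toward persistent and bioaccumulative combinations so the raw
reference scores span several orders of magnitude, as a
well-characterized contaminant set does.

Everything is deterministic given `(config, seed)`; distributional test
assertions use wide 99% binomial intervals to stay stable across seeds.

## Problem sizes

The shipped analysis scripts and the acceptance script screen 2000
synthetic chemicals against the 148-member fixture; the test suite uses
batches of 100-1000 records for the oracle and property suites. A full
screen of 2000 chemicals, including all steady-state solves, runs in a
few seconds on one CPU, so the method scales comfortably to inventories
of 10^4^-10^5^ chemicals.

## Known limitations

* Three compartments only: no sediment, no vegetation, no temperature
  dependence, no spatially resolved transport, no degradation products.
* The fate model is a faithful representative of the evaluative
  steady-state model class, not a bit-exact clone of any particular
  released tool.
* Neutral organics only; ionizable chemicals are excluded at curation
  rather than modelled.
* The B metric is a single-fish balance; laboratory BCF and multi-trophic
  food-web variants are out of scope.
* Scores rank exposure-based hazard; they carry no effects or emissions
  information and are not risk estimates.
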