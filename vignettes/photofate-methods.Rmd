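---
title: "Methods: steady-state photochemical fate modelling in photofate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state photochemical fate modelling in photofate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photofate)
```

## The model and its assumptions

`photofate` predicts the phototransformation kinetics of a dissolved
compound in a sunlit freshwater column. The core assumptions are:

1. **Steady state of the transients.** The photogenerated oxidants (•OH,
   CO₃•⁻, ¹O₂, ³CDOM*) are formed by photon absorption and consumed by
   natural scavengers; pollutant reactions are a negligible sink, so each
   transient's concentration is `formation rate / scavenging rate
   constant`, independent of the pollutant concentration. The engine
   checks this implicitly: the default probe concentration (10⁻⁸ mol L⁻¹)
   is low enough that halving it changes nothing.
2. **Flat Lambert–Beer optics.** The water column is well mixed and
   vertically uniform; the light path equals the depth (optionally scaled
   by a path-correction factor ψ ≥ 1 supplied by the user — its
   latitude/season dependence is not computed here). No scattering,
   surface reflection or solar-geometry refinements.
3. **No temperature dependence.** Photoreactions depend weakly on
   temperature compared with thermal reactions; rate constants measured
   at different temperatures can simply be run as separate inputs.
4. **Iron photochemistry is not modelled separately**: the CDOM •OH
   quantum yield (3×10⁻⁵) empirically subsumes Fe–DOM photoreactions.

At each wavelength the competing chromophores (CDOM, nitrate, nitrite,
and the substrate for direct photolysis) share the absorbed photons in
proportion to their absorbance. Volumetric formation rates are the areal
absorbed fluxes divided by the depth; quantum yields convert absorbed
photons into transients.

## Units and reference conditions

Photon fluxes are spectral photon flux densities in Einstein cm⁻² s⁻¹
nm⁻¹; molar absorption coefficients in L mol⁻¹ cm⁻¹; water absorbance in
cm⁻¹; optical paths in cm internally (water depths accepted in m and
converted; ψ applies to water columns only, never to a laboratory
cuvette). Steady-state concentrations refer to a sunlight UV irradiance
(290–400 nm) of 22 W m⁻² at the surface; `scale_to_uv_irradiance()`
normalizes any input spectrum to that band integral using the photon
energy N_A·h·c/λ.

**The SSD time unit.** Outputs are reported per "summer sunny day" — a
fair-weather mid-July day at mid-latitude including the day–night cycle.
The day–night folding is a convention, not a measurable constant, so the
package exposes it as `ssd_equivalent_seconds` in the profile, default
3.6×10⁴ s (10 h of 22 W m⁻² UV as one fair day). Users comparing against
field data should treat this constant as part of their scenario
definition.

## The parameter profile

Constants the engine needs but that are not compound-specific ship as the
named, versioned profile `"literature-default-1"` (`default_profile()`),
every value overridable:

| parameter | default | unit | role |
|---|---|---|---|
| Φ•OH,CDOM | 3×10⁻⁵ | mol Einstein⁻¹ | •OH from irradiated CDOM (incl. Fe) |
| Φ¹O₂,CDOM | 1.25×10⁻³ | mol Einstein⁻¹ | ¹O₂ via ³CDOM* + O₂ |
| Φ³CDOM* | 1.28×10⁻³ | mol Einstein⁻¹ | triplet formation |
| Φ•OH,NO₃⁻ | 0.01 | mol Einstein⁻¹ | nitrate photolysis |
| Φ•OH,NO₂⁻ | 0.025 | mol Einstein⁻¹ | nitrite photolysis |
| k(•OH+DOM) | 5×10⁴ | L mg_C⁻¹ s⁻¹ | main •OH sink |
| k(•OH+HCO₃⁻) | 8.5×10⁶ | L mol⁻¹ s⁻¹ | CO₃•⁻ source |
| k(•OH+CO₃²⁻) | 3.9×10⁸ | L mol⁻¹ s⁻¹ | CO₃•⁻ source |
| k(•OH+NO₂⁻) | 1.0×10¹⁰ | L mol⁻¹ s⁻¹ | minor sink |
| k(•OH+Br⁻) | 1.1×10¹⁰ | L mol⁻¹ s⁻¹ | saltwater sink (Br⁻ defaults to 0) |
| k(CO₃•⁻+DOM) | 1×10² | L mg_C⁻¹ s⁻¹ | CO₃•⁻ sink |
| k(³CDOM* decay) | 6×10⁵ | s⁻¹ | aerated-water inactivation |
| k(¹O₂ decay) | 2.5×10⁵ | s⁻¹ | collisional deactivation by water |

These are standard aquatic-photochemistry literature values; none is a
fitted quantity of this package. The nitrate and nitrite molar
absorption spectra are **synthetic parametric Gaussians** (302 nm / 354 nm
band centres with literature peak heights); substitute measured spectra
through the `nitrate_spectrum`/`nitrite_spectrum` profile slots when
accuracy in nitrate-dominated systems matters.

The parameter η(CO₃•⁻,CDOM) for carbonate-radical production from
³CDOM* + CO₃²⁻ is exposed but defaults to 0 (CO₃•⁻ sourced from •OH
only): no defensible default value or functional form is established, so
the implementation uses the simplest proportional coupling
`R = η · R(³CDOM*)` for users who have calibrated it.

## Carbonate speciation

`carbonate_from_alkalinity()` solves
`Alk = [HCO₃⁻] + 2[CO₃²⁻] + [OH⁻] − [H⁺]` with the second carbonic-acid
dissociation, using pK₁ = 6.35, pK₂ = 10.33, pK_w = 14.00 (25 °C, zero
ionic strength; configurable). The water terms matter only at high pH and
low alkalinity; `include_water = FALSE` selects the simpler two-term
carbonate alkalinity. Activity corrections are omitted — the package
targets freshwaters.

## Laboratory fitting procedures

All fitters follow one pattern: a forward rate law derived from the
steady-state kinetics of the experiment, fitted by nonlinear least
squares (`minpack.lm`), **initialized from the linearized form** of the
same law. On noiseless data the linearized and nonlinear estimates
coincide (a test asserts this); under noise the nonlinear fit is the
reported estimate. Residual weighting is absolute by default with a
`weighting = "relative"` switch, since the appropriate choice depends on
the detector noise structure.

Specific choices:

- **•OH competition**: the two fit parameters (R_•OH, k₁₇) are
  orthogonal, so the fit is univocal; an optional additive constant
  absorbs residual direct photolysis. A design whose highest scavenger
  level suppresses the rate by less than 50% triggers a warning, and
  rates *increasing* with scavenger are an error.
- **Carbonate-radical screening** returns a verdict, not a constant: the
  "sufficiently lower" criterion for the nitrate-free direct-photolysis
  series is fixed at 50% of the bicarbonate series (configurable) —
  the underlying protocol gives no number, and the verdict is only a
  triage step before competition kinetics.
- **Intermediate yields**: the sequential first-order model
  `[I]_t = k′_I [S]₀/(k_S−k_I) (e^{−k_I t} − e^{−k_S t})` is notoriously
  non-univocal when all parameters float. Identifiability is restored by
  (i) fixing k_S and [S]₀ from the substrate's own trace and (ii)
  initializing k′_I from the analytic initial slope
  `d[I]/dt|₀ = k′_I [S]₀`, estimated by an early-point secant — an
  analytic replacement for the traditional graphical tangent, measuring
  the same quantity. The degenerate k_I → k_S case uses the limit form
  `k′_I [S]₀ t e^{−k_S t}`.
- **Competition kinetics** corrects each compound's direct photolysis by
  its screening factor χ before taking the rate ratio; when substrate and
  reference share an absorption spectrum the χ factors cancel (tested).
  A post-hoc warning flags rate-constant ratios outside [0.1, 10].

## Numerical choices

- **Quadrature**: trapezoidal on the incident-flux wavelength grid, with
  linear interpolation of all other spectra onto it and zero outside
  their tabulated support. Spectra are smooth tabulated curves;
  grid-refinement tests show halving the step changes integrals by well
  under 0.5%.
- **0/0 at transparent wavelengths**: where the total absorbance is zero
  the competitive fraction is defined as 0 (its limit value).
- **Degenerate outputs**: a compound with no active pathway gets an
  infinite half-life, represented as `Inf` and serialized as an empty
  cell in output tables, never thrown as an error.
- **Steady-state guard**: nonzero formation with zero scavenging is an
  error (no steady state exists), while zero formation yields zero
  concentration regardless of scavenging.

## Synthetic data

The package is fully testable offline through `generate_fixtures()` and
the in-memory generators. The synthetic solar spectrum is a smooth
sigmoid-onset curve normalized to 22 W m⁻² over 290–400 nm — it emulates
the band-integrated energetics and smoothness of real surface sunlight
but **not** its Fraunhofer structure, seasonality or solar geometry. The
built-in test compound pairs an exponentially decaying UV absorption tail
with the measured scalar photoreactivity of ibuprofen (Φ = 0.33,
k•OH = 1.0×10¹⁰, k¹O₂ = 6×10⁴, k³CDOM* = 4.5×10⁷ L mol⁻¹ s⁻¹;
intermediate yields 0.25/0.023/0/0.31); its absorption spectrum is
synthetic, so absolute direct-photolysis outputs are illustrative.
Kinetic-trace generators apply multiplicative Gaussian noise (default 2%,
explicit seeds). Consequently, passing tests demonstrate the correctness
of the *algorithms* (conservation laws, closed forms, round-trip
parameter recovery, qualitative depth/DOC/stratification orderings) — not
agreement with any specific field measurement, which requires measured
spectra and site chemistry.

Test and acceptance problem sizes — 111-point wavelength grids, 100
replicate noisy fits, grids of a few depths/DOC values — were chosen as
the smallest sizes at which the statistical assertions are stable.

## Scenario extensions

- **pH**: the engine is pH-agnostic; acid and basic forms are run
  separately and combined by speciation weights (`combine_ph()`).
  Deliberately, pH does **not** feed back into carbonate speciation
  there — the two-run workflow treats the water as fixed; couple them
  explicitly via `carbonate_from_alkalinity()` if desired.
- **Stratified lakes**: epilimnion, hypolimnion and mixed-lake runs
  differ only in incident spectrum (thermocline-attenuated for the
  hypolimnion) and depth; chemistry is shared.
- **Rivers**: flow changes split evenly over the three spatial
  directions (cube-root scaling of velocity, depth and width), with a
  pinned-width option for artificial channels; the half-life length is
  `v · t₁/₂`.
- **Evaporation**: solute concentrations scale as `(d₀/d)³`. Note the
  per-area solute inventory is *not* conserved (the surface shrinks
  too); the literal invariant, asserted in tests, is concentration × d³.
- **Sweeps** replace the historical −1/−2 input sentinels with named
  variables; a compatibility shim (`resolve_sweep_sentinels()`) maps the
  legacy convention.

## Known limitations

- Screening QSAR estimators are phenol-derived, order-of-magnitude
  correlations; their outputs carry a `provenance = "QSAR-estimate"` flag
  end-to-end so they are never mistaken for measured constants.
- Bromide chemistry is a pass-through scavenging term (default 0);
  saltwater systems need more than that.
- No time-resolved kinetics, diel cycles beyond the SSD convention,
  hydrodynamic mixing, or seasonality post-processing.
- The default nitrate/nitrite spectra and the solar fixture are
  synthetic; quantitative site studies should supply measured spectra via
  the molecule-table and profile interfaces.
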