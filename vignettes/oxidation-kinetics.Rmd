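---
title: "Methods: antioxidant thermochemistry and oxidation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antioxidant thermochemistry and oxidation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxikin)
```

## The scientific problem

Unsaturated lipids autoxidize by a radical chain: heat abstracts an allylic
hydrogen from the α-CH₂ next to the C=C bond, the carbon radical adds O₂,
and the resulting peroxyl radical propagates the chain. A phenolic
antioxidant interrupts this by donating its hydroxyl hydrogen to the chain
carrier — a one-step hydrogen atom transfer (HAT). Whether HAT is feasible,
and how strongly an antioxidant retards oxidation, can be quantified at
three levels that this package connects:

* **thermochemistry** — how strong are the relevant bonds?
* **macroscopic kinetics** — how much does the antioxidant raise the
  apparent activation energy of oxidation?
* **radical-scavenging assays** — how much antioxidant is needed to quench
  half of a stable test radical?

The worked system throughout is oleic acid (OA) protected by carnosic acid
(CA, a rosemary diphenol diterpenoid) versus TBHQ, a synthetic food-grade
comparator; the methods are generic.

## Bond-dissociation enthalpies

For a species table giving enthalpies of the parent molecule, its
H-abstracted radical and the free hydrogen atom,

$$\mathrm{BDE} = H_{\mathrm{radical}} + H_{\mathrm{H\cdot}} - H_{\mathrm{parent}}.$$

Inputs may mix hartree and kJ/mol; everything is converted with the fixed
factor 1 hartree = 2625.4996 kJ/mol, exposed in `oxikin_constants()` and
never inferred from data. Round-trip conversion is exact to below 1e-9
relative error. Energies are treated as enthalpies at the tabulation's
implicit standard state — no zero-point or thermal corrections are applied,
because species tables of this kind do not carry the information needed to
add them. A non-positive BDE is physically meaningless for a stable parent
but only warns, so that malformed or exploratory inputs can still flow
through. `rank_sites()` orders sites ascending by BDE (most reactive
H-donor first) and breaks ties lexicographically on the bond label, a
deliberate, documented determinism rather than input-order dependence.

The frontier-orbital gap `frontier_gap()` is plain subtraction
E(LUMO) − E(HOMO) after unit conversion. Its interpretation — a smaller gap
means a more reactive species — is documentation, not a constraint: the
package certifies the arithmetic only, since orbital energies are rarely
tabulated alongside BDEs.

## Rancimat kinetics

The induction period IP (h) from an accelerated-oxidation (Rancimat) run is
inverted to an effective rate constant k = 1/IP (h⁻¹). Two linearizations
are fitted by unweighted ordinary least squares with abscissa
**x = 1000/T (K)**:

* Arrhenius, `ln k = ln A − Ea/(RT)`: slope s gives Ea = −s·R with
  R = 8.314 J mol⁻¹ K⁻¹, so slopes of order −6 correspond to Ea of order
  50 kJ/mol. The 10³/K scaling is the convention under which published
  slopes in this field reproduce their published activation energies; every
  fit object records it.
* Eyring/activated-complex, `ln(k/T) = ln(kB/h) + ΔS/R − ΔH/(RT)`:
  ΔH = −s·R and ΔS = (intercept − ln(kB/h))·R.

**The ln(kB/h) constant.** The SI value ln(kB/h) = ln(1.380658×10⁻²³ /
6.6260755×10⁻³⁴) ≈ 23.76 presumes k in s⁻¹; with k in h⁻¹ the consistent
value would be 31.95. The value conventionally tabulated next to
induction-period entropies, however, is **21.46**, and published ΔS values
for this system are only reproducible with it. The package therefore
defaults to 21.46 as an explicit compatibility constant, carries it in
every Eyring fit object and report, and exposes the SI value as
`oxikin_constants()$ln_kb_over_h_si` for users who want strict SI
entropies. Changing it shifts every ΔS by R·Δln(kB/h) and nothing else.

Temperatures are accepted in °C or K only through an explicit unit column
or argument — no autodetection, because the working range 100–130 is
ambiguous between the two scales. Replicates enter the regression as
individual points by default (`average_replicates = TRUE` pre-averages);
fits refuse fewer than two distinct temperatures and warn below three. R²
is the ordinary coefficient of determination, clamped to [0, 1].

Note that an Arrhenius Ea and an Eyring ΔH fitted to the same data differ
by roughly R·T̄ (≈3.2 kJ/mol at 110 °C). The package fits them
independently and asserts no relation between them, since the two models
are separate conventions for summarizing the same line.

## Isoconversional DSC kinetics

At a fixed degree of conversion — here the exotherm peak — the heating rate
β and peak temperature Tp obey, in Doyle's approximation,

* Flynn–Wall–Ozawa: `lg β = −0.4567·E/(R·Tp) + C1`
* Kissinger–Akahira–Sunose: `lg(β/Tp²) = −0.4343·E/(R·Tp) + C2`

with lg = log₁₀ throughout (the KAS factor 0.4343 = 1/ln 10 fixes the log
base; natural-log variants are deliberately not offered to prevent silent
constant mismatches). OLS on x = 1000/Tp gives E = −s·R/0.4567 (FWO) or
−s·R/0.4343 (KAS). The two methods use different approximations of the
temperature integral, so their estimates on the same data differ
systematically — by construction around 10–15 % here, with FWO the higher —
but they rank samples identically. Only the peak-temperature variant is
implemented: conversion-resolved α(T) integration needs full thermograms,
which are out of scope for a peak-table workflow.

## Radical scavenging and IC50

DPPH and ABTS assays share the arithmetic
`SR% = (A0 − A1)/A0 × 100`; the assay name is metadata. SR is
scale-invariant in the absorbances. The half-scavenging concentration is
estimated by, default first:

* `interpolate` — linear interpolation inside the first consecutive
  concentration pair (ascending) whose SR values bracket 50 %. This is the
  simplest defensible estimator when the underlying convention of a
  reported "scavenging ability" concentration is unknown; it errors,
  rather than extrapolates, when no bracket exists.
* `four_pl` — a four-parameter logistic
  `SR(c) = SRmin + (SRmax − SRmin)·cʰ/(EC50ʰ + cʰ)` fitted by
  Levenberg–Marquardt least squares (`minpack.lm::nlsLM`, hill and EC50
  bounded positive), reporting the concentration where the fitted curve
  crosses 50 % — which differs from EC50 whenever the asymptotes are not 0
  and 100. Starting values come from the data (asymptotes from the observed
  SR range, EC50 from the median concentration, hill = 1).

On smooth data the two agree within the concentration-grid spacing;
interpolation always returns a value inside its bracket.

## The synthetic-data generators

Each generator produces data with exactly the structure its fitter assumes,
which makes it a right-inverse of the fitter at zero noise — the basis of
the package's round-trip tests.

* `simulate_rancimat()`: IP(T) = exp(Ea·1000/(R·T) − ln A), times a
  multiplicative lognormal error exp(N(0, σ²)). Noise on IP is
  multiplicative because induction periods are positive with plausibly
  proportional errors; no additive error model is offered. Default grid
  100/110/120/130 °C, the standard accelerated-oxidation ladder.
* `simulate_dsc_peaks()`: for each β, the linearized FWO or KAS relation is
  solved for Tp by bisection on [200, 2000] K to an absolute residual below
  1e-10 (the FWO case has a closed form, but one solver keeps both paths
  identical and the tolerance explicit). Generating from the linearization
  itself, rather than integrating a reaction model, is exact for the
  fitters — they only ever see (β, Tp) — and exactly invertible. Larger β
  gives larger Tp. Default β grid 5/10/15/20 K/min.
* `simulate_dose_response()`: Hill curve SR(c) = SRmax·cʰ/(IC50ʰ + cʰ) plus
  additive Gaussian noise on SR, converted to absorbances with the control
  fixed at A0 = 0.700 (the standard ABTS working absorbance) and
  A1 = A0·(1 − SR/100), clamped so A1 ≥ 0. Default concentrations
  5–30 µg/mL in steps of 5, the usual assay ladder.

A fixed `seed` makes every generator bit-reproducible.

**What passing round trips do and do not show.** The generators emulate the
*statistical and kinetic structure* of the assays — Arrhenius-linear rate
constants, Doyle-linear peak shifts, sigmoidal scavenging. They do not
emulate instrument drift, baseline ambiguity in IP or Tp determination,
deviations from single-step kinetics, or antioxidant depletion during the
run. Parameter recovery on synthetic data therefore validates the
estimators and their conventions, not the adequacy of the underlying
kinetic models for any particular real oil.

## Numerical choices and degenerate inputs

* OLS via `stats::lm`; a degenerate abscissa (zero variance in 1000/T) or
  fewer than two distinct temperatures/heating rates is an error, not an
  NA.
* Bisection tolerance 1e-10 on the residual, bracket [200, 2000] K;
  parameters that place the peak outside the bracket error with the
  residuals at both ends.
* BDE tie-break in `rank_sites()`: lexicographic on bond label.
* CSV input rejects locale decimal commas instead of guessing, and
  validation errors name the row and column.
* Monte-Carlo test sizes: 200 seeds at σ = 0.05 on four temperatures, a
  grid small enough to run interactively yet wide enough that the mean
  recovered Ea is pinned to a fraction of a percent.

## Known limitations

* No electronic-structure computation, geometry, charge or orbital
  analysis: species energies are inputs.
* No IP detection from conductivity traces or Tp detection from
  thermograms: both are inputs.
* Eyring entropies inherit whatever ln(kB/h) convention is chosen; compare
  ΔS values only within one convention.
* The isoconversional module assumes the peak tracks a fixed conversion
  across heating rates; strongly β-dependent peak conversion violates FWO
  and KAS equally.
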