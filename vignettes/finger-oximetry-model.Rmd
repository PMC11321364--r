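---
title: "A layered-finger Monte Carlo model of skin-pigmentation bias in transmittance pulse oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layered-finger Monte Carlo model of skin-pigmentation bias in transmittance pulse oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseoxmc)
```

## The problem

Pulse oximeters estimate arterial oxygen saturation from the pulsatile
attenuation of red (660 nm) and infrared (940 nm) light. The device-level
quantity is the ratio of ratios

$$R = \frac{(I_d - I_s)/I_s \;\big|_{660}}{(I_d - I_s)/I_s \;\big|_{940}},$$

where $I_s$ and $I_d$ are the transmitted intensities at systole and
diastole. A device maps $R$ to a displayed SpO2 through a calibration line
fitted on a (historically mostly light-skinned) reference population.
Epidermal melanin absorbs strongly at 660 nm, so a calibration fitted on
light skin can misread darker skin, producing positive bias — displayed
saturation above true saturation — precisely in the range where occult
hypoxemia matters.

`pulseoxmc` builds an *in silico* transmittance-mode finger, simulates the
systolic and diastolic transmitted intensities per skin phototype and
saturation with weighted Monte Carlo photon transport, and runs the full
calibration/bias/correction analysis downstream of the simulated (or
tabulated) intensities.

## The tissue model

The finger is a stack of plane-parallel slabs along the optical axis:
six skin sublayers (stratum corneum, epidermis, papillary dermis, upper
blood-net dermis, reticular dermis, deep blood-net dermis), subcutaneous
fat, muscle with an embedded cylindrical bone, fat, and the six skin
sublayers mirrored on the detector side. The source-detector separation —
the finger thickness — is exactly 13 mm; the muscle slab takes whatever
thickness the configured skin and fat layers leave over, so the one firmly
stated geometric datum holds identically under any override.

Default sublayer thicknesses (per side, mm): stratum corneum 0.02,
epidermis 0.08, papillary dermis 0.18, upper blood net 0.08, reticular
dermis 1.5, deep blood net 0.1, fat 0.8. The bone cylinder has radius 2 mm,
axis perpendicular to the optical axis, centred in the muscle slab. All of
these are configurable; they are modelling choices, not measurements.

Chromophore composition drives the absorption coefficients:

* **Epidermis** — melanosome volume fraction `vmel` sets the melanin term
  $v_{mel}\,6.6\times 10^{10}\lambda^{-3.33}$ (mm$^{-1}$, $\lambda$ in nm),
  plus water and a pigment-free baseline power law
  $7.84\times10^{7}\lambda^{-3.255}$ for the residual volume. The three
  phototypes use `vmel` = 2.55% (light, Fitzpatrick I), 15.5% (moderate,
  IV) and 30.5% (dark, VI).
* **Dermal sublayers** — arterial and venous blood at their oxygen
  saturations (oxy/deoxyhemoglobin at 45% hematocrit: 0.15/1.64 mm$^{-1}$
  at 660 nm, 0.65/0.43 at 940 nm), water, and the baseline term. Venous
  saturation is arterial minus 10 percentage points, reading the
  conventional venous-arterial gap as an absolute offset.
* **Stratum corneum, fat, muscle, bone** — fixed tabulated coefficients.

Two modelling details deserve a note:

* *Pulsation.* Diastolic blood volume is split equally between arterial and
  venous compartments; systole doubles the total, again split equally. The
  equal split is stated for systole in the source literature; we apply it
  in diastole too for consistency with the doubling rule.
* *Crowded systolic layers.* Doubling the upper blood net's 30% blood on
  top of 60% water exceeds unit volume. The baseline (residual-tissue) term
  is clamped at zero rather than going negative: the formula's residual
  volume is empty there. This affects only the systolic upper blood net and
  keeps absorption finite and positive.

Dermal and epidermal scattering are not resolved per sublayer in the
tabulated sources; the model uses generic skin-optics defaults
($\mu_s$ = 18.7 / 12.0 mm$^{-1}$ at 660 / 940 nm, Henyey-Greenstein
$g$ = 0.91 / 0.94 shared across the skin sublayers), exposed in the
configuration.

## The transport engine

Standard weighted (implicit-capture) Monte Carlo: hop lengths are
exponential in optical depth, each interaction deposits the albedo
complement of the packet weight, the new direction is drawn from the
Henyey-Greenstein phase function, and low-weight packets play Russian
roulette (threshold $10^{-4}$, survival 0.1 — the conventional values).
All tissue shares refractive index 1.4 inside; Fresnel physics acts only at
the two outer air-tissue surfaces: the entry face subtracts the specular
reflection $((1-1.4)/(1+1.4))^2 \approx 2.78\%$ from the initial unit
weight, and every exit attempt splits the packet deterministically into a
transmitted fraction $1-R(\theta_i)$ (tallied as detected or escaped) and
an internally reflected fraction $R(\theta_i)$ that continues, with total
internal reflection beyond $\arcsin(1/1.4) \approx 45.6^\circ$.
Deterministic splitting at the surface has the same expectation as
stochastic branching with lower variance.

The source is a Gaussian beam (1 mm radius read as the $1/e^2$ intensity
radius, position SD 0.5 mm) entering along the axis; the detector is a
coaxial 1 mm-radius aperture on the far face accepting the full forward
hemisphere (90° half-angle). The finger is laterally bounded — packets
whose interaction site wanders beyond the lateral half-width leave through
the side faces and are tallied as escaped.

Every run satisfies an exact bookkeeping identity, accumulated in extended
precision: specular + absorbed + detected + escaped + residual = launched,
where `residual` collects the (zero-expectation) roulette corrections.

### Variance reduction

A 1 mm detector behind 13 mm of scattering tissue receives a tiny fraction
of launched packets, so the engine supports an optional weight-window
scheme: equidistant importance planes perpendicular to the axis (default
spacing 1.3 mm in grid runs). Crossing a plane towards the detector splits
the packet in two (each child carrying half the weight); crossing away
plays roulette at survival 1/2, doubling the survivor's weight. The
roulette weight threshold scales with the local importance ($2^{-k}$ after
$k$ planes) so the two mechanisms cooperate instead of fighting. Because
every detected packet has made exactly the same number of net upward
crossings, the scheme adds no weight dispersion among detected packets; all
tallies remain unbiased and the conservation identity still holds exactly.
What changes is the meaning of a "detected packet": with splitting, one
launched photon can produce several (correlated) detection events, so a
detected-packet target corresponds to fewer independent photons than the
same target without splitting.

### Reproducibility

The generator is xoshiro256++ seeded through splitmix64 from (seed,
stream). Each launch batch owns one substream, and each grid condition owns
a disjoint block of substreams derived from the condition index, so any
tally is bit-reproducible for a fixed seed and independent of scheduling or
evaluation order. Exponential deviates come from the Marsaglia-Tsang
ziggurat; azimuthal angles from Marsaglia's rejection method on the unit
circle (no trigonometric calls in the inner loop).

## The oximetry analysis

Downstream of the intensities everything is closed-form and lives in plain
tibbles:

* `ac_dc()` and `ratio_of_ratios()` implement the defining arithmetic;
  `acdc_table()` pivots a transmittance grid and flags (never drops)
  conditions where Monte Carlo noise makes the systolic intensity exceed
  the diastolic one.
* `fit_calibration()` is ordinary least squares of SaO2 (%) on $R$,
  matching the published curves being written as $SaO_2 = a + bR$; the
  fitted object supports `tidy()`, `glance()`, `predict()` and
  `autoplot()`.
* `bias_report()` inverts a phototype's calibration at each true SaO2 and
  maps the resulting $R$ through the commercial relation
  $SpO_2 = 110 - 25R$; bias is SpO2 − SaO2. Printed-table reproduction
  rounds half away from zero to one decimal; unrounded values are retained,
  and rounding lives only in the table writers.
* `reference_multiplier()` (ratio of the light curve's $R$ to another
  curve's $R$ at SaO2 = 100%) and `multiplier_profile()` (the same ratio
  across the saturation grid, applied as its arithmetic mean) quantify the
  skin-tone correction; `apply_multiplier()` rescales $R$, which maps a
  line $(a, b)$ exactly to $(a, b/f)$.

One published inconsistency is documented rather than imitated: the printed
dark-skin SpO2 column of the simulated-bias table is consistent with an
intercept of 109 rather than the commercial relation's printed 110 (at
SaO2 = 86%, $110 - 25R$ gives 97.8, not the printed 96.8). The package
follows the commercial equation as written; our dark-skin mean bias is
therefore 10.3 rather than the printed 9.3, and the simulated dark/light
bias ratio 5.93 rather than 5.47. The light-skin column is reproduced
exactly. Similarly, the clinical cohort table's printed White mean bias
(0.5) is coarser than the mean of its printed column (0.5625); the fixture
stores both.

The spacing of the correction-factor analysis follows the fitted lines, not
the raw points: the light/dark multiplier profile computed from the fitted
curves reproduces the published mean factor (~1.8); computing it from raw
noisy $R$ values would mostly propagate Monte Carlo noise.

## The two pipelines

`run_grid()` simulates the full factorial (3 phototypes × 7 SaO2 × 2
phases × 2 wavelengths = 84 conditions) and `assemble_tables()` turns the
result into curves, bias reports and correction factors.
`analytics_from_fixtures()` runs the identical analysis with zero Monte
Carlo from the packaged tables (the published AC/DC table, the calibration
coefficients, the clinical cohort table), so every deterministic claim is
testable without simulation noise.

Photon budgets come as presets: `"paper"` targets $10^6$ detected packets
per condition (the full-study budget), `"ci"` targets $10^4$ — the
reduced problem size used by the package's own test suite, chosen so the
whole grid runs in minutes on one core.

## What the reduced budget can and cannot show

With the weight-window enabled, a $10^4$ detected-packet target
corresponds to only a few times $10^4$ launched photons per condition, so
the per-condition AC/DC values carry appreciable Monte Carlo noise. Two
consequences matter for interpreting reduced-budget grids:

* Because AC/DC is a small difference of two noisy transmittances, the
  per-point noise in $R$ is substantial, and noise in the *regressor*
  attenuates least-squares slopes towards zero (regression dilution). The
  attenuation is strongest for the darker phototypes, whose transmittances
  are smallest.
* The melanin-driven separation between phototype curves in this geometry
  is of the same order as that noise, so at the `"ci"` budget the *sign*
  of every fitted slope is stable, but the light/moderate/dark ordering of
  slope magnitudes and of fitted $R$ at a given saturation is not reliably
  resolved. Resolving the ordering needs the `"paper"` budget (or averaging
  over seeds).

The mechanism by which melanin shifts the calibration at all in a
transmittance geometry is worth stating: a static epidermal absorber
multiplies both $I_s$ and $I_d$ by the same factor on any fixed path, so
single-pass attenuation cancels in AC/DC. The differential effect enters
through multi-pass paths — packets internally reflected at the outer
surfaces recross the pigmented epidermis several times, and higher melanin
preferentially suppresses exactly those long, blood-rich paths. The effect
is therefore sensitive to the unpublished geometric details (sublayer
thicknesses, scattering spectra, lateral extent), which is why exact
reproduction of the published calibration coefficients from fresh
simulation is out of reach by design, and the package instead pins the
deterministic analytics to the published tables.

## Numerical choices

* Interface handling: internal interfaces are index-matched, so the
  remaining optical depth is carried across and rescaled by the new
  attenuation coefficient; positions are nudged $10^{-7}$ mm past any
  crossed boundary to make the region query unambiguous.
* Ray-cylinder intersections solve the quadratic in the plane perpendicular
  to the bone axis; rays within $10^{-12}$ of parallel to the axis are
  treated as non-intersecting.
* A packet that survives $10^6$ transport events (never observed in
  practice) is terminated into the residual tally, preserving conservation.
* Tallies accumulate in `long double`; the conservation identity holds to
  better than $10^{-9}$ relative at any budget.
* Table rounding (half away from zero, one decimal) is applied only in
  writers and printed-table reproductions; all internal computation is full
  precision.

## Limitations

* Melanin is uniform within the epidermis and identical on both sides of
  the finger; depth-resolved or asymmetric pigmentation is not modelled.
* Only the two oximetry wavelengths are first-class; there is no
  continuous spectral model.
* The cardiac cycle is two endpoint states (systole/diastole), not a
  waveform; venous pulsation enters only through the equal-split rule.
* Reflectance-mode probes, polarization, fluorescence and time-resolved
  transport are out of scope.
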