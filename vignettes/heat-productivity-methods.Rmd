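---
title: "Methods: heat exposure, WBGT, and work-capacity accounting under albedo scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat exposure, WBGT, and work-capacity accounting under albedo scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatshift)
```

## The question the pipeline answers

Outdoor workers at large paved sites — the motivating case is an airport
campus near 37.6 N with three 8-hour shifts (07–15, 15–23, 23–07 local) —
lose part of their physical work capacity on hot days. Raising the albedo of
roofs and pavements cools near-surface air, most strongly around midday.
The pipeline quantifies that benefit as *hours of productivity gained per
worker per month*: hourly meteorology per scenario → hourly wet bulb globe
temperature (WBGT) → hourly minutes of work lost → shift/month totals →
difference against the do-nothing baseline.

## WBGT model

For hours without sun exposure (night, or negligible shortwave):

* windy (`u > 3` m/s): `WBGT = 0.7 Tw + 0.3 Ta`
* calm (`u <= 3` m/s): `WBGT = 0.67 Tw + 0.33 Ta - 0.048 log10(u) (Ta - Tw)`

For sun-exposed hours: `WBGT = 0.7 Tw + 0.2 Tg + 0.1 Ta`.

An hour counts as sun-exposed iff downwelling shortwave exceeds 25 W/m² and
the solar zenith angle is below 90°. "Shade or night" versus "sun" is a
qualitative distinction, so the exact threshold is a design choice,
surfaced in `globe_params(sun_kdown_threshold=)`; 25 W/m² is low
enough that every meaningful radiation hour uses the sun form while sunrise
slivers with negligible flux do not.

**Wet bulb** `Tw` comes from Stull's arctangent approximation in `Ta` (°C)
and `RH` (percent). Its stated validity window is RH 5–99 % and roughly
−20–50 °C; outside it the function warns and flags rather than refusing,
because hourly campaigns occasionally brush the edges. The synthetic
generator clamps RH into [5, 99] so generated campaigns never trigger the
flag.

**Globe temperature** `Tg` solves the radiative–convective balance of a
0.15 m black globe (emissivity 0.95, shortwave albedo 0.05):

```
Tg^4 = (L↓ + L↑)/(2σ) − h_c (Tg − Ta)/(ε_g σ)
       + K↓ (1 − α_g)/(2 ε_g σ) (1 − F + F/(2 cos Z))
       + (1 − α_g)/(2 ε_g σ) K↑
```

with all temperatures in Kelvin internally and °C at every interface.
Term grouping follows the standard globe-thermometer formulation: the
longwave mean, a convective exchange, direct-plus-diffuse shortwave with the
`1/(2 cos Z)` sphere interception factor for the direct beam fraction `F`,
and reflected shortwave. `cos Z` is floored at 0.02 so sunrise/sunset hours
cannot blow up the beam term.

The convective coefficient `h_c` is a modelling choice; the package uses the smooth-sphere forced-convection correlation
`Nu = 2 + 0.6 Re^{1/2} Pr^{1/3}` with dry-air properties (Sutherland
viscosity, ideal-gas density, Pr = 0.71) evaluated at the film temperature
and the 0.15 m diameter. At 3 m/s this gives `h_c` ≈ 16 W m⁻² K⁻¹.

*Numerics.* The fixed point is iterated by damped successive substitution,
`Tg ← 0.5 Tg + 0.5 RHS^{1/4}`, stopping when successive iterates differ by
less than 0.02 °C. Because the convective term is stiff (its slope grows
with wind speed), the damped map can oscillate or diverge at high wind; any
sample not converged after 50 iterations falls back to bracketing bisection
of the residual over `[Ta − 5, Ta + 80]` °C, and the per-run manifest counts
those fallbacks. The bisection route is also the independent oracle in the
test suite: solver and oracle agree within 0.04 °C (twice the tolerance) on
1,000 randomized daytime samples.

The wind speed is clamped below at 0.13 m/s before `log10(u)` in the calm
branch, which diverges as `u → 0`; the clamp is configurable
(`globe_params(u_min=)`). The discontinuity between the windy and calm
branches at exactly `u = 3` is small (−0.0071·(Ta − Tw) °C analytically); it
is documented and tested, not smoothed away.

## Work-capacity loss and aggregation

Minutes lost per working hour follow a logistic in WBGT,

```
work_loss = 60 − 60 / (1 + (33.63 / WBGT)^−6.33),
```

the exposure–response for unacclimatized workers doing moderate-to-heavy
work in normal attire. Its half-capacity point is exactly 30 min/h at
33.63 °C; below ~20 °C losses are negligible. Non-positive WBGT (where the
power is undefined) returns zero loss with a flag.

Order of operations matters: the response is convex over the WBGT range that
midday hours occupy, so applying it to shift-mean WBGT would understate
losses (Jensen's inequality — asserted in the tests on a midday-peaked
series). The pipeline therefore applies the response to every hourly,
per-location WBGT first, then averages locations unweighted within each
(day, hour) cell, then sums cells:

```
lost_hours(shift) = Σ_days Σ_hours∈shift mean_locations(work_loss)/60.
```

Because every day of the month is aggregated, assembling the
midnight-crossing 23–07 shift is equivalent to binning samples by
hour-of-day, which is how it is implemented (248 cells per shift for a
31-day month). Missing hours are a hard error listing the gaps — no silent
imputation. Hours gained per scenario are baseline minus scenario lost
hours, per shift and in total; the trapezoidal `productivity_auc()` gives
cumulative percent-hours over any chronological percent-capacity series.

## The synthetic campaign

No mesoscale-model output is redistributed here, so the generator emulates
the *statistical shape* such output has over a coastal airport in August:

| parameter | default | meaning |
|---|---|---|
| `n_locations` | 10 | representative outdoor work locations |
| month | August 2020 | 31 days × 24 h, instantaneous top-of-hour samples, PDT offset |
| `Ta_mean`, `Ta_amplitude` | 21, 8 °C | sinusoidal diurnal cycle peaking at `Ta_peak_hour` = 14 |
| `RH_mean`, `RH_amplitude` | 65, 22 % | anti-correlated with the Ta cycle, clamped to [5, 99] % |
| wind | lognormal, median 3.5 m/s | windy coastal site; exercises both shade branches |
| shortwave | clear-sky, 1361 W/m² × 0.75 × cos Z | zero at night; `K↑ = 0.20 K↓` |
| longwave | `L↓ = 0.75 σ Ta⁴`, `L↑ = 0.97 σ Ts⁴`, `Ts = Ta + 2 + 6·K̂` | blackbody at near-surface temperatures |
| `F_clear` | 0.85 | direct-beam fraction below Z = 80°, tapered to 0 at 90° |
| `scenario_peak_cooling` | 0 / 0.9 / 1.25 / 1.6 °C | peak ΔTa for baseline/low/moderate/high |

The scenario cooling profile is `ΔTa(h) = peak · K↓(h)/max K↓`: largest at
midday, exactly zero at night. Scenario series share every field except
`Ta_C` with baseline — the cooling emulates the post-processed 2-m air
temperature response, not a re-run surface energy budget. Per-location
offsets and hourly noise are seeded and *centred across locations at every
hour*, so the across-location mean equals the deterministic cycle exactly
for any seed; the seeding contract (same seed ⇒ byte-identical output) is
tested.

What the generator deliberately does **not** emulate, and what that implies
for the tests: no clouds, no surface heat retention, no wind–temperature
coupling, no advection. In particular, because cooling is proportional to
instantaneous shortwave, the 23–07 shift receives *exactly zero* cooling and
its gained hours are exactly zero — real campaigns show small positive night
gains from heat stored in pavement. Passing tests therefore demonstrate
that the exposure→response→aggregation machinery is correct and that the
qualitative structure (gains ordered high > moderate > low and
first > second > third shift) emerges from a midday-peaked cooling signal;
they do not validate mesoscale physics. A recovered-vs-imposed check
regresses per-hour ΔWBGT on ΔTa under sun and requires the slope to sit in
the analytic band `[0.1 + 0.7·min ∂Tw/∂Ta, 0.1 + 0.7·max ∂Tw/∂Ta + 0.2]` —
the 0.2 allowance being the globe term's weight, since `∂Tg/∂Ta < 1`.

## Albedo stage

Broadband albedo is the weighted narrowband sum over the blue, green, red,
near-infrared and two shortwave-infrared reflectance bands; the default
weights are the published Sentinel-2 conversion set
(0.2266, 0.1236, 0.1573, 0.3417, 0.1170, 0.0338, zero offset — they sum
to 1) and live in configuration so a Landsat set can be swapped in. Values
above 1 (sensor noise, highly reflective materials) are set to exactly 1;
values below 0 are symmetrically set to 0 for physical validity. Cloud masking is
accepted as a precomputed mask input (the external cloud-score product is
not reproduced). The scenario table maps the six campus surface types to
albedos per modification level, validated to be monotone
baseline ≤ low ≤ moderate ≤ high per type, and `apply_scenario()` remaps a
surface-type raster pixelwise, with an explicit passthrough flag for types
outside the table. Raster I/O uses single-band TIFF when the `tiff` package
is available and a plain delimited-matrix fallback otherwise.

The albedo stage and the meteorological stage are linked *by scenario name
only*: the table defines what "low/moderate/high" mean on the ground, and
the campaign's peak-cooling values represent the modelled air-temperature
response to those surface changes. The package does not itself model the
surface-energy-balance step between them (that is mesoscale-model
territory, out of scope).

## Problem sizes and determinism

The shipped analysis and the acceptance script use the full study
configuration (10 locations × 744 h × 4 scenarios ≈ 30k hourly records,
~16k globe solves), which runs in seconds because the solver is vectorized
across samples. Unit and property tests use 1–3 locations and 100–1,000
randomized samples per property — sizes chosen so the whole suite exercises
every branch, including the bisection fallback, while staying fast. All
randomness flows from explicit seeds; `run_pipeline()` with the same config
and seed produces byte-identical artifacts, and the manifest records the
seed, scenario list, config hash, and solver fallback count.

## Known limitations

* Clear-sky only; overcast daytime hours in real data would still use the
  sun form (with lower `F`), a behaviour the threshold rule supports but the
  generator never produces.
* The exposure–response assumes unacclimatized, fit workers at fixed strain;
  no acclimatization, clothing, or metabolic adjustments are modelled.
* Zero night cooling is a generator artefact (above), so third-shift gains
  are structurally zero in synthetic campaigns.
* The globe-temperature constants (`h_c` correlation, emissivity, albedo)
  are field-standard defaults, not fitted values; all are surfaced in
  `globe_params()`.
* Locations are averaged unweighted; no worker-count weighting is applied.
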