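---
title: "Field-size QA with a large-area chamber: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-size QA with a large-area chamber: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacqa)
```

## The method

A variable-aperture collimator restricted to 12 clinical diameters
(5-60 mm at SAD 800 mm) must hold each field size to ±0.2 mm. The QA
method modelled here replaces film measurements with a single large-area
parallel-plate chamber (sensitive diameter 81.6 mm) mounted at SAD 791 mm,
close enough to the source that every clinical field, penumbra included,
falls inside the sensitive area. The chamber reading is then the dose-area
product

$$\mathrm{DAP}(d) = \mathrm{OF}(d)\int_0^{r_{max}} \mathrm{OCR}(r, d)\,
  2\pi r\,\mathrm{d}r,$$

with OCR the radially symmetric off-center ratio (profile) and OF the
output factor. Because the DAP scales with the field area, it is an
extremely sensitive probe of diameter: the monitored statistic is the
quotient $\theta(d) = \mathrm{DAP}_{Iris}(d)/\mathrm{DAP}_{Fixed}(60\,mm)$,
whose ratio form cancels output drift and daily factors, and each session
is judged by $\delta(d) = (\theta/\theta_{baseline} - 1)\cdot 100$ against
tolerance limits that translate the ±0.2 mm specification into percent.

Under pure area scaling $\theta \propto d^2$, so percent and millimetres
interconvert as

$$\Delta d = d\left(\sqrt{1 + \delta/100} - 1\right), \qquad
  \delta = \left(\frac{(d + \Delta d)^2}{d^2} - 1\right)\cdot 100 .$$

This conversion deliberately excludes output-factor variation: it is the
geometric reading of a percentage deviation, and it reproduces every
printed equivalence the method's validation relies on (0.090 mm for 3.63%
at 5 mm; 0.334% per 0.1 mm at 60 mm versus 2.68% per 0.1 mm at 7.5 mm —
the same absolute error matters far more for small fields).

## The beam model and its parameters

The package needs no machine data to be exercised; a parametric model
stands in for commissioning profiles.

* **Geometry.** Field sizes are specified at SAD 800 mm; the chamber plane
  at `plane_sad_mm = 791` scales every diameter by 791/800. All distances
  are in mm, readings in nC-equivalent model units, percentages on the
  0-100 scale.
* **Profile.** `beam_profile()` uses a flat core with an erfc-shaped
  penumbra centred on the projected field edge. The scale constant is
  chosen so `penumbra_mm` is the 80%-20% penumbra width; the default
  3 mm is plausible for a 6 MV FFF-type small-field machine. The edge is
  renormalized by its on-axis value so that $\mathrm{OCR}(0, d) = 1$ holds
  exactly even for the 5 mm field, where the penumbra is not small against
  the field radius; the half-value point sits on the geometric field edge
  whenever $p \ll R$. `penumbra_mm = 0` selects an ideal step field, for
  which all DAP quantities have closed forms (disk areas and circle-circle
  lens areas) used throughout the tests.
* **Output factors.** `default_of_table()` is a monotone saturating curve
  ($1 - 0.4545\,e^{-d/15}$, normalized to 1 at 60 mm, OF(5) ≈ 0.68). It is
  a synthetic stand-in — flagged as such, and the flag propagates into QA
  reports. Interpolation is piecewise linear; above 60 mm the value is
  clamped (the OF plateaus at large apertures, and the clamp is what makes
  the calculated 60 mm limit the pure area value of ±0.67%), while below
  the smallest tabulated diameter the first segment is extended linearly —
  the OF gradient steepens toward small fields, which is what makes the
  negative small-aperture limit larger in magnitude than area scaling
  alone. Either extrapolation is allowed only 0.2 mm beyond the table.
* **Detuning.** A deliberately mis-tuned beam is modelled as a multiplicative
  depression of the profile shoulder (0.5-0.9 of the field radius, with
  smooth 0.05-R ramps) by 4% per unit level, the worst clinically tolerated
  mis-tune. The quotient is nearly blind to it — the depression divides out
  between numerator and reference — which is the method's claimed
  robustness to beam changes, and what the tests observe (deviations well
  under the tolerance limits at level 1).

## Numerical choices

Aligned DAPs use adaptive Gauss-Kronrod quadrature (`stats::integrate`,
relative tolerance 1e-10; for step profiles the integration stops at the
field edge where the integrand vanishes). Misaligned DAPs integrate over
the offset chamber disk in polar coordinates centred on the chamber, where
the integrand is smooth: an adaptive radial integral (1e-8) of adaptive
angular integrals (1e-9, halved by symmetry). `dap_offset()` never
short-circuits to the radial routine at `shift = 0`, so the agreement of
the two (better than 1e-6 relative, verified against midpoint-grid oracles
at 10^5+ nodes) is a genuine cross-check of both code paths. Ideal step
fields under offset use the exact circle-circle lens area instead of
quadrature, and refuse flatness/detuning (no closed form there).

$\theta$ is computed means-first (the arithmetic mean of the repeat
readings per aperture, then one quotient), matching the measurement
procedure. A deviation exactly on a tolerance limit counts as a pass: the
specification is stated inclusively ("±0.2 mm"). Sample SDs use the n-1
denominator (3-5 repeats per aperture is the norm). Apertures are judged
individually with no multiplicity correction — the limits are engineering
tolerances, not hypothesis tests. An aperture missing from a session is
reported as failed with a reason; a missing 60 mm reference is an error,
since nothing can be normalized without it.

The power-law characterization fit $\mathrm{DAP} = b\,d^c$ is performed in
log-log space by default (scale-free weighting across a 50-fold dynamic
range; raw nonlinear least squares is available as an option), and the
$\theta$-versus-area fit is the through-origin slope $\sum xy/\sum x^2$.

## The error budget

Three measured components dominate: output variation over a series
(0.04%), MU-delivery uncertainty (0.04%, size-independent), and setup
misalignment (0.10% budgeted for a ≤ 2 mm setup; misalignment only becomes
size-*dependent* near 10 mm, where the 60 mm field's penumbra reaches the
chamber edge). Their quadrature sum is 0.115%. The method's published
working value is a conservative 0.2% envelope, which exceeds the
quadrature of its stated components; since the combination rule behind it
is not specified, `error_budget()` reports both numbers and the package
asserts only the quadrature. One further published inconsistency is worth
recording: a 0.2% error converts to 0.005 mm at 5 mm but to 0.060 mm at
60 mm under the quadratic rule, not the 0.012 mm quoted alongside it; the
quadratic rule is implemented and the 5 mm figure reproduced.

## The synthetic-data generator

`simulate_session()` emulates the documented measurement: repeated 100-MU
exposures of the 12 iris apertures plus the fixed 60 mm reference. Per
exposure, the true aperture is nominal + systematic offset + normal jitter
(SD 0.02 mm by default — iris only, fixed cones have no size to jitter),
the deterministic reading comes from the beam model (misaligned if
configured), and two independent multiplicative noises are applied: output
drift (SD 0.04%) and MU-delivery noise (SD 0.04%). All draws are
independent normals — the method's characterization quantifies only SDs,
no correlation structure — and follow a fixed order under a saved/restored
RNG state, so sessions are bit-reproducible; long-term series split
per-session seeds deterministically from the master seed
(`(seed + i * 1000003) mod (2^31 - 1)`).

With every SD at zero the generator returns the model DAPs exactly and
round-trips through `evaluate_qa()` to $\delta \equiv 0$ at machine
precision. Each configured noise magnitude is recoverable from its
targeted statistic (output drift from fixed-cone repeats; jitter from the
iris excess variance, checked against a Monte-Carlo oracle), and sessions
simulated with a true offset $x$ recover mean $\delta$ near
`mm_to_delta(x, d)` under a constant OF table.

What the generator does *not* emulate: machine-history effects (real
long-term series include slow drifts and service events beyond the three
noise SDs, so the simulated between-session spread — roughly 0.05% at
60 mm to 0.25% at 5 mm under the defaults — sits below the spread a clinic
observes over two years, though the size ordering matches), the 12-sided
shape of the real aperture (treated as circular, as the analytical limit
derivation does), head scatter, and any profile asymmetry. Passing tests
therefore demonstrate the statistics and the machinery, not clinical
performance of any particular machine.

Problem sizes used by the test-suite and verification runs — 31 sessions of
5 repeats for long-term properties, 60 exposures for the output-drift
recovery, 10^5-node oracles, 3 sessions per sign for measured-style limits
— mirror the documented measurement campaign (31 series over 22 months,
3-5 repeats) while keeping every run deterministic under fixed seeds.

## Known limitations

* The erfc penumbra redistributes dose only approximately: at the 5 mm
  field the fixed 3 mm penumbra damps the area term, so calculated limits
  there are smaller in magnitude than pure area scaling, whereas a machine
  with a steep measured small-field OF curve shows the opposite (the
  published calculated -13.72% at 5 mm implies an OF drop of several
  percent per 0.2 mm, far steeper than the synthetic table). Supplying
  measured OF and profile data through the YAML configuration removes this
  limitation.
* Uncorrected readings are assumed throughout (no air-density, polarity or
  recombination corrections), as the quotient cancels them.
* No control-chart rule system beyond the linear trend statistic of
  `stability_summary()`.
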