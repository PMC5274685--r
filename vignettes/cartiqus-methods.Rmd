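---
title: "Quantitative ultrasound and micro-CT morphometry on synthetic phantoms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound and micro-CT morphometry on synthetic phantoms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartiqus)
```

## The problem

Estrogen deficiency after menopause degrades both articular cartilage and
trabecular bone, and the two tissues do not respond on the same timescale.
A standard preclinical design compares ovariectomized (OVX) animals with
sham-operated controls, assessing cartilage with quantitative
high-frequency ultrasound at the medial and lateral tibial plateaus (MTP,
LTP) and cancellous bone with micro-CT, then testing each extracted
parameter between groups. `cartiqus` implements that entire measurement
chain — the acoustic parameter definitions, the echo processing that feeds
them, the trabecular morphometry panel, and the exact nonparametric
comparison — together with synthetic data generators that emulate the
acquisition well enough to validate every stage against known ground
truth. No animal data are required or shipped: every input is simulated,
and the generators' parameters are the study conditions.

## The acoustic panel

Four parameters are computed from the radiofrequency (RF) echoes of an
`m`-line scan, relative to a perfect-reflector reference with peak-to-peak
amplitude $A_{ref}$:

* **URI** (ultrasound roughness index, µm): the population standard
  deviation $\sqrt{\frac{1}{m}\sum_i (d_i - \bar d)^2}$ of the per-line
  transducer-to-surface distances $d_i$. The $1/m$ normalization (not
  $1/(m-1)$) is deliberate and matches the definition's printed form.
* **RC1** (%): mean surface-echo peak-to-peak amplitude over $A_{ref}$,
  $\frac{1}{m}\sum_i (A_i/A_{ref}) \times 100\%$.
* **RC2** (%): the same form for the cartilage–bone interface echoes.
  RC2 is *uncorrected*: no compensation for the two-way transmission loss
  through the surface or for attenuation in cartilage. With attenuating
  cartilage it therefore underestimates the physical interface
  reflectivity, and it inherits a coupling to thickness (thinner cartilage
  attenuates less, so RC2 rises). Both behaviours are inherent to the
  uncorrected definition and are reproduced, not "fixed".
* **h** (mm): mean thickness $\frac{1}{m}\sum_i c\,\mathrm{TOF}_i/2$ with
  a fixed cartilage sound speed, default $c = 1675$ m/s.

Each formula's $m$ is renormalized to the number of lines whose relevant
echo was detected; surface and interface counts may differ. Lines that
fail detection are excluded rather than imputed, because the formulas are
plain per-line averages.

## RF simulation

The emitted pulse is a Gabor pulse (Gaussian-enveloped cosine), the
simplest analytic transducer model: centre frequency 50 MHz, −6 dB
fractional bandwidth 0.5, sampled at 400 MHz (8 samples per carrier
period, a realistic digitizer margin). The scan is a 10 × 10 raster over a
0.3 mm × 0.3 mm region, 100 lines. Per line, the surface standoff
$d_i \sim N(10\,\mathrm{mm}, \sigma_{rough})$ and local thickness
$h_i \sim N(\mu_h, \sigma_h)$ are drawn independently; non-positive
thickness draws are redrawn and counted rather than truncated, keeping the
Normal shape intact. The line is then

$$ r_s A\, g(t - 2d_i/c_{sal}) \;+\; r_i (1 - r_s^2)\, 10^{-\alpha f_0
   2h_i/20}\, A\, g(t - 2d_i/c_{sal} - 2h_i/c_{cart}) \;+\;
   \varepsilon(t), $$

with $g$ the unit Gabor pulse and $\varepsilon$ white Gaussian noise.
Attenuation is applied at the carrier frequency only (narrowband
approximation) — adequate because the panel uses peak-to-peak amplitudes,
not spectra. The interface echo includes the two-way transmission factor
$(1 - r_s^2)$ even though RC2's extraction does not correct for it; the
forward model is physical, the extraction is literal.

Defaults (all configurable) describe intact rat tibial cartilage under an
averaged acquisition: roughness SD 5 µm, thickness 0.30 mm (0.28 mm at the
lateral site) with 15 µm line-to-line variation, $r_s = 0.10$,
$r_i = 0.30$, attenuation 2 dB cm⁻¹ MHz⁻¹, saline sound speed 1520 m/s,
noise SD 0.002 · $A_{ref}$ (≈ 54 dB below the reference, ≈ 34 dB below
the surface echo — typical after pulse averaging). The noise default was
chosen from an error budget: at this level the peak-to-peak amplitude bias
stays well under the 1 % relative accuracy the recovery tests demand,
so round-trip errors are dominated by sampling variability rather than by
the noise floor.

## Echo detection

Detection is per-line and deliberately simple:

1. Both the reference and every scan line are band-pass filtered to the
   frequency support where the reference spectrum exceeds 5 % of its
   maximum. Filtering echo and reference identically leaves amplitude
   ratios exactly invariant while rejecting out-of-band noise.
2. The envelope is the magnitude of the analytic signal (FFT Hilbert
   method).
3. The noise floor is the median envelope over the leading (pre-surface)
   samples; the detection threshold is 4 × that floor, but at least 2 % of
   the reference envelope maximum.
4. The surface echo is localized at the envelope maximum within one pulse
   length after the first threshold crossing (robust against noise
   micro-maxima on the rising flank); the interface echo is the largest
   envelope value between one dead time (= one pulse length, the reference
   envelope's full width at 1/10 maximum) after the surface and the end of
   the search window.
5. Echo times are refined to sub-sample precision by a log-parabolic fit
   to the envelope peak — exact for a Gaussian envelope.
6. Peak-to-peak amplitudes are read off the raw (band-filtered) RF within
   ± one pulse length of the peak, after 8× band-limited upsampling. At 8
   samples per carrier period the discrete max − min otherwise carries a
   sampling-phase ripple of several percent; upsampling removes it.

Lines with no surface candidate are flagged invalid; if more than half of
a scan's lines fail, the scan errors out rather than returning a
misleading panel.

## Trabecular morphometry

The panel re-implements the standard model-independent definitions (the
original instrument software's exact variants are proprietary; output
metadata states the conventions used):

* **BV/TV**: foreground voxel fraction of the volume of interest — exact
  integer counting.
* **Tb.Th / Tb.Sp**: volume-weighted mean local thickness of the bone /
  marrow phase (largest-inscribed-sphere definition). Sphere radii are
  centre-to-centre Euclidean distance transform values; this convention is
  exact for even-width slabs and within about one voxel otherwise. The
  distance transform treats the volume boundary as periodic by default
  (matching the periodic phantoms; configurable to background- or
  foreground-extension), replacing ad-hoc edge cropping.
* **Tb.N**: the model-independent inverse mean spacing
  $1/(\mathrm{Tb.Th} + \mathrm{Tb.Sp})$ by default; the plate-model form
  $(\mathrm{BV/TV})/\mathrm{Tb.Th}$ is available.
* **Conn.D**: first Betti number per unit volume. The Euler
  characteristic is computed exactly as $V - E + F - C$ on the cubical
  complex of closed voxel cubes, which realizes 26-connected foreground /
  6-connected background (the convention matters and is stated). Enclosed
  cavities are counted by 6-connected background labeling so
  $\beta_1 = \beta_0 - \chi + \beta_2$ is exact; if the foreground has
  several components the largest is used and a message emitted.
* **SMI**: $6 V S'/S^2$ with both surface quantities evaluated on the
  signed distance field of the binary volume: $S$ via the co-area formula
  (smoothed delta at the zero level set times the gradient magnitude) and
  $S'$ as the total-curvature integral over that level set (divergence of
  the unit normal), which is the analytic derivative of offset-surface
  area. A finite difference of level-set areas at ± half a voxel was
  rejected: on discrete distance fields the offset surfaces are unions of
  balls whose bumps inflate the area difference by ~10 %, while the
  curvature form recovers sphere/cylinder/plate to 4.10 / 2.95 / 0.00
  against the ideal 4 / 3 / 0.

Phantoms with analytically known answers — parallel plates, triaxial rod
lattices, solid blocks, tori, and custom arrays — drive the validation:
plate BV/TV and period are exact by construction, the torus has exactly
one loop, and the rod lattice's loop count follows from its intersection
graph. Rod lattices accept a sub-voxel lattice offset, modelling specimen
positioning relative to the scan grid; cohorts draw it per specimen so
that morphometric values vary smoothly under the null instead of being
quantization-locked.

## Group comparison

Every parameter is compared between groups with a Mann–Whitney U test
using midranks for ties. For pooled sizes up to 16 (the study design is
7 + 7 = 14) the two-sided p-value is exact: all $\binom{n_1+n_2}{n_1}$
assignments of the observed pooled values are enumerated (3432 at 7 + 7),
which remains exact under ties; two-sided p is $2\min(P(U \le u),
P(U \ge u))$ capped at 1 — a documented choice, since the test name alone
does not fix the two-sided convention. Larger samples fall back to the
tie-corrected normal approximation with continuity correction. A constant
pooled sample yields p = 1 with a "degenerate" flag. Significance is
declared at $p \le 0.05$ with *no* multiplicity correction, deliberately
mirroring the single-parameter reporting convention of the study design
this emulates. The discrete 7 + 7 test's attained two-sided size at
nominal 0.05 is below 0.05; the type-I property test therefore checks the
empirical rejection rate against binomial bounds around the exact attained
size computed by enumeration.

## The cohort model and the demo study

A cohort draws per-animal multiplicative factors (lognormal, unit mean)
for roughness, surface reflectivity, thickness, interface reflectivity and
rod radius, with coefficients of variation 0.20 / 0.10 / 0.10 / 0.15 /
0.05 — biological between-animal variability. OVX specimens additionally
multiply selected parameters by effect sizes. The shipped demo
(`default_study_config()`, n = 7 + 7, fixed seed) uses roughness ×3 and
thickness ×0.7 at both plateaus, surface reflectivity ×0.6 at the medial
plateau only, and *no* bone effect — an early time point at which
cartilage has responded to estrogen deficiency but cancellous bone has
not. Its comparison table flags URI and h at both sites and RC1 at the
medial site, while all six bone parameters stay non-significant. The
effect sizes are synthetic defaults chosen to produce that qualitative
pattern; they are not estimates of any measured effect magnitudes. Note
that RC2 can reach significance in the demo through the physical
attenuation–thickness coupling described above.

## Problem sizes, numerics, and limitations

Tests and the acceptance script run the study at its native scale (100
lines per scan, 14 specimens, 48³ bone volumes at 12 µm voxels) in a few
tens of seconds; the type-I error property uses 1000 cohorts drawn at the
latent-parameter level, since repeating the full RF chain 1000 times
measures nothing additional about the test. Sub-seeds for specimens are
drawn from the master seed, so one integer reproduces a whole study
byte-for-byte.

What the generators do *not* emulate — and hence what passing tests do not
establish about real data: no diffraction or beam geometry (echoes are
ideal scaled pulse copies), no speckle from sub-resolution scatterers, no
frequency-dependent pulse distortion from attenuation, flat rather than
curved plateau surfaces, and segmented-perfect binary CT volumes without
grayscale thresholding artifacts. The pipeline validates the *estimators*
against their definitions and known ground truth; instrument-specific
biases of real acquisitions are out of scope. The saline sound speed
(1520 m/s) and the raster pattern are configurable defaults, since
acquisition protocols rarely pin them down.
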