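---
title: "Physics-based tail-artifact removal for OCTA volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-based tail-artifact removal for OCTA volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tartes)
```

## The problem

Optical coherence tomography angiography (OCTA) derives flow contrast from
the temporal variation of the OCT signal: moving red blood cells decorrelate
the speckle pattern between repeated scans, so vessels light up against
static tissue. The technique suffers from a characteristic *tail* (or
projection) artifact: a vessel-like streak extending below every real
vessel. The dominant physical cause is simple — flow in a shallow layer
modulates not only the light reflected *from* that layer but also the light
transmitted *past* it, so every deeper layer sees a fluctuating illumination
and acquires spurious "flow" signal even when its own reflectivity is
perfectly static.

This package implements a corrector that inverts exactly that mechanism,
two standard comparators, the usual preprocessing chain, a synthetic phantom
generator built on the same transmittance physics (so the corrector can be
validated against exact ground truth), and depth-profile metrics to
quantify tail suppression.

## The physical model

Index layers by depth, $n = 0, 1, \dots$ at the tissue surface. With
$T_n$ the fraction of incident light transmitted to layer $n$, $R_n$ the
layer reflectivity and $w_1$ an (inverse) instrument proportionality
constant, the structural and angiographic intensities are

$$S_n = \frac{T_n R_n}{w_1}, \qquad
  A_n = \frac{\delta(T_n R_n)}{w_1}
      = \frac{\delta T_n\, R_n + T_n\, \delta R_n}{w_1}.$$

Only the second term, $T_n \delta R_n / w_1$, reflects flow *in* layer $n$;
the first term is the tail artifact. Assuming flow-induced reflectivity
variations in different layers are uncorrelated, the variation of the
transmitted light accumulates in quadrature,
$\delta T_n = \sqrt{\sum_{i<n} \delta R_i^2}$, which can be rewritten in
terms of the already-corrected shallower layers. Substituting gives the
layer recursion implemented by `tartes_correct_full()`:

$$A_n^{\mathrm{corr}} = A_n - w_1 \frac{S_n}{T_n}
   \sqrt{\sum_{i<n} \frac{(A_i^{\mathrm{corr}})^2}{T_i^2}},$$

and, under the usual further assumption that essentially all light reaches
every imaged layer ($T_i = 1$), the simplified form of `tartes_correct()`:

$$A_n^{\mathrm{corr}} = A_n - w_1 S_n \sqrt{\sum_{i<n} (A_i^{\mathrm{corr}})^2}.$$

The recursion runs shallow to deep, each lateral position independently;
layer 0 has nothing above it and passes through unchanged.

### The comparators

*Mean subtraction* (`mean_subtract_correct()`) removes a per-column
baseline, $w_2/N \sum_i A_i$ with $N$ the A-scan length, computed from the
**uncorrected** profile and identical at every depth — effectively a
per-A-scan window setting. *Step-down exponential filtering*
(`sdef_correct()`) attenuates each layer by
$\exp(-w_3 \sum_{i<n} A_i^{\mathrm{corr}})$; the factor is always positive,
so it never produces missing signal but also never suppresses a tail
completely. `sdef_linearized()` implements the first-order expansion
$A_n (1 - w_3 \sum_{i<n} A_i^{\mathrm{corr}})$; it is kept as a
small-correction limit oracle — the test suite verifies that its gap to the
exact form shrinks quadratically in $w_3$ — not as a production corrector.

### Weights

All three weights are dimensionally tied to the arbitrary intensity units
of the input: $w_1$ absorbs the detector efficiency and the
reflectivity-to-counts proportionality, so it cannot be derived from first
principles and must be tuned per acquisition. Defaults in `run_config()`
(w1 = 0.02, w2 = 3, w3 = 0.02) are the values found adequate on the
reference skin acquisition and are only sensible starting points for data
on a comparable intensity scale. `sweep_weights()` formalizes the manual
protocol — increase the weight until the tail disappears, then bracket with
a 2×-lower and 2.5×-higher value — as a grid sweep.

### Clipping policy

Both subtractive correctors can produce non-physical negative amplitudes.
These are zeroed *immediately*, per layer, and the zeroed value is what
enters the accumulator for deeper layers: propagating a negative amplitude
into a sum of squares would inflate the correction of everything below it.
Every corrected volume carries a `correction` attribute recording the
clipped-voxel count; a large clipped fraction is the practical signature of
an over-aggressive weight.

## Preprocessing

`preprocess_volume()` applies, in order, Gaussian smoothing with a sigma of
one voxel per axis (anisotropic in physical units; the sigma is exposed as
a parameter) and subtraction of the deep-tissue noise floor — the mean
intensity in a 4–7 mm depth window, where no tissue signal survives and
only homogeneous noise remains. Choices the data formats leave open were
fixed as follows:

* depth is array axis 1, layer index increasing with depth, so "all layers
  above $n$" is a contiguous prefix;
* the noise window selects 0-based layers
  $[\lceil z_{\min}/p \rceil, \lfloor z_{\max}/p \rfloor)$ of pitch $p$ —
  at 8.1 µm and 4–7 mm, layers 494 through 863;
* Gaussian boundaries are handled by reflection with a 4-sigma kernel
  truncation, avoiding edge darkening of the shallow layers that seed the
  recursion;
* en face and offset lookups use nearest-layer rounding, never
  interpolation (at 8.1 µm pitch the worst-case error, 4.05 µm, is
  negligible against the 0.2 mm offsets of interest);
* profile peaks are global maxima with first-occurrence tie-breaking, so
  every metric is deterministic.

## The phantom generator

`phantom_spec()` + `simulate_phantom()` build a synthetic acquisition by
running the forward model above on known reflectivity fields: a uniform
scattering background $R$ with cylindrical vessels of uniform $\delta R$
rasterized by voxel-centre membership (exact, countable geometry — no
anti-aliasing). The default geometry is a scaled-down version of the
reference acquisition: 2.3 × 2.2 × 8.1 µm voxels, a 256 × 64 × 64 volume
(2.07 mm deep), one vessel of 0.05 mm radius — a 0.1 mm diameter, matching
the vessel examined in the reference data — centred at 1.5 mm depth, with
background reflectivity 0.002 per layer and $\delta R = 0.002$ in the
vessel, generated at $w_{\mathrm{true}} = 0.02$. The background value keeps
the physical-transmittance mode physical (column sums of $R$ stay below 1
over 256 layers) while giving the structural image a realistic uniform
speckle-free backdrop.

Because generation and correction share the same physics, the corrector
run at the generating weight inverts the phantom *exactly* (to floating
point; the suite asserts ≤ 1e-9 relative on voxels with positive ground
truth), and any other weight strictly under- or over-corrects — the
quantitative analogue of the manual bracketing protocol.

What the phantom deliberately does **not** emulate: coherent speckle
statistics (the optional noise model multiplies intensities by independent
Gamma factors of mean 1 — positive, speckle-like in scale, but not
correlated), multiple-scattering elongated-path artifacts (a second,
distinct artifact source that this corrector does not address), motion
artifacts, and depth-dependent focus or roll-off. Passing phantom tests
therefore demonstrates correctness of the *implementation and of the
transmittance-inversion logic*, not clinical performance on real tissue;
on real data the model is only an approximation and the weight must be
tuned.

A further honesty note on magnitudes: with realistic background
reflectivity the phantom's tail is *dim* relative to its vessel (the
uncorrected tail-to-vessel energy ratio is of order 0.02), far less
dramatic than tails in clinical hemangioma images. Profile-level fractions
measured on the phantom are therefore not comparable to percentages read
off clinical A-scans; all phantom-based checks in this package are
inequalities and orderings, never those clinical values.

## Numerical and design choices

* **Streaming accumulators.** Each corrector keeps one running per-column
  accumulator (sum of squares for TAR-TES, plain sum for SDEF), updated
  once per layer in double precision — O(1) per voxel. A brute-force
  per-voxel prefix re-summation oracle in the test suite pins the
  equivalence to ≤ 1e-10 relative over 100 seeded random volumes.
* **Transmittance estimation.** `estimate_transmittance()` propagates
  $T_n = T_{n-1} - w_1 S_{n-1}/T_{n-1}$ down each column ($R_i = w_1
  S_i/T_i$ inverts the structural-image relation). When accumulated
  reflection would drive $T$ to zero the value is clamped at a floor of
  1e-3 and a warning is emitted; a clamped profile means $w_1$ is too large
  for the volume's intensity scale. The floor only exists to keep the
  optional non-unit-T mode numerically safe.
* **Weight validation** rejects negatives but imposes no upper bound:
  over-correction is a legitimate, deliberately explorable regime.
* **Tail "disappearance" threshold.** `sweep_weights()` suggests the
  smallest weight whose tail-energy ratio falls below `tail_threshold`
  (default 0.1) *times the uncorrected ratio*, i.e. ≥ 90 % tail-energy
  suppression. The criterion is relative because tails are intrinsically
  dimmer than the vessels that cast them: an absolute tail/vessel cut can
  be satisfied with no correction at all, which would make the suggestion
  meaningless. The threshold is a reporting convention and is echoed in
  the sweep result.
* **On-disk formats.** The lossless canonical container is RDS; multipage
  TIFF (one 32-bit page per en face slice, shallow to deep, max-normalized
  with the scale and the three pitches in a YAML sidecar) is the
  interchange form, precise to 32-bit float. Nothing is ever silently
  overwritten.

## Problem sizes in the test suite

Unit and property tests run on single hand-computed columns, random
volumes of 12–20 layers × ≤ 8 × 8 lateral positions, and a 96 × 24 × 24
phantom; the acceptance tests additionally run the full default
256 × 64 × 64 phantom (about a second) and the 100-volume oracle
comparison. These sizes were chosen so the entire suite completes in well
under a minute while still exercising every code path at full depth.

## A worked example

```{r example}
fm <- simulate_phantom(phantom_spec())
corrected <- tartes_correct(fm$A, fm$S, w1 = 0.02)
corrected

max(abs(unclass(corrected) - unclass(fm$A_true_corr)))

mask <- unclass(fm$A_true_corr) > 0
tail_energy_ratio(fm$A, mask, shadow_extent_mm = 0.2)$ratio
tail_energy_ratio(corrected, mask, shadow_extent_mm = 0.2)$ratio
```

## Known limitations

The corrector inherits the model's assumptions: uncorrelated layer-wise
flow variations, the unit-transmittance simplification (unless the full
form is used with an estimated $T$), and a single global $w_1$ — real
detection efficiency varies with depth, so a depth-dependent weight would
be a natural extension. Aggressive weights cause signal loss (clipped
voxels) and can flatten vessel cross-sections, biasing quantitative
morphology. Multiple-scattering tails, motion artifacts and
complex-signal OCTA variants are out of scope.
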