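---
title: "Methods: image statistics and convergence analysis for glass-object colour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image statistics and convergence analysis for glass-object colour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glavenstats)
```

This vignette documents the models implemented in **glavenstats**, their
assumptions, the parameters that matter, and the numerical and design
choices made where the methodology was genuinely open.  It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## 1. Colorimetry

All analyses start from *linear* RGB.  8/16-bit PNG input is decoded with
the calibration's gamma (default 2.2); float images are taken as already
linear.  A `monitor_calibration` describes the display either by the xyY
chromaticity/luminance of its primaries at maximum drive or by their
emission spectra; the RGB→XYZ matrix has the primaries' tristimulus values
as columns (`X = xY/y`, `Y`, `Z = (1−x−y)Y/y`), so RGB (1,1,1) maps to the
reference white by construction.

* **CIELAB** uses the standard two-branch `f(t)` with `δ = 6/29` and the
  *monitor's maximum white* as reference white, so RGB (1,1,1) has
  `L* = 100`, `a* = b* = 0`.  The branches agree at `t = δ³` to better than
  1e-12 (tested).
* **LMS** excitations are linear combinations of the per-primary maximum
  excitations weighted by RGB.  The bundled cone fundamentals are
  normalized so an equal-energy stimulus of unit intensity excites each
  class by exactly 1; the raw curves are available via
  `cone_fundamentals(normalize = "none")`.  This preconditioning removes
  the arbitrary relative scaling of the three cone channels from every
  downstream statistic.
* **MB-DKL** coordinates are differential opponent signals relative to an
  adapting background: `(ΔL−ΔM, ΔS−(ΔL+ΔM), ΔL+ΔM+ΔS)`.  The background
  maps to the origin; for image analysis it defaults to the monitor
  mid-gray (RGB 0.5).  The literature scales these axes in several
  mutually incompatible ways; the default here applies *no* rescaling
  (the axes are mechanism-null directions only), and
  `scaling = "unit_contrast"` divides each cone differential by its
  background value first.  Neither convention is asserted to match any
  particular published scaling.
* **CIEDE2000** is implemented in full (kL = kC = kH = 1) and verified to
  1e-4 against the standard 34-pair verification dataset plus 120 random
  pairs frozen from an independent reference implementation
  (`inst/extdata/ciede2000_reference_pairs.csv`).
* Spectra are tabulated values on an explicit nanometre grid; resampling
  is linear with zero fill outside the tabulated support, and integration
  is a plain Riemann sum on the common grid (default 47 bands over
  360–830 nm).

The bundled sensitivity curves (colour-matching functions, cone
fundamentals) are smooth analytic approximations, adequate for the
synthetic engine and replaceable by measured tabulations through the same
`spectrum` CSV interface wherever exact colorimetry against instruments is
needed.

## 2. Region-ratio statistics

Given an LMS image and disjoint filtered/unfiltered masks:

* `rmc()` — per cone class, mean over the filtered region divided by mean
  over the unfiltered region (filtered in the numerator).
* `rsd()` — the same with standard deviations.  Values above 1 are legal:
  once highlights, caustics and shadows exist, a glass region can carry
  more variance than its background.
* `robust_ratio()` — finds the cone class with the largest background
  standard deviation (MSD), computes `τ_MSD = sd(P)/sd(A)`,
  `u = mean(P) − τ_MSD mean(A)`, `v = (τ_MSD + u) I_MSD`, `δ = u/v`, then
  `τ_i = (mean(P_i) − uδI_i)/(mean(A_i) + δI_i)`.  The illuminant `I`
  defaults to the mean of the unfiltered background
  (`estimate_illuminant()`), with an explicit triplet accepted.  Two
  algebraic identities pin the implementation and are enforced to 1e-10 in
  tests: the general τ formula reproduces `τ_MSD` in the MSD channel, and
  when `u = 0` the whole triplet collapses to the RMC.  The τ numerator /
  denominator reading implemented here is the unique parse of the
  published display that satisfies the MSD self-consistency identity.

Standard deviations are population form (divide by N) by default — the
choice is immaterial at realistic region sizes but must be pinned; a
`sd_type = "sample"` switch exists.  The "unfiltered region" defaults to
the complement of the object mask (`background_mask()`), with an optional
dilation margin to guard against refraction contamination at the object
rim.  `dark_pixel_mask()` implements the exclusion of pixels below 5% of
the maximum object luminance, computed with highlights excluded, since
near-black pixels carry almost no chromatic signal and can distort ratio
and vector-field analyses.  The simpler scaled-RMC variant of the robust
model is deliberately not implemented (it is known to be less robust than
the general version).

## 3. Convergence-model fitting

`build_pairs()` pairs each masked pixel's colour before and after
filtering, in LMS, MB-DKL, CIELAB or linear RGB, optionally projected into
the isoluminant plane (dropping MB-DKL axis 3 or L*; isoluminant fits use
the reduced D = 2 families).  `fit_affine12()` and `fit_affine4()`
minimise the root-mean-squared *Euclidean* colour error — per-component
alternatives differ only monotonically — and report
`RRPE = (RMSE_identity − RMSE_model)/RMSE_identity`.

The default solver is exact least squares (QR; minimum-norm via SVD with a
warning when the unfiltered colours are rank-deficient, e.g. an achromatic
background whose colours lie on the gray line).  A `simplex` fidelity mode
reproduces the historical derivative-free search: Nelder-Mead from seeded
random starts (entries uniform in [−1, 1] around the identity/zero), 5
restarts, relative tolerance 1e-9.  Because the identity transform lies in
every family, closed-form RRPE is always in [0, 1]; the simplex mode can
only approach it from below (enforced over 200 random datasets in the
acceptance suite).  The original search's tolerances and restart policy
are not documented anywhere we could verify, so the fidelity mode makes no
claim of bit-equivalence.

`fit_over()` fits the partial-coverage ("over"-operator) special case
`C_filt = aC_orig + (1−a)C_conv` by re-parameterising the 4-parameter
solution (`β = a`, `C_conv = t/(1−β)`); data that are a pure translation
(`β ≈ 1`) have no finite convergence colour and are flagged
non-representable rather than solved.

`converge_report()` runs the full factorial: {LMS, MB-DKL, CIELAB} ×
{12, 4 parameters} × {full mask, highlights excluded, all specular
excluded} × {full-D, isoluminant} × {dark pixels in/out}, skipping
LMS×isoluminant (declaring a luminance axis in LMS just reconstructs an
opponent space).  Cells fail individually without aborting the table.

A caveat that the tests respect: a map that is affine in linear RGB stays
affine in any *linear* space (LMS, MB-DKL) but not after the CIELAB
cube-root nonlinearity, so "exact affine scene ⇒ RRPE ≈ 1" is asserted
for the linear-space cells only.

## 4. Vector fields and streamlines

`build_field()` turns an image pair into colour vectors (tail = colour
before filtering, tip = after).  Because broad uniform regions map onto
many different filtered colours, the raw field is one-to-many;
`interpolate_field()` regularises it on an `n_per_axis` grid (default 100;
tests use 20 for speed) spanning the bounding box of all tails and tips.
Each grid point averages, component-wise, the vectors whose binning key
falls in a centred box whose side equals the grid step; empty boxes store
the zero vector.  Occupied-cell means are exact (equality to 1e-12 is an
acceptance criterion), and binning never loses samples, so
`sum(cell mean × cell count)` equals the total vector sum at every
resolution.  Whether vectors should be binned by tail, tip or midpoint is
not determined by the method's description; the default is **tail** (the
field is indexed by the pre-filter colour) and the choice is switchable.

`trace_streamlines()` integrates 2-D projections (MB-DKL planes (1,2) and
(2,3) by default) with classical RK4 over bilinear interpolation, from an
8×8 seed lattice, terminating on box exit, stagnation (speed below
1e-6 × the field maximum — for a contracting field this is arrival at the
sink) or a step cap.  Two model-free estimates of the convergence point
complement the fitted one: `affine_fixed_point()` solves `(I−M)p = t`
(flagging singular or non-contracting maps instead of solving them), and
`field_convergence_point()` finds the least-squares crossing point of the
sample lines.  On contracting affine data all three agree within one grid
step (acceptance criterion).

## 5. The synthetic stated world

No stimulus images are publicly available, so the generator recreates the
*statistical structure* of glass-object scenes, not their light transport:

* **Background** — seeded nearest-site Voronoi tessellation (default 40
  sites at 128×128; tests use smaller sizes), each cell carrying a
  reflectance spectrum built from four broadband chromatic bases plus a
  neutral base, clipped to [0, 1]; achromatic, grating and uniform
  variants exist.  Palette biases push the cell distribution toward red,
  green, blue or yellow.
* **Stand-in spectra** — the glass body-colour bases emulate the *nominal
  low-chroma* paint chips used for glass tints (broadband level set by the
  chip's value, modest chromatic bump), while the flat-filter matching
  bases emulate the *saturated* chips of the matching gamut and are
  normalized to max = 1.  Illuminants are broadband blue/yellow
  daylight-locus stand-ins; each scene illuminant is one basis at 70%
  plus 30% of the other, both first halved (`mix_illuminants()`), which
  prevents highlight burn-out and avoids an unrealistically reduced hue
  variance.
* **Object** — a seeded blob (perturbed superellipse) standing in for a
  smooth curved silhouette; arbitrary mask images are accepted everywhere.
* **Filtering** — inside the object, the (refraction-displaced) background
  radiance is multiplied by `transmission^(passes · e(x,y))`.
  `passes = 2` reflects light traversing two walls of a hollow object;
  `e(x,y)` is a smooth seeded exponent field (`body_variation`, default
  ±0.25) standing in for optical-path variation over the curved body.
  Refraction is a smooth random displacement field of stated pixel
  magnitude (default 2), *not* ray optics: its magnitude maps only
  qualitatively onto no/little/default refraction conditions.
* **Effects** — the specular highlight covers `specular_fraction`
  (default 1%, capped at 5%) of the object near its upper right, is
  scaled to 1.5× the maximum background luminance, and is mixed toward
  the body tint by `specular_tint` (default 0.5, because total internal
  reflection tints the inner highlight of hollow glass).  Caustics add
  transmission-tinted illuminant below the object (gain 0.5); shadows
  multiply by `shadow_gain` (0.6).  Every effect region is recorded as a
  ground-truth mask with the invariants highlight ⊂ object and
  caustic/shadow ∩ object = ∅.
* **Determinism** — every generator is a pure function of (spec, seed);
  regeneration is bit-identical, and the caller's RNG state is restored.

What a green test does and does not establish: the generator reproduces
the *qualitative* phenomena — exact affine scenes are recovered perfectly;
nonlinear glass scenes land in an intermediate RRPE regime; excluding the
highlight perturbs the RMC least and the deviation-based statistics most,
reproducing the published sensitivity *ordering* RMC < robust ratio < RSD.
It does not reproduce physically based magnitudes: the synthetic glass is
darker and its highlight relatively brighter than real renders, so the
sensitivity percentages are much larger than the published ones, and no
numeric result of the original study is asserted.  `simulate_affine_scene`
is an oracle, not an emulation: it exists to close the loop with the
fitters.

The flat-filter matching element (`render_flat_filter()`) is a stated
simplification: inside a centred disk (radius defaulting to 0.23 × the
image side) each achromatic background pixel is seen through
`transmission^passes` under the illuminant.  The exact filter equation of
the prior flat-filter literature is external and not reproduced.
`filter_transmission()` implements the mouse-parameterised transmission
`Thickness·((NMX·RF + (1−NMX)·GF) + (NMY·BF + (1−NMY)·YF))`; the
parenthesisation with Thickness multiplying *both* axis mixtures is the
only reading under which circling the mouse sweeps all hues at fixed
transmittance.  `mix_transmission()` implements the 0.5-scaled two-axis
design; its α ∈ [−1, 1] corners are extrapolations that necessarily leave
[0, 1] for any plausible basis pair, which is why the operation clips and
*reports* the clipped fraction (zero on the convex sub-range, enforced in
tests).

## 6. Observer aggregation and pipeline

Observer settings are validated against the display gamut
(components in [0, 1], boundary inclusive) *before* any averaging;
exclusions are counted per stimulus.  Aggregation is two-level — within
observer, then across observers — so the grand mean is the mean of the
observers' means, SEM is computed over observer means, and the (a*, b*)
error ellipse is the eigendecomposition of their covariance scaled to one
SEM.  A stimulus with no surviving records is reported, not fatal.

`run_pipeline()` chains simulate → ratios → converge → field → stats →
diffmap into an artifact directory with a manifest (seed, configuration,
per-stage status and outputs, no timestamps), and is byte-reproducible for
a fixed configuration; stage failures are recorded and dependent stages
skipped.  The CIEDE2000 map colours mask pixels within 15 JND of a
reference and converts the rest to grayscale
`(0.299R + 0.587G + 0.114B)/1.5` — dimmed so residual specular brightness
does not read as colour.

## 7. Known limitations

* No physically based light transport: no true caustic focusing,
  interreflection, or tonemapping; refraction is a displacement field.
* The bundled sensitivity curves and chip spectra are smooth synthetic
  stand-ins; quantitative colorimetry against instruments requires
  supplying measured tabulations.
* CIELAB is used as an approximately uniform space; no chromatic
  adaptation transform or appearance model beyond it is provided.
* The relation between δ and the direct-reflection factor of the
  underlying physical filter model is stated qualitatively in the source
  literature without a formula; no such factor is computed here.
* 8-bit PNG round trips quantize; use the lossless float text format for
  exact interchange.
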