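# glavenstats

Image statistics and convergence-model analysis for the colour of curved
transparent objects.

## The problem

What makes a red glass look red?  For *flat* transparent filters lying on a
textured background, several competing accounts exist of the image quantity
the visual system reads out:

* the **convergence model** — a filter maps the colours it covers toward a
  point in colour space, `b = M a + t` in its general 12-parameter affine
  form, or `b = βa + t` with a single uniform scale β (4 parameters).  A
  fit is scored by the relative reduction in prediction error,
  `RRPE = (RMSE_identity − RMSE_model) / RMSE_identity`;
* the **RMC** — the ratio of mean cone excitations between the filtered and
  unfiltered regions, one ratio per cone class `[τ_L, τ_M, τ_S]`;
* the **RSD** — the same ratio computed on standard deviations;
* the **robust ratio model** — an estimator of the filter colour code τ
  that corrects the mean ratio for illuminant and direct-reflection
  contributions: with `P` the filtered colours, `A` the background colours
  and `I` the illuminant estimate, the cone class with the largest
  background deviation (MSD) gives
  `τ_MSD = sd(P)/sd(A)`, `u = mean(P) − τ_MSD·mean(A)`,
  `v = (τ_MSD + u)·I_MSD`, `δ = u/v`, and then
  `τ_i = (mean(P_i) − u·δ·I_i) / (mean(A_i) + δ·I_i)` for all classes.

Curved glass adds specular highlights, caustics, shadows, refraction and
thickness-dependent filtering, none of which the flat-filter theory covers.
This package implements the full analysis tool-chain needed to ask how far
each account generalizes: calibrated colour-space conversions (linear RGB,
XYZ, CIELAB, LMS cone excitations, MB-DKL opponent coordinates, CIEDE2000
differences), the region statistics above with mask-exclusion variants,
affine/"over" model fitting, colour vector-field interpolation with
streamline tracing, bespoke per-object colour summaries (mean, White Point,
most saturated, most frequent, CIEDE2000 threshold maps), observer-match
aggregation, and — because the original rendered stimuli are not publicly
deposited — a seeded synthetic-scene generator that emulates the
statistical structure of glass-object stimuli with ground-truth masks.

It is intended for colour/material-perception researchers who want to run
these analyses on their own image pairs, and for anyone who needs a tested
reference implementation of the statistics themselves.

## Worked example

```r
library(glavenstats)
cal   <- default_monitor()                        # synthetic calibrated display
spec  <- scene_spec(size = 96L, n_sites = 30L, seed = 7L)
scene <- simulate_glass_scene(spec, cal = cal)    # glass blob in a Voronoi room
scene
#> <synthetic_scene 96x96: object 2632 px, highlight 26, caustic 423, shadow 425>

lms <- convert_space(scene$filtered, "LMS", cal)
obj <- scene$masks$object
bg  <- background_mask(obj)

rmc(lms, obj, bg)
#> <RMC: L 0.03899, M 0.04128, S 0.0553>
rsd(lms, obj, bg)
#> <RSD: L 0.6784, M 0.6947, S 0.787>
robust_ratio(lms, obj, bg)
#> <robust_ratio: tau = (0.7088, 0.6947, 0.6086), u -0.1328, delta -1.163, MSD M>

pairs <- build_pairs(scene$unfiltered, scene$filtered, obj,
                     space = "MBDKL", cal = cal)
fit_affine12(pairs)
#> <affine_fit affine12 (MBDKL, D=3, n=2632): RMSE 0.1336 vs identity 0.7085, RRPE 0.8115>
fit_affine4(pairs)
#> <affine_fit affine4 (MBDKL, D=3, n=2632): RMSE 0.1338 vs identity 0.7085, RRPE 0.8111>
affine_fixed_point(fit_affine4(pairs))$point
#> [1]  0.0122  0.4406 -0.8770
```

Reading the numbers: this glass transmits only a few percent of the mean
cone excitation (RMC ≈ 0.04–0.06) but preserves most of the background's
*variation* (RSD ≈ 0.7–0.8); the robust ratio's τ corrects the mean ratio
toward the deviation-based code.  The affine convergence model removes 81%
of the prediction error relative to leaving the colours untouched
(RRPE 0.81) — substantial convergence, but the nonlinearities contributed
by the highlight, caustics and refraction keep it well below the
near-perfect fits that exact affine data produce.  The 4-parameter model
does essentially as well as the 12-parameter one, and its fixed point is
the colour toward which the glass drags the scene (here: darker and
blue-shifted in MB-DKL coordinates).

Per-object colour summaries and difference maps operate on the CIELAB
conversion:

```r
lab <- convert_space(scene$filtered, "LAB", cal)
mean_lab_color(lab, obj)
#> <summary_color mean: L* 5.172, a* -0.754, b* -5.704 (n = 2632)>
white_point(lab, obj, scene$masks$highlight)
#> <summary_color white_point: L* 11.577, a* -1.096, b* -8.554 (n = 131)>
```

A command-line front end covering the main stages lives at
`inst/cli/glavenstats.R` (`Rscript <path> ratios --image scene.png --mask
obj.png --stat rmc`, plus `simulate`, `stats`, `converge`, `field`,
`diffmap`, `aggregate`, `run`), and `run_pipeline()` executes the whole
chain into an artifact directory with a reproducibility manifest.

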