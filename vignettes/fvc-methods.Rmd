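---
title: "Simulating fixed-virtual-cone radiosurgery dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fixed-virtual-cone radiosurgery dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvcdose)
```

## The technique being modelled

Stereotactic radiosurgery of trigeminal neuralgia delivers 70–80 Gy in a
single fraction to a few-millimetre segment of the trigeminal nerve,
classically with a 4–5 mm physical cone. The *fixed virtual cone* (fVC)
replaces the cone with the smallest symmetric HDMLC aperture — 0.5 cm × 0.5 cm
defined by the two central leaf pairs at 100 cm SAD, backup jaws at
1.5 cm × 1.5 cm — swept over 10–14 non-coplanar partial arcs. Monitor units
per degree of arc are proportional to the sine of the gantry angle measured
from the vertical; with couch angles spread over a half turn this weighting
tends, in the many-arc limit, to a uniform fluence per unit solid angle,
which is what makes the composite dose distribution spherical.

`fvcdose` is a desk-scale simulator of that technique plus its
quality-assurance battery: an analytic beam model standing in for the
commissioned treatment-planning system, a plan generator, a voxelized dose
engine in a water phantom, the dosimetric metrics used for small fields
(FWHM, equivalent square field size $S_{clin}=\sqrt{FWHM_X\,FWHM_Y}$,
isodose equivalent diameters $d=\sqrt{d_1 d_2}$), a global gamma-index
comparison, and a synthetic diode-array measurement generator. No hardware,
planning system or Monte Carlo engine is required; conversely, nothing here
is a commissioned clinical model — it is a physically structured surrogate
calibrated to published commissioning observables.

## The analytic beam model

Fluence at the isocenter plane is a separable product of error-function edge
profiles between the *effective* field edges, with a transmission floor
inside the jaws and a lower floor outside:

$$F(x,y) = t_{MLC} + (1-t_{MLC})\,P_X(x)\,P_Y(y), \qquad
P(x) = \Phi\!\left(\tfrac{e_2-x}{\sigma}\right)-\Phi\!\left(\tfrac{e_1-x}{\sigma}\right).$$

The effective edges push the geometric leaf positions outward: by
`leaf_end_offset` on the leaf-travel axis (X), standing in for the rounded
leaf tips (the dosimetric-leaf-gap effect), and by a smaller
`leaf_side_offset` on Y. Distinct offsets keep the X profile wider than the
Y profile at the 50% level, as observed clinically, while letting the
single-field $S_{clin}$ land in the published per-energy ranges. A subtlety
worth recording: at a 5 mm width the two erf edges overlap at clinical
penumbra sigmas (1.4–1.6 mm), so the profile peak falls below 1 and the
FWHM exceeds the effective width — the FWHM equals the effective aperture
width only in the small-sigma limit, which is how the unit tests probe the
edge geometry. The same overlap is why the central fluence of the nominal
field is ~0.87, not ~1; the dose calibration absorbs this factor.

Point dose from a control point is the standard SAD-geometry factorization

$$D = MU \cdot k_{cal}\cdot OF(S_{eff}) \cdot TMR(d) \cdot
F\!\left(x\tfrac{SAD}{z}, y\tfrac{SAD}{z}\right)\cdot\left(\tfrac{SAD}{z}\right)^2,$$

with radiological depth $d$ and source distance $z$ from ray tracing.
$k_{cal}$ is fixed per preset so 1 MU of the nominal field at the 95 cm SSD /
5 cm depth reference deposits the preset's calibration dose per MU (0.547
cGy for 10 MV FFF, 0.558 for 6 MV FFF). The TMR tables place knots at 50 and
100 mm whose ratio equals the published dose-per-MU ratio between the two
clinical settings, so both settings are reproduced exactly; between knots a
monotone cubic interpolates, beyond the peak the shape is exponential.
Output-factor tables (one per clinical setting) are indexed by the effective
equivalent-square size $\sqrt{w_{x,eff}\,w_{y,eff}}$ and anchored at the
published nominal-field values (0.550/0.510 for 10 MV FFF, 0.605/0.560 for
6 MV FFF); the 6 MV FFF table falls off more steeply at small sizes, which
encodes the observation that the 10 MV FFF beam delivers the more stable
output under leaf-position errors. These tables and the edge offsets are
calibration constants of this package, not published data.

There is no explicit scatter-kernel convolution: every acceptance observable
here is a near-axis, small-field quantity, and phantom scatter is folded
into the OF/TMR/penumbra calibration. That is the main respect in which the
model is *not* a dose algorithm — off-axis, large-field or heterogeneous
configurations are outside its validity.

## Plan generation and arc weighting

`sine_weights()` discretizes an arc into gantry bins (default 2°, which
keeps voxel doses within 1% of the 1° result) and integrates $|\sin\theta|$
exactly over each bin, so plan MU is conserved to machine precision for any
spacing and the weighting is invariant under arc reversal. The reference
axis of the sine is the vertical: vertex beams get zero dose per degree,
which is the choice under which the couch-spread uniform-fluence limit
actually holds (verified numerically: 72 ideal full arcs give a direction
density CV of 0.03 over equal-area sphere bins).

`default_tgn_plan()` emulates a clinical arc ensemble: couch angles spread
over ±85° with a small seeded jitter, arc spans of 30–38° crossing gantry 0
on alternating sides (anterior "vertex" arcs — posterior delivery through
the couch, and through the posteriorly located brainstem, is avoided),
collimator angles cycled over 0–90°, alternating rotation sense. Arcs keep a
minimum gantry magnitude of ~9° so that no two control-point beam directions
come within 0.5° of each other. The published clinical couch/gantry sets are
not available; these defaults were chosen from the geometry of the
technique, and they reproduce the published coronal 50% isodose equivalent
diameter (6.1 ± 0.7 mm) and the anterior–posterior dose spill. Wider, more
oblique ensembles (spans toward 90° centred laterally) inflate the coronal
50% diameter towards ~7 mm; users probing that regime can pass their own arc
table to `fvc_plan()`.

## Dose grid and metrics

`compute_dose()` superposes the point-dose model over all control points on
a 1 mm isotropic grid (the clinical grid size); plans are normalized so the
maximum voxel equals the prescription — where the prescription is defined is
not published, and max-dose normalization is the documented, configurable
default. The default analysis grid is 81 × 81 × 61 mm so that the coronal
plane covers the 77 mm detector array; the acceptance analyses run at this
size in a few minutes on one core.

`isodose_geometry()` extracts the level contour of the planar maximum with
marching squares (`grDevices::contourLines`), rejects contours touching the
map edge, and measures caliper widths in 72 directions (2.5° steps — enough
for sub-0.05 mm diameter accuracy on mm-scale contours). `fwhm()`
interpolates the two half-maximum crossings linearly; profiles that do not
fall below half maximum on both sides are an error, not a guess.

`percent_difference()` uses the symmetric (relative-to-mean) convention,
$200\,(m-c)/(m+c)$: it is the only convention that reproduces the published
calculated-vs-measured table cells (2.45, 3.35, 1.42, 0.98, 2.56) at two
decimals. Three further printed cells (1.30, 1.10, 1.85) are not
reproducible under any single convention and are excluded from testing.

## Gamma comparison

`gamma_map()` implements the global gamma index with normalization to the
reference maximum and a low-dose threshold (defaults 3%/1 mm field-by-field,
2%/1 mm cumulative, 10% threshold). For each scored reference point the
minimization over evaluated positions runs on a bilinear lattice at
0.04 × DTA spacing within the *exact* pruning radius DTA × γ(zero offset) —
no candidate farther away can beat the zero-offset value through its
distance term alone — followed by a 0.02 × DTA refinement around the best
node and around zero offset. `gamma_oracle()` is the single-stage dense
(0.02 mm) reference implementation; the two agree within 0.003 γ on the
50-pair random-map suite, and the map's candidate lattice is constructed as
a subset of the oracle's so the fast path can never undercut it. A
vanishing DTA degrades gracefully to a pure dose comparison.

## The synthetic measurement

`sample_measurement()` emulates a stereotactic diode array: Gaussian
pre-blur (`widening_sigma`, 0.3 mm by default — calibrated so the measured
single-field $S_{clin}$ comes out ~0.27 mm wider than calculated, matching
the published measured-vs-calculated gap), optional sub-mm registration
offset, bilinear resampling at a 2.47 mm lattice over 77 × 77 mm, and
multiplicative Gaussian noise (1% — the published work quotes no noise
figure; 1% puts the cumulative 2%/1 mm passing rates in the published
≥ 97% regime). Detector counts are odd so one diode sits exactly on the
beam axis, as in the physical array; this matters, because with the peak
falling between diodes no evaluated position can reproduce the reference
maximum and the cumulative gamma saturates around 91% no matter how small
the noise. The widening blur trims about 1% from the axis reading of a
single field (the erf-model field top is rounded, not flat).

What the generator does *not* model: angular and field-size dependence of
diode response, volume averaging (0.48 mm diodes, an order of magnitude
below pitch and penumbra), film dosimetry, and setup errors beyond a rigid
in-plane offset. Passing synthetic QA therefore demonstrates the internal
consistency of the pipeline under the stated noise model, not detector
physics.

## Numerical choices and degenerate inputs

* Angles are stored in degrees and converted once; couch angles outside
  [−90°, 90°] after wrapping are rejected.
* Points at the source plane (`z_along = 0`), rays missing the phantom,
  apertures closed by a negative leaf shift, open isodose contours, zero
  reference maxima and non-overlapping gamma maps all raise errors rather
  than returning sentinels.
* Output-factor and TMR interpolation is monotone cubic (Fritsch–Carlson),
  clamped at the table ends (with a warning for output-factor
  extrapolation).
* Below-threshold gamma points carry `NA`, never 0, and are excluded from
  the passing rate.

## Reproducibility and problem sizes

Every stochastic step (plan jitter, measurement noise) is seeded;
`run_viability_report()` writes the seed and a configuration hash into every
output header and regenerates byte-identical CSVs from the same seed. The
shipped analyses use a 12-arc plan on a 400k-voxel grid, 10 measurement
seeds for the cumulative gamma, and 50 seeded 21 × 21 map pairs for the
gamma-oracle cross-check; these sizes were chosen so the whole battery runs
in minutes on a single core while leaving the headline quantities
seed-stable (the 50% equivalent diameter varies by < 0.03 mm across plan
seeds).

## Known limitations

Water phantom only; primary-beam analytic model without explicit scatter or
electron transport; no tongue-and-groove, interleaf leakage or head-scatter
source modelling; no DVH/conformity metrics; planar (not volumetric) isodose
analysis, matching the published coronal-plane reporting; no DICOM-RT
import/export. The 90% isodose equivalent diameter of the simulated plan
(~2.7 mm) runs larger than the published 1.95 ± 0.30 mm — the analytic dome
is flatter near the maximum than the clinical one — and is reported but not
used as a validation anchor.
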