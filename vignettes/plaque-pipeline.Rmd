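---
title: "Quantifying amyloid plaque burden, immunoassay limits and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid plaque burden, immunoassay limits and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquetools)
```

plaquetools implements the quantitative core of a longitudinal
mouse-model amyloid study: brightfield immunohistochemistry (IHC) image
analysis for DAB-stained amyloid-beta plaques, plate-based immunoassay
calibration with detection/quantification limits, and the nonparametric
statistics used to compare small per-genotype cohorts. Every input can be
produced by the built-in synthetic-data module with known ground truth, so
the whole chain is testable end to end without animal material.

## Stain model

Transmitted-light microscopy obeys the Beer-Lambert relation: for channel
intensity $I$ against a blank-glass reference $I_0$, the optical density
$D = -\ln(I/I_0)$ is linear in the amount of absorbing chromogen. Stain
amounts are therefore separated in density space, not in RGB space — this
is the density axis of the hue-saturation-density (HSD) colour model for
transmitted light, and the reason the pipeline's thresholds are expressed
in absorbance units (au, natural log).

`rgb_to_density()` applies the transform per channel, clipping intensities
to $[1, I_0]$ first so an 8-bit zero cannot produce an infinite density.
`unmix_stains()` then solves, per pixel, the least-squares decomposition of
the 3-channel density vector onto two reference unit vectors: DAB (brown,
default $(0.269, 0.568, 0.778)$ normalised) and hematoxylin (blue,
$(0.650, 0.704, 0.286)$). Negative coefficients are clamped to zero and
the Brown+ve raster is defined as brown minus blue *after* clamping, so
`brown_pos_au == brown_au - blue_au` holds exactly by construction.

Two points deserve emphasis:

* The reference vectors are configuration, not constants of nature. Stain
  lots and scanners differ; `stain_reference()` exposes both vectors and a
  calibrated deployment should measure them from single-stain controls.
* Projection-based unmixing carries the same information as HSD
  chromatic-plane classification for a two-stain slide, and is fully
  deterministic; whether the original rule set classified in the chromatic
  plane or by projection is not recoverable from its published
  description, so the choice here is documented rather than asserted.

## Working resolutions

Scans are taken at a nominal x40 objective; tissue detection runs on a
x10-equivalent raster and stain detection on a x20-equivalent raster.
"Equivalent" is implemented as deterministic block-mean downsampling by
the integer magnification ratio (factors 4 and 2), which is alias-free for
factor-of-two steps and keeps every au threshold meaningful: a block mean
of densities approximates the density of the average intensity well at
these factors. The tissue mask is carried to the stain grid by
nearest-neighbour upsampling. Areas are always reported in
$\mu m^2$ via $|{\rm pixels}| \cdot ({\rm mpp} \cdot {\rm factor})^2$, so
results are invariant to the working grid for objects large relative to a
pixel.

## Tissue detection

The grey raster is the per-pixel minimum over R, G and B (the darkest
layer). The threshold is dynamic: the 95th percentile of the grey values —
the level separating the brightest 5% of the area — adjusted by $-10$ grey
levels on the 256-level scale, and pixels strictly below it are tissue.
The offset exists because unstained but non-glass area is slightly darker
than glass; without it the mask leaks into the background. Whether the
tissue mask should constrain stain detection is not stated in the source
description; this implementation does mask (pixels outside tissue are
forced to class `none`), because the tissue step exists to exclude glass
from "further analysis" and unmasked glass edges otherwise produce
spurious brown at coverslip boundaries. This is recorded as an assumption.

## Plaque segmentation

Brown classification uses three printed thresholds with their printed
inequality directions: a pixel is brown when `brown_au > 0.15` **and**
`brown_pos_au > 0.1` (both strict); brown pixels split into light
(`< 0.5`) and dark (`>= 0.5`, inclusive on the dark side). Candidates are
grown from every connected dark component (8-connected by default, as
region growing in object-based image analysis is neighbourhood-inclusive;
the connectivity is a parameter): each light component adjacent to a seed
is attached to it, a light component touching several seeds merges them
into one object, and light with no adjacent seed is discarded.

Accepted plaques must survive five removal rules, any one of which
rejects:

| rule | fires when | flag |
|------|-----------------------------|------|
| a | area $< 10\ \mu m^2$ | `min_area` |
| b | dark area $< 1.5\ \mu m^2$ | `min_dark_area` |
| c | mean brown $> 0.5$ au **and** SD $< 0.25$ au | `uniform_dark` |
| d | area $< 40\ \mu m^2$ and elliptic fit $< 0.65$ | `non_elliptical` |
| e | area $> 40\ \mu m^2$ and dark fraction $> 70\%$ | `dark_fraction` |

An object of exactly 40 $\mu m^2$ is subject to neither (d) nor (e) — the
rules are printed as strict "less than"/"greater than" and are implemented
that way. Rule (c)'s "stain intensity" is read as the mean brown density
over the object and its "standard deviation" as the population SD of the
same values; these are the only per-object stain statistics the rule set
refers to, but the reading is an interpretation. Rejected candidates carry
the full set of violated rules, which is what makes artifact-by-artifact
validation possible.

### Elliptic fit

The shape score compares the object with the ellipse sharing its
centroid, second-moment orientation and axis ratio, scaled to the
object's pixel count; the score is the intersection-over-union of the two
pixel sets. Two degenerate conventions matter. A single pixel scores 1. A
collinear set (minor-axis variance numerically zero) scores 0: the
moments define no finite-axis-ratio ellipse. Deliberately, no pixel-extent
(+1/12) term is added to the central moments — with that term a one-pixel-
wide line acquires a thin but valid moment ellipse that overlaps it almost
perfectly (IoU near 0.87 by direct computation), and thin streak
artifacts, which the shape rule exists to remove, would pass it. The 0.65
cutoff itself is a configurable default: the source rule set names a
"non-elliptical shape" without publishing its metric or threshold.

## Quantification

A plaque belongs to a region when its centroid lies inside the polygon
(boundary inclusive). The centroid rule, rather than any-overlap, makes
counts additive over a partition of the section, which is what a
per-region export implies; a boundary-straddling plaque contributes its
full area to exactly one region. Coverage percentages divide by tissue
area inside the region (not polygon area), so glass within a generous
annotation cannot dilute the burden.

## Immunoassay calibration

Standards follow a four-parameter logistic,
$y = d + (a - d) / (1 + (x/c)^b)$, with $a$ the zero-dose asymptote, $d$
the saturating asymptote, $c$ the inflection concentration and $b$ the
slope — the standard model of the plate-reader software families this
replaces. Fitting is Levenberg-Marquardt least squares with deterministic
data-driven initialisation ($a$ = smallest per-concentration mean signal,
$d$ = largest, $c$ = geometric mid concentration, $b = 1$). Optional
$1/y$ or $1/y^2$ weighting is available; the default is unweighted.
Under multiplicative (constant-CV) noise the $1/y^2$ weights are the
statistically matched choice, and the package's own recovery validation
uses them: with duplicate twelve-point 1:3 standards at 1% CV, all four
parameters return within a few percent, whereas the unweighted fit leaves
the zero-dose asymptote poorly determined because residuals at the top of
the curve dominate the objective. Back-interpolation uses the closed-form
inverse; signals at or beyond the asymptotes are censored (`below`/
`above` range) and never extrapolated — censoring is one-way and no
censored well ever receives a numeric estimate. Note that
back-interpolation becomes ill-conditioned near the upper asymptote, so
samples should be diluted into the dynamic range.

Limits follow the fixed published rules. The limit of detection is the
blank mean plus 2.5 sample SDs of the blank signals, back-interpolated to
concentration; a configuration switch (`lod_add_blank_mean = FALSE`)
reproduces the bare 2.5-SD form, which is the literal printed formula but
lands below the blank signal itself whenever blanks are nonzero. The
lower limit of quantification is the lowest standard passing all of:
back-interpolation within 100 +/- 20% of nominal, replicate CV at most
20%, and mean signal above the blank mean plus 9 blank SDs. The printed
form of that third clause compares the blank mean with itself; the
reading implemented here — the *standard's* mean signal must clear the
blank gate — is the only non-vacuous one, and is flagged prominently
because it is an interpretation. Sample SDs (n-1) are used throughout, as
duplicates are the norm.

## Group statistics

`kruskal_dunn()` computes the tie-corrected Kruskal-Wallis statistic on
midranks with the chi-square reference ($k-1$ df), then Dunn's pairwise
$z$ statistics from mean ranks and the tie-corrected variance, Bonferroni-
adjusted over the *requested* comparison set. Comparison sets are explicit
inputs because studies of this design test selected contrasts (each
transgenic line against its own control and against its receptor-null
counterpart), not all pairs; adjusting over all pairs would overcorrect.
When every pooled observation is tied the tie-correction denominator
vanishes; the convention here is $H = 0$, $p = 1$ rather than an error.

`spearman_exact()` addresses correlations at n = 4-5 animals, where
asymptotic p-values are meaningless. For untied data with $n \le 10$ the
p-value is exact: the fraction of all $n!$ rank permutations whose
correlation is at least as extreme as observed, in the direction of the
observed sign (enumerated in compiled code; the statistic is monotone in
the sum of squared rank differences, so the tail is a count over that
integer). One-sided reporting is the default: at these sample sizes the
published two-decimal p-values for coefficients 0.9 (n = 5) and -0.8
(n = 4) equal the one-sided enumeration fractions 5/120 and 4/24 — the
two-sided values would be twice those — so one-sided is the reading
consistent with practice; a `two_sided` flag enumerates both tails of
$|\rho|$. Ties fall back to the t approximation with a warning.

## The synthetic-data module

`simulate_slide()` inverts the stain model: per pixel, total density is
hematoxylin times the blue vector plus the local DAB load times the brown
vector (plus optional Gaussian density noise), exponentiated to intensity
and quantised to 8 bits; glass outside the tissue polygon sits at the
reference intensity with +/-1 grey-level jitter. Plaques are discs — a
dark core (0.8 au) inside a lighter halo — optionally perturbed by a
low-order radial wobble to exercise the shape score. Five artifact types
are built to violate exactly one removal rule each: a sub-10 $\mu m^2$
speck, a pale blob with under 1.5 $\mu m^2$ of dark core, a uniformly
dark mid-size blob, a thin 30 $\mu m$ streak, and a large mottled blob
with over 70% dark area whose dark values alternate between 0.55 and
1.35 au precisely so that its SD stays above 0.25 au and only the
dark-fraction rule fires.

Two rendering decisions keep ground truth exact. Noise is added in
density space, so au thresholds translate directly into detection
margins. And object boundaries are anti-aliased: an edge pixel carries
density in proportion to its geometric coverage (linear one-pixel ramp),
with the ground-truth footprint defined as the fractional coverage sum.
Binary centre-in/out rendering would quantise the 2x2-block coverage seen
by stain detection to quarters, and the inclusion threshold then falls
between quantisation levels, biasing measured area by about +/-3%
whichever side it lands on; with anti-aliasing the blended coverage is
continuous, and the default halo density (0.40 au) against the default
hematoxylin background (0.08 au) places the effective inclusion boundary
at ~50% coverage — computed through the intensity-space block mean and
the unmixing — so discretisation is area-unbiased (residual bias under
0.5%). Artifacts are instead drawn in blocks aligned to the even-pixel
grid, so they survive the 2x downsampling with crisp edges and exact
statistics.

The canonical validation fixtures are regenerated from code:
`clean_section_spec()` (a 4000 x 4000 px section at 0.5 $\mu m$/px with
200 detectable plaques and 50 artifacts, ten per type, on a jittered
80 $\mu m$ grid), `null_section_spec()` (tissue and glass only), and
`boundary_case_candidates()` (objects sitting exactly on each rule
boundary: 10 and 40 $\mu m^2$, 1.5 $\mu m^2$ dark, 70% dark fraction,
0.5/0.25 au mean/SD). Clean-section radii (core 2-2.8 $\mu m$, halo
7-11 $\mu m$) keep every plaque's mean brown density below the 0.5 au
uniform-dark rule with margin.

What the generator does **not** emulate: histological texture, optics and
point-spread, scanner compression, stain-intensity drift between slides,
and anatomically realistic plaque morphology. Passing the end-to-end
recovery tests therefore demonstrates that the measurement chain is
correct and unbiased for objects obeying its own optical model — it does
not validate performance on real tissue, where stain calibration and the
configurable thresholds carry the burden.

`simulate_plate()` renders signals as $4PL(x)(1+\varepsilon)$ with
$\varepsilon \sim N(0, {\rm CV}/100)$ truncated at $-0.99$, blanks at the
zero-dose asymptote under the same noise, twelve 1:3 standards in
duplicate by default (a 1:2 series bottoms out at $x/c \approx 0.02$,
too far from zero dose to pin the lower asymptote).
`simulate_groups()` draws lognormal (or normal) samples whose population
median equals the requested median exactly. All generators are pure
functions of (spec, seed).

## Numerical conventions

* Percentiles and quartiles: R's default type-7 (linear interpolation);
  medians use the midpoint convention for even n.
* SDs: population SD for per-object stain statistics (a descriptive
  moment of a fixed pixel set); sample SD (n-1) for assay replicates and
  blanks (an estimate from few wells).
* Intensities are clipped to $[1, I_0]$ before the log; densities are
  clamped non-negative after unmixing.
* Coordinates are 0-based pixel indices, x right / y down, with polygons
  in scan-grid pixel space and the calibration (microns per pixel)
  carried separately. Downsampled-grid centroids map back to scan
  coordinates at block centres.
* Duplicate region names are suffixed `#2`, `#3`, ... deterministically
  in feature order.

## Problem sizes used by the validation suite

The test suite exercises: the full 4000 x 4000 px clean section once;
800 px sections for quantification properties; 1000 randomised candidate
objects against an independently coded five-predicate oracle; 100
simulated plates for 4PL recovery; a 10,000-permutation Kruskal-Wallis
reference on 3 x 5 shifted groups; and 2000 null simulations for the
exact-Spearman calibration check, whose achievable level at n = 5 is
5/120. These sizes were chosen so the whole suite completes in a few
minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* Two-stain unmixing only; no adaptive per-slide stain estimation or
  inter-slide colour normalisation.
* No pyramidal whole-slide formats; inputs are flat 8-bit TIFF/PNG.
* The segmentation is faithful to a printed rule description; where that
  description is silent (elliptic-fit metric, tissue masking of stain
  detection, boundary handling at region edges) the choices above are
  defaults, not claims about the original software's internals.
* Exact Spearman enumeration is limited to $n \le 10$ untied
  observations; ties use the t approximation.
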