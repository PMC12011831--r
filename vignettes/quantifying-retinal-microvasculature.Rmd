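---
title: "Quantifying retinal microvasculature from en-face OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal microvasculature from en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octavasc)
```

# The problem

Optical coherence tomography angiography (OCTA) images retinal blood flow
without dye by detecting motion contrast. In diabetic retinopathy (DR) the
superficial capillary plexus drops out progressively, and en-face OCTA of
the peripapillary retina and macula makes that loss measurable long before
it is visible on fundus examination. `octavasc` implements the measurement
chain: a flow image goes in; a binary capillary map, skeleton and perimeter
map come out; six scalar vessel parameters are computed per region of
interest; and cohort-level statistics relate them to structural OCT
thickness, visual acuity and blood biomarkers.

Because patient images and health-record extracts cannot be redistributed,
the package carries a first-class synthetic-data module: procedural vessel
phantoms with exact ground-truth masks, and grade-conditional cohorts whose
marginal distributions are the published per-grade means and standard
deviations. Every stage of the pipeline is exercised against those
synthetic inputs.

# Region-of-interest geometry

Scans are square fields of view, by default 3 mm on a side, with physical
coordinates attached by `image_grid()`. Conventions, chosen once and used
everywhere:

* image row 1 is anatomically superior; x increases to the right, y upward;
* the physical origin is the image centre, and scan centres default there
  (disc and macular scans are acquired centred); an explicit centre is
  accepted;
* distances are measured from pixel centres, and annulus membership is the
  half-open interval `inner_radius <= d < outer_radius`, so concentric
  rings and sector partitions are exactly disjoint.

The standard ROIs are annuli of outer diameter 1.375 mm with inner
diameter 0.5 mm at the disc and 0.75 mm at the macula (the inner disc
excludes the neural rim / foveal avascular zone respectively). The disc
annulus is partitioned into four 90-degree quadrants with boundaries on the
45-degree diagonals — superior is [45, 135) with 90 degrees at the image
top — matching the usual RNFL quadrant convention; the macular annulus is
split into six 60-degree sectors, three per hemifield (S, SN, ST / I, IN,
IT). Neither partition's angular bounds are dictated by the imaging device,
so both are configuration, not hard-coded truth. Nasal/temporal labels flip
with laterality (`OD` puts the nasal retina on the image right), and
`flip_laterality()` is an involution — a property the tests assert.

The outer diameter of 1.375 mm is small relative to a typical optic disc;
it is implemented exactly as published, and every diameter is a plain
argument, so a user who prefers a wider annulus changes one number.

# From flow image to vessel maps

`segment_vessels()` runs four steps, each available separately.

**Vesselness enhancement** (`enhance_vessels()`). A Frangi-type multiscale
Hessian filter for bright curvilinear structures: at each scale *s* (default
1, 2, 3 px, matching capillary radii at ~6 um/px) the image is convolved
with gamma-normalised Gaussian second-derivative kernels (the kernels are
projected to zero DC so a flat field yields an exactly zero response), the
Hessian eigenvalues are ordered by magnitude, and the response is
`exp(-Rb^2/2b^2) * (1 - exp(-S^2/2c^2))` for pixels with a negative
principal curvature, with blob discrimination `b = 0.5` and `c` set
adaptively to half the maximal Frobenius norm per scale. The per-pixel
maximum over scales is rescaled to [0, 1].

**Binarization** (`binarize()`). Default is a global Otsu threshold; a
fixed level is available when reproducibility across images matters more
than per-image adaptation. By default the pipeline takes the *union* of the
Otsu mask of the enhanced image and the Otsu mask of the raw intensities
(`combine_raw = TRUE`): vesselness alone under-segments the interior of
vessels much wider than the probed scales (the plateau has no tubular
curvature), while raw thresholding alone is noise-prone for faint
capillaries. The union keeps both regimes and is what the phantom-recovery
tests exercise.

**Large-vessel removal** (`remove_large_vessels()`). Capillary metrics must
not be dominated by the major arcades, so connected structures wider than a
cutoff (default 6 px, about 60 um at 10 um/px — arteriole scale) are split
off: morphological opening with a disc of the cutoff diameter finds their
cores, and a short geodesic reconstruction (2 dilation steps) inside the
mask recovers the boundary pixels the opening eroded. The reconstruction is
deliberately *not* run to convergence: a full geodesic reconstruction would
flood through junctions and swallow every side branch connected to a trunk.
The capillary and large-vessel masks are disjoint and union to the input,
which is asserted property-style on random masks.

**Skeleton and perimeter.** `skeletonize_mask()` is Guo–Hall parallel
thinning: only simple points are deleted, so the number of 8-connected
components is preserved, and the result is one pixel wide. Rare "locked"
2x2 blocks whose pixels are all locally non-simple are resolved by an exact
global component-count check before a pixel is removed. `perimeter_map()`
marks foreground pixels with at least one 4-neighbour outside the mask
(out-of-image counts as background).

# The six vessel parameters

Within an ROI mask *R*, with `V`, `S`, `P` the vessel, skeleton and
perimeter pixel counts inside *R*:

| metric | definition | reading |
|---|---|---|
| VAD | `V / |R|` | fraction of the region occupied by vessels |
| VSD | `S / |R|` | vessel length density (one pixel per centreline) |
| VDI | `V / S` | mean vessel calibre in pixels |
| VPI | `P / |R|` | boundary density |
| VCI | `P^2 / (4 pi V)` | isoperimetric shape complexity |
| flux | mean flow intensity over `vessel AND R` | perfusion proxy |

Degenerate regions are flagged, not silently zeroed: VDI is undefined when
the skeleton is empty, VCI and flux when there are no vessel pixels.
Because the skeleton and perimeter are subsets of the vessel mask and all
three are normalised by the same ROI area, `VSD <= VAD` and `VPI <= VAD`
hold identically — both are asserted on every quantified image in the test
suite.

Two published verbal definitions could not be implemented literally. The
diameter index is described circularly ("VSD divided by VSD"); it is
implemented as vessel pixels per skeleton pixel, the only reading that *is*
an average diameter. The complexity index is described as a perimeter/area
ratio; the package uses the isoperimetric form `P^2/(4 pi V)`, the standard
dimensionless complexity measure consistent with its use as a tortuosity
index (a raster disc scores ~0.8–1, any branching network scores far
higher). The literal ratio is available via `quant_config(literal_vci =
TRUE)`. Flux is the mean normalised flow intensity over capillary pixels —
an en-face image carries no per-erythrocyte information, so per-pixel decorrelation
intensity is the only available perfusion proxy, and this is documented
rather than hidden. One further silent choice is made explicit here: large
vessels are excluded from *all six* metrics including flux; every reported
number is a capillary-bed number.

Scan quality gates everything: `qc_filter()` passes an image only when its
device signal-strength index strictly exceeds 7, so an SSI of exactly 7
fails.

# Clinical metrics

Snellen acuities convert to LogMAR as `-log10(numerator/denominator)`
(20/20 = 0.0, 20/200 = 1.0). Low-vision codes get the conventional imputed
values CF 1.9, HM 2.3, LP 2.7, NLP 3.0 and are flagged `imputed`. The
default chart runs 20/10 through 20/400 plus the four codes and is an
argument everywhere it is used; acuities off the chart map to the nearest
line and carry a `nearest_line` flag. Stability over follow-up is the
two-line rule: fewer than two chart lines of change is stable, two or more
is worsened (or improved, symmetrically — the classifier is antisymmetric
under swapping the visits). Reporting bins are 20/20–20/30, 20/40–20/60,
20/70–20/100, and 20/200-or-worse.

Blood panels are standardised per analyte against the control group:
`z = (x - mean_ctrl)/sd_ctrl`, so control z-scores have mean 0 and sd 1 by
construction; analytes with fewer than two control values or zero control
spread are excluded and listed, never silently dropped.

# Statistical battery

* **Mann-Whitney U** — exact two-sided p by full enumeration of
  `choose(n, n_a)` rank assignments when total n is at most 12 (valid under
  ties, which is why it is hand-written); otherwise the tie-corrected
  normal approximation without continuity correction via `wilcox.test`.
  The exact path reproduces `wilcox.test`'s exact p to machine precision in
  the tie-free case. Note the exact two-sided p at n = 6 + 6 is discrete
  with jumps up to ~0.07, so exact and asymptotic p can differ by more than
  that discreteness no implementation can remove.
* **Kruskal-Wallis H** — tie-corrected, chi-square reference on k - 1 df
  (`kruskal.test`). Its type-I error at alpha = 0.05 is verified to sit in
  [0.04, 0.06] over 2,000 null replicates.
* **Pearson chi-square** on contingency tables, no continuity correction.
* **Welch's t from summary statistics** — closed form with
  Welch–Satterthwaite df, because group summaries (not raw values) are what
  published demographic tables provide; verified against `t.test` on
  samples engineered to have exactly those summaries.
* **Spearman rank correlation** — Pearson on mid-ranks with a two-sided t
  approximation on n - 2 df; constant inputs yield a flagged undefined rho.
* **Correlation matrices** (`correlation_matrix()`) — one cell per OCT
  variable x OCTA variable over pairwise-complete eye-level rows, Bonferroni
  family defaulting to all testable cells of that matrix (disc and macula
  panels corrected separately, the presentation convention for such
  figures); a global family size can be supplied instead. Strength labels
  by absolute rho: [0, 0.3) weak, [0.3, 0.7) moderate, [0.7, 1] high, with
  boundary values assigned upward since the verbal intervals overlap at
  their endpoints. Eyes are treated as independent observations, mirroring
  per-eye analyses in this literature; averaging the two eyes per subject
  before correlation is a caller-side option since the cohort table carries
  subject identifiers.

# The synthetic-data module

**Phantoms.** `generate_phantom()` renders random-walk vessel trees: a few
wide trunks (12 px) crossing the field, thin side branches (3 px), and
additional capillary strokes added until the thin-vessel ground truth
reaches the requested coverage (default 0.2, a typical peripapillary
capillary density on a binarised en-face image). Vessels are bright
(0.75–0.92 with per-pixel gain jitter) on a dark background (0.08), with
Gaussian speckle (sd 0.05 by default) added last. The generator returns the
exact ground-truth capillary and trunk masks, so segmentation accuracy is a
measurable Dice coefficient, not an impression. `generate_grade_series()`
models progressive dropout: capillary strokes are deleted in one fixed
random order at nondecreasing per-grade fractions, which makes measured
density monotone by construction — the point being to exercise the
pipeline's ability to *detect* that monotone loss.

**Cohorts.** `generate_cohort()` samples one row per eye. Marginals are
grade-conditional Gaussians with the published per-grade mean/sd for the 24
blood analytes and the RNFL/GCC thickness regions (one degenerate published
sd of 0.00 is replaced by 0.05 so the generator is well-defined), truncated
at physiologic floors (e.g. EGFR >= 5 mL/min/1.73m2); floors sit far from
the means for every analyte the tests check, so truncation bias is
negligible there. Three dependence structures are injected:

* a per-eye vascular latent factor shared between RNFL quadrant thickness
  and the disc OCTA metrics flux, VAD and VCI, with loading chosen so their
  Pearson correlation equals `latent_coupling` (default 0.4 — the scale of
  published disc OCT-by-OCTA correlations). For bivariate normals the
  implied Spearman coefficient is `(6/pi) asin(c/2)` (`implied_spearman()`),
  which is what parameter-recovery tests compare against. Macular GCC and
  macular OCTA stay uncoupled, emulating the reported disc-but-not-macula
  pattern;
* a renal latent factor coupling creatinine, urea nitrogen and (negatively)
  eGFR — an explicit modelling choice reflecting diabetic nephropathy, not
  a published covariance;
* visual-acuity transitions sampled directly on the Snellen chart: with a
  per-grade worsening probability the follow-up drops two-plus lines
  (geometric step), otherwise it stays within one line, so the two-line
  classifier is exercised natively. Control baselines put 90% of eyes in
  the 20/20–20/30 bin, matching the reported control distribution.

Default group sizes (95 control eyes; 88/50/40/20/20 across DR0–DR4,
totalling 218 diabetic eyes) mirror the scale of the motivating series; the
published table does not give the per-grade split, so the declining profile
(no-retinopathy most common) was fixed once as the realistic choice.
Follow-up intervals are uniform on 4–7 years.

**What the phantoms do not emulate** — and hence what passing tests do not
show about real scans: projection and motion artefacts, signal fall-off
with defocus, the foveal avascular zone, capillary calibre heterogeneity,
true device SSI behaviour, missing-data patterns, and inter-eye correlation
within subject. Results on real images depend on segmentation quality in
ways the clean phantom geometry cannot probe.

# Numerical and testing choices

Problem sizes were fixed once as the package's own test conditions:
phantoms at 512 px for analytic-recovery checks (bar gratings recover
VAD/VSD/VDI within 10%; clean-phantom Dice >= 0.95) and 256 px where only
monotonicity is at stake; 2,000 replicates for the Kruskal-Wallis null;
1,000 simulations for the family-wise-error bound; 10 seeds x n = 500 eyes
for latent-coupling recovery (tolerance +/- 0.1 on rho). All generator
randomness flows through explicit integer seeds; the orchestration layer
derives per-module seeds from one master seed by fixed offsets, and rerunning
any configuration reproduces output byte-for-byte.

Known limitations: the thinning-based VSD under-counts by roughly half a
vessel width at each line end (visible as 38 px skeleton for a 40 px bar);
Otsu binarization of the *enhanced* image alone halos thin vessels by about
a pixel, which is why the hybrid default exists; and the complexity index
is resolution-dependent through the discrete perimeter, so VCI comparisons
are only meaningful at a common scale.

# A worked example

```{r example, eval = FALSE}
library(octavasc)

# phantom with ground truth, quantified over the standard disc annulus
ph <- generate_phantom(phantom_spec(seed = 1))
quantify_image(ph$image)

# synthetic cohort, full report bundle
cfg <- run_config(synthetic = TRUE, output_dir = "reports", seed = 1)
res <- run_analysis(cfg)
res$summary
```
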