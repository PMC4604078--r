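---
title: "Measurement models and design choices in dystromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and design choices in dystromorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dystromorph)
```

dystromorph re-implements, as one tested pipeline, the quantitative
measurements used to phenotype dystrophin-deficient (*mdx*) mice: muscle
fiber morphometry from stained cross-sections, immunofluorescence and
trichrome quantification, micro-CT trabecular bone morphometry, qPCR and
RNA-Seq expression summarisation, scalar functional assays, and the
statistical decision procedure that produces the reported p values. This
vignette explains each measurement model, the tunable parameters and their
defaults, the synthetic-data generator used to verify every stage, and the
numerical choices made where the underlying protocols leave the design
open.

## Muscle fiber morphometry

A stained cross-section presents two channels: a membrane/matrix channel
(collagen IV) that is bright along fiber borders, and a nuclei channel
(Hoechst). The macro proceeds in the classical six steps:

1. subtract the low-frequency background (estimated by a wide Gaussian,
   `background_radius_px`, default 50 px) to suppress illumination drift;
2. threshold the border signal (automatic Otsu on the background-subtracted
   channel unless `bandpass_low`/`bandpass_high` are given -- the original
   protocols do not publish numeric thresholds, so a stated automatic rule
   is the reproducible choice);
3. dilate by `dilation_radius_px` (default 2 px) so staining gaps up to
   roughly twice that radius are bridged;
4. skeletonise (Zhang-Suen thinning) to a one-pixel closed border network;
5. label the enclosed regions (4-connected) and discard regions outside
   the `min_fiber_area_um2`-`max_fiber_area_um2` window (default
   50-10,000 um^2, the particle filter that removes stray non-border
   signal) and regions touching the image frame, whose geometry is
   censored; removal counts are logged;
6. overlay the thresholded nuclei and measure each fiber.

Pixel conventions: origin top-left, 0-based, row-major; fiber regions are
4-connected, border skeletons 8-connected; a pixel is treated as a unit
square, so region widths are measured across pixel boundaries (a 30-pixel
wide bar measures 30 px, and a degenerate single-pixel region one pixel
pitch).

### Minimum Feret diameter

The minimum Feret (caliper) diameter -- the smallest projection width over
all orientations -- is the standard fiber-size measure because it is
robust to oblique sectioning. `min_feret()` computes it exactly by
rotating calipers on the convex hull: the minimum over hull edges of the
farthest vertex-to-edge distance. Whether historical measurements were
taken on the raw region or its hull is not documented; the caliper
definition is intrinsically a hull property, so the hull is used.
`min_feret_sweep()` is a deliberately independent brute-force kernel (a
0.05-degree projection sweep with iterative local refinement around the
minimum; refinement is needed because the width function has a kink, not a
smooth minimum, at edge-aligned angles) that the test-suite compares
against the calipers on random polygons to 1e-6 relative error.

### Central nucleation

A fiber is centrally nucleated (C/N) when at least one nucleus centroid
lies deeper inside the fiber than `central_margin_fraction` (default 0.1)
times the fiber's equivalent-circle radius, with depth measured on the
distance transform of the labelled fiber regions. The margin separates
internal nuclei from subsarcolemmal ones; since the published protocols do
not define "central" numerically, the classifier also reports each fiber's
maximum nucleus depth fraction so the sensitivity of the %C/N to the
margin can be inspected directly from the records.

## Region counting and area fractions

Immunopositive cells are counted by threshold (Otsu default), 8-connected
labelling, and an object-size window (default 20-500 um^2); counts are
expressed per mm^2 and diaphragm sections are summarised as the arithmetic
mean over fields of view. Touching cells count as one object (no watershed
split; documented behaviour). Area fractions are percent of section area,
either from an automatic threshold or by replaying manually delineated ROI
polygons (shoelace area), with the mode recorded in the output. Trichrome
collagen is classified per pixel by blue dominance (`B > R + margin` and
`B > G + margin`, margin 20 on the 8-bit scale) over the tissue area,
excluding near-white slide background by a luminance cutoff; the
historical protocol names no numeric rule, so the rule and its two
parameters are explicit configuration. Revertant (dystrophin-positive)
fibers are counted as connected components per mm^2; whether historical
counts treated clusters as one or many is ambiguous, and components are
the reproducible choice.

## Trabecular bone morphometry

Bone is segmented from micro-CT volumes by seeded region growing: a FIFO
flood from seed voxels annexing 6-connected neighbours whose intensity
lies within `tolerance` of the running region mean. The technique is named
in the source protocols without a homogeneity criterion; the running-mean
criterion is the common one and is stated here. Guards: seeds must exceed
the volume's foreground (Otsu) threshold, and a region exceeding 95% of
the volume aborts with an overflow error rather than silently flooding.

BV/TV is the voxel ratio within the ROI (a contiguous slice range, e.g.
100 slices below the growth plate). Tb.Th is Hildebrand-style
model-independent local thickness: exact 3-D Euclidean distance transform,
distance ridge, and maximal-sphere painting, with a half-voxel correction
so an n-voxel slab measures exactly n voxels; Tb.Sp is the same measure on
the complement; Tb.N is reported under the plate model (BV/TV / Tb.Th per
mm) with the alternative 1/(Tb.Th + Tb.Sp) estimate alongside, because the
two scanner pipelines used historically may not have shared one
convention and both code paths are exposed. The thickness map is computed
over the whole volume and averaged over ROI voxels; the first and last
slice are treated as phase boundaries (the stack is cropped there), while
the in-plane field of view is assumed to contain the structure. On plate
phantoms this recovers plate thickness exactly and underestimates wide
separations by about one voxel pitch (the discretisation cost of the
sphere model); both effects are inside the two-voxel-pitch acceptance
band.

## Expression summarisation

**geNorm stability.** For candidate reference genes, M(gene) is the mean
over the other candidates of the SD across samples of the pairwise log2
expression ratio; on the Ct scale the log2 ratio of genes j, k is simply
`Ct_k - Ct_j`, which makes M invariant to constant per-gene offsets.
Ranking is by iterative exclusion of the highest-M gene until two remain.
At least three candidates are required (pairwise SDs cannot rank two).

**2^-ddCt.** Per sample, dCt = Ct_target - mean(Ct_references); per group
ddCt = mean dCt(group) - mean dCt(calibrator); fold = 2^-ddCt. Group
aggregation uses the mean of per-sample dCt (the convention consistent
with the cited method); averaging per-sample fold changes instead is
available behind `aggregate = "mean_fold"`. Missing Ct values are a hard
error, never silently imputed.

**Heatmap stage.** FPKM rows with missing values are removed, the matrix
is log-transformed (base 2, pseudocount 1 -- the source only says
"log-transformed", so base and pseudocount are configuration keys), rows
are z-scored, and zero-variance rows are removed with a report because
they cannot be scaled. Clustering is Ward's method in the ward.D2 variant
(distances entering the criterion squared); the historical citation is
ambiguous between Ward variants, and ward.D2 is the one that matches the
textbook minimum-variance-increase objective, which is also what the
test-suite's brute-force oracle implements. Dendrograms export as Newick.

## Assay metrics

Discrimination index = 100 x novel / (novel + familiar), 50 = chance.
Grip strength is the mean of the (two, configurable) trial maxima. Force
traces are baseline-corrected by the median over a pre-stimulus window
(default 0.05 s; baseline handling is not documented in the source
protocols, and a median window is robust to pickup noise); the maximal
twitch and tetanic responses are the tallest corrected peaks of their
respective trace sets, normalised to muscle wet weight (N/g). A missing
stimulus kind reports NA, never zero.

## The statistical decision procedure

Two groups: unpaired Student's t (pooled variance -- the convention
consistent with the integer degrees of freedom in the published legends).
Three or more: one-way ANOVA with Tukey's HSD (Tukey-Kramer SE when
unbalanced). When the parametric p falls below alpha = 0.05 the
Anderson-Darling normality gate is applied to the pooled group-centred
residuals (n >= 8 required; smaller samples skip the gate with a recorded
warning): non-normal data are re-routed to Mann-Whitney U (two groups) or
Kruskal-Wallis H, which then provide the reported p; otherwise a
label-shuffling permutation ANOVA (p = (1 + #{F* >= F}) / (B + 1), B
default 9,999, seed mandatory) is run alongside as confirmation. Whether
the historical permutation script shuffled raw labels or residuals is
unstated; raw-label shuffling is implemented and named as such in the
recorded decision path, which lists every applied rule in order.

Conventions worth stating prominently: the Mann-Whitney statistic W is the
rank sum of the **first** sample (the only reading consistent with the
published W = 388 at group sizes 18 and 16); the exact null distribution
is used when n1 + n2 <= 12 without ties, otherwise the normal
approximation with tie correction and (default, toggleable) continuity
correction; and significance stars follow the unusual published scheme
*p < 0.05, **p < 0.005, ***p < 0.001 (configurable).

The pipeline's operating characteristics are verified by simulation: under
a two-group normal null its type-I error over 10^4 seeded replicates must
lie in [0.04, 0.06], and the two-group identity F = t^2 must hold to
1e-10.

## The synthetic-data generator

Every pipeline input can be generated with exact ground truth from a
single integer seed (all randomness flows through one seeded generator
with the session RNG state restored afterwards; equal seeds give
byte-identical outputs).

* **Fiber fields**: a jittered-grid nearest-seed partition tiles the frame
  into disjoint convex-ish fibers with known pixel geometry; borders are
  drawn only between fibers (a one-fiber field is the full rectangle), the
  membrane channel is the blurred, noisy border (noise SD 0.02 on [0,1],
  border width 3 px by default -- typical of a 20x montage at ~1 um/px),
  and every truth minimum Feret is cross-checked against a 0.1-degree
  sweep at generation time. Each fiber receives one peripheral
  (subsarcolemmal) nucleus drawn straddling the border so its centroid
  depth is unambiguously below the C/N margin, and the planted fraction
  (default 30%) of fibers receives an additional nucleus at least 25% of
  the equivalent radius deep. Central fibers are drawn stratified by
  edge-touching status so the planted rate holds within the measurable
  interior subset, which is what the analysis reports after excluding
  edge-censored fibers.
* **Area-fraction and cell-field images**: painted discs with the realized
  positive fraction trimmed to the target (always recomputable by pixel
  count), and non-overlapping bright cells in exact number.
* **Trabecular phantoms**: parallel plates, rod lattices or sphere
  lattices with whole-voxel thickness and separation; for plates, BV/TV
  within complete periods equals t/(t+s) exactly, and the truth carries
  per-plate seed voxels and the complete-period ROI.
* **Tables**: grouped measurements (normal, lognormal, contaminated 10% x
  5 SD), Ct tables whose first genes covary with the per-sample loading
  offset at 5% of the stated noise (so the stable set is planted by
  construction, and zero noise makes every geNorm M zero), and FPKM
  matrices with a planted two-cluster sample split.

What the generator deliberately does **not** emulate: photorealistic
staining texture, uneven illumination beyond a smooth background, fiber
shape irregularity beyond convex-ish tiles, partial-volume and
beam-hardening effects in micro-CT, or amplification-efficiency
differences between qPCR assays. Passing the recovery suites therefore
demonstrates correctness of the measurement algorithms under controlled
conditions, not robustness to every artefact of real histology.

## Numerical choices and problem sizes

Otsu thresholds use a 256-bin histogram over the data range. Connected
components are labelled by breadth-first search with labels in scan order.
Tie-breaks: the deepest-pixel rule places central nuclei at the distance
transform's argmax (first index on ties); Ward merge ties follow
`stats::hclust`. The permutation p lower bound is 1/(B + 1) by
construction. The test-suite sizes simulations to run on one CPU in a few
minutes: 100-fiber fields at 512 x 512, 256^3 plate phantoms, 10^4
null replicates for pipeline calibration, 200 random polygons for the
Feret oracle, and brute-force cluster oracles up to n = 12; these are the
package's chosen verification conditions, and all tolerances quoted above
are asserted by the suite at exactly those sizes.

## Known limitations

* Tb.Sp is biased low by about one voxel pitch on coarse-voxel phantoms
  (sphere-model discretisation) and the slice-axis boundary convention
  matters for structures running through the first/last slice.
* The border-mask stage assumes pre-montaged fields of view; montage
  seams, fiber typing and 3-D reconstruction are out of scope.
* The C/N classifier depends on `central_margin_fraction` for nuclei near
  the margin; the per-fiber depth fractions in the records are the tool
  for assessing that sensitivity on real data.
* Mann-Whitney exact p values are unavailable with ties (the normal
  approximation with tie correction is used instead).
* Per-gene qPCR tests are reported without a panel-wide multiplicity
  correction, mirroring the source analysis; apply one downstream if the
  inferential context requires it.
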