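# dystromorph

Quantitative morphometry and decision statistics for preclinical studies
of dystrophic (mdx) mice.

Phenotyping a muscular-dystrophy mouse model spans very different
measurements: muscle-fiber size distributions from stained cross-sections,
inflammatory-cell counts and fibrosis area fractions, micro-CT trabecular
bone architecture, qPCR/RNA-Seq expression summaries, functional assay
scalars, and a statistical decision procedure tying them together.
dystromorph implements that whole measurement layer as tested, reusable R
functions, plus a synthetic-data generator that produces every input with
exact ground truth — so each stage is verifiable end to end without the
original animals or images. It is aimed at labs quantifying dystrophic
pathology (or any fiber-morphometry / bone-morphometry workload) who want
the semi-automated ImageJ-macro workflows as auditable, scriptable code.

## What it computes

* **Fiber morphometry** (`fiber_morphometry()` and friends): the six-step
  border-mask macro — background subtraction, band-pass threshold,
  dilation, skeletonisation, particle filtering — then per-fiber area,
  **minimum Feret diameter** (exact rotating calipers on the convex hull:
  min over hull edges of the farthest vertex-to-edge distance), and
  centrally nucleated (C/N) classification by nucleus-centroid depth;
  summaries report fibers/mm², %C/N, per-class mean min-Feret and the
  frequency histogram.
* **Region quantification**: thresholded cell counts per mm² with
  field-of-view averaging, IgG-positive and trichrome (blue-dominance)
  area percentages, revertant-fiber densities.
* **Bone morphometry**: seeded region growing segmentation, BV/TV, Tb.Th
  and Tb.Sp by Hildebrand maximal-sphere local thickness (exact 3-D EDT,
  distance ridge, sphere painting — compiled in C++), plate-model Tb.N =
  BV/TV / Tb.Th.
* **Expression**: geNorm reference-gene stability M (mean pairwise
  log-ratio SD, iterative exclusion), 2^−ΔΔCt relative expression,
  log + row z-scoring, Ward (ward.D2) clustering with Newick export.
* **Assays**: discrimination index (100·novel/total), grip strength,
  twitch/tetanic peak force in N/g.
* **Decision statistics**: Student's t (pooled) / one-way ANOVA + Tukey
  HSD, an Anderson–Darling normality gate on significant results with
  re-routing to Mann–Whitney U / Kruskal–Wallis H, a seeded
  label-shuffling permutation ANOVA run alongside, recorded decision
  paths, and stars under the *p<0.05, **p<0.005, ***p<0.001 scheme.
  Mann–Whitney W is reported as the **first sample's rank sum**.

## Worked example

Generate a synthetic fiber field with known truth, run the morphometry
macro, and test a three-group comparison:

```r
library(dystromorph)

f <- generate_fiber_field(100, c(512, 512), pct_central = 0.3, seed = 42)
res <- fiber_morphometry(f$membrane, f$nuclei)
#> label_fibers: kept 65 fibers; removed 1 edge-touching and 1 size-filtered regions
s <- res$summary
c(n = s$n_fibers, per_mm2 = round(s$fibers_per_mm2, 1),
  pct_cn = round(s$pct_central_nucleated, 1),
  feret = round(s$mean_min_feret_um, 1))
#>       n per_mm2  pct_cn   feret
#>    65.0   248.0    29.2    51.4
```

65 measurable (non-edge) fibers were recovered from the 100 planted
(64 lie fully inside the frame), 29.2% classified C/N against a planted
interior rate of 29.7%, with a mean minimum Feret diameter of 51.4 µm.

```r
d <- generate_group_measurements(data.frame(
  group_name = c("wt", "mdx", "mdx_ko"), n = 10, distribution = "normal",
  mean = c(52, 38, 47), sd = 6, seed = c(101, 102, 103)))
decision_pipeline(d, decision_config(seed = 1))
#> F = 12.89, df = 2, 27, p = 0.0001173 ***
#> post hoc:
#>         pair      diff        p_adj
#> 1 mdx_ko-mdx  2.313422 0.5684381520
#> 2     wt-mdx 10.887866 0.0001424481
#> 3  wt-mdx_ko  8.574444 0.0021209908
#> decision path: one_way_anova -> tukey_hsd -> anderson_darling_gate -> permutation_anova(label_shuffle)
```

The ANOVA is significant, residuals pass the Anderson–Darling gate, and a
seeded permutation ANOVA is recorded alongside as confirmation; the
decision path documents every rule applied.

A thin command-line wrapper is installed with the package
(`inst/cli/dystromorph`), dispatching
`dystromorph {simulate|fibers|regions|bone|qpcr|heatmap|assays|stats}` to
these same functions.

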