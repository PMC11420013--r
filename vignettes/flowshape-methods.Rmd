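---
title: "Quantifying endothelial cell shape and flow alignment from label masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endothelial cell shape and flow alignment from label masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowshape)
```

## The biological question

Endothelial cells lining a vessel experience laminar shear stress from blood
flow. In culture, cells kept static are polygonal and randomly oriented;
cells under sustained laminar flow elongate and align their long axes with
the flow direction. flowshape quantifies both phenotypes from the output of
any instance segmenter: a 2-D label mask in which 0 is background and each
positive integer covers one cell.

Two summary statistics carry the analysis:

* the **elongation factor** (EF) of each cell — the ratio of the major to
  the minor axis of the ellipse with the same second central moments as the
  cell mask; EF = 1 for an isotropic cell;
* the **alignment** of the population — each cell's axial deviation from
  the median orientation of cells in its image, summarised by a radial
  (rose) histogram and a coefficient of variation (CV).

## Morphometry from pixel moments

For a cell with pixel set $\{(r_i, c_i)\}$ we use pixel centres with
$x = c$, $y = -r$ (the image row axis points down, so this makes positive
angles counter-clockwise from the horizontal, the usual "angle from the
x-axis" convention). The normalised central second moments
$\mu_{20}, \mu_{11}, \mu_{02}$ form the covariance matrix whose eigenvalues
$\lambda_1 \ge \lambda_2$ give

* major axis length $4\sqrt{\lambda_1}$, minor $4\sqrt{\lambda_2}$,
* elongation factor $\sqrt{\lambda_1/\lambda_2}$,
* orientation $\tfrac12\,\mathrm{atan2}(2\mu_{11},\,\mu_{20}-\mu_{02})$,
  reported in $(-90^\circ, 90^\circ]$.

No per-pixel variance correction ($+1/12$) is applied; this is the dominant
region-properties convention and makes a solid 5x3 rectangle yield exactly
$\mu_{20} = 2$, $\mu_{02} = 2/3$, EF $= \sqrt3$. Degenerate inputs follow
documented conventions: a single-pixel cell has EF 1 and orientation 0; a
collinear cell has minor axis 0 and an `Inf` EF sentinel, and is always
removed by the aspect filter below. Orientation of an exactly isotropic
cell ($\mu_{11}=0$, $\mu_{20}=\mu_{02}$) is 0 by convention. A label whose
pixels are not one 8-connected component is measured as a single region
with a warning; shape QC removes pathological cases in practice.

```{r rectangle}
m <- matrix(0L, 9, 11); m[4:6, 4:8] <- 1L   # solid 5 x 3 rectangle
measure_cells(m)[, c("area_px", "orientation_deg", "major_len",
                     "minor_len", "elongation_factor")]
```

## Quality control

Three filters remove unreliable segmentations, mirroring standard practice
for confluent monolayers:

| rule | threshold | default |
|---|---|---|
| relative area | area strictly below `min_area_fraction` x largest cell | 0.2 |
| aspect ratio | EF strictly above `max_aspect` | 10 |
| border | any pixel on the image border | on |

The reference area (the largest cell) is computed **before** any removal
and all three rules are evaluated in one pass over the original set: a
border-touching largest cell is itself removed but still anchors the 20%
rule. This single-pass reading avoids order dependence among the rules; its
one consequence — the filter is not guaranteed idempotent when the largest
cell is removed — is documented and tested. Both numeric thresholds are
strict inequalities ("less than 20%", "greater than 10"). When a cell fails
several rules the recorded reason follows the priority border >
too_elongated > too_small; membership of the removed set does not depend on
that ordering.

## Axial orientation statistics

A major axis is an undirected axis: $\theta$ and $\theta + 180^\circ$ are
the same orientation. All angle arithmetic therefore happens on the
period-180 circle, with representatives in $(-90^\circ, 90^\circ]$.

* `axial_median()` returns the observed value minimising the summed
  absolute axial distance to all observations (ties: smallest angle).
* `deviations_from_median()` subtracts the per-image median, wrapping the
  short way around, so the median maps to 0.
* `radial_histogram()` bins each deviation twice, at $d$ and $d + 180$,
  so every cell contributes a diameter and the rose plot is
  point-symmetric. The default is 36 bins of 10 degrees — fine enough to
  show alignment structure, coarse enough not to be dominated by counting
  noise at ~100 cells per image; any divisor of 360 is accepted.
* `alignment_cv()` shifts the deviations by $+90^\circ$ onto $(0, 180]$
  and returns the sample standard deviation (n-1) over the sample mean.

The CV definition deserves a note, because "coefficient of variation of
the deviations" admits two readings: SD/mean of the absolute deviations,
or SD/mean of the shifted signed deviations. Both give $1/\sqrt3 \approx
0.577$ for unaligned (uniform) orientations, but only the shifted form
scales down as the angular spread shrinks — absolute deviations have a
scale-free CV near 0.76-1.0 regardless of alignment strength — so only the
shifted form can distinguish strongly aligned monolayers (CV well below
0.3) from static ones (CV near 0.5-0.6). flowshape therefore uses the
shifted form.

Two properties of this statistic matter when interpreting values:

* For i.i.d. uniform deviations the CV converges to $1/\sqrt3$; with
  per-image **median centring** at n = 100 cells the expected value is
  biased slightly low (about 0.54), because the centring rotation itself
  minimises summed absolute deviation. Unaligned monolayers therefore
  report CVs in the 0.48-0.6 range at realistic cell counts.
* The CV decreases monotonically with the concentration of orientations;
  perfect alignment gives 0.

Deviations are centred per image (the median is an image-level quantity)
and then pooled across the replicate images of a condition, giving e.g.
3 x 100 = 300 cells per condition; `analysis_config(pooling = "image")`
switches to per-image summaries instead, since published per-condition
CVs can be computed either way.

## Group comparisons

Elongation-factor distributions are compared with the field's standard
nonparametric tests: a two-tailed Mann-Whitney U for two conditions
(exact enumeration up to a pooled n of 12 without ties, tie-corrected
continuity-corrected normal approximation otherwise) and Kruskal-Wallis
for three or more, followed by Dunn's pairwise post hoc
$$ z_{ij} = \frac{\bar R_i - \bar R_j}
 {\sqrt{\bigl(\tfrac{N(N+1)}{12} - \tfrac{\sum_t (t^3-t)}{12(N-1)}\bigr)
 \bigl(\tfrac1{n_i}+\tfrac1{n_j}\bigr)}} $$
with Bonferroni adjustment over all pairs by default ("Dunn's correction"
is most commonly read as Bonferroni; the `adjustment` argument accepts any
`p.adjust` method). Significance is annotated with the conventional tiers
\*p < 0.05 through \*\*\*\*p < 0.0001.

## The synthetic monolayer generator

Real deposited image sets are large; the package instead validates itself
on synthetic monolayers with known ground truth. `generate_monolayer()`
builds an **anisotropic Voronoi tessellation**: seeds on a jittered
lattice, each carrying its own orientation $\varphi_i$ (drawn by
`sample_orientations()` from a von Mises distribution on the doubled-angle
circle — concentration $\kappa = 0$ is the unaligned/static case) and a
common anisotropy `stretch`; every pixel joins the seed minimising the
squared distance after rotating into the seed's frame and shrinking the
along-axis coordinate by 1/stretch. A per-seed metric, rather than a
single global affine stretch, is essential: a global stretch would force
perfect alignment and make CV recovery untestable.

Generator choices, fixed once:

* **Jittered lattice** (default jitter 0.35 of the spacing) rather than a
  Poisson point process, so cell areas stay comparable and QC does not
  remove large fractions of tiny cells.
* **Connectivity repair**: anisotropic Voronoi cells can be disconnected;
  each label keeps its largest 8-connected component and every detached
  fragment is reassigned to the 4-neighbouring label with the longest
  shared boundary, iterated to a fixed point. Masks are confluent (no
  background) by construction.
* **Determinism**: a single `rng_seed` drives lattice jitter, site
  selection, orientations and rendering noise; the caller's RNG state is
  left untouched.
* Default `n_cells = 100` per image matches the typical number of cells
  analysed per condition and image in flow-alignment experiments;
  `stretch = 1, kappa = 0` is the static phenotype, `stretch ~ 3-4,
  kappa ~ 8` the flow phenotype.

The measured EF of generated cells is related to, but not equal to,
`stretch` (neighbouring cells compete for pixels), so recovery tests
assert monotonicity and bands, not equality: median EF is non-decreasing
in stretch over {1, 2, 3, 4}, alignment CV is non-increasing in kappa over
{0, 1, 2, 4, 8}, an imposed 30-degree flow direction is recovered within
5 degrees at kappa = 8, and at kappa = 0 the pipeline CV matches the
uniform null. `render_channels()` adds optional membrane/nuclei channels
(boundary indicator and centroid blobs, Gaussian PSF, Poisson shot noise)
for testing intensity-based tooling; the analysis itself never uses them.

What the simulator does **not** emulate: segmentation errors other than
the geometrically induced ones (no merged or split cells, no debris),
intensity-dependent artefacts, curvature of real junctions, and any
mechanical coupling between neighbours beyond tessellation competition.
Passing recovery tests therefore demonstrates correctness of the analysis
chain, not performance of any upstream segmenter on real images.

## Problem sizes and numerical choices

The validation suite runs tessellations at 160 x 160 px with 48 cells and
10 seeds per parameter value, and Monte-Carlo nulls with 200-2000
replicates — sizes chosen so the full suite completes in a couple of
minutes while leaving comfortable statistical margins. Angle comparisons
use exact wrap arithmetic (no tolerance loss at the ±90 boundary, where
-90 is identified with +90); morphometry agrees with a brute-force
double-loop oracle to 1e-9; elongation change under arbitrary-angle
re-rasterisation is bounded by 5% for blobs of at least 200 px, a
resampling tolerance.

## Worked example

```{r example}
masks <- lapply(1:3, function(r) {
  generate_monolayer(
    synthetic_spec(c(160, 160), 48, stretch = 3, kappa = 8, rng_seed = r),
    image_id = paste0("flow_", r), condition = "flow",
    replicate = as.character(r))$mask
})
static <- lapply(4:6, function(r) {
  generate_monolayer(
    synthetic_spec(c(160, 160), 48, stretch = 1, kappa = 0, rng_seed = r),
    image_id = paste0("static_", r), condition = "static",
    replicate = as.character(r - 3))$mask
})
res <- run_analysis(masks = c(masks, static), config = analysis_config())
res$elongation
sapply(res$alignment, `[[`, "cv")
res$stats
```

The flow condition shows the expected phenotype: higher median elongation
factor and a markedly lower alignment CV than the static condition, with
the Mann-Whitney comparison of the pooled elongation factors strongly
significant.

## Limitations

* The analysis consumes label masks; it neither runs nor audits a
  segmenter, and QC can only remove, not repair, bad masks.
* The alignment CV is a dispersion summary, not an inferential statistic;
  no circular-statistics tests (Rayleigh, kappa estimation) are exposed.
* Replicate-level hierarchical inference is out of scope: tests treat
  pooled cells as the sample, the convention the pipeline reproduces.
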