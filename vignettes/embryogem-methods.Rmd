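---
title: "Methods: GEM coexpression search and shared-motif dotplots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GEM coexpression search and shared-motif dotplots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryogem)
```

## The model

embryogem implements the computational core of genome-wide expression-map
(GEM) searching over in situ hybridization embryo images.

Every curated image is reduced to a **binary spatial expression profile**: a
mask over a standardized embryo frame in which black pixels mark expression
presence and white pixels expression absence. A gene's profiles within one
*key* — the combination of data source (BDGP, FlyFISH or PubMed-curated),
developmental stage range and anatomical orientation — are combined into one
composite profile. All composites under a key are aggregated into a **GEM**:
an inverted index mapping each pixel to the set of genes expressed there,
together with a per-pixel count of expressed genes.

Two similarity scores drive search:

* **GEM coexpression, n/t.** A query is an ordered set of *t* search pixels
  (a profile's black pixels, a painted region, or clicked points). For a
  candidate gene, *n* is the number of search pixels at which the candidate
  is expressed, and the score is *n/t*. Evaluating it is a column subset of
  the index — no pairwise image comparison is needed.
* **Jaccard pairwise similarity**, the legacy search: intersection of black
  pixels over union of black pixels of two full profiles.

For a full-coverage query taken from profile *A*, and any candidate *B*,

$$J(A,B) \;=\; \frac{|A \cap B|}{|A \cup B|} \;\le\; \frac{|A \cap B|}{|A|}
\;=\; \frac{n}{t},$$

since the union always contains *A*. Hence at any common score threshold,
the pairwise result set is a **subset** of the GEM result set. This
inequality is the package's central comparative claim and is asserted
gene-by-gene on every synthetic library in the test suite.

The third component is a **shared-motif dotplot** of two upstream
intergenic regions (IGRs): all maximal exact matches of length at least
*k* (default 8) between the two sequences, listed as motifs, rendered to a
self-contained SVG, and optionally shaded by mean per-base PhastCons-style
conservation binned as 0–0.25 white, >0.25–0.5 light gray, >0.5–0.75 dark
gray, >0.75–1 black.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| frame | 320 × 160 | pixels | wide-embryo convention; configurable everywhere |
| stage bins | 1-3, 4-6, 7-8, 9-10, 11-12, 13-16 | stages | midpoint assignment, ties to the earlier bin |
| binarization | Otsu | — | stain is dark-on-light, so expressed = intensity ≤ threshold |
| composite rule | union | — | a pixel is composite-expressed if any image shows it |
| min score / min similarity | 0 | fraction | compared with ≥ using exact rationals |
| pixel coverage | 1 | fraction | subsample of `round(coverage × t)` pixels, half-up, min 1 |
| k (dotplot) | 8 | bp | minimum maximal-match length |
| bedGraph gap score | 0 | — | unscored bases treated as unaligned |

## Standardization and binarization

Embryo standardization segments the embryo, crops to its bounding box and
rescales to the frame (bilinear). Segmentation estimates the background as
the **median intensity of the border pixels** and takes the largest
connected component of pixels darker than background − 16. A global Otsu
cut was considered and rejected for this step: a stained embryo is
trimodal (stain ≪ tissue < background), and Otsu's two-class criterion
frequently thresholds at the stain, which would crop the frame to the
expression domain rather than the embryo. The border median is robust to
staining because stain lies inside the embryo, away from the borders.

Otsu *is* used for binarization, where separating the darkest class is
exactly what is wanted: a pixel is expressed when its intensity is at or
below the threshold. On two-level noise-free images the planted domain is
recovered with zero pixel errors; this is tested, not assumed.

Composites are **unions** of per-image masks. Whether production systems
union, intersect or vote per-image masks is not derivable from the
published description; union matches the semantics of "composite spatial
expression" (any observed expression counts), is monotone in added
images, and is our documented choice. Stage ranges straddling two bins go
to the bin containing the range midpoint, half-integer ties to the earlier
bin, and midpoints above the last bin clamp into it so stage-17 records
remain assignable.

## Numerical choices

* **Exact threshold comparisons.** "At least 25% similarity" is a statement
  about the rational n/t, not about a float. Score filters rationalize the
  threshold by continued fractions (denominator ≤ 10⁶) and decide
  `n/t ≥ p/q` as the integer comparison `n·q ≥ p·t`, so boundary cases
  like 10/100 vs 0.1 or 1/3 vs 1/3 never misclassify.
* **Subsampling.** `round(coverage × t)` pixels (round half up, minimum 1)
  are kept, drawn uniformly without replacement. How production systems
  thin "pixel coverage" is unstated; uniform random under a seed is our
  documented stand-in. The implementation permutes the pixel order once
  per seed and takes a prefix, so subsets at decreasing coverage are
  nested and a gene's *n* is monotone in coverage (scores need not be).
* **Tie-breaking.** Equal scores are ordered lexicographically by gene
  identifier; hitlists are fully deterministic.
* **Degenerate inputs.** Jaccard of two empty masks is undefined and
  returned as `NA`, never 0. Genes with all-empty masks stay in the GEM's
  gene set (score 0, rankable) but index no pixel. Empty queries error.

## The dotplot matcher

Matches are found by k-mer seeding: shared k-mers are grouped by diagonal
(`q_start − s_start`) and maximal runs of consecutive seeds on one diagonal
are merged into a single span. A run that is maximal in seed starts is
maximal in the character sense too (any flanking matching character would
contribute another seed), so no extension step is required; distinct
diagonals are never merged, and gapped near-diagonal matches are not
merged either. k-mers containing N never match — ambiguity is not
identity. Reverse-complement matching is available behind a flag and is
rendered as anti-diagonal lines. Internally all coordinates are 0-based
half-open; axis labels and match context use 1-based inclusive genomic
coordinates.

Conservation shading averages the per-base track over each match span at
render time, per side; when the two sides fall in different bins the
darker bin is drawn (the published description does not address two-sided
rendering). Motif highlighting uses exact string equality with the listed
motif; substring semantics were rejected to keep dropdown-style selection
unambiguous.

## What the synthetic generator emulates

The generator produces every input the pipeline consumes, with known
ground truth:

* **Embryo images** — an elliptical embryo (tissue 200) on a light
  background (245) with stained domains (40): anterior–posterior or
  dorsal–ventral stripes and circular patches, all inside the embryo.
  The ellipse raster includes a half-pixel boundary band so a native-frame
  embryo touches all four borders, making standardization an exact no-op
  there — that is what lets end-to-end tests demand *exact* recovery.
  Noise is additive uniform intensity jitter, clipped to 0–255: the
  simplest model that stresses thresholding without changing ground truth.
  Default domain sizes keep stained area above roughly 2% of the frame so
  the stain remains the Otsu-darkest class.
* **Libraries** — blocks of genes share a (optionally jittered) domain
  template, giving a controlled coexpression structure and a ground-truth
  Jaccard matrix computed directly from the planted masks.
* **IGR pairs** — random-GC backgrounds with planted shared motifs. The
  backgrounds are made collision-free at a guard k-mer length by iterative
  repair: any accidental shared maximal match has one background base
  mutated and the pair is rescanned, up to a bounded number of passes.
  Silent acceptance of collisions is forbidden (ground truth would be
  wrong), so exhausting the budget is an error. Feasibility is physical:
  roughly, `len × k / 4^k` must be well below 1 (e.g. 2 kb backgrounds can
  be cleaned at k = 8 but not at k = 6).
* **Conservation tracks** — a flat base level with rectangular plateaus.

What the generator does **not** emulate: real embryo morphology and
stage-dependent shape change, imaging artifacts, rotation/flip
misorientation (inputs are assumed pre-oriented; registration is out of
scope), multi-embryo plates, and realistic sequence composition beyond GC
content. Passing tests therefore demonstrate the correctness of the
algorithms on well-posed inputs, not the robustness of segmentation on
real micrographs.

## Problem sizes used by the tests and the acceptance script

Chosen as comfortable desk-scale study conditions: 20 seeded libraries of
50–200 genes (frame 160 × 80) for the subset property; 100 seeded queries
at coverages 0.2/0.4/0.8/1.0 against a 60-gene library for search oracle
equivalence; 50 sequence pairs of 300–1200 bp at k ∈ {6, 8, 12} for the
dotplot oracle; 25 planted pairs (400–800 bp, guard k = 8) for motif
recovery; and two 30-gene libraries at the native 320 × 160 frame (noise 0
and 20) for end-to-end pipeline recovery. Headline counts published for
the production database (hundreds to thousands of hits for a single gene
query) depend on its full image library and are not reproducible at this
scale; the package instead verifies the properties that make those results
trustworthy.

## Known limitations

* Standardization assumes one embryo per image, darker than its
  background; it does not rotate, flip or quality-filter.
* GEMs are built per stage bin independently; a gene imaged across several
  bins contributes one composite per bin, and no cross-bin aggregation is
  defined.
* The dotplot reports exact matches only — no mismatches, gaps or
  degenerate-base awareness beyond excluding N.
* The SVG is a static rendering of the interactive viewer: highlighting
  and match context are emitted as attributes/titles, not behavior.
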