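---
title: "Tracking figure-panel reuse across documents with provenance graphs"
author: "panelprov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking figure-panel reuse across documents with provenance graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Paper mills — undisclosed operations that fabricate scientific articles at
scale — tend to reuse the same source imagery across many manuscripts with
unrelated authors and venues: the same micrograph cropped differently, a
Western blot mirrored and recompressed, a flow-cytometry panel rescaled and
recolored. Finding these links in a collection of thousands of PDFs is a
needle-in-a-haystack problem: no metadata connects the documents, only the
pixels do.

`panelprov` implements an end-to-end provenance-analysis pipeline for this
setting. It extracts figures from documents, isolates the panels inside
compound figures, and then links panels — and ultimately documents — that
demonstrably share pixel content, summarizing the evidence as provenance
graphs an integrity analyst can read.

## Pipeline overview

1. **Ingest** (`extractFigures`, `detectPanels`, `cropAndFilter`): figures
   are pulled from PDFs (embedded-raster extraction, not page rendering) or
   read from image directories; panels are located by one of three detector
   backends (supplied annotations, a whitespace-gutter splitter, or a
   plugged-in learned detector) and cropped. Five panel types are
   recognized; graphs-and-plots panels are dropped by default because
   analytically generated charts look alike across unrelated data and
   produce spurious links.
2. **Evidence store** (`describePanel`, `buildEvidenceDB`,
   `retrieveSimilar`): each panel gets a global descriptor; retrieval
   returns the top-K most similar panels of the same type from *other*
   documents, by cosine similarity.
3. **Consistency check** (`extractKeypoints`, `matchAndVerify`):
   candidate pairs are verified at pixel level with scale-invariant interest
   points, brute-force descriptor matching under a ratio test, and a robust
   homography fit, with a mirrored retry.
4. **Content-sharing score** (`contentSharingScore`): the fraction of a
   panel's area covered by the convex hull of its verified matches —
   directional, so a crop scores 1.0 against its source while the source
   scores the crop's area fraction.
5. **Table and graphs** (`processProbe`, `buildSharedTable`,
   `provenanceComponents`, `maximumSpanningTree`): a sparse score table is
   filled by a bounded processing-queue loop per probe; panels with scores
   at or above the threshold are linked, grouped into connected components,
   and each component is pruned to its maximum spanning tree for
   visualization. The highest-degree tree node is the suspected hub of a
   reuse group.
6. **Document level** (`buildDocumentMatrix`, `documentGraphs`): panel
   evidence is aggregated into an n x n matrix of shared-element counts
   between documents, with its own components and spanning trees.
7. **Evaluation** (`contentPairing`, `contentGrouping`,
   `contentClassification`, `evaluateProvenance`): predictions are scored
   against annotations with three harmonic-mean metrics (CP, CG, CC) at
   both levels.

## The panel descriptor

The default descriptor is deliberately weight-free and deterministic so the
pipeline runs with no model download: the panel is converted to BT.601
grayscale, anti-alias blurred (Gaussian, sigma half the shrink factor) and
resampled to a 64 x 64 grid, contrast-normalized, and transformed with a
2-D DCT. The 63 lowest-frequency coefficients (DC excluded) are kept as
*magnitudes*: mirroring an image only flips the signs of its odd-frequency
coefficients, so magnitudes are exactly mirror-invariant — a more stable
flip canonicalization than choosing an orientation by a center-of-mass
rule, which can flip for near-symmetric content. A coarse 8-bin-per-channel
color histogram (weighted so it contributes less than the structure part)
adds color evidence. The vector is L2-normalized; cosine similarity is the
retrieval score.

This descriptor is robust in the ranking sense to rescaling, mirroring,
recompression, mild color shifts and moderate crops. A convolutional
backend can be plugged in as a plain function (`describePanel(...,
backend = "conv", convFn = ...)`) where a pretrained network is available;
descriptor learning itself is out of scope.

## Pixel-level verification

Interest points come from a difference-of-Gaussians scale space (3 layers
per octave, base sigma 1.6, 2x initial upsampling) with sub-pixel
refinement, contrast threshold 0.04 and edge-response threshold 10, and
128-dimensional 4 x 4 x 8 gradient-orientation descriptors. One deliberate
departure from common practice: pixel reads outside the image replicate the
border and near-border keypoints are *kept* (the usual border margin is not
applied), because duplication evidence frequently sits at crop boundaries.

Candidate correspondences use brute-force nearest-neighbour matching under
Lowe's ratio test at 0.75 — raw brute force with no filter floods the
robust fit with outliers. The homography is then estimated by a
RANSAC-family robust fit with truncated-quadratic (MSAC) scoring,
reprojection tolerance 3 px, adaptive iteration count (cap 2000, confidence
0.995) and a deterministic sampler seeded per panel pair, followed by two
normalized-DLT least-squares refits on the consensus set. Degenerate
samples (three collinear points on either side) are rejected; a degenerate
or underpopulated fit makes the pair *inconsistent*, never an error.

Because the local features are not mirror-invariant, a failed attempt is
repeated against the horizontally flipped panel (a vertical-axis retry is
configurable); a success there sets `mirrored = TRUE`, and both the stored
homography and the inlier coordinates are mapped back to the unflipped
frame.

After a successful fit, matches are re-collected by *guided matching*:
every keypoint is projected through the homography and paired with the
geometrically nearest keypoint within the tolerance, gated by an absolute
descriptor distance (1.2 on unit-normalized descriptors — unrelated
descriptor pairs sit near sqrt(2)). This recovers correct correspondences,
typically near panel borders, whose ratio-test score was ambiguous, so the
matched region reflects the full shared content. Consistency itself — at
least 20 inliers, or the pair is discarded — is still decided on the
pre-guided robust consensus, so guided matching cannot create consistent
pairs.

## The content-sharing score

For a consistent pair, the directional score of P with respect to R is

    score(P | R) = A(ConvexHull(matched points in P)) / A(P)

and symmetrically for R. One numerical convention matters: matched interest
points mark *pixels*, so each point is dilated by half a pixel in each
direction before the hull is taken and A(P) = W x H. Under this convention
the two canonical cases are exact: corner-to-corner matches on identical
panels score 1.0, and a crop covering half its source's area scores exactly
(1.0, 0.5). Hull areas use the shoelace formula; hull points are clipped to
the panel, so scores never leave [0, 1]. A side with fewer than three
non-collinear points contributes (essentially) zero area.

## The processing-queue loop

Per probe panel P: the queue starts with the top-K same-type,
other-document panels (K = 400); panels are dequeued FIFO; each previously
unexamined pair is verified and, if consistent, both directional scores are
written into the content-shared table. If either score reaches the
threshold (1%, inclusive), the queue expands with the top-L neighbours of
the matched panel (L = 40), again excluding the probe's document and
anything already queued or examined. The loop stops when the queue is empty
or 300 panels have been examined for this probe — dequeued-and-examined
counts include inconsistent candidates. The examined-pair registry is
shared across probes, so each unordered pair is analyzed at most once
globally and the full table build is order-independent in its contents.

Defaults (K = 400, L = 40, cap 300, threshold 0.01, 20 inliers) are the
reference operating point of the method; all are fields of
`retrievalConfig()`.

## Graphs

Panels are linked when the larger of the two directional scores is at or
above the threshold (the inclusive reading is used consistently). Connected
components are found with igraph; each component is pruned to its maximum
spanning tree by Kruskal's algorithm on descending weights, with ties
broken by the lexicographically smaller (from, to) pair — igraph's own
spanning-tree routine is minimum-only and does not document tie order, and
cross-platform determinism is a hard requirement here. The undirected edge
weight is the larger directional score, so a complete crop reuse weighs
1.0. Trees, components and tables export to JSON (lossless round trip),
GraphML and DOT.

At the document level, the matrix cell d(i, j) counts suspicious panel
*pairs* between documents i and j (counting pairs rather than distinct
panels preserves additivity with the panel table); documents are linked
when d >= 1, with the same component/spanning-tree treatment on integer
weights.

## Evaluation metrics

Content pairing: link precision LP (correct predicted links over predicted)
and recall LR (over annotated), combined as the harmonic mean
CP = 2 LP LR / (LP + LR). Content grouping: predicted groups (components)
are assigned to annotated categories greedily by largest member overlap,
each category used once; NP averages overlap/|group| over predicted groups,
NR averages overlap/|category| over categories, CG is their harmonic mean.
Greedy assignment is used because the metric's source describes no
assignment rule; on realistic predictions (partitions close to the truth)
it coincides with exhaustive best matching, which the test suite verifies.
Content classification: set precision/recall of the suspicious set (all ids
in any provenance graph) with harmonic mean CC. All harmonic means are
defined as 0 when both arguments are 0. Truth links are derived from
category labels as all within-category cross-document pairs.

## The synthetic corpus generator

`generateCorpus()` builds a corpus that emulates the structure of a
paper-mill collection planted among distractors: compound figures laid out
as panel grids with white gutters, five procedural panel types (textured
blob fields for microscopy; low-entropy smoothed bands for blots; smooth
gradient shapes for body imaging; sparse scatter on white for flow
cytometry; axes and bars for charts), and reuse groups whose instances are
distributed round-robin across the designated mill documents under recorded
transformation chains. The default chain — central crop to 75% of the area,
rescale 0.75–1.3, mirroring with probability 0.5, small color shift,
Gaussian noise (sigma 0.008), JPEG recompression at quality 85 — stays
inside the robustness envelope the descriptors and matcher are designed
for, not at adversarial extremes. The standard study corpus is 30
documents (5 mill) with 2 figures per document and 4 panels per figure,
and three reuse groups (two microscopy, one flow cytometry); body-imaging
panels appear only as distractors and blots are not used for planted reuse,
mirroring where this family of methods is known to be weak. Everything —
figure PNGs, optional one-figure-per-page PDFs, and the `truth.json`
annotation (per-panel boxes, types, group labels, suspicious sets, exact
transformation parameters) — is a pure function of the spec and its seed.

What passing on this corpus does *not* show: procedural textures are richer
in stable keypoints than real low-entropy imagery (especially real Western
blots), JPEG artifacts here come from one recompression rather than a
publishing pipeline, and panel boxes are exact rather than detector output.
Results on the synthetic corpus certify the pipeline's mechanics, not its
real-world recall.

## Numerical choices and degenerate inputs

- Grayscale is ITU-R BT.601 luma everywhere.
- Coordinates are 0-based with origin top-left; boxes are half-open on
  their max edges; panel ids are assigned in reading order (row-bucketed by
  vertical overlap, then left to right) over the full detected box set, so
  ids are a pure function of the figure and its boxes.
- Retrieval ties are broken by panel id, spanning-tree ties by edge id
  order, and the robust fit is seeded per pair from a hash of the pair ids
  plus the configured base seed — three places where determinism would
  otherwise be platform-dependent.
- Zero keypoints, empty retrieval sets, empty tables and zero-entry
  matrices all flow through as empty results, not errors; the only hard
  errors are contract violations (scoring an inconsistent match, unknown
  panel ids, non-disjoint predicted groups, missing document metadata).
- Duplicate detector boxes are collapsed at IoU > 0.8 keeping the higher
  confidence; panels below 64 x 64 px are dropped (the minimum-size filter
  plays the role of the icon/label suppression stage).

## Problem sizes

The test suite exercises the full pipeline on the 30-document study corpus
(about 200 panels after filtering, roughly 6,000 verified pairs) plus a
10-document corpus for unit tests; robust-matching properties are checked
over 50 planted transformation pairs and 50 unrelated pairs; graph
construction is compared against brute-force oracles on hundreds of random
graphs of up to 7 nodes (spanning-tree enumeration) and 30 nodes
(components). These sizes keep a full run in a few minutes on one CPU while
covering every operation.

## Limitations

- The panel-type detector ships with an annotation backend and a gutter
  heuristic; the learned backend is an interface for externally supplied
  models, and no trained weights are included.
- Western-blot-like low-entropy content yields few interest points; pairs
  of such panels can fall below the 20-inlier rule and be missed — a known
  weakness of keypoint-based verification that the synthetic corpus
  reproduces by design.
- The provenance graphs are undirected: the method identifies shared
  content and its hubs but does not infer which panel is the ancestor.
- Scores quantify matched-region coverage, not intent; links must be
  reviewed by a human analyst, since legitimate, properly cited reuse also
  produces links.
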