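---
title: "Methods: laminar mapping of tau tangles and ghost tangles in cleared cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar mapping of tau tangles and ghost tangles in cleared cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Neurofibrillary tangles of hyperphosphorylated tau begin inside a neuron and
can outlive it: once the host neuron dies, the extracellular aggregate that
remains is a *ghost tangle*. In volumetric images of cleared human cortex,
stained for tau (AT8), neurons (HuD) and nuclei (DAPI), a ghost tangle is
operationally an AT8-positive object whose segmented volume shares **zero**
voxels with every segmented neuron and every segmented nucleus. Because ghost
tangles are rare (tens among thousands of tangles), the analysis must segment
hundreds of thousands of objects reliably, match them across channels, place
each in a cortical layer, and only then ask statistical questions about their
laminar distribution.

`tanglescape` implements that post-imaging analysis end to end, together with
a synthetic six-layer cortex generator that plants a known scene so that
every stage is testable without any microscope data.

# Pipeline model and assumptions

1. **Per-plane percentile normalization.** Light-sheet and confocal volumes
   lose intensity with imaging depth. Each z-plane is rescaled so that its
   `low_pct` percentile maps to 0 and its `high_pct` percentile maps to 1
   (defaults 0.01 and 0.998), clipped to [0, 1]. Percentiles are robust to
   the sparse, very bright objects that dominate tau planes, which is why a
   percentile anchor is used rather than mean matching. The anchors are
   computed over *all* voxels of a plane (no mask exists before
   segmentation). One consequence, deliberate and tested: on a noiseless
   image whose foreground occupies less than the upper-tail mass
   `1 - high_pct` of a plane, both anchors fall on the constant background
   and the plane maps to zero by the degenerate-spread rule. With real
   (noisy) data the spread is never zero.

2. **Trainable pixel classification.** A random forest (100 trees, seeded)
   is fit on sparse "brush" annotations — voxels labelled `signal` or
   `background` — over a 16-feature multiscale stack: raw intensity plus
   Gaussian smoothing, Gaussian gradient magnitude, Laplacian of Gaussian,
   and the largest and smallest Hessian eigenvalues, each at scales
   sigma = 0.7, 1.6, 3.5 voxels (five filter families x three scales + raw).
   Filters are separable with reflecting borders; Hessian eigenvalues come
   from the closed-form solution for symmetric 3x3 matrices. The scales
   follow common trainable-segmentation defaults; the feature count was kept
   at 16 for speed.

3. **Thresholding and blockwise labelling.** Voxels with signal probability
   at or above 0.5 become foreground. Connected components are labelled
   under 26-connectivity (the usual choice for 3D cell data) per processing
   block of (20, 500, 500) voxels in (z, y, x), then merged across block
   faces by union-find, which is provably equivalent to one global pass —
   the test suite checks equality against an independent graph-based oracle
   and across arbitrary partitions. Components below `min_voxels = 30` are
   discarded as sub-nuclear debris. Both threshold and minimum size are
   exposed in the run config.

4. **Object features and classification.** Each object gets size (voxels
   and um^3 via the voxel spacing), centroid, bounding box, intensity
   statistics, and three shape scores designed for the two taxonomies
   (`noise`/`single`/`cluster` for cells and nuclei;
   `noise`/`incomplete_circle`/`complete_circle`/`solid` for tau):

   * `sphericity` — surface proxy (boundary-voxel count) against the
     volume-equivalent sphere;
   * `ring_score` — mean intensity of the object's shell divided by the
     mean intensity of the spatial region within 0.5 equivalent radii of
     the centroid. A hollow ring has a background-level core, so it scores
     high; a solid object scores about 1. The core region is taken from the
     intensity image rather than from object voxels, because a hollow
     object has no voxels of its own in the core;
   * `angular_coverage` — fraction of 36 azimuthal bins of the object's
     z-projection containing foreground, measured about the *underlying
     circle centre*. The centre is estimated by iterating a Kasa algebraic
     circle fit on the outer-radius pixels (6 iterations, outer 20% band),
     because the centroid of an incomplete circle lies inside its own mass
     and would see nearly the full azimuth. With 36 bins, small lattice
     objects (radius below about 7 voxels) cannot populate every bin, so
     complete shapes saturate slightly below 1; the classifier uses the
     score comparatively and this does not affect discrimination.

   A seeded random forest maps features to classes. Training requires at
   least one example of every class in the taxonomy.

5. **Exclusion filters.** Objects classed `noise` or `cluster` are excluded
   rather than split, as are objects above a size cutoff: 5000 for DAPI
   (read literally as "above", i.e. strictly greater; size exactly at the
   cutoff is kept) and 20 000 um^3 for HuD. The DAPI cutoff's unit is not
   fixed by its source and is treated as um^3, configurable; the HuD
   merged-neuron cutoff is likewise configurable and flagged as
   underdetermined.

6. **Colocalization and ghost detection.** Overlaps are counted voxelwise
   on the segmented label masks. Every AT8 object links to the HuD and DAPI
   objects of maximal overlap (ties to the lower id); HuD links to DAPI the
   same way. The ghost criterion is strict zero overlap with *all* HuD and
   *all* DAPI objects — a single shared voxel disqualifies. No dilation or
   smoothing tolerance is applied: the criterion is defined on raw
   segmentation voxels, not on smoothed surfaces.

7. **Layers, densities, thickness.** An object's layer is the mask value at
   its centroid voxel (0 = outside; excluded from laminar statistics); a
   majority-voxel vote is available as an option for boundary straddlers.
   Neuron density per layer divides kept single HuD objects by the layer's
   mask volume in mm^3; non-neuron nuclei are kept single DAPI objects not
   matched to any HuD object; tau burden is the per-layer tangle count as a
   percent of all layered tangles. Cortical thickness is measured by
   sampling `n_lines >= 2` random (z, x) columns and taking mean and
   standard error of the labelled y-extent, emulating repeated ruler lines
   from the pial surface.

8. **Statistics.** Laminar enrichment of ghosts uses the 2x2 table
   (ghost status x layers {3,5} vs others): cross-product odds ratio with a
   Woolf (log-normal) interval, Haldane–Anscombe +0.5 on all cells when any
   cell is zero, and Pearson's chi-squared without continuity correction.
   The Woolf interval was chosen because it yields the familiar asymmetric
   interval on the OR scale; the continuity correction is omitted to match
   common large-sample practice. Group comparisons use Student's two-sample
   t (Welch by flag) and one-way fixed-effects ANOVA, with pairwise t-tests
   across group pairs (resolving the ambiguous "multiple paired tests" as
   pairwise comparisons), alpha = 0.05 reported alongside. The percent
   density decrease is `100 (mc - ma) / mc` with a first-order delta-method
   standard error; a bootstrap oracle checks it in the tests. Cell-size
   models are linear mixed-effects fits (REML, via lme4):
   `size ~ AT8 status + layer + (1 | donor)` with treatment contrasts and
   layer 1 as the reference level (the coding had to be fixed somewhere;
   layer 1 is the natural first level).

# The synthetic cortex generator

The generator is first-class, tested code; its defaults define the study
conditions every acceptance-style check runs under.

* Six layers are slabs orthogonal to the y axis (pial surface at y = 0),
  with thickness fractions (0.10, 0.10, 0.25, 0.10, 0.25, 0.20) — a
  plausible laminar profile for association neocortex.
* The default grid is 48 x 320 x 160 voxels (z, y, x) at 1 um spacing,
  about 2.5 million voxels. This size keeps a full multichannel pipeline
  run in the minutes range while holding 500 neurons; it is a scaled-down
  slab, chosen once, not a tuning knob.
* 500 neurons are placed across layers (30, 90, 130, 80, 110, 60) by
  rejection sampling with a hard-core constraint (no soma–soma overlap,
  minimum surface gap 2 um, 1000 retries per object before an explicit
  per-layer failure). Somata are ellipsoids with base radius 3.5–5.5 um and
  15% anisotropy — scaled with the slab, small enough to pack, large
  enough to segment. Each soma contains one nucleus (radius 1.8–2.8 um,
  strictly inside).
* Each neuron hosts a tangle with a per-layer probability
  (0.02, 0.08, 0.18, 0.08, 0.28, 0.10): tangles peak in layer 5, then
  layer 3, the laminar profile characteristic of tau pathology in the
  inferior temporal gyrus. Per-layer counts of hosted tangles are Bernoulli
  draws, so only their expectation is fixed. Tangle morphology mixes
  solid : ring : partial at 0.5 : 0.3 : 0.2 (shell from 0.55 R to R;
  partial shells lose an azimuthal wedge of 35–55%).
* Ten ghost tangles are planted at (0, 1, 3, 1, 4, 1) across layers —
  concentrated in layers 3 and 5 like the real phenomenon — with at least
  3 um clearance from every soma and nucleus, so the zero-overlap
  criterion is unambiguous after rendering and segmentation.
* Rendering: background 100, foreground 1000 (arbitrary units), each
  z-plane attenuated by exp(-0.01 per um x depth), then Poisson shot noise
  (scale 1) and Gaussian read noise (sd 20). The SNR is deliberately high:
  at these settings a segmentation failure indicates a code bug, not an
  ambiguous image; noise and attenuation knobs exist for stress tests.
* Brush annotations for classifier training are sampled from the clean
  foreground masks (200 voxels per class by default), emulating manual
  paintbrush strokes with a perfectly informed annotator.

**What the generator does not emulate** — and hence what passing tests do
not show about real tissue: optical point-spread blur, light-sheet striping,
vasculature and glial morphologies, staining texture and antibody
variability, touching cells (the hard-core constraint forbids them), and
partial-volume mixing at object borders beyond voxelization. Clean scenes
also contain no true `noise` or `cluster` objects, so the orchestrated
pipeline classes segmented objects by their ground-truth correspondence
(overlapping 0 / 1 / >1 planted objects maps to noise / single / cluster)
and records that in the report; the supervised object classifier itself is
exercised and audited on labelled feature tables in the test suite.

# Numerical choices and degenerate inputs

* Axis order is (z, y, x) everywhere; 0-based voxel index times spacing
  gives physical um. One convention, asserted at module boundaries.
* Normalization of a zero-spread plane returns zeros (not NaN).
* Labelling of an empty foreground returns an empty label volume, not an
  error; blocks larger than the volume degenerate to a global pass.
* Ties in colocalization overlap break to the lower object id, making
  matching deterministic under label permutation.
* The odds ratio fails loudly if a whole row or column is empty even after
  Haldane correction; the chi-squared fails on a zero marginal.
* ANOVA on groups with zero within-group variance and equal means defines
  F = 0, p = 1 (the variance ratio limit), rather than NaN.
* The mixed model refuses a single donor (the random effect is
  unidentifiable) and points to a fixed-effects fallback.
* Cortical-thickness lines that miss the labelled band are resampled, with
  a retry guard; n_lines = 1 is refused because a standard error needs two.
* All random stages (placement, noise, brush sampling, forests, thickness
  lines) flow from explicit integer seeds; identical seeds give
  byte-identical outputs, which the suite asserts.

# Problem sizes

The test suite runs most modules on 24 x 96 x 64 scenes (about 150 000
voxels, 30 neurons) and the end-to-end audit on the default
48 x 320 x 160 scene (500 neurons, about 70 tangles, 10 ghosts). Mixed-model
recovery uses 50 simulations of 6 donors x 2000 cells. The enrichment
estimator check simulates 8050 + 57 tangles per replicate for 200
replicates. These sizes are the package's chosen balance between
statistical resolution and a test suite that runs in minutes.

# Known limitations

* Equivalence with interactive segmentation tools is functional, not
  numerical: the exact feature sets and annotations of a trained human
  session are not reproducible.
* The ghost criterion is defined on raw segmentation voxels; a pipeline
  that smooths surfaces before overlap testing could classify borderline
  objects differently.
* Layer assignment by centroid misplaces objects straddling a boundary;
  the majority-vote option mitigates but cannot remove this.
* The laminar profile of non-ghost tangles is qualitative (peak in layer 5,
  then 3); per-layer counts are not calibrated to any measured table.
* Absolute tissue-scale counts (thousands of tangles, hundreds of
  thousands of cells) require the original imaging volumes; the package's
  claims at that scale are property-based and synthetic-recovery claims,
  not reproductions.
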