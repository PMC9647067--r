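---
title: "Methods: 3D methylation image cytometry with qdmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D methylation image cytometry with qdmi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qdmi)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what a passing test suite does and does not
establish. Nothing here states an empirical result that the tests or
`scripts/acceptance.R` do not themselves compute.

## The measurement model

Global DNA hypomethylation in cancer is concentrated in repeat sequences
that reside in compact heterochromatin — the same chromatin that binds DAPI
most strongly. A two-channel 3D stack (DAPI for genomic DNA, antibody
fluorescence for 5-methylcytosine) therefore carries a per-nucleus signature:
the joint distribution of voxelwise (DAPI, 5mC) intensities. The pipeline
operates in three steps:

1. **3D segmentation** of nuclei from the DAPI channel, each object keeping
   a numerical identifier so every downstream number is traceable to one
   nucleus.
2. **Per-nucleus parameters**: (a) the global 5mC intensity, integrated over
   the nucleus, and (b) the 5mC/DAPI codistribution and its regression
   angle. Both channels are first rescaled by the full detector range
   (2^bit_depth − 1; 12-bit typical). 5mC is regressed on DAPI (DAPI on the
   x-axis) by ordinary least squares with an intercept, over all voxels of
   the nucleus; the colocalization index is δ = arctan(slope) in degrees.
   The intercept is included so that uniform background offsets cannot
   masquerade as methylation signal; δ uses the slope only.
3. **Population similarity**: each nucleus's codistribution histogram is
   scored against the count-weighted composite of the imaged population by
   Kullback–Leibler divergence, D(cell ‖ composite) in bits, and binned
   into four soft-qualifiers (similar / likely similar / unlikely similar /
   dissimilar → green / blue / yellow / red).

Assumptions inherited from the acquisition regime: near-identical microscope
settings across images of a batch (δ is *not* invariant to a single-channel
gain change — the test suite demonstrates this deliberately), plane-sequential
TIFF export, and anisotropic voxels (finer laterally than axially; the
defaults are 189 × 189 × 500 nm).

### Interpreting δ

If 5mC tracked DNA density one-for-one at equal channel gain, the
codistribution would lie on the diagonal and δ = 45°. Proportional loss of
5mC tilts the regression down (δ ≈ arctan of the retained fraction when the
coupling is strong), and *decoupling* — 5mC no longer co-varying with DNA
density — flattens it further. Nuclei with δ below 15° are flagged
aberrantly hypomethylated; the cutoff is exposed as a parameter everywhere
it is used.

### Two open readings resolved

* *Regression on voxels or on the binned heat map?* Both are provided;
  voxelwise OLS (`codistribution_index()`) is the default because it has no
  binning bias, and `codistribution_index_binned()` exists for the display
  route. A property test keeps them in agreement at fine binning.
* *Integrated or mean 5mC?* Both are reported per nucleus (`mc5_total`,
  `mc5_mean`); integrated intensity is what population reductions use.

## Segmentation

The pipeline is deliberately conventional and fully deterministic:
Gaussian pre-smoothing (σ 200 nm lateral / 400 nm axial) → global Otsu
threshold (fixed threshold available) → 3D hole filling (6-connected
background components not reaching any face) → 26-connected labeling →
optional watershed split of touching objects → volume filter (default
minimum 30 µm³) → optional removal of objects touching the lateral image
border. Objects cut by the top/bottom z-planes are *kept* by default: thin
confocal stacks truncate most nuclei axially, and discarding them would
bias sampling; the behavior is configurable.

The watershed runs on the anisotropic exact Euclidean distance transform,
flooding from seed maxima by descending distance; ties resolve toward the
lower seed label (seeds are enqueued in ascending label order with FIFO
tie-breaking), so results are reproducible voxel for voxel.

**Seed selection.** Candidate seeds are local maxima of the lightly
smoothed distance transform, accepted greedily in descending order subject
to (a) a minimum mutual separation of 1 µm and (b) a *saddle criterion*:
the distance profile along the line to the nearest accepted seed must dip
at least h = 0.4 µm below the candidate. Criterion (a) alone oversplits
single eccentric ellipsoids — an ellipsoid with semi-axes 2.8 and 2.2 µm
has a medial ridge about 1.1 µm long, so two ridge maxima can exceed the
1 µm separation while belonging to one nucleus. The saddle criterion
rejects such candidates (along a ridge the profile never dips), while two
genuinely touching nuclei joined by a thin neck pass easily (the neck
distance is far below either center's). Both constants are parameters of
`seg_params()`.

## The synthetic world

No images are published for this method, so the generator *is* the test
bed, and its defaults are the stated world of the acceptance criteria — they
were chosen once, from the acquisition geometry and the printed
population-level contrasts, and are not adjusted to make tests pass.

Per nucleus, the DAPI texture is `T = 1 + (focus_contrast − 1) · F`, where
`F` sums 3–8 Gaussian heterochromatic foci (sd 0.4 µm, centers well inside
the ellipsoid) over a unit euchromatin baseline; the DAPI channel is
`base · T` (base 800 detector units, 12-bit range). The 5mC channel is

```
5mC = base · mc5_scale · ( c · T  +  (1 − c) · R )
```

with `R` a PSF-smoothed white-noise field rescaled, within the nucleus, to
the mean and variance of `T`. Because `R` matches the mean of `T`, the
mixture preserves the expected 5mC load at every coupling `c`, so
`mc5_scale` alone controls the population reduction while `c` alone
controls decoupling (and hence δ ≈ arctan(mc5_scale · c) before noise).
Both channels are blurred by an anisotropic Gaussian PSF (σ 150/150/350 nm)
and then noised identically: Poisson photon noise (gain 1.0) plus Gaussian
read noise (sd 2% of the amplitude), clipped to the dynamic range. A single
RNG seed drives every draw, so stacks are bit-reproducible.

The class presets are calibrated to the three printed contrasts:

| preset               | mc5_scale | coupling | emulates                                     |
|----------------------|-----------|----------|----------------------------------------------|
| `normal`             | 1.00      | 0.95     | normal bronchial epithelium                  |
| `a549_like`          | 0.80      | 0.85     | adenocarcinoma-like, ~20% reduced load       |
| `h157_like`          | 0.35      | 0.45     | aggressive carcinoma, 65% reduced load       |
| `aberrant_decoupled` | 0.15      | 0.10     | severely hypomethylated, decoupled (δ < 15°) |

Ground truth records, per nucleus: class, center, semi-axes, the coupling
parameters, and the integrated DAPI/5mC of the *blurred, noise-free* field
over the truth label voxels — blur precedes noise in the forward model, so
this is the exact conservation target the tests check.

Geometry defaults: a 256 × 256 × 24 voxel field at the paper-typical voxel
size, 10 nuclei per stack (populations of 100 span 10 stacks), semi-axes
2.5 ± 0.3 µm drawn per axis, placed uniformly without overlap (center
distance > sum of the largest semi-axes + 1 voxel), fully inside the grid.
A 100 + 100-nucleus contrast runs in about a minute and a half on one CPU.

When two populations are generated from the same base seed, all geometric
and textural draws coincide (class parameters only multiply the 5mC field,
and noise is drawn last), so preset contrasts are measured on matched
geometry — this is how the 20%/65% reductions are recovered within a
fraction of a percentage point despite n = 100.

**What the generator does not emulate:** chromatin polymer structure,
spectral crosstalk, axial PSF asymmetry beyond the anisotropic Gaussian,
uneven illumination, mitotic figures, overlapping or z-truncated nuclei,
and the cytoplasm/cytokeratin channels real specimens carry. A green test
therefore establishes that the *algorithms* recover known parameters from
realistic-looking data — not that the biological effect sizes would be
reproduced from patient material.

## Numerical choices

* **Histograms**: 64 bins per axis by default (12-bit range / 64 ≈ stable
  occupancy for the 10³–10⁴ voxels of one nucleus); edges are fixed to the
  full dynamic range, never data-driven, and the top bin is closed, so
  histograms are comparable across nuclei and images.
* **KL smoothing**: pseudocount ε = 0.5 is added to every *raw count* of
  both histograms before normalizing (Jeffreys-style), keeping scores
  finite on empty bins. A consequence worth knowing: because the cell and
  the composite have different totals, a cell identical in *shape* to the
  composite still scores slightly above zero; scores are comparable within
  a population of similar-sized nuclei, which is how they are used.
  Logarithms are base 2; scores are in bits.
* **Similarity thresholds**: the score-to-qualifier cutoffs of the original
  software are unpublished, so the package calibrates its defaults on the
  simulator, as specified: thresholds were chosen once — before the test
  suite was frozen — so that a homogeneous normal population classifies
  ≥ 80% similar + likely similar, and decoupled spike-ins separate cleanly.
  On this generator (64² bins, ε = 0.5, ~50-nucleus populations) normal
  cells score ≈ 0.9–2.1 bits and decoupled aberrant cells ≥ 3 bits, giving
  defaults (t1, t2, t3) = (1.2, 1.7, 2.6) bits. A quantile mode
  (25/50/75th percentiles of the population's own scores) is available when
  absolute calibration does not transfer. Boundary scores take the more
  similar class (≤ semantics).
* **Color mapping**: the four qualifiers map to green/blue/yellow/red in
  that order. The source material is internally inconsistent about
  green/blue in one figure legend; the Methods-section mapping is adopted.
* **Degenerate inputs**: all-background thresholding yields an empty
  labeling with a warning (not an error); a single-nucleus population is
  scored against itself with a warning (KL 0); zero DAPI variance makes the
  regression undefined and errors; background (label 0) is never a valid
  nucleus id.
* **Determinism**: identical configs produce byte-identical result tables
  (fixed `%.6g` formatting, binary-mode writes); run manifests record a
  parameter digest.

## Package-level choices

* TIFF I/O is implemented in the package (baseline uncompressed grayscale,
  8/16/32-bit, multi-page, both byte orders) because the runtime carries no
  TIFF-capable R package; an embedded description block persists channel
  names, voxel size and bit depth across round trips. Compressed or
  proprietary microscope formats are out of scope; an independent Python
  reader is used as a cross-check in the tests only.
* 3D morphology (26/6-connected labeling, exact anisotropic Euclidean
  distance transform, seeded watershed, local maxima) is compiled C++
  (Rcpp), as is usual for voxel-level image analysis in R; Gaussian
  blurring is separable dense matrix multiplication in base R (BLAS).
* Configuration files for the CLI are YAML (the environment provides no
  TOML parser); the CLI verbs mirror the pipeline stages.

## Known limitations

* δ compares only against a same-batch acquisition: any change in relative
  channel gain between images shifts δ systematically.
* The absolute KL thresholds are calibrated to this simulator's nucleus
  size and bin count; real data should use `quantile_mode` or a dedicated
  calibration population.
* The segmentation is classical; densely packed tissue with touching,
  truncated nuclei will need the watershed parameters (and possibly a
  learned method outside this package's scope) tuned per specimen.
* Reduction percentages are ratios of mean integrated intensities; they are
  unbiased only under matched segmentation behavior across populations,
  which holds on the simulator (identical DAPI statistics by construction)
  and approximately on batch-matched real data.
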