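# qdmi — 3D quantitative DNA methylation image cytometry

`qdmi` is an R package for image cytometry of **global DNA methylation** in
3D confocal stacks. Cancer cells are globally hypomethylated — they lose
5-methylcytosine (5mC), mostly in the repeat-rich, densely packed
heterochromatin that DAPI stains brightest. Immunofluorescence against 5mC,
co-visualized with DAPI, turns that loss into an imaging phenotype: in a
normal nucleus, voxelwise 5mC intensity tracks DNA density; in a
hypomethylated cancer nucleus it does not. The package quantifies this per
nucleus and per population, so that aberrant cells can be flagged in
heterogeneous specimens (cultured lines, tissue sections, exfoliated sputum
cells) without destroying them.

It is aimed at microscopists and image-analysis scientists who have
two-channel (DAPI + 5mC) z-stacks and want per-cell methylation phenotypes
with a fully testable, scriptable pipeline.

## What is computed

For every segmented nucleus *k* with voxel intensity pairs
(DAPI_i, 5mC_i), both rescaled to [0, 1] by the detector range
2^bit_depth − 1:

* **Global 5mC load** — the integrated (and mean) 5mC intensity over the
  nucleus: `mc5_total = Σ_i 5mC_i`.
* **5mC/DAPI codistribution** — the joint 2D histogram of (DAPI, 5mC)
  intensities (the per-nucleus "scatter plot"), on fixed full-range bins.
* **Colocalization index δ** — ordinary least squares of 5mC on DAPI
  (intercept included) over all voxels gives slope β̂; the index is
  `δ = arctan(β̂)` in degrees. δ ≈ 45° when 5mC rises one-for-one with DNA
  density at equal channel gain; δ → 0° when 5mC is depleted or decoupled.
  Nuclei with δ < 15° are flagged aberrantly hypomethylated.
* **Similarity score** — the Kullback–Leibler divergence (bits) of each
  nucleus's codistribution from the population composite,
  `D(cell ‖ composite) = Σ p log2(p/q)` after pseudocount smoothing, mapped
  onto four soft-qualifiers rendered as a map: green (similar), blue
  (likely similar), yellow (unlikely similar), red (dissimilar).

Populations are compared by the percent reduction of mean integrated 5mC,
`100 × (1 − mean(test)/mean(normal))`, and a two-sided rank-sum test on δ.

Because no public image data accompany this method, the package ships a
**synthetic stack generator** with known ground truth: ellipsoidal nuclei
with bright heterochromatic DAPI foci, a 5mC channel coupled to the DAPI
texture by a tunable coupling weight and amplitude scale, Gaussian-PSF
blur, and Poisson + Gaussian noise. Four presets emulate the calibration
classes: `normal`, `a549_like` (~20% reduced 5mC load), `h157_like`
(65% reduced), and `aberrant_decoupled` (severely reduced and decoupled,
δ < 15°). Every pipeline stage is tested against this generator and
against independent brute-force oracles.

## Worked example

Simulate a mixed field (8 normal + 2 severely hypomethylated nuclei),
segment, extract features, classify:

```r
library(qdmi)

cfg <- sim_config(n_nuclei = 10, seed = 7,
                  class_mix = c(normal = 0.8, h157_like = 0.2))
sim     <- generate_stack(cfg)
labels  <- segment_nuclei(sim$stack)
records <- analyze_stack(sim$stack, labels)
cl      <- classify_cells(records)

# trace detected objects back to the simulated class via center containment
id_at_center <- labels$labels[cbind(sim$truth$center_z + 1,
                                    sim$truth$center_y + 1,
                                    sim$truth$center_x + 1)]
true_class <- sim$truth$class[match(cl$records$nucleus_id, id_at_center)]
cl$records[, c("nucleus_id", "mc5_total", "delta_deg", "kl_score",
               "similarity_class")]
```

```
   nucleus_id mc5_total delta_deg kl_score similarity_class
1           1   2073444     43.89   1.0793          similar
2           2   3140731     43.58   0.6939          similar
3           3    866511     11.89   2.1429 unlikely_similar
...
10         10   1087515     10.98   2.1020 unlikely_similar
```

The two simulated `h157_like` nuclei (rows 3 and 10) stand out exactly as
the method intends: collapsed 5mC load, flat regression (δ ≈ 11° < 15°,
aberrant), and the highest KL scores of the field.

```r
print(cl$profile)
#> PopulationProfile: 10 nuclei
#>   thresholds (bits): 1.2 / 1.7 / 2.6
#>   similar           8 (green)
#>   ...
#>   homogeneity fraction: 0.800

compare_groups(cl$records[true_class == "normal", ],
               cl$records[true_class == "h157_like", ],
               names = c("normal", "h157_like"))
#> GroupComparison: normal vs h157_like
#>   normal     n=  8  mc5_total 2.931e+06 +/- 4.23e+05  delta 43.6 +/- 0.138 deg  aberrant 0 (0.0%)
#>   h157_like  n=  2  mc5_total 9.77e+05 +/- 1.56e+05  delta 11.4 +/- 0.64 deg  aberrant 2 (100.0%)
#>   reduction of mean 5mC load: 66.67%
#>   rank-sum test on delta: W=16, p=0.0502
```

Real stacks enter through `read_stack("stack.tif", c(DAPI = 0, "5mC" = 1))`
(multi-page TIFF or a directory of per-plane TIFFs), and `run_pipeline()`
drives everything from one `run_config()`, writing a TSV result table,
per-stack similarity-map PNGs, and a YAML run manifest.

A command-line interface mirrors the pipeline:

```sh
exec/qdmi simulate --config sim.yaml --out simdir
exec/qdmi segment --in simdir/stack.tif --out labels.tif
exec/qdmi analyze --stack simdir/stack.tif --labels labels.tif --out results.tsv
exec/qdmi similarity --results results.tsv --labels labels.tif --out map.png
exec/qdmi compare --a normal.tsv --b tumor.tsv
```

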