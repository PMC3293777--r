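# mitoseg

Automatic segmentation of mitochondria in serial block-face scanning
electron microscopy (SBFSEM) volumes.

SBFSEM images large tissue blocks at ~10 nm XY resolution but with 50–70 nm
Z steps, so stacks are anisotropic and Z-sparse. Mitochondria appear as
dark, internally striped (cristae) bodies in a background crowded with
equally dark membranes and vesicles — neither plain intensity thresholding
nor a generic edge-driven active contour works. `mitoseg` implements a
three-step pipeline that separates the problem into texture, shape and
smoothness:

1. **Patch classification** — a random forest on raw 11×11 pixel patches
   produces a per-voxel mitochondria probability map
   (`P(mito | patch) = ` fraction of trees voting positive).
2. **Contour-pair classification** — isocontours of the map are extracted
   at 7 levels (12%–96% of the map maximum), size-filtered to perimeters in
   [0.6, 6] μm, and described by 7 features (perimeter, mean gray on the
   contour, mean probability inside, area, ellipse overlap, ellipse width
   and height). Contours on adjacent planes with centers closer than
   D = 0.4 μm form pairs; a second forest scores each 22-feature pair
   vector `[f(a), f(b), ‖c(a) − c(b)‖, f(a) − f(b)]`, and pairs with
   probability below a threshold `T` are eliminated. `T` is chosen on a
   7/7 slice split of the training data by minimizing
   `E = α·FPR + β·(1 − TPR)` with α = 7, β = 1 over
   T ∈ {0.05, 0.10, …, 1.0}.
3. **Seeded level set** — interiors of the surviving contours, eroded by a
   10-pixel disc, seed a 3D geodesic active contour (advection 160,
   curvature 6.75, propagation 1) evolved on an edge potential derived
   from the probability-map gradient, yielding smooth 3D bodies and
   filling planes where a contour was wrongly eliminated.

The package also provides stack I/O with physical voxel spacing (multipage
TIFF or per-slice PNG), a synthetic EM phantom generator with exact ground
truth, pixel-level ROC evaluation, and Z-slab processing for large volumes.
Everything is testable at desk scale without microscope data.

## Worked example

```r
library(mitoseg)

# a synthetic EM-like volume with ground truth: dark striped organelles,
# membrane and vesicle confusers, Gaussian noise
ph  <- generate_phantom(phantom_params(shape = c(14, 160, 160),
                                       n_organelles = 4,
                                       organelle_axes_xy_um = c(0.15, 0.30),
                                       organelle_axes_z_um  = c(0.10, 0.20),
                                       n_membranes = 4, n_vesicles = 25,
                                       n_blobs = 2, seed = 11))

cfg <- mitoseg_config(n_pos = 250, n_neg = 350, rf_trees = 60, seed = 11)
fit <- mitoseg(ph$intensity, ph$label, cfg, select_T = FALSE)
fit
#> <mitoseg> three-step segmentation pipeline
#>   patch model:   11x11 raw patches, 60 trees (OOB AUC 0.988)
#>   contour model: M = 2, trained on 256+/988- examples
#>   threshold T:   0.25 (configured)

seg <- predict(fit, ph$intensity)          # binary label volume
round(metrics(confusion(seg, ph$label)), 3)
#>      tpr      fpr accuracy
#>    0.969    0.007    0.992
```

`fit` reports the patch classifier's out-of-bag ROC AUC (0.99: the forest
separates cristae texture from background) and the contour training set
(256 ground-truth-salient pairs against 988 negatives, labeled by the
rule that ≥ 90% of a contour's interior must be annotated mitochondrion).
The final metrics are voxelwise on the phantom: 97% of mitochondrial
voxels recovered at a 0.7% false-positive rate, pixel accuracy 0.992.

`predict(fit, vol, type = "all")` exposes the intermediates (probability
map, all detected contours, the salient subset, the level-set labels);
`plot(fit, vol, z = 7, contours = predict(fit, vol, type = "salient"))`
overlays salient contours on a slice. For stacks too large for memory,
`predict(fit, vol, slab_max_z = 15)` processes overlapping Z-slabs and
ORs the results.

A thin command-line wrapper with `synth` / `train` / `segment` /
`evaluate` / `select-threshold` / `split-slabs` subcommands is installed
at `inst/scripts/mitoseg-cli.R`:

```sh
Rscript inst/scripts/mitoseg-cli.R synth --out phantom --seed 1
Rscript inst/scripts/mitoseg-cli.R train --volume phantom/intensity \
        --labels phantom/label --out model.rds
Rscript inst/scripts/mitoseg-cli.R segment --volume phantom/intensity \
        --model model.rds --out seg
Rscript inst/scripts/mitoseg-cli.R evaluate --pred seg/labels --truth phantom/label
```

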