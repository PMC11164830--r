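---
title: "Methods: multi-task image-to-expression prediction for spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task image-to-expression prediction for spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `spotgene`, its
assumptions, the tunable parameters and the reasoning behind their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## The prediction problem

A spatial-transcriptomics (ST) section pairs an H&E-stained slide image
with an N × M counts matrix over N grid-arranged capture spots and M
genes, plus a per-spot binary pathological annotation (1 = tumor). Each
spot corresponds to a square image patch centred on its pixel coordinates.
The package learns a map from the patch to three outputs at once:

1. **target genes** — the m genes with the highest mean (training-split)
   expression, modelled as a multi-output regression (primary task);
2. **non-target genes** — the remaining M − m genes (auxiliary
   regression); they are typically sparse and individually hard to
   predict, but fitting them shapes the shared representation through
   gene–gene co-expression structure;
3. **tumor probability** — a binary classification head.

All heads read one shared convolutional embedding (hard parameter
sharing). The underlying assumptions are (a) morphology carries
expression-relevant signal at patch scale, and (b) adjacent spots inside
one annotated region have similar expression — assumption (b) is exploited
explicitly by the spatial loss below.

## Losses

With B spots in a batch, predictions `ĝ`, truths `g`, labels `y`,
probabilities `ŷ`:

* primary: `L_prim = 1/(mB) Σ (g − ĝ)²` over target genes;
* auxiliary: same form over the M − m non-target genes;
* tumor: mean binary cross-entropy, probabilities clamped to
  `[1e-7, 1 − 1e-7]` before the logs for numerical stability;
* spatial: over all ordered (central spot i, neighbor j) pairs in the
  batch with j in i's 3×3 grid neighborhood and `y_i = y_j`,
  `L_spat = 1/K Σ mean_genes (ĝ_i − ĝ_j)²`, with K the number of such
  pairs and `L_spat = 0` when K = 0.

Total: `L = L_prim + λ L_aux + β L_tmr + γ L_spat`.

Three points here were genuinely open and are resolved as follows:

* **Gene reduction in the spatial term.** For vector-valued predictions
  the squared difference must be reduced over the m genes. The mean (not
  the sum) is the default so that `γ` has the same scale as `L_prim`
  whatever m is; `spatial_reduce = "sum"` is available.
* **Definition of K.** K counts all same-annotation ordered
  (central, neighbor) pairs in the batch, aggregated over central spots.
  When both members of a pair are present each direction is counted,
  which leaves the mean unchanged for symmetric contributions and makes
  the loss manifestly symmetric in (i, j).
* **Which head the constraint touches.** The spatial penalty is applied
  to the target-gene head only: it is motivated as a constraint on the
  primary predictions, and pushing the sparse non-target outputs toward
  regional constancy mostly amplifies their noise. Ground-truth labels
  (not predicted probabilities) decide `w_ij` during training.
* **Loss weights.** λ = β = γ = 1 by default; the terms are roughly
  scale-matched by construction (mean reductions everywhere), and the
  ablation runner exists precisely to examine the toggles.

## Architecture and training

The implemented backbone (`tiny_cnn`) is two convolution blocks
(defaults: 12 then 24 channels, 5×5/3×3 kernels, stride 2, ReLU), global
average pooling, a fully connected shared embedding (default width 32),
and three linear heads; the tumor head ends in a sigmoid. Global average
pooling makes the network independent of patch size, so desk-scale
experiments can use 16–64 px patches while the extraction default remains
224 px. The forward and backward passes are exact, vectorized matrix
computations (convolution as an im2col gather plus one matrix multiply);
the test suite verifies every analytic gradient against central finite
differences at 1e-4 tolerance. A `resnet50` backbone value is recognized
for configuration compatibility but requires externally supplied
pretrained weights and is not shipped.

Training uses Adam (default learning rate 5e-3, chosen so the small
network converges within the ~10-epoch budgets of the bundled
experiments; β₁ = 0.9, β₂ = 0.999). Regression-head biases initialize at
the training-set gene means, which centres the initial predictions and
removes several epochs of bias-only learning. When γ > 0, batches are
built as sampled central spots plus their available grid neighbors
(neighborhood batching) so the spatial term always has in-batch pairs;
with γ = 0 plain shuffled batches are used. Optional augmentation applies
random flips and 90° rotations. When a validation patient exists, the
epoch with the best validation target-gene aPCC is kept (aPCC is the
headline metric, so model selection follows it); early stopping is
available via a patience parameter.

Splits are always at patient level: no spot from a validation or test
patient enters training, the gene-detection filter, the image channel
statistics, or the gene ranking. The partition, channel statistics, QC
thresholds, and normalization constants are frozen into the checkpoint
and reapplied verbatim to new samples at evaluation/prediction time.

## Preprocessing parameters

| parameter | default | meaning |
|---|---|---|
| `min_umi`, `max_umi` | 200, 20 000 | inclusive bounds on per-spot total UMIs ("fewer than 200"/"more than 20 000" are strict exclusions, so the bounds themselves pass) |
| `max_mito_frac` | 0.05 | maximum fraction of counts on genes with the `MT-` name prefix (prefix configurable; name matching is the only mitochondrial signal available in a plain counts matrix) |
| `min_genes_per_spot` | 200 | minimum detected (count > 0) genes |
| `min_spots_per_gene` | 3 | minimum spots in which a gene is detected, counted after spot QC on training spots and applied cohort-wide |
| `scale`, `pseudocount` | 10 000, 1 | counts are divided by the spot total, multiplied by `scale`, and natural-log-transformed after adding `pseudocount`; the transform is exactly invertible given the stored spot totals |
| `window_px`, `out_size_px` | 150, 224 | crop side at the native magnification and the CNN input side (bilinear resize) |
| `m` | 250 | number of target genes, ranked by mean normalized expression of the training split; ties broken by gene name |

Order of operations: boundary exclusion → spot filters → gene filter →
normalization, so gene detection reflects retained spots only. Whether
the top-m ranking should use raw or normalized means is not determined by
convention alone; the default is the normalized layer (the same scale the
losses operate on) and `partition_layer = "raw"` is available, with the
choice recorded in the checkpoint metadata.

Patch geometry: a window of side w centred at pixel (x, y) covers the
half-open intervals `[c − ⌊w/2⌋, c − ⌊w/2⌋ + w)` per axis with 0-based
pixel coordinates (x = column, y = row). This convention is deterministic
for odd and even windows and is what the translation-consistency and
boundary-mask tests assert. Spots whose window exits the slide are
excluded, never padded.

## The synthetic-data generator

`simulate_sample()` emulates the statistical structure the method relies
on, not tissue appearance:

* spots on an `n_rows × n_cols` grid, centre-to-centre spacing equal to
  the patch side so patches tile without overlap and no default window
  exits the slide;
* tumor annotations as the union of disc-shaped blobs in grid space —
  spatially autocorrelated region-level labels of the kind pathologists
  produce (verified in the tests by a permutation test on neighbor label
  agreement);
* patch rendering as a pinkish base texture whose mean intensity, hue,
  and noise scale shift with the latent state, plus a continuous
  per-spot intensity covariate; `image_signal_strength` (0–1) gates every
  image–expression coupling, and at 0 the pixel distribution is provably
  independent of the labels;
* counts drawn per spot and gene from a negative binomial
  (variance μ + μ²/size) with state-dependent means for the coupled
  genes, followed by dropout zeroing.

Default levels: 16×16 grids, 32 px patches, 50 genes of which 10 are
coupled, `nb_mean_normal = 5` vs `nb_mean_tumor = 15` (a 3-fold change,
in the range of strong marker genes in breast-cancer ST sections — the
generator is meant to emulate *strong* morphology–expression coupling, the
regime in which an image model can work at all), dispersion 2 (strongly
overdispersed, as ST counts are), 2% dropout on top of the sampling
zeros, and an intensity-covariate effect of 0.5 log-fold on odd-indexed
coupled genes. Coupling direction alternates by default — half the
coupled genes up in tumor, half down — so that per-spot library size is
state-balanced; a single direction would couple library size, and through
total-count normalization every decoy gene, to the tumor state, making
"noise-only" decoys weakly predictable. Patients in a cohort receive a
lognormal per-gene mean effect (`patient_effect_sd`, default 0.15) as a
simple batch effect.

What the generator does **not** emulate: nuclei, stain variation,
segmentation artefacts, spatial gene–gene correlation beyond the shared
latent state, continuous tumor gradients, or annotation noise. Passing
the recovery tests therefore shows that the pipeline is correct and that
the model can exploit patch-scale signal; it does not certify performance
on real slides, where signal is far weaker and annotations imperfect.

## Problem sizes in the bundled experiments

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
full pipeline (simulation, preprocessing, training, evaluation) exercises
every code path in minutes on one CPU: 3-patient cohorts with two 16×16
sections each (512 training spots), 32 px patches, 50 genes with m = 10,
10 training epochs; unit tests go smaller still (8×8 grids, 16 px). QC
thresholds are scaled alongside (`min_umi = 50`, `min_genes_per_spot = 5`)
because a 50-gene panel cannot meet thresholds written for
transcriptome-wide data.

## Numerical choices and degenerate inputs

* Probabilities clamped at 1e-7 inside the cross-entropy; gradients use
  the algebraically stable `(p − y)/B` form w.r.t. the pre-sigmoid score.
* Genes with zero variance in truth or prediction receive Pearson
  correlation 0 (reported via a message) rather than being dropped, so
  aPCC and NGPC keep fixed denominators across models.
* ACC thresholds the tumor probability at 0.5; AUC/AUPRC are undefined
  and reported as `NA` (with a warning) when the evaluation spots contain
  one class only.
* AUPRC is average precision with tied scores grouped into one threshold
  step.
* Ranking ties (gene partition, differential ranking) break
  lexicographically on gene name for determinism.
* A zero-total spot makes normalization impossible; the error tells the
  user to run spot QC first. Degenerate (zero-variance) image channels
  are rejected when standardizing.
* With a fixed seed, simulation, initialization, batching, and therefore
  entire training trajectories are bit-reproducible (asserted in the
  tests).

## Known limitations

* The implemented backbone is intentionally small; it recovers planted
  desk-scale signal but is not sized for 224 px patches of real tissue,
  and no pretrained encoder ships with the package.
* The spatial constraint requires complete annotations on training spots
  (γ > 0 errors otherwise) and inherits any annotation noise: with
  region-level labels, mislabelled boundary spots feed wrong pairs into
  the constraint.
* Gene QC and partitioning assume all cohort samples share one gene
  universe; cross-platform gene-set reconciliation is out of scope.
* Batch-effect correction, spot deconvolution, and stain normalization
  are out of scope; the per-patient simulator effect exists only to make
  patient-level splitting meaningful.
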