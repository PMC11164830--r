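# spotgene

Multi-task prediction of spot-level gene expression and tumor annotation
from H&E histology patches.

## The problem

Spatial transcriptomics (ST) platforms measure gene expression at
grid-arranged capture spots on a tissue section while a routine H&E stain
records the same section's morphology. Sequencing every section is
expensive, and spot-level pathological annotation is slow; tissue
morphology, however, is cheap to image and correlates with expression.
`spotgene` trains a convolutional model that maps the image patch around
each spot to (i) the expression of the *m* most highly expressed genes (the
**target** set, the primary task), (ii) the expression of the remaining
*M − m* **non-target** genes (an auxiliary task that regularizes the shared
representation), and (iii) the probability that the spot lies in tumor
tissue. It is aimed at computational biologists who want an end-to-end,
CPU-scale, fully testable implementation of this image-to-expression
approach, including preprocessing, evaluation, and a synthetic-data
generator so that every stage runs without external downloads.

## The model

All three heads share one convolutional encoder (hard parameter sharing)
and the training objective is

```
L = L_prim + λ·L_aux + β·L_tmr + γ·L_spat
```

* `L_prim  = 1/(mN) Σ_i Σ_j (g_ij − ĝ_ij)²` — MSE over the m target genes;
* `L_aux   = 1/((M−m)N) Σ_i Σ_j (g_ij − ĝ_ij)²` — MSE over non-target genes;
* `L_tmr   = −1/N Σ_i [y_i ln ŷ_i + (1−y_i) ln(1−ŷ_i)]` — cross-entropy of
  the tumor head;
* `L_spat  = 1/K Σ_(i,j) w_ij ‖η(x_i) − η(x_j)‖²` — the **spatial-aware
  constraint**: over every (central spot, grid-neighbor) pair in the 3×3
  neighborhood, `w_ij = 1` iff the two spots carry the same pathological
  annotation (`w_ij = 0` otherwise), `K` is the number of such pairs, and
  the squared difference of predicted target expression is averaged over
  genes. Adjacent spots inside one annotated region are thereby pushed
  toward similar predicted expression.

Preprocessing follows standard ST practice: spots are dropped when their
patch window exits the slide, when total UMIs fall outside [200, 20 000],
when mitochondrial counts exceed 5%, or when fewer than 200 genes are
detected; genes detected in fewer than 3 spots are dropped; counts are
total-count normalized to 10 000 and log-transformed with a pseudocount;
patches are standardized per channel with training-split statistics. All
thresholds are configurable. Evaluation reports aMSE, aPCC (mean per-gene
Pearson correlation), NGPC (genes with positive correlation), and
ACC/AUC/AUPRC for the tumor head, always on held-out patients.

## Worked example

```r
library(spotgene)

# 1. simulate a 3-patient cohort of paired H&E / expression sections
cohort <- simulate_cohort(sim_config(seed = 1), n_patients = 3,
                          sections_per_patient = 2)

# 2. patient-level split and preprocessing (QC, normalization, patches)
split <- split_spec("P1", val_patients = "P2", test_patients = "P3")
thr <- qc_thresholds(min_umi = 50, max_umi = 50000, min_genes_per_spot = 5)
cfg <- train_config(epochs = 10, m = 10, window_px = 32, out_size_px = 32,
                    seed = 1)
ds <- prepare_dataset(cohort, split, thr, cfg)

# 3. train the multi-task model with all loss terms
ckpt <- train_model(ds, weights = loss_weights(1, 1, 1), config = cfg)

# 4. evaluate on the held-out patient
evaluate_model(ckpt, ds, role = "test")
#> <eval_report>
#>   target genes:     aMSE 2.4497  aPCC 0.4064  NGPC 10
#>   non-target genes: aMSE 2.8333  aPCC 0.0075
#>   annotation:       ACC 1.0000  AUC 1.0000  AUPRC 1.0000
```

The held-out aPCC of 0.41 on the ten target genes (which the simulator
couples to the latent tumor state through patch morphology) against ~0.01
on the forty decoy genes shows the model recovering exactly the planted
image–expression signal; AUC 1.0 reflects the strong morphology shift of
simulated tumor regions. Ranking genes by tumor-vs-normal mean difference
on the held-out spots returns the coupled genes first:

```r
test_e <- Filter(function(e) e$role == "test", ds$entries)
expr <- do.call(rbind, lapply(test_e, function(e) unclass(e$expr)))
ann <- unlist(lapply(test_e, function(e) e$labels))
differential_gene_ranking(expr, ann, k = 3)
#>     gene mean_tumor mean_normal difference abs_difference
#> 1 CPL006   4.145228    5.574629  -1.429401       1.429401
#> 2 CPL001   5.565489    4.152554   1.412935       1.412935
#> 3 CPL009   5.857050    4.467698   1.389352       1.389352
```

The same pipeline runs from the shell via the bundled CLI
(`inst/cli/spotgene`), with subcommands `simulate`, `prepare`, `train`,
`evaluate`, `predict` (image + spot coordinates only, no expression
needed), and `ablate`.

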