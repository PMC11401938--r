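# ampgraph

Multimodal patient-network diagnosis in R. `ampgraph` is for researchers who
have several per-subject feature tables of very different kinds — e.g. a
small demographic block, quality-control metrics, and a high-dimensional
functional-connectivity vector — and want a single transductive classifier
that exploits *inter-patient similarity* instead of treating subjects
independently.

## The model

Three jointly trained parts:

1. **Adversarially regularized encoder.** A per-modality feature extractor
   `f_k : R^{d_k} -> R^{d_c}` (two Leaky-ReLU layers) with a linear
   classification head, plus a shared modality discriminator `d(·)`. The
   discriminator minimizes a squared loss against true modality labels; the
   extractors minimize `L_f + β·L̂_{d,f}`, where `L̂` uses *inverted* modality
   targets, pushing the K embedding distributions toward indistinguishability.
2. **Learnable patient graphs.** Per modality,
   `A_ij = cos(W_A f_i, W_A f_j)` with a learnable projection `W_A`,
   thresholded at θ; the K graphs are fused as `𝒜 = Σ_k w_k A_k` with learned
   simplex weights `w` (readable as modality importance).
3. **S²GC classifier.** With `T̃ = (D+I)^{-1/2}(𝒜+I)(D+I)^{-1/2}`,
   predictions are
   `Ŷ = softmax((1/C) Σ_{c=1..C} ((1−α) T̃^c X + α X) W)` over the
   concatenated embeddings `X = f̂`; only training labels enter the masked
   cross-entropy. Training alternates one discriminator step, one extractor
   step, and one joint step on `L_g + η (L_f + β L̂_{d,f})` per epoch (Adam,
   rates 0.004/0.001/0.001/0.001).

A synthetic multimodal cohort generator with planted latent class structure
and per-modality distribution shifts makes every stage testable without any
external download, including a `planted_similarity_oracle()` giving the
ground-truth patient similarity a learned graph should recover.

## Worked example

```r
library(ampgraph)

# a separable 3-modality cohort: two clinical-sized blocks + one wide block
spec <- synthetic_spec(n_subjects = 200, n_modalities = 3,
                       dims = c(20, 30, 120), class_sep = 6,
                       modality_shift = 5, seed = 11)
ds <- generate_synthetic(spec)
cv <- run_cv(ds, run_config(epochs = 200, seed = 11), k = 5)
cv
#> <ampgraph_cv> 5-fold, variant=full
#> # A tibble: 4 × 2
#>   metric report
#>   <chr>  <chr>
#> 1 acc    99.50 ± 1.12
#> 2 auc    99.95 ± 0.11
#> 3 sen    99.00 ± 2.24
#> 4 spe    100.00 ± 0.00
```

Per-fold metrics and learned modality importance are tibbles:

```r
tidy(cv)                    # fold × (acc, auc, sen, spe)
glance(cv)                  # one-row mean/sd summary
cv$fusion_weights           # learned w_k per fold (sums to 1)
autoplot(cv)                # per-fold metric plot (ggplot2)
```

The printed `report` column is mean ± SD in percent across folds: here the
model recovers the planted diagnosis almost perfectly (ACC ≈ 99.5%), with
sensitivity/specificity at the fixed 0.5 cutoff. On a label-permuted copy of
the same cohort the mean AUC drops to chance (~50%), confirming the signal
is real rather than leakage.

A single fit exposes the learned artifacts directly:

```r
fit <- fit_ampgraph(ds, run_config(epochs = 200, seed = 11),
                    train_mask = which(seq_len(200) %% 5 != 0))
predict(fit)                # subject_id, case score, predicted label
fitted_adjacency(fit)       # learned fused patient graph (N × N)
autoplot(fit)               # loss trace per epoch
```

There is also a thin command-line interface (see `inst/cli/ampgraph`) with
`simulate`, `train`, `evaluate`, `ablate` and `combos` commands, a YAML
config mirroring `run_config()`, and a manifest written beside every output.

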