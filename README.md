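# pathfusion

Pathway-guided graph fusion networks for multi-omic patient
classification, with semi-supervised regularization and gradient-based
pathway attribution — written for computational biologists who want a
classifier whose internal representations follow curated biology
(pathways and molecular interaction networks) rather than an opaque
latent space, and who must cope with the missingness endemic to
multi-omic cohorts.

## The model

A patient's feature vector is partitioned into modality blocks
x = [x^(1), …, x^(M)] (e.g. transcripts, proteins, methylation), with a
binary mask m marking observed entries; the model only ever sees
x̃ = m ⊙ x and never imputes. The forward pass is:

1. **Modality encoders** h^(m) = φ(W_m x̃^(m) + b_m) into a shared
   d_h-dimensional space.
2. **Cross-modal attention**: for each present modality m, scalar
   scores s_n = h^(m)ᵀ T_mn h^(n) / √d_h over the other present
   modalities, softmax weights, attended vector a^(m) = Σ_n w_n h^(n);
   absent modalities are simply omitted from the summation. A gated
   residual h′ = h + g ⊙ a fuses context with modality-specific signal.
3. **Graph-guided pathway embedding**: per-feature node states
   H⁰_j = x̃_j w_j + h′_(mod(j)) are propagated over the interaction
   network by graph convolutions H^(l+1) = σ(Â H^(l) W^(l)) with the
   self-loop symmetric-normalized adjacency Â, then pooled per pathway,
   p^(k) = mean_{j∈P_k} H^(L)_j, and concatenated to z ∈ R^{P·d_h}.
4. **Variational latent prediction**: a two-layer projection gives
   z_fused; linear heads give μ and a clamped log-variance;
   z̃ = μ + σ ⊙ ε (reparameterization trick; z̃ = μ at evaluation);
   ŷ = softmax(W_out z̃ + b_out).

The graph itself also supplies a heat diffusion kernel K = exp(−βL)
(optionally used to pre-smooth inputs) and the attribution map
S_kj = ∂ŷ_target / ∂p^(k)_j, computed analytically, which ranks pathways
by their influence on a prediction.

Training minimizes the composite semi-supervised objective

    L = L_pred + λ₁·L_weak + λ₂·L_context + λ₃·L_intra + λ₄·L_inter
        + λ₅·L_entropy + λ₆·L_consist

(cross-entropy; KL to soft pseudo-labels; ‖z_fused − W_c·C x̃‖²
alignment to pathway activations; intra-group compactness and a cosine
hinge between group centroids; entropy minimization; prediction
consistency under feature dropout) with AdamW, learning rate 1e-4,
linear warm-up/decay, gradient clipping at norm 1.0 and early stopping
on validation accuracy. All gradients are derived analytically and are
verified against finite differences in the test suite.

## Worked example

```r
library(pathfusion)

# the package's reference study: 600 samples, 3 classes, 3 modalities,
# 12 pathways of 10 features, 2-SD effects on 2 causal pathways per
# class, 20% missing values
sim <- simulate_multiomic(simulation_config(seed = 42))
cohort <- zscore_by_modality(sim$cohort)
cohort
#> <pf_cohort> 600 samples x 120 features, 3 modalities (mod1:40, mod2:40, mod3:40)
#>   classes: class1, class2, class3
#>   labeled: 600, with pseudo-labels: 600, observed entries: 75.4%

fit <- pf_train(cohort, sim$prior, sim$pathways, tc = train_config(seed = 1))
pf_evaluate(fit, cohort)
#> # A tibble: 1 × 5
#>   accuracy macro_recall macro_f1 macro_auc     n
#>      <dbl>        <dbl>    <dbl>     <dbl> <int>
#> 1        1            1        1         1    90

idx1 <- fit$split$test[cohort$y[fit$split$test] == 1]
att <- pf_attribute(fit, cohort, indices = idx1, target_class = 1)
head(att$per_pathway, 4)
#> # A tibble: 4 × 4
#>   pathway   score embed_score  rank
#>   <chr>     <dbl>       <dbl> <int>
#> 1 pw08    0.00392       0.110     1
#> 2 pw12    0.00321       0.105     2
#> 3 pw10    0.00217       0.147     3
#> 4 pw01    0.00154       0.112     4
sim$truth$causal_pathways$class1
#> [1] "pw08" "pw12"
```

The evaluation row reports test-split metrics as fractions; on the
90-sample held-out split every sample is classified correctly. The
attribution ranking orders pathways by the mean input-times-gradient
contribution of their member features to the class-1 probability
(`score`; `embed_score` is the embedding-level sensitivity aggregate
`sum_j |S_kj|`): the two pathways planted for class 1 — `pw08` and
`pw12` — rank first and second, exactly the recovery behaviour the
acceptance checks quantify. `tidy(fit)`, `glance(fit)`,
`autoplot(fit)` and `autoplot(att)` expose the training history and
the ranking in broom/ggplot2 idiom.

A command-line front end with `simulate`, `train`, `evaluate` and
`attribute` subcommands is installed under `exec/pathfusion`:

```sh
Rscript exec/pathfusion simulate --config config.yaml --out data/
Rscript exec/pathfusion train --config config.yaml --data data/ --out run/
```

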