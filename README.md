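# pathembed

Pathway-level multi-omics embedding and consensus clustering for patient
stratification.

Multi-omics cohorts measure the same patients on several molecular layers
(mRNA, miRNA, DNA methylation, copy number) whose dimensionalities and
numeric ranges differ by orders of magnitude. `pathembed` clusters such
cohorts at the level of biological pathways instead of individual features:

1. **Map** — gene sets (GMT) and feature→gene annotation tables assemble,
   per pathway, one feature block per omics modality over the shared
   patients.
2. **Score** — a *multi-modal sparse denoising autoencoder* per pathway
   (modality-private first hidden layers, a single shared tanh bottleneck
   whose activation is the pathway score, laterally mirrored decoder)
   compresses those blocks into one score per patient. Training minimizes

   F(W) = ½·σ(W) + (λ/2)·[ (1−α)·Σ_j √(s_j·s_j′)·Σ (W_uv^(j))² + α·Σ |W_uv| ]

   where σ(W) is the mean per-patient summed squared reconstruction error
   across modalities, the group term runs over the modality-private input
   weight blocks and the ℓ1 term over all weight matrices; inputs are
   corrupted by feature dropout (retention probability p) during training.
   Hyper-parameters (batch size, λ, α, learning rate, p, SGD variant,
   hidden sizes h_j ≤ ⌊p_j/2⌋) are searched by a tree-structured Parzen
   estimator under 5-fold cross-validated reconstruction error.
3. **Bi-cluster** — the P×n score matrix (rows min–max rescaled to [0,1])
   is factorized by sparse NMF, min ½{‖X−BH‖²_F + η‖B‖²_F + β·Σ‖H(:,j)‖²₁}
   s.t. B,H ≥ 0, with consensus clustering over random restarts,
   cophenetic-correlation diagnostics, and permutation-calibrated rank
   selection; per-cluster descriptive pathways come from the largest-gap
   prefix of each basis column.
4. **Interpret** — exact and sampled Shapley values attribute each pathway
   score to features and modalities; Kruskal–Wallis tests on per-pathway
   mutational burden, age-aware survival tests (Cox LRT or log-rank), and
   chi-square/ANOVA clinical associations characterize the clusters, with
   Benjamini–Hochberg correction.

A synthetic multi-omics generator with planted clusters, survival hazards
and mutation enrichment makes the whole pipeline testable end to end
without any download.

## Worked example

```r
library(pathembed)

# a synthetic cohort: 150 patients, 3 planted clusters, 20 pathways
# (5 cluster-driving), three modalities (mrna / mirna / meth)
study <- generate_synthetic_study(synthetic_config(seed = 11))
views <- build_pathway_views(study$blocks, study$gene_sets, study$maps)

# tune + train one pathway autoencoder and score the patients
tuned <- tune_pathway_autoencoder(views[["PW01"]], budget = 10, folds = 5,
                                  seed = 101, max_epochs = 150)
fit <- train_pathway_autoencoder(views[["PW01"]], tuned$hidden, tuned$config)
round(tapply(score_patients(fit$model, views[["PW01"]]),
             study$labels[views[["PW01"]]$patients], mean), 2)
#>     1     2     3
#> -0.88  0.87  0.00
```

The three planted clusters separate cleanly on the single bottleneck score
(the within-cluster spread is an order of magnitude smaller than the
between-cluster gaps). Scoring every
pathway and consensus-clustering the score matrix recovers the planted
structure exactly:

```r
models <- lapply(seq_along(views), function(i) {
  t <- tune_pathway_autoencoder(views[[i]], budget = 10, folds = 5,
                                seed = 100 + i, max_epochs = 150)
  train_pathway_autoencoder(views[[i]], t$hidden, t$config)
})
names(models) <- names(views)
scores <- assemble_score_matrix(models, views)

cons <- consensus_cluster(scores$scores, m = 3, beta = 0.01,
                          runs = 50, seed = 5)
adjusted_rand_index(cons$labels, study$labels[scores$patients])
#> [1] 1
glance(cons)[, c("cophenetic", "silhouette_consensus")]
#>   cophenetic silhouette_consensus
#> 1          1                    1
```

Post-hoc statistics find the planted signals:

```r
mutational_burden_test(study$mutations, study$gene_sets, cons$labels) |>
  dplyr::filter(p_adjusted < 0.05) |>
  dplyr::pull(pathway_id)
#> [1] "PW01" "PW02" "PW03"
survival_association(cons$labels, study$clinical, "os")[, c("method", "p_value")]
#> # A tibble: 1 x 2
#>   method  p_value
#>   <chr>     <dbl>
#> 1 logrank 0.000617
```

The one-shot orchestration (`run_pipeline()`) runs all stages with
content-hash caching and a manifest; `inst/cli/pathembed.R` exposes
`simulate` and `run` subcommands for shell use:

```sh
Rscript inst/cli/pathembed.R simulate --out fixture --seed 1
Rscript inst/cli/pathembed.R run --input fixture --out results --profile fast
```

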