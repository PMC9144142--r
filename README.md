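# psnfuse

Patient similarity networks (PSNs) from heterogeneous clinical data, fused
for outcome classification.

A PSN is a weighted graph whose nodes are patients and whose edges encode
pairwise clinical similarity; outcome prediction on a PSN is
nearest-neighbor reasoning over that graph. Clinical cohorts mix a *static*
profile per patient (demographics, comorbidity flags, free-text symptom
fields) with *dynamic* longitudinal visit records of varying length, and no
single similarity measure serves both. `psnfuse` builds one network per
channel and merges them:

* **Static similarity** — the weighted sum
  `STPS_ij = Σ_k w_k · fs_ij^k` over per-feature rules (age: min/max ratio;
  categorical/boolean: exact match; free text: cosine of multi-hot token
  encodings), or a numeric feature embedding compared under Euclidean,
  Manhattan, cosine, Chebyshev, or weighted Manhattan distance.
* **Dynamic similarity** — an in-package LSTM encoder–decoder (trained on
  masked reconstruction MSE, verified against finite-difference gradients)
  compresses each visit sequence to a fixed-length embedding; embeddings
  are compared by distance and converted to similarities via `1/(1+d)`.
* **Fusion** — both matrices are row-normalized, symmetrized, and
  KNN-sparsified, then iterated through the coupled weighted-average
  recursion
  `MP1_{t+1} = (wts·S' + (1−wts)·MP2_t)/2`,
  `MP2_{t+1} = (wtd·D' + (1−wtd)·MP1_t)/2`,
  and averaged into the fused network `FM = (MP1_T + MP2_T)/2`. The
  recursion is linear with a closed-form fixed point (`snf_fixed_point()`),
  used as an analytic oracle in the tests.
* **Evaluation** — pairwise TP/TN/FP/FN confusion over patient pairs,
  patient-level KNN majority vote, top-p%-similar neighborhoods, and
  stratified cross-validation.
* **Synthetic cohorts** — a seeded generator with controllable static and
  dynamic outcome-signal strength emulates the shapes of a line-list cohort
  and a longitudinal cardiovascular cohort, so the full pipeline is testable
  without clinical data.

For whom: anyone prototyping similarity-network classification on tabular +
longitudinal clinical data, or needing a transparent, dependency-light SNF
reference with an analytic convergence check.

## Worked example

```r
library(psnfuse)

# synthetic longitudinal cohort: 200 patients, binary outcome,
# 2-10 visits each of 9 measurements
lc <- make_longitudinal_cohort(cohort_recipe(n_patients = 200,
                                             n_classes = 2, seed = 42))
lc$visits
#> visit_sequences: 200 patients, 1313 visits total, 9 features, lengths 2 - 10

# static channel: weighted per-feature similarity
S <- static_similarity_matrix(lc$cohort, default_feature_specs(lc$cohort))

# dynamic channel: autoencoder embeddings -> distances -> similarities
model <- train_autoencoder(lc$visits,
                           autoencoder_config(9, 32, n_iter = 600,
                                              seed = 42))
emb <- embed_patients(lc$visits, model)   # 1313 visit rows -> 200 embeddings
D <- dynamic_similarity_matrix(emb)

# fuse and compare all three networks by 5-fold patient-KNN
res <- run_fusion_stage(S, D, lc$cohort$outcome,
                        fusion = fusion_config(K = 15),
                        protocol = eval_protocol("patient_knn", K = 5,
                                                 seed = 42))
res$comparison
#>   channel accuracy recall.no_event precision.no_event f1.no_event
#> 1  static    0.835           0.856              0.856       0.849
#> 2 dynamic    0.965           0.973              0.966       0.968
#> 3   fused    0.980           0.982              0.982       0.982
```

The comparison table is the headline result: cross-validated accuracy of
the static, dynamic, and fused networks under identical evaluation. Here
both channels carry planted outcome signal (`beta_static` and
`beta_dynamic` default to 0.8) and the fused network matches or beats the
better single channel.

A command-line driver wraps the same stages
(`simulate | static | dynamic | fuse | eval`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "psnfuse.R", package = "psnfuse"))')" \
    simulate --seed 3 --out run1
```

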