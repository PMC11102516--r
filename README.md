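# siamdr

Contrastive representation learning for cancer drug response
prioritization.

`siamdr` is for computational biologists who work with secondary
drug-repurposing screens (PRISM/DepMap-style tables of fitted
dose-response parameters plus cell-line expression) and want, for each
cancer cell line, a ranked list of the drugs most likely to be highly
effective against it. The package implements the full pipeline:
effectiveness scoring, screen-quality filtering, Siamese (twin-network)
contrastive pretraining of drug and cell-line encoders, end classifiers,
per-cell drug prioritization, and the ranking / embedding-quality
metrics to judge the result — together with a synthetic-study generator
that plants known structure so everything is testable offline.

## The method

**Scoring.** Each screened (drug, cell) pair is summarized by its fitted
curve's AUC *a*, lower viability limit *l*, and IC50 *c*, combined into
a continuous effective score

> CES = log( (a + l + c) / (2 · a · l · c) ),

which is symmetric in its arguments and strictly decreasing in each, so
more potent, more efficacious, deeper-killing drugs score higher. Pairs
in the top decile of CES are labeled effective (empirical 90th
percentile by default; a μ + 1.28σ normal rule is available). Records
with missing parameters, negative lower limits, or curve fit R² < 0.7
are dropped; duplicate screens resolve to the preferred screen id, then
highest R²; withdrawn drugs and uninformative cell lines (under 1%
effective drugs, unknown cancer, no expression) are excluded.

**Representation learning.** A shared-weight encoder Enc maps drug
fingerprints **f** (256-bit Morgan, radius 3) to embeddings
**e**_d and expression vectors **g** to **e**_c. During pretraining the
twin network predicts the probability that a pair of entities belongs to
different groups, σ(w·‖Enc(x_a) − Enc(x_b)‖₂ + b), with binary
cross-entropy; drugs are grouped by shared gene targets and cell lines
by cancer type, so same-group entities are pulled together and
different-group entities pushed apart. A reconstruction autoencoder
provides the baseline embedder.

**Prioritization and evaluation.** An end classifier (ridge logistic,
random forest, or dense network) is trained on concatenated drug‖cell
features and every pool drug is ranked per cell by predicted
effectiveness. Quality is measured by P_cell@k (precision of the top-k
list against the cell's effective set) and P_cancer@k (mean-pooled per
cancer), embedding quality by intra-group cosine similarity and
inter-group separability (the intra/inter ratio), model differences by
Bonferroni-corrected independent t-tests.

## Worked example

```r
library(siamdr)

cfg <- sim_config(seed = 1)                      # 100 drugs / 4 MOAs, 120 cells / 4 cancers
drugs <- gen_drugs(cfg)
cells <- gen_cells(cfg)
dr <- gen_dose_response(drugs, cells, cfg)

scored <- score_pairs(dr$records, drugs$table, cells$table, cells$expression)
nrow(scored$pairs); mean(scored$pairs$label)
#> [1] 10608
#> [1] 0.1014
scored$rule
#> <binarization_rule empirical_quantile: threshold 4.9033 (mu 1.0749, sigma 2.2104)>
scored$reports$quality
#> <filter_report>
#>                   stage  n_in n_out
#> 1        missing_values 12444 12321
#> 2  negative_lower_limit 12321 12196
#> 3 nonpositive_parameter 12196 12196
#> 4                low_r2 12196 11529
```

About 10% of surviving pairs are labeled effective, and the stage counts
telescope through the cascade (the remaining 11,529 → 10,608 step is
duplicate-screen resolution plus entity exclusion). Pretraining the drug
encoder and measuring expressiveness:

```r
targets <- parse_gene_targets(drugs$table$gene_targets, drugs$table$drug_id)
enc <- train_encoder(drugs$fingerprints, group_by_targets(targets),
                     encoder_config(input_dim = 256, embedding_dim = 64),
                     train_config(seed = 1), kind = "drug")
moa <- setNames(drugs$table$moa, drugs$table$drug_id)

group_similarity(embed_entities(enc, drugs$fingerprints), moa)
#> <separability_report: mean intra 1.000, inter 0.001, separability 100.000>
group_similarity(drugs$fingerprints, moa)
#> <separability_report: mean intra 0.888, inter 0.524, separability 1.695>
```

The contrastive encoder collapses each mechanism-of-action group to a
tight cluster (intra ≈ 1) while pushing different groups to near-zero
cosine similarity — separability saturates the reporting cap of 100 —
whereas the raw fingerprints separate the same groups only by a factor
of ~1.7.

A command-line surface wraps the same pipeline
(`inst/cli/siamdr <simulate|score|pretrain|train|prioritize|evaluate>`
with `--seed`, `--config`, `--outdir`); every stage writes a JSON
manifest sufficient to reproduce it.

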