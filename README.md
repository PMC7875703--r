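# edembed

Self-supervised disease-concept embeddings from emergency-department
triage records.

## What it does

When a patient arrives at an emergency department, only limited
information exists: fifteen structural fields (age, gender, blood
pressures, heart rate, SpO2, respiratory rate, temperature, height,
weight, pain score, Glasgow coma scale), a free-text chief complaint, and
past history records. `edembed` learns a bounded embedding
ε ∈ [−1,1]^d of that information **without outcome labels**, so that
similar disease presentations land close together. The embedding drives
two applications:

* **patient retrieval** — top-k cosine search over past visits, scored by
  a 0–5 hit count against the query's label;
* **critical-care-outcome prediction** — the union of ICU admission and
  death within 3 days of triage; a small labeled set finetunes the
  pretrained encoder, evaluated by AUROC.

The encoder β_ED is a BERT-style Transformer over the token sequence
[CLS], M_S, M_CC, M_Hx, where M_S = L_S(S) projects the standardised
vitals and M_CC, M_Hx = L_B(·) project frozen text features of the chief
complaint and the mean history. Pretraining minimises

    Loss = DIM loss + γ · prior loss + SimCLR loss,    γ = 0.1

— a Deep InfoMax noise-contrastive term (a second Transformer β_D scores
matched vs mismatched (ε, input) pairs), adversarial matching of ε to a
Uniform[−1,1]^d prior through a linear domain discriminator L_DD, and an
NT-Xent contrastive term between two augmented views (structural noise +
random history masking) at temperature τ. All training runs on a compact
reverse-mode autodiff tape written in base R and verified against finite
differences in the test suite.

The package also implements the surrounding pipeline: triage-record
cleansing with machine-readable rejection codes (SBP > 300 mmHg,
DBP > SBP, HR > 250, RR > 100, BT outside 20–48 °C, WT > 400 kg,
HT > 250 cm, missing chief complaint), account-level revisit
deduplication, strict pre-triage history selection, mean imputation with
training statistics, 80/10/10 splitting that reproduces the published
split tables exactly, an NHAMCS-style survey converter, an exact t-SNE
for visualisation, and a seeded synthetic-cohort generator with latent
cluster structure for fully self-contained testing.

## Worked example

```r
library(edembed)

# a synthetic 600-visit cohort with 4 latent disease clusters
co  <- generate_cohort(cohort_config(n_visits = 600, invalid_rate = 0.05,
                                     seed = 2))
cl  <- cleanse_visits(co$visits)
nrow(cl$rejected)                 # 33 records carry injected violations
table(cl$rejected$reason)[1:3]

# pretrain the small preset (hidden 32, 2 layers, 4 heads)
cfg <- ed_config(preset = "small", d_text = 64L)
fit <- edembed(cl$kept, cfg,
               ed_train_config(batch_size = 64L, epochs = 10L,
                               learning_rate = 1e-3, seed = 1))
summary(fit)
#> Self-supervised disease-concept embedding model
#>   encoder: 2-layer Transformer, 4 heads, hidden 32; text width 64 (hash encoder)
#>   trained on 567 visits; pretrained: yes (DIM: TRUE, SimCLR: TRUE, 80 steps)
#>   loss parts (first step -> last step):
#>     dim_nce      0.6933 ->   0.6007
#>     prior_gen    0.7315 ->   0.7157
#>     prior_disc   0.6750 ->   0.6902
#>     simclr       4.8442 ->   3.8408
#>     total        5.6106 ->   4.5130

# embeddings, retrieval, clustering
eps <- predict(fit, cl$kept)
lat <- co$latent_cluster[match(rownames(eps), co$visits$visit_id)]
retrieval_precision(eps, lat, n_queries = 100, seed = 3)
km  <- kmeans(eps, 4, nstart = 10)
mclust::adjustedRandIndex(km$cluster, lat)
```

Output from this exact script (seeds as shown):

```
#> retrieval precision@5: 0.862
#> adjusted Rand index:   0.581
```

A ten-epoch run on 567 clean visits already places 86 % of each query's
top-5 neighbours in the query's own latent cluster, and k-means on the
embeddings recovers the latent clusters with ARI 0.58. The reference
desk-scale protocol (2,000 visits, 30 epochs; see the methods vignette)
pushes precision@5 above 0.95 and the ARI to ~0.6-0.7.

Finetuning for the outcome:

```r
lab <- label_critical_outcome(cl$kept)        # 3-day ICU/death window
clf <- finetune(fit, cl$kept, lab, epochs = 6L, seed = 1)
scores <- predict(clf, cl$kept)
evaluate_auroc(scores, lab)
```

A command-line wrapper over the same functions lives in
`inst/cli/edembed.R` (`simulate`, `cleanse`, `split`, `label-outcome`,
`embed`, `retrieve`).

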