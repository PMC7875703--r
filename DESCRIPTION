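Package: edembed
Title: Self-Supervised Disease-Concept Embeddings from Emergency-Department Triage Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns fixed-width disease-concept embeddings from emergency
    department visit records (vital signs, chief complaint, past history)
    without outcome labels, using a Transformer encoder over fused structural
    and text features trained with a Deep InfoMax noise-contrastive loss,
    adversarial matching of the embedding distribution to a uniform prior,
    and a SimCLR contrastive loss. Includes record cleansing and
    deduplication for triage data, cohort splitting, a pluggable text
    encoder with a hashing reference implementation, cosine-similarity
    patient retrieval with top-k hit scoring, t-SNE visualisation,
    finetuning of the pretrained encoder for critical-care-outcome
    classification with AUROC evaluation, and a seeded synthetic-cohort
    generator with known latent cluster structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
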