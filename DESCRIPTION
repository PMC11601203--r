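Package: thermlm
Title: Temperature-Guided Protein Language Modelling for Variant Scoring
    and Multisite Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale temperature-guided protein language model for
    protein engineering. Implements a transformer encoder with two heads -- a
    masked-language-model head over the 20 amino acids and an optimal-growth-
    temperature (OGT) regression head -- trained with an alternating multitask
    objective that includes a Pearson-correlation alignment between mutant
    log-odds scores and predicted OGT. Provides zero-shot variant-effect
    scoring by log-odds, unsupervised fine-tuning on homologous sequences, a
    frozen-backbone low-N supervised regression protocol with dynamic epoch
    selection and seed ensembling, an iterative multisite mutation-stacking
    design loop, an in-silico directed-evolution harness on epistatic fitness
    landscapes, and a synthetic-data generator (protein families,
    composition-driven OGT labels, additive-plus-epistatic landscapes) so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
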