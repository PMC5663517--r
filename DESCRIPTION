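Package: motifdeconv
Title: Deconvolution of Label-Specific Sequence Features at Multi-Labeled Genomic Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discriminative k-mer models for collections of genomic sites that
    carry overlapping annotation labels (for example cell-type, timepoint or
    promoter-proximity labels on transcription-factor binding sites).
    Distinct label combinations are treated as subclasses of a multinomial
    logistic regression on reverse-complement-collapsed k-mer counts, while
    per-label models are learned through an L1 fused penalty tying each
    subclass to the labels that span it. The model is fit with a relaxed
    alternating direction method of multipliers (ADMM). Trained k-mer models
    are scanned across the input sequences to extract short high-scoring
    "hills", which are clustered and summarised as position weight matrices
    whose label-specific scores deconvolve which sequence features belong to
    which annotation label. Includes a synthetic-data generator (Markov
    background plus planted PWM instances with controlled label overlap), a
    naive multi-class baseline, and evaluation utilities (motif matching,
    assignment error rates, cross-validated auROC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    cluster,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
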