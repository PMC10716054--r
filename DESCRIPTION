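Package: promoforge
Title: Design and Screening of Bacterial Promoters with Generative and
    Supervised Sequence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing 50-bp Escherichia coli promoters and
    predicting their function. Provides sequence dataset handling
    (FASTA and activity tables, windowing, non-promoter sampling),
    one-hot and pseudo-dinucleotide-composition feature encodings,
    supervised ResNet/self-attention and simple CNN networks for
    promoter recognition (real versus fake), strength classification
    (strong versus weak) and activity regression, a denoising diffusion
    generator over one-hot promoter matrices with a UNet denoiser,
    constraint-based sigma70 promoter generation with fixed -35/-10
    hexamers and variable spacer, a screening cascade that filters
    generated candidates by predicted realness and strength and ranks
    them by predicted activity, 6-mer functional-motif scans,
    information-content sequence logos, and synthetic promoter corpora
    with known ground truth for model validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
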