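Package: clsmei
Title: Bayesian Adaptive Categorical Loudness Scaling with Maximum
    Expected Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for categorical loudness scaling (CLS). Provides
    multi-category psychometric function (MCPF) listener models, synthetic
    MCPF catalogs spanning normal hearing to sensorineural hearing loss,
    Bayesian posterior inference over catalog entries with Shannon-entropy
    bookkeeping, a maximum-expected-information (MEI) adaptive stimulus
    selector, fixed-level, slope-adaptive and uniform-random tracking
    procedures, CLS loudness-growth function estimation by the
    median-per-category and maximum-likelihood catalog methods, threshold
    estimation, categorical-unit to phon conversion, agreement and
    reliability statistics (Bland-Altman, Cronbach's alpha, root mean
    square error), and a Monte-Carlo simulated-listener framework for
    comparing adaptive trackers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
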