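Package: microresp
Title: Null-Model Analysis of Gut Microbiome Response to Dietary Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies interindividual variability of the gut-microbiome
    response to dietary interventions from paired before/after amplicon count
    tables. Implements the Raup-Crick null-model response metric built on
    Bray-Curtis dissimilarities (RC_bray), randomisation diagnostics of the
    computational dependence between alpha and beta diversity,
    Dirichlet-multinomial-mixture enterotyping with nearest-medoid
    classification, community summary statistics (Shannon alpha diversity,
    average gene number per organism, Bacteroidetes:Firmicutes ratio),
    mixed-effect partial-correlation networks linking them to the response, a
    reference-based response-potential estimator, and a gradient-boosted-tree
    cross-validation protocol testing how much of the response is predictable
    from baseline composition. A seeded synthetic-data generator with known
    ground truth makes every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    lme4,
    lmerTest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
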