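Package: dosig
Title: Disease-Ontology-Guided Discovery of Tumor-Discriminating Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers small gene signatures that discriminate tumor from
    normal samples in normalized expression data. Chains normality-gated
    differential-expression testing (Anderson-Darling gate routing each gene
    to a Mann-Whitney U test or a two-sample z-test, Benjamini-Hochberg
    correction, fold-change thresholds), hypergeometric over-representation
    filtering against a disease-to-gene annotation map, stepwise forward
    feature selection by Wilks' lambda with partial-F entry tests inside an
    adaptive niveau trimming loop, and a grid-tuned RBF support vector
    machine with kappa/specificity/no-information-rate acceptance gates.
    Selected signatures are screened for single-gene prognostic value by
    Kaplan-Meier estimation and the log-rank test. Includes a deterministic
    synthetic-fixture generator with planted differential genes, a planted
    enriched disease term, and a planted prognostic gene, plus a command-line
    interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
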