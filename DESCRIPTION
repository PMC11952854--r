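Package: panelDRP
Title: Drug Response Prediction from Clinical Gene-Panel Mutation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tumor drug response from the restricted gene panels used
    in clinical-grade next-generation sequencing (cNGS) reports. Somatic
    mutation calls are converted into gene-level vectors of variant-annotation
    statistics (ClinVar significance, protein-location categories, and a
    17-algorithm deleteriousness score), compressed by per-domain
    zero-inflated variational autoencoders whose latent spaces are aligned
    across cell lines and patients with a correlation-alignment (CORAL) loss,
    and fed with binary circular drug fingerprints into a multi-task head
    that regresses area under the dose-response curve for cell lines and
    classifies RECIST response for patients under Chebyshev scalarization.
    Includes a two-domain synthetic cohort simulator with a planted
    mutation-to-response signal, split/metric evaluation utilities, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
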