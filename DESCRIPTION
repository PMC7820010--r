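Package: dlbcl2s
Title: Two-Step Genetic Subtype Classification of Diffuse Large B-Cell
    Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based assignment of diffuse large B-cell lymphoma (DLBCL)
    samples to the five genetic subtypes N1, MCD, BN2, EZB and ST2 from the
    mutation status of a 26-gene panel plus BCL2 and BCL6 translocation
    status. Implements the post-annotation variant-quality filter used to
    binarize targeted-panel somatic calls into a gene-by-sample mutation
    matrix, the two-step marker-count classifier with NOTCH1 precedence,
    Fisher exact marker ranking for panel curation, one-vs-rest
    sensitivity/specificity evaluation against a reference labelling, and a
    seeded synthetic-cohort simulator with known latent subtypes for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
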