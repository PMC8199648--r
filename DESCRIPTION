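Package: cernet
Title: Clinically Relevant circRNA-miRNA-mRNA Competing-RNA Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers clinically relevant circRNA-mRNA co-expression networks and
    circRNA-miRNA-mRNA competing-endogenous-RNA (ceRNA) triplets from paired
    tumor/non-tumor expression profiles. Implements paired differential
    expression with fold-change and FDR gating, clinical-phenotype association
    and prognosis calling, Pearson co-expression networks with nodal (master)
    circRNA identification by greedy set cover, ceRNA pair scoring by
    hypergeometric shared-miRNA tests, partial Pearson correlation, sensitivity
    correlation and conditional mutual information, biomarker evaluation by ROC
    and ridge-stabilized logistic panels, and gene-set over-representation.
    Ships a paired-cohort simulator with planted differential expression,
    clinical associations and miRNA-mediated ceRNA triplets so that every stage
    can be verified against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    igraph,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
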