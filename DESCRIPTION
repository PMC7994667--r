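Package: pluriomics
Title: Time-Resolved Multi-Omics Analysis of Naive Pluripotency Induction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for time-resolved isobaric-label proteomics,
    phosphoproteomics and metabolomics of mouse embryonic stem cells
    transitioning to the naive pluripotent state under 2i or Cdk8/19
    inhibition. Implements within-plex cyclic loess normalization,
    empirical-Bayes batch adjustment across plexes, moderated one-sample
    t-tests on log2 ratios versus the serum/LIF reference with
    Benjamini-Hochberg control and fold-change gating, hypergeometric
    treatment-overlap statistics with representation factors, gap-statistic
    k-means clustering of z-scored temporal trajectories, preranked gene-set
    enrichment (ES/NES with permutation FDR), class-I phosphosite filtering
    with Gsk3 priming-pair substrate inference from mono- and
    di-phosphorylated peptidoforms, left-censored metabolomics imputation
    with quantile-median centering, and protein-versus-mRNA
    post-transcriptional divergence classification. A seeded synthetic-data
    generator with exported ground truth makes every stage testable without
    access to the original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    limma,
    sva,
    fgsea,
    cluster,
    mclust
Config/testthat/edition: 3
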