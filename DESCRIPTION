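Package: seqTaxAudit
Title: Taxonomic Reliability Auditing of Sequence Reference Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Audits the taxonomic annotations of nucleotide reference
    databases such as the mitochondrial portion of GenBank. Sequences are
    assigned to mitochondrial genes by local alignment against per-gene
    reference panels with Karlin-Altschul significance statistics, clustered
    by greedy length-sorted centroid clustering at fixed identity thresholds,
    and screened for clusters whose members carry conflicting taxonomic
    labels at phylum to genus rank. Per-rank minimum/maximum mislabel counts
    are computed, individual mislabeled sequences are resolved by a
    similarity-consensus rule, likely error causes are assigned through an
    ordered decision tree, and sequence- versus cluster-sampling estimation
    strategies can be compared by simulation. A synthetic database generator
    with planted, fully known mislabels supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Collate: 
    'RcppExports.R'
    'align.R'
    'taxonomy.R'
    'auditdb.R'
    'causes.R'
    'clustering.R'
    'gene_classify.R'
    'mislabel.R'
    'pipeline.R'
    'sampling.R'
    'scoring.R'
    'seqTaxAudit-package.R'
    'simulate.R'
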