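Package: codonMAP
Title: Codon-Context Modelling of MHC-I Peptide Presentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how synonymous codon arrangement in the mRNA
    regions flanking MHC-I associated peptide (MAP) coding codons relates to
    peptide presentation. Builds labelled hit/decoy codon-context datasets
    from coding sequences, expression tables and detected peptide lists;
    provides three synonymous-shuffling null models that preserve the amino
    acid sequence; trains a shallow codon-embedding classifier on flanking
    codons only; extracts analytic per-codon positional preferences and
    Kullback-Leibler positional diagnostics; designs synonymous coding
    variants that maximise or minimise the classifier score; and combines
    classifier scores with ligand rank and transcript expression for
    presentation prediction. A synthetic-data generator with planted
    codon-usage signal supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    glmnet,
    nnet
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
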