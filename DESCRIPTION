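Package: oglcnac
Title: Motif Discovery and Two-Layer Prediction of Protein O-GlcNAcylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies O-GlcNAc transferase (OGT) substrate motifs from peptide
    windows centred on Ser/Thr residues by recursive maximal dependence
    decomposition (MDD) over physicochemical amino-acid groups, trains a profile
    hidden Markov model per motif subgroup, and stacks the resulting bit-score
    vectors into an RBF-kernel support vector machine that emits a site-level
    probability. Includes k-means undersampling of the negative class, repeated
    stratified cross-validation, homology filtering, independent-test
    evaluation, position-specific composition and enrichment analysis, and a
    synthetic-data generator with planted group-level motifs for end-to-end
    testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
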