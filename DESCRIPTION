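Package: mplig
Title: Sequence-Based Prediction of Ligand-Binding Residues in Membrane
    Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts ligand-binding residues in alpha-helical membrane
    proteins from sequence information alone.  Ground-truth binding labels
    are derived from protein-ligand atomic contacts in PDB structures at a
    4.5 Angstrom cutoff; residues are encoded by sliding windows of
    amino-acid properties, BLOSUM62 rows, or PSI-BLAST PSSM profile rows;
    classification uses a Gaussian Naive Bayes model with a
    likelihood-ratio decision rule, evaluated by leave-one-protein-out
    cross-validation with accuracy, sensitivity, specificity, Matthews
    correlation and ROC curves.  Includes generators for fully synthetic
    structures and profiles so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
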