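Package: tefamkit
Title: Curation Toolkit for Transposable Element Family Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and curating transposable element (TE)
    family models from seed alignments. From a multiple alignment of
    family instances the package derives both a CpG-aware consensus
    sequence (using a neutral log-odds substitution model with
    ancestral-CpG inference) and a profile hidden Markov model, keeping a
    positional correspondence between the two. It classifies families
    with an unranked path-string taxonomy and by terminal-sequence
    signatures of DNA transposons (including target site duplication
    detection), filters tandemly repetitive consensi before import, and
    persists families together with an embedded organismal taxonomy in an
    indexed HDF5 store with FASTA/EMBL/HMM export. A TE evolution
    simulator generates genomes, families and ground-truth seed
    alignments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    rhdf5,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
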