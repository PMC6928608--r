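Package: biopepkit
Title: Bioactive Peptide Profiling, In Silico Proteolysis and Peptide
    Chemoinformatics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline, scriptable toolkit for screening protein sequences
    as precursors of bioactive peptides. Locates annotated bioactive
    fragments in query sequences (activity profiles), computes quantitative
    precursor scores (occurrence frequency A and reciprocal-potency B),
    simulates proteolysis under enzyme specificity rules (recognition
    sequence, cutting residue, bond side) with release scores A_E, W, B_E,
    V and the theoretical degree of hydrolysis, enumerates the proteolytic
    events needed to liberate a peptide from its precursor, processes FASTA
    sets with set-level occurrence and release parameters, and converts
    extended one-letter peptide sequences (D-enantiomers as lowercase,
    phosphoserine as B/b, C-terminal amide as "~") into aromatic SMILES
    with elemental composition, mass and InChIKey support. Ships a
    documented JSON/TSV database schema and a reproducible synthetic
    fixture generator in place of any hosted database content.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (the 'obabel' executable) for InChI/InChIKey
    derivation and structure validation; optional for all other
    functionality.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
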