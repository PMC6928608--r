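# Fixtures are built in code; nothing here touches the network or any
# hosted database content.

# minimal bundle around the AP dipeptide and a Phe-carboxyl-side enzyme
apBundle <- function(withAPGF = FALSE, apEC50 = 4) {
  pep <- data.frame(id = 1L, name = "AP dipeptide", sequence = "AP",
                    activity = "ACE inhibitor", ec50_uM = apEC50)
  if (withAPGF)
    pep <- rbind(pep, data.frame(id = 2L, name = "APGF tetrapeptide",
                                 sequence = "APGF",
                                 activity = "ACE inhibitor", ec50_uM = NA))
  makeBundle(
    peptides = pep,
    enzymes = data.frame(enzyme_id = 1L, name = "Phe-C proteinase",
                         ec_number = "3.4.21.999", merops_id = NA),
    rules = data.frame(connection_id = 1L, enzyme_id = 1L,
                       recognition_seq = "F", cut_residue_index = 1L,
                       side = "after"))
}

# plasmin-like (two single-residue carboxyl-side rules) plus a
# zingipain-like enzyme with a multi-residue recognition sequence
plasminLikeBundle <- function() {
  makeBundle(
    peptides = data.frame(id = 1L, name = "VPP", sequence = "VPP",
                          activity = "ACE inhibitor", ec50_uM = 9),
    enzymes = data.frame(
      enzyme_id = c(1L, 2L),
      name = c("plasmin-like proteinase", "zingipain-like proteinase"),
      ec_number = c("3.4.21.7", "3.4.22.67"),
      merops_id = c("S01.233", "C01.017")),
    rules = data.frame(
      connection_id = 1:3, enzyme_id = c(1L, 1L, 2L),
      recognition_seq = c("K", "R", "GPA"),
      cut_residue_index = c(1L, 1L, 2L),
      side = c("after", "after", "after")))
}

randomLSequence <- function(n)
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")

# independent oracle: naive position-by-position token scan
bruteForceOccurrences <- function(fragment, sequence) {
  f <- parseSequence(fragment)@tokens
  s <- parseSequence(sequence)@tokens
  m <- length(f); n <- length(s)
  hits <- integer()
  if (m <= n)
    for (w in seq_len(n - m + 1L))
      if (all(s[w:(w + m - 1L)] == f)) hits <- c(hits, w)
  data.frame(start = hits, end = hits + m - 1L)
}

# independent cheminformatics oracle: rdkit via the system python builds
# the peptide from its sequence (its own residue templates) and reports
# InChI + formula; entirely separate from the package's block table and
# from the OpenBabel backend.
rdkitSequenceInchi <- function(sequences) {
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.rdMolDescriptors import CalcMolFormula",
    "for seq in sys.argv[1:]:",
    "    m = Chem.MolFromSequence(seq)",
    "    print(Chem.MolToInchi(m) + '\\t' + CalcMolFormula(m))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), sequences),
                 stdout = TRUE, stderr = FALSE)
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(sequence = sequences,
             inchi = vapply(parts, `[`, "", 1L),
             formula = vapply(parts, `[`, "", 2L))
}

rdkitSmilesFormula <- function(smiles) {
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.rdMolDescriptors import CalcMolFormula",
    "for s in sys.argv[1:]:",
    "    m = Chem.MolFromSmiles(s)",
    "    print(CalcMolFormula(m) if m is not None else 'PARSE_FAILURE')",
    sep = "\n")
  system2("python", c("-c", shQuote(script), shQuote(smiles)),
          stdout = TRUE, stderr = FALSE)
}
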