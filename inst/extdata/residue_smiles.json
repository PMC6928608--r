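{
  "comment": "Per-residue SMILES blocks for chain-context concatenation (free alpha-amine through carbonyl), L form; D blocks are derived by inverting every chirality tag (@@ <-> @). B is L-phosphoserine with a neutral phosphate. Layouts follow the SwissSidechain/CycloPs convention; mixed [C@@H](..) and [C@@]([H])(..) styles are residue-specific data and deliberately not normalized.",
  "terminal": { "acid": "O", "amide": "N" },
  "blocks": {
    "A": "N[C@@H](C)C(=O)",
    "C": "N[C@@H](CS)C(=O)",
    "D": "N[C@@H](CC(=O)O)C(=O)",
    "E": "N[C@@H](CCC(=O)O)C(=O)",
    "F": "N[C@@H](Cc1ccccc1)C(=O)",
    "G": "NCC(=O)",
    "H": "N[C@@H](Cc1c[nH]cn1)C(=O)",
    "I": "N[C@@H]([C@@H](C)CC)C(=O)",
    "K": "N[C@@H](CCCCN)C(=O)",
    "L": "N[C@@H](CC(C)C)C(=O)",
    "M": "N[C@@H](CCSC)C(=O)",
    "N": "N[C@@H](CC(=O)N)C(=O)",
    "P": "N1[C@@H](CCC1)C(=O)",
    "Q": "N[C@@H](CCC(=O)N)C(=O)",
    "R": "N[C@@H](CCCNC(=N)N)C(=O)",
    "S": "N[C@@]([H])(CO)C(=O)",
    "T": "N[C@@H]([C@H](O)C)C(=O)",
    "V": "N[C@@H](C(C)C)C(=O)",
    "W": "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)",
    "Y": "N[C@@H](Cc1ccc(O)cc1)C(=O)",
    "B": "N[C@@]([H])(COP(=O)(O)O)C(=O)"
  }
}
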