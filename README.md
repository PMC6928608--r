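# biopepkit

An offline, scriptable R toolkit for screening proteins and peptides as
precursors of bioactive peptides. Food proteins (caseins, rapeseed or soy
proteins, ...) harbour short fragments — ACE inhibitors, DPP-IV
inhibitors, opioid or antioxidative peptides — that become active once a
proteolytic enzyme releases them. `biopepkit` answers the questions a
peptide researcher asks of such a precursor: *which annotated bioactive
fragments does it contain, where, and how densely? Which of them would a
given set of endopeptidases actually liberate?* It works entirely against
a local peptide/enzyme database bundle (a documented JSON/TSV schema with
a reproducible synthetic fixture generator — no hosted database content is
required or included) and speaks the extended one-letter sequence code:
lowercase letters for D-enantiomer residues (`FhL` = L-Phe–D-His–L-Leu),
`B`/`b` for L-/D-phosphoserine, and a trailing `~` for a C-terminal amide.

## The quantities it computes

For a precursor of length N (D = N − 1 peptide bonds):

- **A = a/N** — frequency of bioactive fragment occurrence, where `a`
  counts all (overlapping) occurrences of fragments with a given activity;
- **B = [Σᵢ aᵢ/EC₅₀ᵢ]/N** (µM⁻¹) — potency-weighted score over fragments
  with a known half-maximal concentration (fragments without one are
  skipped; B is *absent*, not zero, when none has one);
- **A_E = d/N** and **W = A_E/A** — frequency (and relative frequency) of
  release of active fragments by the selected enzymes, counting digest
  fragments that *exactly* equal an annotated peptide;
- **B_E = [Σⱼ dⱼ/EC₅₀ⱼ]/N** (µM⁻¹) and **V = B_E/B** — the released
  analogues of B;
- **DH_T = d/D × 100 %** — theoretical degree of hydrolysis;
- set-level parameters over a FASTA set of L sequences (N_T total
  residues): **a_T = Σ a_l**, **a_S = a_T/L**, **A_S = a_T/N_T**, and the
  release counterparts **a_TE**, **a_SE**, **A_SE**.

Proteolysis is simulated to completion: every bond matched by an enzyme's
specificity rule (recognition sequence + cutting residue + bond side) is
cleaved, and bonds flanked by D-residues or phosphoserine resist by
default. The release planner enumerates the *proteolytic events* (1N, 1C,
2N, 2C, ...) needed to excise each occurrence of a peptide and lists every
annotated enzyme able to catalyze each event, with cutting sequences in
`X-`/`X+` notation (bond on the carboxyl/amine side of residue X).

The chemoinformatics layer converts sequences to aromatic SMILES by
concatenating per-residue blocks (SwissSidechain/CycloPs layout, shipped
as editable JSON), derives elemental composition and average/monoisotopic
masses from IUPAC atomic weights, and — via OpenBabel's `obabel`, if
present — standard InChI/InChIKeys for neutral, stereo-defined, reduced
structures.

## Worked example

```r
library(biopepkit)

db <- makeBundle(
  peptides = data.frame(id = 1L, name = "AP dipeptide", sequence = "AP",
                        activity = "ACE inhibitor", ec50_uM = 4),
  enzymes  = data.frame(enzyme_id = 1L, name = "Phe-C proteinase",
                        ec_number = "3.4.21.999", merops_id = NA),
  rules    = data.frame(connection_id = 1L, enzyme_id = 1L,
                        recognition_seq = "F", cut_residue_index = 1L,
                        side = "after"))

findOccurrences("AP", "RWAFAPGFAPGHIP")
#>   start end
#> 1     5   6
#> 2     9  10

digestSequence("RWAFAPGFAPGHIP", db, 1L)
#> DigestResult: RWAFAPGFAPGHIP, enzyme id(s) 1
#>   2 cleaved bond(s) of 13 (DH_T = 15.38%), 3 fragment(s): RWAF / APGF / APGHIP

pr <- buildProfile("RWAFAPGFAPGHIP", db, "ACE inhibitor")
frequencyA(pr)   # 0.1428571  = 2 occurrences / 14 residues
potencyB(pr)     # 0.03571429 = (2/4 uM) / 14, in uM^-1

ev <- enzymesForRelease("AP", "RWAFAPGFAPGHIP", db)[["AP"]]$events
ev[c("label", "side", "bond")]
#>   label side bond
#> 1    1N    N    4
#> 2    1C    C    6
#> 3    2N    N    8
#> 4    2C    C   10

toSmiles("GHS")
#> "NCC(=O)N[C@@H](Cc1c[nH]cn1)C(=O)N[C@@]([H])(CO)C(=O)O"
toInchiKey("GHS")
#> "LPCKHUXOGVNZRS-YUMQZZPRSA-N"
```

Releasing both copies of `AP` needs four proteolytic events; the
Phe-carboxyl enzyme catalyzes the two N-side events (bonds 4 and 8) but no
enzyme in this bundle cuts bonds 6 or 10, so `AP` itself is never freed —
it leaves the digest only inside the longer fragments `APGF`/`APGHIP`,
which is why `releasedBioactive()` reports `d_released = 0` and `W = 0`.

A command-line front end covering the same operations ships at
`inst/scripts/biopepkit.R`
(`Rscript .../biopepkit.R profile --db bundle.json --seq prec.fasta ...`).

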