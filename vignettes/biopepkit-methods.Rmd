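---
title: "Methods: precursor scoring, in-silico proteolysis and peptide encoding"
author: "biopepkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: precursor scoring, in-silico proteolysis and peptide encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopepkit)
```

## The screening model

`biopepkit` implements the fragmentomic view of protein bioactivity: short
peptides (often 2–3 residues) carry a biological activity of their own and
occur as common subsequences of many unrelated proteins. A precursor is
therefore characterized not by what it *is* but by what it *contains* and
by what a protease could *release* from it.

The primary object is the **activity profile**: for a query sequence of N
residues, every annotated peptide in the database is located in the query
(token-exact matching, all overlapping occurrences, 1-based inclusive
coordinates). From the profile come the precursor scores

- A = a/N, with a the total occurrence count for one activity, and
- B = [Σᵢ aᵢ/EC₅₀ᵢ]/N in µM⁻¹, a reciprocal-potency weighting in which a
  fragment ten times more potent contributes ten times more.

Proteolysis is simulated to completion under **specificity rules**. A rule
is (recognition sequence, cut-residue index, side): the enzyme recognizes
a contiguous motif and hydrolyzes the bond on the carboxyl side
(`side = "after"`, the "C-terminus" annotation, cutting sequence `X-`) or
the amine side (`side = "before"`, "N-terminus", `X+`) of the residue at
the cut index. Every matching bond is assumed cleaved — an acknowledged
simplification; real digests are incomplete, so the release scores are
upper bounds (false positives), while gaps in the annotated specificities
create false negatives. The digest quantities are A_E = d/N, W = A_E/A,
B_E = [Σⱼ dⱼ/EC₅₀ⱼ]/N, V = B_E/B, and the theoretical degree of
hydrolysis DH_T = d/D × 100 with D = N − 1 total bonds. Released-fragment
counting requires **whole-fragment identity** with an annotated peptide: a
digest product merely containing a bioactive subsequence does not count,
because the score models peptides *released*, not peptides *present*.

The **release planner** inverts the question: given a peptide and its
precursor, which bonds must break? Each internal occurrence needs one
N-side event (bond start − 1) and one C-side event (bond end), labeled
1N, 1C, 2N, 2C, … in occurrence order; each event lists every
(enzyme, connection) whose rule cleaves exactly that bond *in this
precursor*. N- and C-side enzyme lists are kept separate since the two
termini are frequently liberated by different proteases.

**Set-level screening** over L sequences (N_T total residues) aggregates
per target peptide: a_T = Σ a_l, a_S = a_T/L, A_S = a_T/N_T, and the
release counterparts a_TE, a_SE, A_SE. The per-sequence step-1 outputs are
bit-identical to the single-sequence tools; the aggregates are exact
integer ratios, which the test suite asserts as identities
(a_S·L = a_T, A_S·N_T = a_T, a_TE ≤ a_T).

## Sequence code and chemistry

Sequences use an extended one-letter code: uppercase = L-residues,
lowercase = D-enantiomers (no lowercase g — glycine is achiral), `B`/`b` =
L-/D-phosphoserine, trailing `~` = C-terminal amide. The amide marker is
not a residue: it does not count toward N, and a `~`-terminated fragment
can only match at the C-terminus of an amidated sequence, because an
internal residue cannot carry a terminal amide. Matching is
case-sensitive throughout: a D-residue is a different molecule from its L
form and annotated as a distinct peptide.

Elemental composition is the sum of in-chain residue formulas plus one
water; amidation substitutes NH₂ for the terminal OH (net −O +N +H);
phosphoserine is serine + HPO₃. Average and monoisotopic masses are
derived from this composition with IUPAC conventional atomic weights and
principal-isotope masses — never from a per-peptide mass table. Stored
`chemical_mass_Da`/`monoisotopic_mass_Da` fields are treated as display
data only: database mass fields in the wild are not always consistent with
the recorded structure, and recomputation from the formula keeps the mass
search and the mass report mutually consistent.

## SMILES, InChI and the validation oracle

`toSmiles()` concatenates one literal block per residue (free α-amine
through carbonyl, SwissSidechain/CycloPs layout) and closes the chain with
a one-atom suffix: `O` (acid) or `N` (amide). The leading `N` of the first
block is the free α-amine, so no N-terminal block variant is needed. A
D-residue block is the L block with every chirality tag inverted
(`@@` ↔ `@`); for Ile and Thr this inverts both centres, i.e. the full
mirror image, which is the correct D-amino acid. Blocks live in an
editable JSON data file; their mixed `[C@@H](…)`/`[C@@]([H])(…)` styles
are residue-specific data and deliberately not normalized, since byte-level
stability of the output strings is part of the contract. Phosphoserine is
encoded as the neutral phosphate and cysteine reduced, matching the
convention that identifiers describe neutral, stereo-defined, reduced
linear peptides. Only linear peptides are supported.

InChI and InChIKey derivation is delegated to a standard InChI
implementation behind a minimal backend contract (the OpenBabel `obabel`
executable); without it the core library still works and the InChI
operations raise an explicit unsupported-operation error.
`validateStructure()` closes the loop: the generated SMILES is re-parsed
by the backend and its molecular formula must equal the formula computed
independently from the residue composition table. The test suite adds a
second, fully independent oracle — a cheminformatics toolkit that builds
peptides from sequence with its own residue templates — and requires
agreement of complete InChI strings, checking connectivity, stereo and
protonation end to end.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `ec50_uM` | optional | µM | EC₅₀ and IC₅₀ are stored as one half-maximal field; B-type scores use them interchangeably. Non-positive values are demoted to absent with a warning: 1/EC₅₀ must stay finite, and scores skip unknown potencies rather than inventing zeros. |
| `cleaveModified` | `FALSE` | — | bonds flanked by D-residues/phosphoserine resist cleavage; most proteases do not accept D-residues near the scissile bond. Set `TRUE` to relax. |
| `lengthCap` (batch) | 1500 | residues | advisory warning only, mirroring interactive batch forms; the library handles longer sets. |
| CLI enzyme limit | 3 | — | interactive digestion tools conventionally offer 1–3 enzymes jointly; `--max-enzymes` lifts it, and the library accepts any number. |
| fixture `ec50Fraction` | 0.5 | — | roughly half of literature-annotated peptides carry a quantitative potency. |
| fixture EC₅₀ range | 0.01–1000 (log-uniform) | µM | spans nanomolar inhibitors to weak millimolar-range binders. |
| fixture lengths | 2–15 | residues | the size range of annotated food-derived bioactive peptides. |

## Design choices made where the design was open

- **Overlap counting.** Whether `a` counts overlapping occurrences is
  unspecified in the scoring literature; `biopepkit` counts them, since a
  fragment's bioactivity is positional and undercounting would bias A
  downward. The convention is isolated in `findOccurrences()`.
- **Database redundancy.** Duplicate (sequence, activity) records collapse
  to a single profile hit, so A does not depend on how many times a
  curator entered the same annotation; duplicates are flagged at load
  time. When duplicates disagree on EC₅₀, the lowest-id record with a
  known value supplies it.
- **Absent vs zero.** B, W, and V are reported as `NA` — not 0, not ∞ —
  when their numerator's potencies or their denominator are unavailable.
- **Terminal occurrences.** A peptide abutting a precursor terminus needs
  no cleavage on that side; such events are reported as TERMINAL with an
  empty enzyme list rather than being dropped, keeping the
  two-events-per-occurrence accounting visible.
- **Set score naming.** The mean release frequency is exposed as `A_SE`
  (with a_TE/N_T as its definition); the symbol `A_TE` appears in some
  descriptions of the same quantity and is documented as an alias.
- **Simultaneous digestion.** Multi-enzyme digestion is the union of the
  single-enzyme site sets (order-independent); sequential digestion
  schedules are out of scope.
- **Event deduplication.** Two occurrences sharing a bond are reported per
  occurrence in the release planner, but the digest's bond set is
  deduplicated with contributing rules merged.

## The synthetic fixture: what it does and does not emulate

`generateFixture()` produces a bundle with the *shape* of a curated
peptide database: records keyed one-per-(sequence, activity), a controlled
activity vocabulary, enzymes with 1–3 recognition/cutting rules, and a
realistic potency mix (see table above). Proportions in `activityMix` are
apportioned by largest remainder, so requested mixes are met within
rounding, and the same seed yields a byte-identical bundle.

It does **not** emulate: the sequence composition biases of real bioactive
peptides (proline-rich ACE inhibitors, cationic antimicrobials), real
enzyme specificities (rules are random motifs, not digested from MEROPS
matrices), bibliographic metadata, or database scale. Tests passing on
fixtures therefore certify the *algebra* of the scores and the *mechanics*
of matching, digestion and serialization — not any biological conclusion
about real precursors, and no count obtained from a live curated database
(hit totals for a given activity, per-database record numbers) is
reproducible offline by construction.

## Numerical and degenerate-input choices

- All score identities are exact integer ratios in double precision; tests
  compare them with `all.equal` tolerances only where a product of ratios
  is involved.
- Masses: the shipped atomic weights give monoisotopic sums accurate to
  well under 0.001 Da for peptides of this size, which is the tolerance
  the tests assert.
- A single-residue precursor has D = 0 bonds; DH_T is defined as 0.
- Bonds computed from a rule that fall outside [1, N − 1] (e.g. a
  carboxyl-side match at the C-terminal residue) are discarded.
- A release query peptide absent from the precursor yields a report with
  zero occurrences, not an error; an unknown activity label is an error.
- JSON serialization uses a fixed key order and full-precision numbers, so
  save → load → save is byte-identical (asserted in tests).

## Problem sizes

The test suite and the reproduction script run on deliberately small
inputs — fixtures of 25–60 peptides and 2–5 enzymes, precursors of 20–60
residues, property loops of 5–10 seeded repetitions — chosen so the whole
suite completes in seconds while still exercising every code path;
the score identities they check are size-independent.

## Known limitations

Endopeptidases only (no exopeptidase trimming); complete hydrolysis (no
kinetics, pH/temperature effects or cleavage probabilities); linear
peptides only (no disulfide, branched or cyclic structures); no
post-translational modifications beyond phosphoserine and the C-terminal
amide; activity is looked up, never predicted, so unannotated fragments
are invisible to every score.
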