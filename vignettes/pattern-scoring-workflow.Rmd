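---
title: "Substructure pattern scoring: fingerprints, signatures, and scaffold-filtered screening"
author: "PatternSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure pattern scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatternSig)
```

## The problem

Rare modes-of-action - such as the activation of an efflux transporter
like ABCC1 - are documented by small, structurally homogeneous compound
collections: a few dozen literature reports, a handful of chemical
classes, and bioactivities spread over several orders of magnitude. Such
datasets are too small and too biased for QSAR-style machine learning,
but they still carry exploitable structure: a curated catalog of
substructure patterns can describe the entire collection, and the
*pattern occurrence statistics* can rank a screening library.

`PatternSig` implements this workflow as a reusable library plus command
line: compound tables and substructure catalogs go in; occurrence and
flexibility fingerprints, a score-binned signature with a
primary/secondary tier partition, and scaffold-filtered ranked candidate
lists come out.

## Defined hydrogens and pattern compilation

Catalog entries are SMILES strings in which some hydrogens are written
explicitly as `[H]`. A written hydrogen marks a position that must stay
unsubstituted in any match; every unwritten hydrogen may be replaced by
an arbitrary substituent. `compilePattern()` turns a catalog SMILES into
a substructure query implementing exactly this:

* the pattern is canonicalised through OpenBabel first, so kekulé-written
  input is aromatised by the same perception model that parses the target
  molecules (one model, applied to both sides);
* each `[H]` becomes a minimum-hydrogen-count constraint on its heavy
  atom (`!H0`, or `!H0;!H1` for two written hydrogens, ...);
* stereo marks are stripped - the patterns are 2D; charges and isotopes
  must match exactly as written;
* multiple embeddings count once: all downstream statistics are
  presence/absence.

Because OpenBabel folds explicit hydrogens during canonicalisation, the
defined positions are protected as `[3H]` isotope markers for the round
trip and rewritten afterwards. The one consequence worth knowing: an
actual tritium atom in a catalog SMILES would be misread as a defined
hydrogen. Aromatic ring hydrogens that SMILES forces you to write, as in
pyrrole's `[nH]`, behave like defined hydrogens in matching (the atom
must carry that hydrogen) but are *not* counted as defined in the
flexibility bookkeeping, which counts `[H]` tokens only.

Each compiled pattern also records its hydrogen accounting, reading the
pattern as a molecule with implicit hydrogens filled by standard
valence:

```{r accounting}
as.data.frame(compilePattern("Oc1ccc([H])cc1", "S1"))[
  , c("n_heavy", "n_H_total", "n_H_defined", "n_H_variable", "flexibility")]
```

The **average flexibility** is the number of substitutable hydrogens per
heavy atom. Permissive patterns (dimethyl amine: 7 variable hydrogens on
3 heavy atoms, flexibility 2.33) score high; tightly specified patterns
with many defined hydrogens score low. A pattern in which *every*
hydrogen is defined has flexibility 0; its quotient fingerprints are
undefined and the signature falls back to the thresholded fraction
scores for it (this cannot occur in typical catalogs, but the contract
is total).

## The four fingerprints

Given a compound set, a catalog, and per-compound chemical-class labels,
`occurrenceMatrix()` computes the boolean compounds x substructures
matrix, and `fingerprintTable()` derives per substructure:

| fingerprint | value | definition |
|---|---|---|
| I | `f1` | fraction of compounds containing the substructure |
| II | `f2` | fraction of chemical classes with at least one matching member |
| III | `q3` | `f1 / flexibility` |
| IV | `q4` | `f2 / flexibility` |

Fingerprint II de-biases the dominant classes of a homogeneous dataset:
a pattern carried by a single large class has a large `f1` but `f2` of
only one class in however many there are. A class counts as containing a
pattern as soon as one member matches; any stricter quorum would be an
additional assumption. Fingerprints III and IV reward structural
specificity: at a fixed fraction the quotient grows as flexibility
shrinks. All fractions are kept on the 0-1 scale internally; formatting
to percent happens only at I/O.

## From values to the signature

`binScore()` maps any non-negative fingerprint value to an integer score
0-10 with lower bin edges `0.01, 0.10, 0.20, ..., 0.90`. Bins are
inclusive at the lower edge, open above (a value of exactly 0.20 scores
3, anything at or above 0.90 scores 10). The inclusive-lower reading is
forced by the workflow's own presence rule - "at least 20% present"
corresponds to score 3 - and makes the bins tile `[0, Inf)` without
gaps; the largest quotient observed in any given catalog is an
observation, not a cap.

The fraction fingerprints I/II are then thresholded: below 20% presence
the score is zeroed. One exception - the *gap fill*: when the paired
quotient fingerprint scores above 2 (III for I, IV for II) and the
zeroed raw score was 1 or 2, that raw score is restored. This keeps
structurally specific but rare patterns in play. The pairing III->I,
IV->II mirrors how the quotients are constructed from the fractions;
quotient scores themselves are never thresholded.

The total score is `s1 + s2 + s3 + s4` (0-40). Independently of the
scores, each substructure is classified:

* **primary positive**: fraction occurrence (I and/or II) >= 20%; *or*
  quotient (III and/or IV) >= 0.2 together with fraction occurrence
  >= 10%;
* **secondary positive**: everything else.

The thresholds (0.20, 0.2, 0.10) are the workflow's published constants
and are exposed as configuration. `buildSignature()` orders the table by
total score descending; equal totals are broken by higher `s1`, then
higher `s3`, then substructure id - the ordering of equal-total rows is
not otherwise meaningful, it is merely fixed.

## Scaffold-filtered screening

`defaultScaffolds()` ships the five basic ring-system cores used as
library pre-filters: chromone, xanthone, phenothiazine, purine and
9-deazapurine. Scaffold detection is plain substructure containment of
the named core - no Bemis-Murcko reduction, no ring pruning - so a
xanthone also reports the embedded chromone core, and a molecule may
legitimately carry two scaffolds. Exclusive assignment, where wanted, is
a reporting choice left to the caller.

`screenLibrary()` filters a library to scaffold-bearing compounds,
matches them against the catalog, and scores each compound as the sum of
the signature totals of its distinct matched substructures, per tier
selection (primary / secondary / combined). Summing the published totals
is the minimal aggregation consistent with "scoring according to
primary and/or secondary positive substructures"; count- or max-based
alternatives would discard the signature's ranking information. Ranked
lists are produced per (scaffold x selection) with deterministic
tie-breaks: more distinct matched primary substructures first, then
lower molecular weight, then compound id. `shortlistBalanced()` stands
in for the human "balanced selection" step: a greedy round-robin over a
CLogP x MW grid that takes the best unused candidate per occupied cell
until `k` compounds are chosen. It deliberately encodes no expert
judgment beyond property balance.

## Descriptors

`computeProperties()` reports CLogP, MW, MR, TPSA, H-bond donors and
acceptors, rotatable bonds and heavy atoms from OpenBabel; every output
carries a `descriptor_provider` tag. MW and the simple counts are
implementation-independent; CLogP, MR and acceptor definitions are
provider-specific, so parity with values computed by other descriptor
engines is not promised and no unit conversion is attempted. CLogS is
not offered by this provider and is reported as `NA`. Molecules are used
exactly as given - no charge normalisation - so a zwitterion and its
neutral form give different CLogP. Dataset summaries use the
mean-of-middle-two median by default (`median = "lower"` selects the
lower-middle convention).

## The synthetic generator

`generateCompoundSet()` exists so that every stage is testable with
known ground truth and no downloads. Its default study shape follows the
curated activation dataset: 174 compounds in 18 classes with the
published class sizes (70 flavonoids, 31 verapamil analogs, ...). Each
planted substructure is inserted into exactly `round(frequency * n)`
molecules, optionally restricted to classes. Host molecules and decoy
decorations are purely aliphatic, so aromatic or heteroatom-bearing
planted patterns cannot arise by accident; the generator additionally

* refuses patterns that would match an undecorated host (e.g. a pure
  alkyl pattern), and pattern pairs where one is implied by the other's
  carrier fragment - both are *planting conflicts*, reported before
  generation;
* rejects valence-corrupt assemblies (OpenBabel tolerates some
  hypervalent neutral atoms when parsing concatenated SMILES; explicit
  probes for neutral O/N/C with impossible valences filter them);
* verifies the finished set against the matcher: the ground truth must
  be recovered exactly, accidental extras are counted and reported.

What the generator does **not** emulate: real medicinal chemistry
(molecules are valence-valid but not drug-like), correlated
substructures (real catalogs contain nested and overlapping patterns),
bioactivity values, or catalog breadth (tests use a handful of patterns,
not hundreds). Passing tests therefore demonstrate that the *statistics
and bookkeeping* are exact and deterministic - planted frequencies are
recovered bit-exactly, matching agrees with an independent toolkit on
tame chemistry - not that the workflow's biological conclusions transfer
to any particular real dataset.

Problem sizes in the shipped tests are chosen for exactness, not scale:
fingerprint recovery runs at n = 100 over five seeds, the study-shaped
pipeline at n = 174 with four planted patterns, screening at libraries
of a few dozen molecules. All randomness flows through explicit seeds;
reruns are byte-identical.

## Numerical and degenerate-input choices

* Bin edges are compared with `findInterval`, i.e. inclusive lower
  edges; scores are exact integers throughout.
* A flexibility of 0 yields `NA` quotients, never `Inf`; downstream the
  signature substitutes the thresholded fraction scores.
* Empty pattern sets give 0-column occurrence matrices; empty libraries
  give empty (but well-formed) screening results with a warning.
* Readers skip-and-report invalid rows by default and fail fast under
  `strict`; duplicated identifiers are always an error, since silently
  dropping one record would corrupt every downstream fraction.
* Matching is invariant under rewriting the target SMILES because both
  sides pass through one canonicalisation/perception model.

## Limitations

* Aromaticity perception is OpenBabel's; a catalog tuned against a
  different perception model may classify borderline rings differently.
* Tautomers are not enumerated; a purine written as one tautomer matches
  that tautomer's hydrogen placement only.
* Ring-nitrogen hydrogens (`[nH]`) are constrained in matching but not
  counted as defined hydrogens (the bookkeeping counts `[H]` tokens),
  so N-substituted analogues of such patterns do not match.
* Scaffold filtering is containment-based: exclusive scaffold tallies
  (counting a xanthone only under xanthone) require post-hoc resolution
  by the caller.
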