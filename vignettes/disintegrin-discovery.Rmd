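---
title: "Motif-based discovery of putative disintegrins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based discovery of putative disintegrins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disintegrindb)
```

## The problem and the model

Disintegrins antagonize integrin receptors by presenting a tripeptide
recognition sequence on a loop held open by a disulfide bridge. The
residues that matter for detection by sequence alone are therefore the
tripeptide itself and the two cysteines that bracket the loop. The
search pattern implemented here is a literal tripeptide — one of RGD,
MLD, KGD, VGD, KTS, RTS, WGD, RED by default — with a cysteine
required within a bounded spacer window on each side:

```
C - x(0,16) - X Y Z - x(0,16) - C
```

This is a pattern search, not a homology search: it finds candidates,
including proteins from unrelated folds (lipocalins, Kunitz-domain
protease inhibitors, antigen-5 proteins) that have convergently
acquired an exposed motif. Every hit is *putative*; functional
confirmation is outside the scope of sequence analysis, which is why
the annotation module labels its integrin assignments as putative
targets of the motif class rather than properties of the protein.

### Matching semantics

The scanner examines every occurrence of every configured tripeptide
(occurrences may overlap each other). An occurrence is reported iff a
cysteine lies within the left window and one within the right window;
when several qualify, the **innermost** cysteine is reported on each
side, giving one canonical match per motif occurrence rather than one
per cysteine pair — this matches the loop picture (the bracketing
cysteines closest to the motif form the loop) and avoids combinatorial
duplication. Flanking cysteines must lie strictly outside the
tripeptide. A single cysteine may close one loop and open the next
(`CRGDCRGDC` has two matches sharing the middle cysteine). Coordinates
are 1-based throughout. The unknown residue `X` is accepted in input
sequences but never matches a pattern position; patterns themselves may
not contain `X`.

Two decisions deserve a note. First, the spacer bound is applied
symmetrically (0–16 on each side); the pattern is sometimes written
asymmetrically, but the biology it encodes — a motif flanked by
cysteines — is symmetric. Second, scanning runs on the **full
precursor**, signal peptide included: a match upstream of the predicted
cleavage site is kept but flagged `overlaps_signal`, because a mature
protein would not contain it. Filtering happens at the sequence level
(secreted or not), not at the residue level.

### Verification

The scanner is verified against an independent brute-force reference
(`enumerate_flanked_motifs()`): enumerate every (left-cysteine,
occurrence, right-cysteine) triple, filter on the spacer definition,
keep the innermost flank on each side. The two implementations share no
code path — the scanner works with per-occurrence windows, the
reference with explicit triple enumeration — and the test suite
requires exact set equality on all coordinate fields over 1000 random
sequences with cysteine frequency elevated to 8% (lengths 20–400),
plus boundary cases at spacers (0,0), (16,16) and 17.

## The secretion gate

The original discovery run kept only proteins with a predicted signal
peptide. Signal-peptide prediction here is a deliberately transparent
heuristic modelled on the classical tripartite architecture, so that it
is exactly reproducible offline:

* **n-region**: positions 1–10 contain K or R, or the sequence starts
  with M;
* **h-region**: positions 1–30 contain a run of ≥ 8 consecutive
  residues from {A, I, L, M, F, V, W};
* **cleavage site**: the first position `p` after the h-region end
  (searched up to 45, a ceiling on plausible signal length) with small
  residues {A, G, S, C, T} at `p−2` and `p` — the (−3,−1) rule;
  fallback h-end + 5, capped at 45 and at length − 1;
* **score**: h-run length / 30, capped at 1. Sequences shorter than 15
  residues are never called secreted.

This is not a reimplementation of a neural-network predictor and is
not expected to reproduce one's accept/reject set on real proteins.
Users who have run a real predictor can import its verdicts as a TSV
(`load_external_predictions()`); imported verdicts take precedence over
the heuristic, because measured predictions should beat a rule of
thumb. The gate has two policies: `require` (drop non-secreted records,
logging each drop) and `annotate` (keep everything, carry the verdict).

## Annotation, duodegrins, and the database table

Each motif class maps to the integrin and cell targets reported for
characterized members of that class: RGD and WGD to the
αIIbβ3/αvβ3/α5β1 group on platelets and endothelial cells, KGD
selectively to αIIbβ3, MLD to the leukocyte integrins α4β1/α4β7/α9β1,
KTS and RTS selectively to the collagen-IV receptor α1β1, VGD to the
fibronectin receptor α5β1, and RED to αIIbβ3 (the disagregin-style
substitution of RGD on a Kunitz fold). The mapping is shipped as data
(an editable TSV schema), not code, because all of these assignments
are putative for pattern-discovered sequences.

A **duodegrin** is a sequence carrying more than one tripeptide motif
of *distinct* types (VGD with RTS, RED with VGD, ...). Two occurrences
of the same motif — common in some fly platelet-aggregation-inhibitor
families with one or two RGDs — raise `n_matches` but do not flag the
sequence; every in-context usage of the term involves distinct pairs,
so the distinct-type rule is the consistent reading. When user-supplied
motifs overlap in sequence the same rule applies without further
interpretation.

The output table has one row per match (12 fixed columns: identifiers
and taxon metadata, motif and coordinates, spacers, signal overlap,
targets, duodegrin flag, sequence length), sorted by (organism code,
sequence id, motif start) with byte-stable radix ordering so repeated
runs are byte-identical.

## Phylogenetics

The phylogram module consumes alignments (aligned FASTA or Clustal
blocks) — computing multiple alignments is out of scope.

* **Distance**: uncorrected p-distance with pairwise gap deletion.
  Phylogram scale bars in this literature read "% amino acid
  divergence", i.e. a raw proportion; no substitution-model correction
  is applied and none is claimed. A pair with zero comparable columns
  is an error naming the pair rather than a silent NaN.
* **Tree**: standard Saitou–Nei neighbor joining (via `ape::nj`).
  Negative branch lengths, which NJ can produce on non-additive input,
  are clamped to zero after computation (the raw values are retained in
  an attribute) so the phylogram stays drawable. On additive matrices
  the tree reproduces all splits and leaf-to-leaf path lengths to
  within 1e-9; the suite checks this on 100 random trees and checks the
  three-taxon closed form ((d(A,B)+d(A,C)−d(B,C))/2 etc.) exactly.
* **Supports**: `replicates` column resamples with replacement
  (seeded), NJ on each, and the support of each internal bipartition of
  the full-data tree is the rounded percentage of replicate trees
  containing it — supports annotate the displayed tree, not a consensus
  tree. A replicate that produces an undefined p-distance is resampled
  and counted. The default of 1000 replicates is a conventional choice.
  One caveat: NJ tie-breaking necessarily depends on taxon order, so on
  degenerate data (exactly tied Q criteria, e.g. many duplicated
  columns) supports can shift by a replicate or two under a permutation
  of the input leaf order; on tie-free data they are exactly invariant.
* **Newick**: branch lengths with six decimals, integer supports as
  internal node labels; round-trips through standard parsers within
  1e-6.

## The synthetic proteome generator

Offline testing needs inputs whose ground truth is known *exactly*.
The generator emulates the shape of a downloaded secreted-protein set:

* taxon labels and five-letter organism codes drawn from the eleven
  blood-feeder taxa that scope a discovery run (Ixodoidea,
  Cimicomorpha, Tabanidae, Glossina, Culicidae, Psychodidae,
  Simuliidae, Ceratopogonidae, Siphonaptera, Hirudinea, Rhabditida);
* background residues uniform over the 20 amino acids with a
  configurable cysteine weight (default 2%, roughly natural abundance;
  the oracle stress tests elevate it to 8% to exercise flanking);
* signal peptides built to satisfy the gate heuristic *by
  construction* (M-K + hydrophobic run + A·A cleavage site);
  non-secreted sequences have their 1–30 window broken so no
  hydrophobic run of 8 can occur — the planted secretion status is the
  gate's exact expected output, which is what makes 100% recall /
  rejection a meaningful fixture property rather than an empirical one;
* planted motifs `C + spacer + XYZ + spacer + C` with spacers drawn
  uniformly from 0–16 and kept cysteine-free, so the planted flanks are
  provably innermost and the ledger coordinates are exact;
* three decoy kinds: no cysteine anywhere in one window
  (undetectable), a spacer of exactly 17 (undetectable, probing the
  boundary), and a motif inside the signal region (detectable, expected
  `overlaps_signal`);
* optional duodegrin plants (two distinct motifs in one sequence).

Defaults (`n = 200` for pipeline-level checks, lengths 90–260, signal
fraction 0.7, motif density 0.45, decoys ~8% each) give a proteome
where every stage has work to do and every count is predicted. Because
the random background can still create *accidental* motifs, the
generator audits its ledger with the brute-force enumerator before
returning it: accidental hits are added as ledger entries, planted
decoys are verified absent. After the audit, "database rows = ledger
rows" is an exact equality, not a statistical statement.

What the fixtures deliberately do **not** emulate: real amino-acid
composition, homology between sequences, codon-level structure, or
signal peptides that fool a real predictor. Passing tests demonstrate
the algorithmic contracts — pattern semantics, gate determinism,
bookkeeping exactness — not discovery performance on a live sequence
repository, which depends on the repository snapshot and the external
predictor used.

## Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; seeded helpers
  save and restore the global RNG state.
* Output orderings use byte-order (radix) sorting, floats are printed
  with fixed formats, and no timestamps enter output files, so pipeline
  reruns are byte-identical (checked with file hashes).
* Problem sizes in the shipped tests (1000-sequence oracle stress,
  200-sequence pipeline fixture, 100 NJ recovery trees, 200 bootstrap
  replicates) are chosen so the full suite runs in well under a minute
  while leaving each property nowhere to hide.
* Degenerate inputs have defined behavior: empty FASTA → empty outputs
  with exit 0; all-tied distance matrices → deterministic NJ output;
  header-only prediction tables → empty maps; ragged alignments and
  unknown residues → errors naming the offender.

## Known limitations

* The signal-peptide heuristic is a gate, not a predictor; its
  false-positive/negative behavior on real proteomes is uncharacterized
  by design, and external predictions should be imported for real runs.
* Only literal tripeptide + bounded-cysteine-flank patterns are
  supported — no character classes or general PROSITE grammar.
* Non-standard residues (B, Z, U) are rejected rather than translated;
  how such entries were handled in historical runs is not documented
  anywhere we could follow, so refusal is the safe behavior.
* Gene-ontology and BLAST-derived family columns of the original
  worksheet are out of scope: they depend on external services and no
  derivation method is stated for them.
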