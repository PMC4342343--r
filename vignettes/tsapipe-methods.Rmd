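---
title: "Methods: models, surrogates and design choices in tsapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, surrogates and design choices in tsapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsapipe)
library(dplyr)
```

`tsapipe` reimplements, as one tested toolkit, the downstream analyses
that typically follow a Trinity *de novo* transcriptome assembly of a
non-model animal's nervous system: assembly summarization, ORF
discovery and classification, unigene reduction, expression
quantification, secreted-protein prediction, neuropeptide derivation,
and cross-sample decontamination. This vignette records the models each
stage assumes, the constants that matter and why they have the defaults
they do, and the design decisions taken where more than one reasonable
convention exists.

## Assembly model and summary metrics

Trinity names transcripts `comp{X}_c{Y}_seq{Z}`: components are putative
gene loci, subcomponents gene-like clusters within them, and `seq`
indices isoforms. All stages key off this hierarchy, and identifiers
without a `_seq` suffix are accepted as subcomponent-level records
(isoform 1), because expression tables are produced at the
subcomponent ("gene") level.

N50 is computed on total assembled bases: the largest length $L$ such
that contigs of length $\ge L$ jointly cover at least half of all bases,
resolved at the contig length where the descending cumulative sum first
reaches half. GC content excludes ambiguous bases from numerator and
denominator; an all-N assembly yields `NaN` rather than a misleading 0.

## ORF discovery and completeness

The scanner enumerates stop-to-stop segments in all six frames and
reports at most one ORF per segment:

* an ATG in the segment → ORF from the *first* ATG, `complete` if the
  segment is stop-terminated, `partial_3prime` otherwise;
* no ATG, segment open at the transcript 5′ end → `partial_5prime` if
  stop-terminated, `internal` if open at both ends;
* no ATG in a stop-bounded interior segment → nothing (an ORF with
  neither evidence of a start nor the excuse of truncation is not a
  credible coding region).

Reporting only the first-ATG ORF per segment avoids counting one
segment under two classes. The default minimum length is 100 amino
acids, the conventional protein-prediction cut-off; it is a parameter,
not a claim about coding potential — there is deliberately no
hexamer/Markov coding score here, so selection is purely by length and
completeness. Codons containing N translate to X, which counts toward
length but can never act as start or stop; this keeps ORF lengths
stable under sporadic ambiguity. Coordinates are 0-based half-open on
the forward strand of the transcript (minus-strand ORFs store the
forward-strand coordinates of their region), and the stop codon is
excluded from both peptide and coordinates.

## Unigene reduction and E-value summaries

Two reductions are supported: the longest contig per component (LCPC,
the operational "unigene" sequence; ties to the lexicographically
smallest identifier) and the best hit per component over tabular
homology hits (BHPC: maximal bitscore, then lowest E-value, then
subject id). Hit tables use the de facto standard 12-column tabular
dialect; extra columns are ignored. E-value range summaries assign each
hit to one half-open interval `(upper_{i+1}, upper_i]`; when the final
edge is 0 the last bin holds exact zeroes only, and when it is positive
the last bin absorbs everything at or below it, zeroes included — both
conventions appear in published tables, so both are expressible.
E-values of 0 are kept as exact zeroes, never floored.

## Quantification: TPM and EM allocation

TPM is computed from estimated counts and effective lengths with
effective length equal to sequence length: no fragment-length
correction is applied because no fragment model is available for the
data this package targets, and all downstream consumers (expression
shares, ratio rules) need only relative abundances.

The EM allocator treats a read as generated by choosing a subcomponent
with probability $\theta_i$ and a position uniformly along its length,
so a read compatible with set $S$ has likelihood
$\sum_{i \in S} \theta_i / l_i$. The E-step assigns reads fractionally
$\propto \theta_i/l_i$; the M-step sets $\theta_i$ to expected counts
over total reads, which maximizes the complete-data likelihood, so the
observed-data log-likelihood is non-decreasing — the test suite asserts
this per iteration. Initialization is uniform; convergence is declared
when the largest TPM change falls below $10^{-3}$ (on a scale of
$10^6$) with a 1,000-iteration cap; identical inputs give identical
output (no randomness inside the fit). Reads are collapsed into
equivalence classes of identical compatibility sets first, making cost
proportional to the number of distinct classes rather than reads.

## The secretome cascade and its surrogate scorers

The cascade reproduces the classical secreted-protein filter: inputs
are start-bearing (complete or 3′-truncated) non-redundant proteins;
a protein is *secreted* iff its signal-peptide score is at least 0.5,
it lacks a mitochondrial presequence, and it has no transmembrane
helix — or exactly one ending within the first 60 residues, since such
early "helices" are overwhelmingly signal peptides mis-assigned by
hydropathy. The 60-residue rule is evaluated on the helix *end*
coordinate.

Rather than wrapping external predictors, the three decisions are made
by transparent scorers with the same decision contracts:

* **Signal peptide.** Three binary features on residues 1–45: n-region
  basicity (a K/R within residues 2–8), h-region hydrophobicity (some
  7-residue window within residues 5–30 with mean Kyte–Doolittle score
  ≥ 1.8), and a c-region cleavage site obeying the (−3,−1)
  small-residue rule (−1 ∈ {A,G,S,C,T,Q}, −3 ∈ {A,G,S,C,T,V,I,L}) at
  position 15–45. They combine through a fixed logistic
  (`sp_weights()`: intercept −4.3; weights 0.9, 2.6, 1.9) chosen so the
  contract holds *exactly*: all three features ⇒ score ≥ 0.5, while a
  missing h-region or missing cleavage site ⇒ score < 0.5. The reported
  cleavage position is the best site, ranking by how canonical (small:
  A/G/S) the −1 and −3 residues are and breaking ties toward the
  N-terminus. The 0.5 threshold is a contract match with the filter the
  cascade implements, not a probability calibration claim.
* **Transmembrane helix.** Window-17 Kyte–Doolittle hydropathy;
  maximal runs of window centers above 1.6 spanning at least 15
  centers (runs separated by fewer than 5 centers merged), extended by
  half a window to residue intervals. Window 17 and threshold 1.6 are
  the classical hydropathy-analysis convention for membrane spans; all
  three constants are arguments.
* **Mitochondrial presequence.** Composition of residues 2–30: ≥ 4
  arginines, ≤ 1 acidic residue, ≥ 2 serines/threonines. A protein
  whose N-terminus simultaneously shows a fully canonical cleavage
  site *and* a qualifying h-region is treated as a signal peptide
  instead — the same arbitration targeting predictors perform between
  the two competing N-terminal signals.

Redundancy removal is exact: duplicates and exact substrings collapse
to the longest representative. A similarity-threshold mode was
deliberately not implemented — exactness keeps the stage fully testable
and order-invariant, at the cost of leaving near-identical allelic
variants separate.

## Prohormone processing

Cleavage sites sit immediately after the basic residues of a dibasic
pair (KR, RR, KK, RK; overlapping pairs — basic runs — merge into one
site at the run end) or after a monobasic arginine licensed by an
additional basic residue at offset −4, −6 or −8. Two refinements
matter in practice: the licensing basic must itself be a *lone* basic —
residues already consumed by a dibasic site do not double as spacing
partners, otherwise every repeat adjacent to a cleavage site would be
spuriously subdivided — and monobasic sites immediately followed by
proline are suppressed, reflecting convertase disfavor. Sites inside
the signal peptide are discarded.

Fragments between sites are trimmed of flanking K/R runs; a remaining
terminal glycine is removed as the amide donor and the peptide flagged
amidated. The stage satisfies an exact conservation law — kept
peptides, trimmed basics and removed glycines jointly reconstruct the
mature region — which the tests assert on random precursors, and it is
idempotent on already-mature peptides. Repeat counting compares derived
peptides (amidation-normalized) against a motif, so a precursor with
*n* planted `peptide-G-KR` cassettes counts exactly *n*.

## Decontamination

Co-multiplexed samples contaminate one another at low levels; the
removal rule captures the expected signature: a component is dropped
when any member sequence aligns into the other assembly over at least
50 nt at ≥ 97% identity while expressed at no more than 1/10 of the
matched sequence's TPM. All three comparisons are inclusive.
Ratio comparisons use subcomponent-level TPM of the specific matched
sequences; a subject with zero TPM cannot certify contamination (an
unexpressed source is no evidence of carry-over). Removal is
component-atomic.

The aligner is a k-mer (k = 21) seeded, greedily extended local
aligner (match +1, mismatch −2, gap −2.5, X-drop 20; at each mismatch
the three edit options are compared by the exact-match run each
re-synchronizes to). This is adequate because the rule only consults
the near-identity regime; the test suite cross-checks identities
against a full local dynamic-programming alignment and requires
agreement within 0.5 percentage points. A pre-computed tabular hit
file can be substituted for the internal aligner.

## The synthetic generator

`generate_transcriptome()` emulates the statistical structure the
stages assume: a multi-component assembly with isoform groups (extra
isoforms are internal deletions of the first), log-normal contig
lengths (median 363 nt, heavy tail to ~20 knt, the shape typical of
molluscan CNS assemblies), GC content 39.4%, an ORF class mix of
51.3 / 19.6 / 12.7 / 16.4 percent, and planted protein families. The
defaults are the study conditions the tests run under; they were chosen
once, from the characteristics summarized above, and the acceptance
benchmarks run at those defaults.

Implementation choices worth knowing:

* Untranslated regions are drawn from {C,G,T} — an alphabet containing
  neither ATG nor any stop codon in any frame — which lets planted ORF
  boundaries and classes be exact truth labels rather than
  probabilistic ones.
* Coding sequence is drawn codon-wise with synonymous choices weighted
  toward the target base composition; background contig composition is
  then *solved* so the realized assembly-wide GC lands on target
  (within ±2 points, asserted in tests).
* Protein templates are parameterized families, not fixed strings: the
  signal peptide is M + basic n-region + 8–10 hydrophobic residues +
  c-region ending in a canonical S-x-A site; mitochondrial presequences
  spread 5–7 arginines evenly across residues 2–30 (so no 7-residue
  window becomes h-region-like) with no acidics; cytosolic controls use
  natural residue frequencies with a hydrophilic-leaning N-terminal 40
  residues — the biological contrast the signal-peptide scorer relies
  on. This keeps predictor tests non-trivial: the scorers see varied
  instances, not their own constants echoed back.
* Secreted precursors carry `KR`-flanked peptide repeats with amide
  glycines; a third are emitted 3′-truncated to exercise the
  `c_terminal_truncated` path of the cascade.
* Reads are drawn with probability ∝ θ·length (θ is the molar/TPM-scale
  proportion); an ambiguity fraction gains compatibility with a random
  sibling subcomponent. Contamination injection copies components
  across assemblies with per-base substitutions and assigns the copy a
  TPM equal to `expression_ratio` times the source.

What the generator does **not** emulate — and hence what green tests do
not show about real data: sequencing error and coverage gradients,
fragment-length effects on quantification, paralogy and repeat families
(homology between distinct true genes), non-classical secretion,
signal anchors, and amino-acid composition biases of real proteomes
beyond the frequency tables used. Benchmarks on these synthetic
conditions bound implementation correctness, not biological accuracy of
the surrogate predictors on real proteins.

## Problem sizes and determinism

The test and benchmark sizes were picked to give stable statistics at
interactive run times: 1,000 random sequences for the ORF
finder-vs-oracle equivalence, 50,000 reads for EM proportion recovery
(errors are compared against three binomial standard errors), 430
labelled proteins for cascade sensitivity/specificity (floors at 0.9),
and 20 planted contaminants at 1% relative expression and 1% mutation
for decontamination recall (floor 19/20). Everything downstream of a
seed is deterministic: the generator, the EM fit and the pipeline
driver contain no un-seeded randomness, and the full pipeline is tested
to produce byte-identical reports across runs with the same
configuration.

## Known limitations

* The signal-peptide and targeting scorers are rule-based surrogates;
  their scores are decision devices honouring published thresholds, not
  calibrated probabilities, and they will underperform learned models
  on real sequences (twin-arginine signals, signal anchors, and
  lineage-specific presequence variants are out of scope).
* Exact-substring deduplication does not merge allelic or
  fragment-overlapping variants that a clustering tool would.
* The greedy aligner is tuned for the ≥ 97% identity regime the
  contamination rule consults; it is not a general homology search
  tool, and divergent-homology alignment should come from a dedicated
  aligner whose tabular output the pipeline accepts directly.
* Quantification has no fragment-length, positional or GC bias model;
  TPM values are comparable within a run, not across libraries.
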