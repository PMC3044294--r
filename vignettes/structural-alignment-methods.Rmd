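---
title: "Methods: greedy maximum expected accuracy structural alignment of RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: greedy maximum expected accuracy structural alignment of RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamea)
```

## The problem and the model

Non-coding RNAs conserve their folded structure better than their primary
sequence, so a useful multiple alignment of an RNA family must agree with
the common secondary structure, not only with sequence homology.
Progressive aligners commit to pairwise merge orders early and propagate
early errors; `rnamea` instead builds the alignment *non-progressively*, by
greedily assembling a directed acyclic graph (DAG) of alignment columns
from the most trustworthy evidence first.

Two posterior probability families drive everything:

* **Base-alignment probabilities** `P_a(x_i ~ y_j)` — the probability that
  position `i` of sequence `x` and position `j` of `y` are matched in the
  (unknown) true alignment.  They are computed by forward–backward over a
  three-state (match / insert-x / insert-y) pair hidden Markov model, in
  log space.
* **Base-pairing probabilities** `P_b(x_i ~ x_j)` — the probability that
  positions `i < j` of one sequence pair in its (unknown) secondary
  structure, marginalised over the Boltzmann ensemble of all pseudoknot-free
  structures by an inside–outside partition-function computation.

Both matrices are stored sparsely: entries below a threshold (default
0.01) are dropped, which on realistic families keeps only a few nonzero
entries per row and makes the consistency stage fast.

## Consistency transformations

Three transformations sharpen the posteriors with information from the
whole sequence set before any alignment decision is made.

1. **Inter-sequence consistency.**  For each pair `(x, y)` the alignment
   matrix is replaced by a homology-weighted average of relay products
   `P_xz P_zy` over all sequences `z` (including `x` and `y` themselves
   with identity self-relays).  The weight of relay `z` is
   `P(x◊z)·P(z◊y)`, where the homology probability `P(x◊y)` is the
   expected accuracy of the pairwise maximum-expected-accuracy (MEA)
   alignment: the summed posterior along the MEA path divided by the
   shorter sequence length.
2. **Intra-sequence consistency.**  Each sequence's pairing matrix is
   mixed (weight `alpha`, default 0.4, on the original) with the
   homology-weighted expectation of its homologs' pairing matrices mapped
   through the alignment posteriors, `A P̂_b(y) Aᵀ`.  Soft homology
   weights replace a hard homolog set: each sequence contributes in
   proportion to its homology probability.
3. **Four-way consistency.**  Each alignment matrix is mixed (weight
   `beta`, default 0.1, on the structural term) with
   `P̂_b(x) P_a P̂_b(y)`: an alignment `(i, j)` is reinforced when the
   structural partners of `i` and `j` also align.

The transforms run in that order, once by default (`rounds` is exposed).
Homology probabilities are computed once from the untransformed posteriors
and reused, which avoids feedback instability.  All three are implemented
as sparse matrix products; after each transform values are clamped to
[0, 1] and re-pruned so no entry below the sparsity threshold survives.

The printed forms of these transformations (and of the homology
probability and the Step-1 match score below) are reconstructions in the
style of the cited probabilistic-consistency lineage; the package
documents them explicitly so that the dense brute-force oracles used in
the test suite are unambiguous.

## Graph construction

The alignment is a DAG whose vertices are columns (at most one residue per
sequence) and whose edges are precedence constraints from residue
adjacency.  Two legality rules are enforced: the graph stays **acyclic**
after every insertion, and Step-1 paired columns satisfy **left-right
compatibility** (for a stem's paired columns, every sequence's left
residue precedes its right residue).

* **Step 1 — structural skeleton.**  All base pairs with transformed
  pairing probability above `tb` (default 0.5) form the candidate set
  **B**, sorted by probability.  For each unused pair `(x_i, x_i′)` the
  best partner pair `(y_j, y_j′)` from another sequence maximises
  `P′_a(x_i ~ y_j) · P′_a(x_i′ ~ y_j′)`; both endpoint alignments are
  inserted transactionally.  Two admission rules guard against noise
  anchors: the match score, being a probability, must clear the same
  sparsity threshold used everywhere else, and the match must be
  *reciprocal-best* (the anchor is also the partner's best-scoring match),
  which suppresses shifted stem registers.  Each base pair participates in
  at most one skeleton match.
* **Step 2 — local alignments.**  All stored alignment entries, sorted by
  transformed probability, are inserted one at a time subject to
  acyclicity (left-right checking for Step 2 is available as the stricter
  `strict_lr` switch).  A new pair either creates a column, extends one,
  or merges two; redundant (transitively implied) edges are pruned after
  each insertion.
* **Linearisation.**  Residues never inserted are wrapped in singleton
  columns, per-sequence adjacency edges are completed, and the columns are
  emitted in a deterministic topological order (Kahn's algorithm; among
  ready columns the one whose lowest-indexed member sequence and position
  sort first is emitted).  Any legitimate topological ordering yields a
  valid alignment; the fixed tie-break makes runs byte-reproducible.
  De-gapping any output row reproduces its input sequence exactly — this
  invariant is asserted throughout the test suite.

Ties anywhere in candidate ordering are broken by (probability descending,
sequence id lexicographic, left index, right index), so the whole pipeline
is deterministic.

## Discriminative refinement

For each sequence `x` in turn: the set of sequences similar to `x` is
found by k-means (k = 2 by default, deterministic farthest-point
initialisation) over homology-probability feature vectors; `x`'s row is
removed and realigned against its cluster's profile by posterior-sum
profile dynamic programming (column-pair score = summed transformed
posterior between member residues, gap score 0); finally the cluster
profile is profile–profile aligned with the rest.  After each full pass
the total posterior score of the alignment is compared with the pre-pass
score and the better alignment is kept, making the expected-accuracy
objective non-decreasing by construction.

Refinement improves low-similarity regions *without breaking the
confidently aligned bases*: the base alignments inserted by the
structural skeleton (Step 1) have their posteriors saturated to 1 in the
refinement's scoring, so tearing a skeleton anchor apart is never
profitable.  Without this protection the refinement objective — a pure
sequence-posterior sum — undoes the structural gains of the skeleton on
low-identity families, pulling stems back to the (wrong) sequence
consensus.  The protection is deliberately limited to the skeleton's own
insertions, which the reciprocal-best admission rule makes highly
reliable; saturating whole paired columns would also freeze Step-2
residues that may be misplaced.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.4 | weight on a sequence's own pairing matrix in the intra-sequence transform |
| `beta` | 0.1 | weight on the structural term in the four-way transform |
| `tb` | 0.5 | minimum transformed pairing probability for skeleton candidates |
| `threshold` | 0.01 | sparsity threshold for all probability matrices |
| `rounds` | 1 | consistency rounds |
| `passes` | 1 | refinement passes |
| `k` | 2 | k-means clusters in refinement |

`alpha`, `beta` and `tb` follow the aligner's standard setting; the
sparsity threshold 0.01 keeps the matrices in the few-nonzeros-per-row
regime that the sparse complexity analysis assumes (inter-sequence
transform `O(μ²Lm³)` for `μ` nonzeros per row, `m` sequences of length
`L`).

The pair-HMM defaults (`match_prob = 0.6`, gap-open `delta = 0.02`,
gap-extend `epsilon = 0.7`, uniform insert emissions) form a deliberately
simple, fully documented parameterisation — identity-favouring match
emissions rather than a trained substitution model.  All parameters can be
overridden programmatically or from a YAML file.

The pairing model is a Boltzmann-weighted Nussinov-style ensemble, not a
full thermodynamic nearest-neighbour model: canonical pair weights
(GC = 6, AU = 3, GU = 1.5, in stability order), a minimum hairpin loop of
`h = 3`, and a stacking bonus (`stack = 8`) multiplying every directly
stacked pair of pairs.  The stacking term is what concentrates probability
mass on contiguous helices, as thermodynamic ensembles do; without it the
ensemble is too diffuse for any true stem to reach the `tb` confidence
needed by the skeleton.  The simple model keeps the partition function
exactly checkable against exhaustive structure enumeration, which the test
suite exploits.

## The synthetic family generator

`simulate_family()` provides ground truth without external data.  It
samples a nested stem-loop structure (minimum hairpin 3, stems 3–8 bp
biased towards GC), an ancestral sequence, and a two-level phylogeny: deep
branches to subfamily ancestors and shallow branches (rates scaled by
`within_scale = 0.25`) to the descendants of each of two subfamilies.
Substitutions at paired sites are compensatory with probability 0.95 —
mostly Watson–Crick to Watson–Crick, with rare wobble excursions — and hit
stems at a higher deep-branch rate (0.7 per pair) than unpaired sites
(0.25): stems diverge in sequence while staying paired, the covariation
signal that structural aligners exploit.  Indels are confined to unpaired
regions so the true alignment is unambiguous at stems.  Candidate
ancestors are resampled (best of up to 40 draws) until the designed stems
dominate the Boltzmann ensemble, reflecting that real structured families
are under selection to fold into their native structure.  The defaults
produce mean pairwise identities around 0.55–0.60.

What the generator does **not** emulate: realistic phylogenies beyond two
levels, pseudoknots, non-canonical pairs, structure variation across the
family, indels inside stems, and base composition biases of particular
Rfam families.  Passing tests on these families therefore demonstrate the
machinery works as specified under its stated assumptions — not that
benchmark accuracies on curated databases are reproduced.

## Numerical and design choices

* All pair-HMM dynamic programming is in log space with log-sum-exp; the
  forward and backward totals are required to agree to 1e-8 in the tests.
* The partition function is computed in linear space with an overflow
  guard; for the lengths this package targets (≲ 500 nt) doubles are
  ample.
* MEA and profile dynamic programs break ties deterministically (match,
  then gap in the second profile, then the first).
* When a transform's homology-weight denominator is zero (no informative
  relay), the matrix is left unchanged rather than zeroed.
* Degenerate inputs: a single input sequence is emitted unchanged with a
  warning; sequences without canonical pairs yield empty pairing matrices
  and the pipeline degrades to sequence-only greedy alignment; `N` is
  scored as the marginal over the four bases and never pairs.
* Reachability queries on the alignment graph use exact depth-first
  search; the test suite cross-checks acyclicity with an independent
  Floyd–Warshall closure after every insertion.

## Problem sizes used by the checks

The test suite verifies the posterior machinery against exhaustive
enumeration (alignments for lengths ≤ 4 over 50 parameter draws;
structures for lengths ≤ 12 over 50 model draws), the sparse transforms
against dense oracles on 100 random instances (m ≤ 4, L ≤ 10), graph
legality across 200 randomized constructions, two-sequence MEA agreement
on 100 simulated pairs (L = 20), the skeleton benefit on 20 families at
the generator defaults (m = 6, L = 80), and the m³ scaling trend of the
inter-sequence transform at L = 40, m ∈ {4, 8, 16}.  These sizes exercise
every contract at full strength while keeping a complete run of the suite
within a few minutes on one CPU.

## What the skeleton buys

On the generator's default low-identity families the structural skeleton
improves the mean sum-of-pairs score relative to a skeleton-disabled run,
but the effect is modest (fractions of an SPS point on average, with
occasional multi-point rescues of individual families) and not uniform:
a family whose posteriors coherently prefer a shifted stem register for
one sequence pair can anchor that shifted register, and the refinement
objective (a posterior sum) is not the sum-of-pairs score it is evaluated
by.  The test suite asserts the mean improvement over a fixed panel of
twenty families; single families can go either way.

## Known limitations

* The pairing ensemble is qualitative: probabilities are well-calibrated
  relative to the model, not to thermodynamics; absolute values differ
  from Turner-model computations.
* The pair-HMM is untrained; on real, distantly related families a trained
  parameterisation would give sharper posteriors.
* The skeleton's benefit depends on stems reaching confident transformed
  pairing probabilities; families whose structure is not ensemble-dominant
  fall back to sequence-level greedy construction.
* SCI (structure conservation index) is only available through the
  external RNAalifold/RNAfold hook; it is reported as unavailable when the
  tools are absent.

## A worked example

```{r example}
fam <- simulate_family(m = 4, L = 60, seed = 7)
aln <- rna_align(fam$sequences)
aln
sps(aln, fam$alignment)
```
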