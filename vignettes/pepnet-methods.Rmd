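---
title: "pepnet: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepnet: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

`pepnet` predicts, from primary sequence alone, (1) the probability that a
peptide (1–50 residues) interacts with a protein (> 50 residues) and (2) a
binding score for every peptide residue. The two tasks are learned jointly:
the per-residue labels, where available, act as auxiliary supervision that
also sharpens the pair-level decision, and the per-residue output is of
direct practical value when choosing positions for chemical modification.
Protein-side binding-residue prediction is deliberately out of scope:
proteins are an order of magnitude longer, residue supervision on the protein
side is far noisier, and the package's design (one compact peptide head on
per-position features) does not transfer to that setting.

## Feature profiles

Every sequence becomes a fixed-length, masked profile.

**Categorical tracks.** (a) Amino-acid identity: codes 1–21 over the 20
canonical residues plus `X` for anything non-standard; 0 is reserved for
padding. (b) A combined (amino acid, secondary structure) code using the
3-class alphabet {H, E, C}: `code = (aa − 1) × 3 + ss`, an explicit bijection
onto 1..63. Any injective indexing of the 21 × 3 grid carries the same
information; we fix this one and test its bijectivity exhaustively. (c) A
polarity/hydropathy class code. The shipped table
(`inst/extdata/polarity_hydropathy.tsv`, editable) classifies side chains as
nonpolar/polar/charged and bands the Kyte–Doolittle index at ±2 into
hydrophobic/neutral/hydrophilic; `X` has its own unknown/unknown category.
The 21 letters fall into 7 distinct class pairs, so this channel is coarser
than identity by design — it lets the model share statistical strength across
chemically similar residues.

**Numeric tracks.** Three per-residue intrinsic-disorder scores in [0, 1]
for both roles; proteins additionally carry a 20-column PSSM. Raw PSSM
log-odds read from files are squashed through the logistic `1/(1+e^{−x})`,
which maps them to [0, 1] on the same scale as the disorder tracks;
providers that already emit probabilities pass through unchanged.

**Providers.** PSSM, secondary structure and disorder normally come from
external predictors. The package consumes them through a provider interface
(manifest TSV → per-sequence sidecar files) and ships deterministic stub
providers — Dirichlet-like normalized rows for the PSSM, a sticky 3-state
Markov chain for secondary structure, smoothed uniform noise for disorder —
seeded from a hash of the sequence. The stubs are plumbing, not biology: they
make every downstream stage runnable and testable without external binaries,
and any conclusion that depends on *real* evolutionary or structural signal
requires real providers.

**Padding.** Peptides are zero-padded to 50. Proteins need a cap too; the
default is 800 with tail truncation (N-terminus kept, with a warning), and
fits use `min(800, longest protein in the data)`. Padding uses code 0 /
numeric 0 / mask 0 everywhere, embedding row 0 is frozen at zero, and every
stage re-applies the mask, so all outputs are invariant to the amount of
trailing padding (a tested property, not an aspiration).

## Network

Per role, the three categorical channels are embedded at `embed_dim` each and
the numeric tracks pass through an affine map to `embed_dim`, giving
per-position vectors of width `4 × embed_dim`. Two reductions run in
parallel:

* **CNN.** Three length-preserving 1-D convolutions with ReLU; activations at
  masked positions are zeroed after every layer. Column-wise max pooling over
  real positions yields the branch vector. Zeroing masked activations
  (rather than only masking at the pool) is what makes the residue head and
  the padding-invariance property exact.
* **Self-attention.** Single-head scaled dot products on the *embedding*
  output (not the CNN features): the CNN captures local context, attention
  captures global, position-pair structure, and feeding it the embeddings
  keeps the two reductions complementary rather than stacked. Padded keys are
  excluded from the softmax (equivalently, logit −∞); each attention row is
  therefore a probability distribution over real positions. The attended
  vectors are mean-pooled over real positions — a reduction has to be chosen,
  and the masked mean is the neutral one (max pooling here would duplicate
  the CNN's reduction).

The pair head concatenates the four pooled vectors into FC layers
(`fc_sizes`, then 1) with ReLU and inverted dropout after the first two
layers (training mode only), ending in a sigmoid. The residue head applies
`b_j = σ(W·h_j + c)` to each pre-pooling peptide CNN row; `c` is a single
shared bias — a per-position bias would be meaningless under variable-length
input and padding. Padded positions are scored (they get `σ(c)`) but every
consumer masks them.

Default architecture: `embed_dim` 16, filters 64/64/128 with kernels 7/5/3,
`d_k` 32, FC 256/128/1, dropout 0.2. These are conventional magnitudes for
sequence CNNs of this size; everything is configurable, and the tests use a
much smaller configuration (below).

## Objective, training, thresholds

The pair loss is the mean binary cross-entropy. The residue loss is a masked
cross-entropy; since the number of real positions `M_i` varies per sample, we
normalize each sample by its own `M_i` and then average over samples, so a
short peptide counts as much as a long one. Pairs without residue labels
(all sampled negatives, and any unannotated positives) contribute zero to the
residue term and receive no residue-head gradient. Probabilities are clipped
at `ε = 1e−7` before logs — purely numerical. The combined objective is
`loss_pair + λ·loss_pep`.

Both classifications use the inclusive threshold: a score of exactly 0.5 is
called positive.

Optimization is RMSProp (decay 0.9, ε 1e−7) over hand-derived
backpropagation; a finite-difference check on a small model holds to
1e−4 relative error, which pins down every backward path (embeddings,
convolutions, both pooling routes, attention, both heads). All stochasticity
— initialization, shuffling, dropout, sampling — derives from one seed, and
refitting with the same seed reproduces weights bit-for-bit.

**Defaults `λ = 0.5`, learning rate `2e−3`.** λ weights an auxiliary task, so
values below 1 are natural; but with λ an order of magnitude smaller the
residue head receives so little gradient that it stays near chance within a
few dozen CPU-scale epochs, while λ = 0.5 trains both heads fully without
hurting the pair task (the learnability tests exercise exactly this regime).
The learning rate 2e−3 simply reaches the same optimum in fewer epochs than
1e−3; both are configurable.

## Homology-aware evaluation

Benchmarks built from curated complexes contain families of similar entities,
and random cross-validation lets a model score well by recognising relatives
of training entities. The package therefore implements similarity-clustered
splitting: normalized Smith–Waterman similarity
`SW(a,b)/√(SW(a,a)·SW(b,b))` under BLOSUM62 with gap open 11 / extend 1 (the
standard protein parameterisation), single-linkage clusters at a threshold
`t` (defaults offered: 0.3/0.4/0.5), and fold constructions in which clusters
— never individual entities — cross the train/test boundary:

* `novel_protein` / `novel_peptide`: clusters of that role are distributed
  over k groups, balancing pair counts greedily (largest cluster first into
  the lightest group — deterministic);
* `novel_pair`: peptide clusters and protein clusters are each split into 3
  groups; the 3 × 3 grid gives 9 folds in which the test block shares neither
  a peptide nor a protein cluster with its training block. Some pairs are
  unused in any given fold — the price of double disjointness;
* `random`: a seeded k-fold partition of pairs, the baseline regime.

`leakage_check()` re-audits any plan against the cluster assignment and lists
violating (fold, entity) pairs; `make_folds()` output must always pass it.

Negative sampling draws, per positive, `ratio` peptide × protein combinations
uniformly without replacement, excluding known positives and duplicates —
"shuffled pairs" interpreted as uniform sampling over the non-positive
combination space. At the reference curation scale (7417 positives over 5399 peptides
× 3412 proteins, ratio 5) this yields a 44,502-pair benchmark exactly,
which the acceptance script recomputes.

**Metrics.** Rank-based ROC AUC (ties at half weight), AUPR by step
integration over distinct thresholds, per-pair residue AUC (pairs lacking
both residue classes are skipped and counted), and residue MCC at 0.5. MCC
is *pooled* over all unmasked residues of all labelled pairs by default —
the pooled count statistics are well-defined even when single peptides are
degenerate — with a per-pair-averaged variant available via
`mcc_per_pair = TRUE`.

## The synthetic generator

`simulate_interactions()` emulates the statistical skeleton the model
assumes: interaction is driven by a *complementary motif rule*. Every peptide
and every protein carries one planted k-mer (k = 4) from a library of
complementary (peptide, protein) motif pairs; a pair interacts iff the motif
indices match. Positives pair matching entities and carry binding vectors
that are 1 exactly at the planted peptide positions (then flipped with
probability η; default η = 0, the clean construction). Negatives are sampled
uniformly from mismatched combinations, so no negative contains a
complementary motif pair — verified by exhaustive k-mer scan in the tests.
Backgrounds are i.i.d. uniform over the 20 canonical letters, organised into
`n_families` mutated-ancestor families (default substitution rate 0.05) so
that similarity clustering has real structure to find. The default library
holds two motif pairs: with one pair, motif *presence* alone would separate
the classes; with two, the model must learn the *pairing*, which is the
point of the architecture.

What the generator does **not** emulate: real amino-acid composition, motif
degeneracy, structural context, or informative PSSM/disorder features (the
stub features are noise). Passing the learnability tests shows the
architecture, objective, and training machinery can extract a planted
sequence-pair signal end-to-end; it says nothing about accuracy on real
interactomes, which depends on real features and curated labels.

## Numerical choices and degenerate inputs

* Softmax rows are stabilized by subtracting the row maximum.
* Max-pool argmax ties break to the first (lowest-index) position; gradients
  flow to that single position.
* Empty masks (no real position) are errors for pooling and attention;
  samples with `M_i = 0` contribute zero to the residue loss by convention.
* MCC returns 0 when any denominator factor vanishes; AUC and AUPR refuse
  single-class inputs.
* Normalized SW clamps negative local scores at 0 (can only occur for exotic
  scoring schemes) and is exactly symmetric.
* `sample_negatives()` indexes the combination space as a single integer
  range and therefore requires it below 2³¹; larger universes should be
  sampled in id-partitioned blocks.

## Problem sizes used by the test suite

The suite trains compact models (embed 4, filters 8/8/16, `d_k` 8, FC
32/16/1) on generated datasets of 40–200 positives with proteins up to 300
residues — sizes chosen so the full suite, including three 30-epoch fits of
the 200-positive task and a five-seed held-out-residue check, completes on a
single CPU in well under half an hour. The acceptance script mirrors those
sizes. Oracle-equivalence tests run on micro instances (N ≤ 7 positions for
attention, sequences ≤ 18 aa for alignment) where brute force is exact.

## Known limitations

* Stub features carry no signal; with them the model can only learn from raw
  sequence composition, which is exactly what the synthetic task provides.
* Training is single-threaded R; at the reference benchmark scale (44k pairs,
  proteins to 800 aa) a fit is an overnight job, not the minutes-scale runs
  of the test suite.
* The similarity threshold interacts with sequence length: for very short
  peptides a shared 4-mer already yields normalized SW ≈ 0.2–0.3, so
  clustering thresholds at the low end merge unrelated short peptides that
  share a motif. This mirrors the behaviour of local alignment, not a bug in
  the clustering.
* The ensemble option in the CLI is plain prediction averaging over seeded
  models; no stacking or calibration.
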