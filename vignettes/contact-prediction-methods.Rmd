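---
title: "Contact prediction from alignment covariation: model, features and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact prediction from alignment covariation: model, features and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactnet)
```

## The problem

Two residues of a protein are in *contact* when their C-beta atoms lie
within 8 Å in the native structure (C-alpha for glycine). Contacting
positions constrain each other evolutionarily: substitutions at one are
compensated at the other, so the columns of a deep multiple sequence
alignment (MSA) covary at contact pairs. `contactnet` turns an MSA into a
pairwise feature tensor that exposes this covariation and feeds it to a
deep, fully convolutional residual network that outputs a per-pair
contact probability map.

## The feature tensor

For a protein of length $L$ the network input is a $501 \times L \times
L$ tensor (see `channel_manifest()`):

* **Striped per-residue features (50 channels).** The 21-state sequence
  profile (20 amino acids + gap), 3-state predicted secondary structure
  and predicted relative solvent accessibility are each defined per
  residue; every per-residue column $v$ becomes two $L \times L$ maps,
  $v_i$ (constant along rows) and $v_j$ (constant along columns), so the
  convolution sees both residues' features at every pair.
* **Pair statistics (8 channels).** Mutual information in nats, its
  APC-corrected form (subtracting $\bar m_i \bar m_j / \bar m$ over
  off-diagonal pairs), the joint column entropy, a profile-weighted mean
  contact-potential map, three externally computed coupling maps
  (PSICOV / CCMpred / FreeContact style, zero-filled when not supplied),
  and the mean per-column gap fraction of the pair.
* **Raw covariance (441 channels).** For every ordered residue-type pair
  $(a, b)$ over the 21-state alphabet, channel $(a,b)$ holds
  $f_{ij}(a,b) - f_i(a) f_j(b)$: the deviation of the weighted joint
  column frequency from independence. Sequences are weighted by the
  inverse of their 62%-identity neighbourhood size before counting, so
  redundant alignment rows do not dominate.
* **Geometry channels (2).** A sequence-separation map
  $\min(|i-j|, 100)/100$ and an all-ones bounds channel. The bounds
  channel lets the first convolution distinguish true zeros in the data
  from the zero padding a fully convolutional architecture introduces at
  the sequence boundary.

Estimation details worth knowing:

* MI and entropy sums run over cells with $f_{ij}(a,b) > 0$ only. A
  positive joint cell forces both marginals positive, so no pseudocount
  or floor is required and analytic cases (a perfectly coupled
  two-symbol pair gives exactly $\ln 2$) hold to machine precision.
* Covariances use the raw (unfloored) frequencies. At every pair the 441
  covariance cells sum to zero — a useful invariant the tests exploit.
* Channels enter the network unscaled. The Maxout input layer followed
  by instance normalization adapts to the very different channel
  magnitudes (covariances are $O(10^{-2})$, entropies $O(1)$); this is a
  deliberate simplification and the main cost is slower early training.
* The 20x20 contact-potential table shipped with the package is a
  synthetic stand-in built from the Kyte-Doolittle hydropathy scale
  ($p_{ab} = -h_a h_b / 25$; hydrophobic pairs score favourably). It is
  *not* a published statistical potential; it fills the feature slot
  with a physically sensible, deterministic surrogate.

## The network

`model_config()` defaults describe the full-scale model: the 501
channels pass through a convolutional Maxout layer (two 1x1 linear
pieces, elementwise max) down to 64 feature maps — with two pieces a
Maxout unit can represent $|w \cdot x|$, a natural detector for
covariance magnitude — then instance normalization, then 18 residual
blocks. Each block is conv(5x5, dilation $d$) → ReLU → conv(5x5, $d$) →
add input → ReLU. The dilation schedule alternates regular and dilated
blocks as 1, 2, 1, 4, 1, 8, 1, 16, 1, 32, 1, 64, followed by six regular
blocks; the receptive field, $1 + \sum_{\text{convs}} 4d = 1105$
residues, comfortably covers any chain. A 1x1 convolution, instance
normalization and a sigmoid produce the $L \times L$ score map;
`symmetrize()` averages scores for $(i,j)$ and $(j,i)$, and
`ensemble_predict()` averages several independently initialized models
(canonically five).

Design points that were genuinely open:

* The Maxout layer's kernel size is not pinned down by the architecture
  description; 1x1 is used, reading the layer as a learned channel
  reduction. Residual-block filters are 5x5.
* Both convolutions of a block share the block's dilation rate, and no
  normalization is applied inside blocks — instance norm appears only
  after the input layer and before the output sigmoid.
* The first block's skip connection is an identity: the input is already
  64 channels wide, so no projection is needed.
* Maxout uses two pieces; more pieces buy little and cost linearly.

Forward and backward passes are implemented in the package itself (conv
kernels in C++ via im2col + BLAS); gradient correctness is established
against central finite differences in the test suite.

## Training

Training minimizes the masked binary cross-entropy: the mean of
per-pair BCE over upper-triangle pairs with sequence separation at
least 5 (trivially short-range pairs are excluded from both the loss
and the validation metric). Examples pass through the network one at a
time with gradients accumulated over a batch of 8 — examples of
different lengths therefore never need padding — followed by one Adam
step (initial learning rate 0.001, Xavier-uniform initialization).
Batch loss is the mean of per-example mean losses, so long proteins do
not dominate. After each epoch the mean per-protein Matthews
correlation coefficient (threshold 0.5) on a validation set is
computed; training stops when it has not improved for `patience`
(default 10) consecutive epochs, and the best-MCC weights are returned.
Validation MCC is averaged per protein rather than pooled over pairs,
so short and long validation chains count equally. A non-finite loss
aborts with a diagnostic rather than silently continuing.

Three augmentations run on the fly per batch:

1. **Loop sampling.** With probability 0.5, and only when at most 40% of
   residues are loops, each loop residue is deleted with probability
   0.3: its row and column are removed from every channel and the truth
   map, and the separation channel is recomputed for the new length.
   Deletion (not masking) is implemented — recomputing the separation
   map only makes sense when the chain actually shortens.
2. **Feature interpolation.** When a second tensor built from a shallow
   alignment of the same protein is available, the input becomes
   $m X_1 + (1-m) X_2$ with one uniform $m \in [0,1]$ per example; the
   truth map is never interpolated. This simulates alignments of
   continuously varying quality.
3. **180° flips.** With one batch-level coin of probability 0.5, flipped
   copies (both spatial axes reversed — a chain reversal) are appended
   to the batch. The separation channel is invariant under the flip and
   the bounds channel is all ones, so both survive unchanged.

## Effective sequence counts

`compute_meff()` reports the number of clusters from greedy incremental
clustering at 62% identity: rows sorted by descending non-gap length
(ties by input order), each row joins the first representative it is at
least 62% identical to, else founds a cluster. Identity is identical
aligned non-gap matches over the shorter sequence's non-gap length.
The k-mer prefilter used by fast clustering tools is an optimization,
not part of the statistic's definition, and is not implemented; the
brute-force greedy scan is exact at desk scale.

## Evaluation

`topk_precision()` follows the CASP conventions: long-range pairs have
$|i-j| \ge 24$, medium-range 12–23; the top $\lfloor L/k \rfloor$
highest-scoring eligible pairs (minimum 1) are taken with deterministic
tie-breaks (descending score, then ascending $(i,j)$), and precision is
the percentage that are true contacts. `aggregate_table()` reproduces
mean-precision summaries over the packaged per-domain assessment table,
and `splice_domain_scores()` copies re-predicted domain score blocks
back into a full-length map. RR-format readers and writers round-trip
predictions with 1-based indices sorted by descending probability.

## The synthetic generator

Real training corpora (thousands of PDB chains with deep alignments)
are far beyond desk scale, so `make_family()` builds fixtures with the
statistical structure the method assumes:

* `generate_toy_structure()` packs ideal alpha-helices (rise 1.5
  Å/residue, 100°/residue, C-beta radius 2.3 Å) on a circle with
  alternating up/down axes, connected by outward-arcing loops, and
  retries until the chain is self-avoiding (min 3.5 Å for $|i-j| \ge 3$)
  and has long-range contacts. Helix axes sit 9.5 Å apart so adjacent
  helices form contact seams. Lengths of at least ~40 residues are
  needed for $|i-j| \ge 24$ contacts to be geometrically possible;
  the packaged experiments use $L = 60$.
* `sample_coupled_msa()` draws i.i.d. sequences from a Potts-like
  model: per-column fields plus, for every contact with $|i-j| \ge 5$, a
  coupling of strength 2 (in the packaged experiments) favouring one
  compatible residue pair in both orientations, Gibbs-sampled with 25
  sweeps. Couplings are restricted to $|i-j| \ge 5$ so the learnable
  signal lives entirely inside the loss mask. Gaps are injected at rate
  0.05 in loop columns (the query row stays gap-free). Coupling
  strength 0 recovers independent columns — the null the tests check.
* The shallow alignment of a family is a query-preserving row subsample
  of the deep one, standing in for a lower-quality alignment of the
  same protein as the mixup partner.
* Residue features come from the generator's ground truth: profile =
  weighted empirical column frequencies, secondary structure = one-hot
  true labels smoothed 0.9/0.05/0.05, solvent accessibility = min-max
  scaled distance from the coordinate centroid.

What the generator does *not* emulate: phylogenetic correlation between
rows (sequences are i.i.d. draws), realistic gap patterns, beta-sheet
topologies (structures are all-alpha bundles), higher-order epistasis,
and alignment errors. Tests passing on these fixtures therefore show
that the pipeline detects pairwise covariation and trains stably — not
that it matches published precision on real proteins, which would
require the original training corpus and alignments.

## Scaled-down experiment sizes

The packaged end-to-end experiment (in the test suite) trains a reduced
model — 4 residual blocks, width 16, dilations 1, 2, 4, 1 — on 30
synthetic families ($L = 60$, 300 deep / 30 shallow sequences, coupling
strength 2) and evaluates top-$L/5$ long-range precision on 10 held-out
families against 3x the random-selection baseline, taking the median
over 3 training seeds. For this short run (8 epochs of 30 examples) the
learning rate is raised to 0.005 — with only ~120 optimizer steps the
full-scale rate of 0.001 leaves the model near its initialization,
while 0.01 is visibly unstable; 0.005 trains cleanly. All other
training settings keep their defaults. As a reference point, ranking
pairs by raw covariance-channel energy alone reaches roughly 30%
long-range top-$L/5$ precision on such families, so the bar verifies
genuine learning, not the ceiling.

## Known limitations

* All-pairs frequency tables are dense; memory grows as $O(L^2 \cdot
  441)$, which is fine for desk-scale chains (hundreds of residues) but
  not optimized for proteome-scale runs.
* The identity-clustering Meff is exact greedy, $O(N^2 L)$; very deep
  alignments (tens of thousands of rows) will be slow.
* The network trains on one CPU; there is no device or multi-process
  support.
* External coupling maps are consumed, never computed: the package does
  not reimplement PSICOV, CCMpred or FreeContact.
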