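---
title: "Link prediction for drug-target interaction on a pocket-similarity knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link prediction for drug-target interaction on a pocket-similarity knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

pocketDTI predicts binary drug-target interactions by link prediction on a
heterogeneous proteome-wide graph. Nodes are protein targets and drugs. Five
typed edge sets connect them:

* `target_sim` -- two targets are joined when the cosine similarity between
  the language-model embeddings of any pair of binding-pocket residues
  (the nested maximum over pockets and residues) strictly exceeds 0.95;
* `drug_sim` -- two drugs are joined when the cosine similarity of their
  chemical language-model embeddings strictly exceeds 0.8;
* `ppi` -- protein-protein interactions kept when the combined confidence
  score is at least 700 *and* the experimental or database channel reaches
  700 (inclusive thresholds, following the sources' "at least" semantics,
  versus the strict "greater than" of the similarity rules);
* `bind` -- labeled binding interactions (positives and negatives) used
  exclusively for supervision;
* `bind_mp` -- positive-only binding interactions from a knowledge-base
  source used exclusively for message passing, never for the loss.

The encoder is a stack of (by default three) heterogeneous transformer
convolutions. For one edge type with destination $i$ and in-neighbours
$\mathcal{N}(i)$,

$$x_i' = W_1 x_i + \sum_{j \in \mathcal{N}(i)} \alpha_{ij} W_2 x_j,
\qquad
\alpha_{ij} = \mathrm{softmax}_j\!\left(\frac{(W_3 x_i)^\top (W_4 x_j)}{\sqrt{d}}\right),$$

with a single attention head and $d$ the layer's output dimension. Each edge
type owns its message weights $W_2, W_3, W_4$; the self-transform $W_1$ is
shared per node type within a layer. (With a per-edge-type self term, an
edge type that happens to have no edges would still shift every node's
embedding, so removing an empty edge type would not be a no-op; with a
per-node-type self term it is, and an isolated node's update reduces to
$W_1 x_i$ exactly.) Per-edge-type outputs are aggregated by sum (mean is
available), undirected edges are expanded into two directed messages, and
binding edges contribute two typed relations (drug to target, target to
drug). ReLU is applied between, not after, the convolutions. A virtual hub
node with a learned feature vector connects to every drug node through a
dedicated edge type, is updated like any node, and is dropped from the
matrix handed to the link head. Raw inputs (drug embeddings; targets
represented by the mean of their pocket residue embeddings) are linearly
projected to the embedding dimension per node type before the first layer.

The link head concatenates a drug and a target embedding, in that order, and
applies affine, Leaky ReLU (slope 0.01), affine, sigmoid. Training minimizes
mean binary cross-entropy over labeled pairs with Adam; negatives come from
the labeled set itself, never from random sampling. The full graph is
encoded once per gradient step; batching applies only to the supervision
edges.

## Supervision/message-passing discipline

Labeled binding edges never message-pass: internally, no message-passing
relation is ever constructed from the labeled table, and every epoch records
a hash of the adjacency actually used, which is compared against the
allowlisted one. Auxiliary positive-only edges are the only binding edges
that message-pass and never enter the loss. `auditLeakage()` checks a plan
against a graph before any training starts; `trainModel()` refuses plans
with violations. A pair present in both binding sources is kept as
supervision and removed from the message-passing set, so no pair is both
evidence and label.

# Splits

The random split shuffles interactions 80:10:10. The drug-similarity split
is the rigorous protocol: drugs are clustered by Tanimoto distance between
substructure fingerprints (average-linkage agglomeration by default; the
linkage is configurable because the sources do not pin it down), the
dendrogram is cut at a fixed number of clusters, and clusters are assigned
whole to five cross-validation folds plus a held-out test set, so all of a
drug's interactions share its cluster's partition. Cluster-to-partition
assignment is a seeded greedy procedure: clusters in decreasing interaction
count go to the partition with the largest relative quota deficit. The
realized test fraction must land within a configurable tolerance of the
target, otherwise the plan construction fails loudly with the cluster
inventory.

Auxiliary (knowledge-base) drugs are assigned to the cluster with the most
similar medoid fingerprint; a fold may only message-pass auxiliary records
whose drug maps to a cluster in that fold's *training* partition -- not its
own validation clusters and not test clusters. Epochs are selected post hoc
by validation AUROC (earliest epoch on ties); the test partition is scored
once, at the selected epoch.

# Training regularization

Three conventional augmentations are on by default; each counters a
shortcut that is measurably harmful for cold-start (held-out chemistry)
generalization:

* **Drug feature dropout** (`featureDropout`, default 0.9): each training
  step zeroes each drug node's raw feature vector with probability $p$;
  after training, the $(1-p)$ test-time scale is folded into the drug input
  projection, so checkpoints score full-feature graphs directly. Without
  it, the trunk memorizes a lookup from drug feature vectors to their
  training labels and transfers nothing to drugs whose chemistry was never
  labeled.
* **Edge dropout** (`edgeDropout`, default 0.3): each epoch drops each
  undirected message-passing edge (jointly with its reverse direction).
  This prevents memorizing node identities through exact neighborhood
  constellations; attention renormalizes per destination, so evaluation on
  the full edge set needs no rescaling.
* **Feature noise** (`featureNoise`, default 0.1): Gaussian noise added to
  all raw node features per step, so single nodes cannot be identified from
  minor feature idiosyncrasies (e.g. a model fitting the label-noise flips
  of single targets).

Defaults that matter, with units: embedding dimension 128 (32 is used in the
package's own studies, which are small), trunk depth 3, head hidden width =
embedding dimension (the sources leave it open), learning rate $10^{-3}$,
batch 512 supervision edges, epoch budget 100 with post hoc selection. All
randomness of a run flows from one integer seed; plans and epoch logs are
reproducible to serialization identity and $10^{-6}$ respectively.

# The synthetic data generator

`generateBundle()` emits the five input tables with planted structure, so
the whole pipeline is testable without external databases:

* **Targets** fall into families; each family has a unit-norm archetype in
  residue-embedding space and residues are archetype plus Gaussian noise,
  renormalized. The default noise (0.03 at dimension 32) keeps the maximal
  residue-pair cosine within a family above the 0.95 edge threshold and
  across families below it; generation verifies the realized margins and
  fails with quantiles when a configuration is infeasible.
* **Drugs** fall into chemotypes with unit-norm embedding archetypes
  (within-chemotype cosine above 0.8, across below). A chemotype's
  archetype also mixes in `drugProfileWeight` (0.3 in the strong preset)
  times the sum of fixed random "pharmacophore" directions of its
  compatible families -- but only for a visible fraction of families
  (`profileVisibleFraction`, default 0.5). Chemical language-model
  embeddings do encode some binding determinants; a generator whose
  features carry either all or none of the binding rule makes cold-start
  evaluation either trivial or impossible. Fingerprints are archetypal
  on-bit sets per chemotype with per-bit dropout and additions.
* **Auxiliary-only drugs**: a pool of drugs per chemotype appears only in
  the positive-only message-passing source, never labeled (knowledge-base
  pools are much larger than curated labeled sets; the auxiliary record
  count is `auxFraction` times the labeled count, 1.0 in the strong
  preset). With probability `fpDecoupleRate` (0.5) an
  auxiliary drug's fingerprint is drawn from another chemotype's archetype:
  fingerprint space and embedding space are only partially correlated in
  real chemistry, and this partial decoupling is exactly why a
  medoid-assignment rule can reduce but not eliminate message-passing
  leakage around held-out chemistry.
* **Binding truth** is a random family-by-chemotype compatibility matrix at
  `compatibilityDensity` (0.5 in the strong preset), with fix-ups
  guaranteeing every family and every chemotype at least one compatible and
  one incompatible partner. A chemotype compatible with everything has no
  genuine negatives, and its held-out evaluation would be degenerate by
  construction. Labeled interactions are sampled stratified by family with
  a flat positive rate per family (curated benchmarks are balanced;
  without stratification, per-family label frequencies alone dominate
  cold-start ranking). Labels flip with probability `labelNoise` (0.02).
* **PPIs** are within-family pairs with passing confidence scores (drawn in
  [700, 1000]) plus cross-family background records with failing scores
  (in [0, 699]), which exercises the boundary of the filter.

`strongRegime()` freezes the preset used by the acceptance studies: 5
families of 40 targets, 8 chemotypes of 25 labeled drugs plus 25
auxiliary-only drugs each, 2,400 labeled interactions, drug embeddings of
dimension 128 (noise 0.025).

## What the synthetic data does and does not show

The generator reproduces the geometry the method exploits -- similarity
cliques, guilt-by-association paths through auxiliary binding edges, a
recoverable planted rule -- but not real chemistry: embeddings are isotropic
archetypes rather than language-model output, fingerprints are random bit
sets rather than circular substructures, and binding truth is block
structured at the family-chemotype level. Passing the package's recovery
bars demonstrates that the implementation can extract relational binding
signal under a controlled, leakage-audited protocol; it does not calibrate
expected performance on real proteomes.

With whole chemotypes held out, a held-out chemotype's test AUROC is
effectively a ranking of five family blocks, so single runs have high
variance; the acceptance study therefore reports the mean over three seeded
replicates, and individual replicates can be far from the mean in both
directions. Where the compatibility draw makes a family's profile nearly
collinear with others across the training chemotypes, the transfer readout
is weakly identified and single bundles can score poorly regardless of
training seed; this is a property of small discrete truth matrices, not of
the optimization.

# Numerical choices and degenerate inputs

* Similarity thresholds are strict inequalities; confidence-score
  thresholds are inclusive -- both taken verbatim from the sources' wording.
* All-pairs similarity scans are chunked block matrix products over
  unit-normalized embedding matrices; the chunk size only affects memory.
* Zero-norm embeddings are an error everywhere, never a silent zero.
* Both-empty fingerprints have Tanimoto 0 with a warning.
* Attention softmax subtracts the per-destination maximum; a destination
  with a single in-neighbor gets weight exactly 1, and attention weights
  always sum to 1 per destination.
* The binary cross-entropy clamps scores to [1e-12, 1 - 1e-12] with a
  warning; AUROC uses midranks, so ties count one half.
* Percentiles in proteome scoring count strictly greater scores; equal
  scores share a percentile and the top score has percentile 0.
* Medoid ties break to the lexicographically smallest drug id; external
  cluster-assignment ties break to the smallest cluster id; best-epoch ties
  break to the earliest epoch.
* Parameters initialize with a seeded uniform Glorot scheme; the run seed
  is recorded in the fit.
* Conflicting duplicate labels in the labeled table are an error, never a
  silent resolution; duplicated pairs across the two binding sources stay
  supervised and leave message passing (counted in the graph metadata).

# Scoring previously unseen drugs

`insertDrug()` adds a drug node with its embedding as features, computes
drug-similarity edges against existing drugs at the configured threshold,
and adds no binding edges; connectivity through the virtual hub guarantees
the drug is reachable even with no similarity edge. How novel drugs attach
to a deployed graph is this package's explicit choice (the sources do not
describe the mechanics); it is recorded here and in the function
documentation. `scoreProteome()` re-encodes once with frozen weights and
scores the drug against every target of the base graph's largest connected
component, reporting scores, strictly-greater percentiles and a
high-confidence flag at a configurable threshold (default 0.9). Checkpoints
carry a hash of the node ordering of the graph they were trained on and
refuse other graphs unless explicitly overridden; drugs inserted after
assembly are excluded from the hash.

# Problem sizes used in the package's own studies

The acceptance study trains on the strong preset (600 graph nodes, roughly
25,000 directed message-passing edges) with embedding dimension 32, 100
epochs, one fold per seed, three seeds per arm -- sizes chosen so the full
property suite exercises every component at desk scale. Two split
granularities serve two different questions:

* *Recovery* runs the drug-similarity split at the module defaults (100
  fingerprint clusters, 10% held-out test), the protocol used on real
  curated benchmarks. Held-out clusters are small chemical neighborhoods,
  and recovery of the planted rule is stable across seeds.
* *Ablation* runs with one cluster per chemotype, so whole chemotypes are
  held out and the allowlisted auxiliary edges are the only informative
  channel for test chemistry; there the comparison of interest is the
  direction (with auxiliary edges at least as good as without), not the
  absolute level, because a single held-out chemotype's AUROC is a ranking
  of five family blocks and is intrinsically high-variance (see above).

# Known limitations

* The trunk is single-headed, exactly as the printed update rule; multiple
  heads are left as a configuration extension and are off.
* No edge features; no alternative convolution operators.
* The virtual hub connects drugs only; whether targets should also connect
  is left open by the sources and answered here as drug-only.
* Hierarchical clustering materializes the full drug-drug distance matrix;
  beyond ~20,000 drugs this needs a different clustering backend.
* The hand-written training loop is plain R plus small compiled kernels; it
  is adequate for desk-scale graphs, not for proteome-scale training runs.
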