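---
title: "Bipartite link prediction from concept lattices with a position-free transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bipartite link prediction from concept lattices with a position-free transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcalink)
```

## The problem

Many biological and relational datasets are bipartite: metabolites
participate in reactions, authors appear on papers, reviewers endorse
manuscripts. Two prediction tasks recur on such networks:

* **object–object (O-O)**: will a group of same-side nodes (e.g. a set of
  metabolites) come to share a common neighbor (a reaction involving all of
  them)? Formally, a group $G \subseteq U$ has an object–object link in
  $(U, V, E)$ when $\exists v \in V$ with $(u, v) \in E$ for every
  $u \in G$.
* **object–attribute (O-A)**: is a specific missing edge $(u, v)$ a real
  but unobserved link?

`fcalink` approaches both through formal concept analysis (FCA). A
bipartite network *is* a formal context $(G, M, I)$; its formal concepts
(pairs $(A, B)$ with $A' = B$, $B' = A$) *are* its maximal bi-cliques, and
the concept lattice orders them by extent inclusion. Maximal bi-cliques
are cohesive modules — co-author groups, reaction neighborhoods — and the
lattice's neighbor (Hasse) relation describes how modules nest. The
package trains a transformer encoder to internalize both the membership
structure of concepts and their neighbor relation, then fine-tunes it for
the two link-prediction tasks.

## Pipeline

### 1. Concepts and the lattice

`extract_concepts()` enumerates all concepts with the NextClosure
algorithm run over the smaller side of the context. Any complete
enumeration algorithm yields the same set by definition; NextClosure was
chosen because it is compact, deterministic, and easy to verify — the test
suite checks set-equality against an independent subset-closure oracle on
hundreds of random contexts. Output order is canonical (extent cardinality
ascending, then lexicographic), so all downstream sampling is
reproducible.

`build_lattice()` computes the strict order by pairwise extent containment
($O(n^2)$ bitset tests, fine up to the ~20k-concept scale the package
targets) and the Hasse edges as its transitive reduction.
`algorithm1_lower_neighbors()` runs the breadth-first topological pass
that assigns each non-minimal concept one lower neighbor: pop a concept
whose strictly-below counter has reached zero, decrement the counters of
everything above it, and record the popping concept when a counter hits
zero. Because the queue drains the down-set of a concept before the
concept itself, the recorded concept is always maximal in the down-set,
i.e. a true lower neighbor; the tests verify the no-intermediate property
directly.

The full Hasse relation and the one-per-concept map are both exposed as
sources for neighbor-prediction examples (`neighbor_source` in
`sampling_config()`), since either is a defensible reading of "neighboring
relations"; the Hasse relation is the default because it is the complete
relation.

### 2. Tokenization

Each side of the network gets its own vocabulary (`build_vocab()`):
four specials `[PAD]=0, [CLS]=1, [SEP]=2, [MASK]=3`, then node tokens in
sorted-identifier order. `encode_pair()` lays out an extent pair as
`[CLS] a… [SEP] b… [PAD]…` with segment ids 0 through the separator and 1
after; `encode_group()` encodes a single set after `[CLS]`. Set elements
are always emitted sorted, so encoding is permutation-invariant by
construction. `[CLS]` is prepended and a single `[SEP]` separates the pair
(with no trailing separator); these are layout conventions of this
package, documented rather than inherited. Pairs longer than `max_len`
are reduced by seeded uniform subsampling of the extents, and a message is
logged.

### 3. The encoder

The encoder (`encoder_config()`, `encode_sequences()`) is a standard
post-layer-norm transformer block stack — multi-head softmax attention
with `[PAD]` keys masked, GELU feed-forward, residual connections — with
one deliberate change: **no position embeddings**. The input embedding is
the sum of token and segment embeddings only, because extents are sets;
with the position term removed, permuting the tokens of a group provably
leaves the `[CLS]` state unchanged, and the tests assert this to 1e-5
over random permutations. GELU is used inside the encoder blocks (the
usual choice for this architecture); the fine-tuning output heads use ReLU
exactly as specified below.

The full-scale preset is 768-dimensional, 12 heads, 6 layers,
feed-forward width 3072, head hidden width 512, batch size 24. All
experiments in this package run the test preset (32/4/2/64), which keeps
single-CPU runs in seconds-to-minutes; the architecture is identical.

Forward and backward passes are hand-written matrix code (the attention
inner loops in RcppArmadillo, everything else vectorized R on BLAS).
The backward pass is validated against central-difference numerical
gradients in the test suite — the single most load-bearing test in the
package.

### 4. Pre-training

Two models are pre-trained independently: the *object model* on extent
pairs and the *attribute model* on intent pairs (via the transposed
network, `dual_network()`). There is no weight sharing; a joint
two-sided model is out of scope.

The corpus is the balanced neighboring-concepts example set
(`make_ncp_examples()`): positives are all neighbor pairs with non-empty
extents, negatives an equal number of uniformly sampled non-neighboring
pairs. Concepts with empty extents (the lattice bottom, and the top of an
empty-relation context) yield no token sequence and are excluded. Within
an example the two extents are presented larger-first with lexicographic
tie-break — a label-free rule, so presentation order cannot leak labels.

Each batch is corrupted by `mask_tokens()`: `round(mask_rate × n)`
positions (at least 1, at most `max_masked = 4`) are selected among
non-special tokens; a selected token becomes `[MASK]` with probability
0.8, a random vocabulary token with 0.1, or stays put with 0.1, and the
original is always the prediction target. The default `mask_rate` of 0.15
follows the masked-language-model convention. The loss is the sum of the
masked-token cross-entropy (averaged over masked positions) and the
neighboring-concepts binary cross-entropy at `[CLS]` — both tasks trained
simultaneously on the same batches.

`pretrain_fraction < 1` holds out the complement of the NCP corpus and
reports held-out F1/AUC/AUPR after training: the package's probe of
whether lattice structure was actually learned.

### 5. Fine-tuning

* **O-O** (`finetune_oo()`): encoded groups pass through the encoder, and
  the score is exactly
  $P = \sigma(\mathrm{ReLU}(h_{[CLS]} W_{CLS}) W)$ — no bias terms.
* **O-A** (`finetune_oa()`): the object token and attribute token feed
  their respective towers; the two `[CLS]` states are concatenated
  (object first) into the same ReLU-sigmoid head with a
  $2d \times d_{hidden}$ first layer. Both towers update jointly.

Fine-tuning starts from the pre-trained checkpoint, or from seeded random
weights when `skip_pretrain` is set — the second ablation arm.

### 6. Labeled samples

`generate_oo_train()` enumerates *all* groups of size 2..$\varepsilon_p$
with an object–object link (per attribute, over its neighborhood) as
positives and samples negatives uniformly without replacement from
non-linked groups, matched in total and per size. Sizes start at 2
(singletons are vacuous), and $\varepsilon_p$ defaults to 3 to keep the
enumeration polynomial. When a small network simply lacks enough distinct
negatives of a size, the generator takes what exists and logs the
shortfall rather than sampling with replacement, which would distort class
balance.

`generate_oo_test()` takes an input/target split: positives are groups
whose witnessing attribute is joined to every member by *new* edges
(target-minus-input) and which have no link in the input; negatives are
groups with no link in the target. `generate_oa_samples()` does the
analogous thing for edges.

### 7. Evaluation

`f1_sweep()` evaluates exactly the 20 thresholds $0.00, 0.05, …, 0.95$
(prediction is positive when score ≥ threshold; F1 is defined as 0
whenever precision or recall has a zero denominator) and reports the
maximum with the smallest threshold achieving it. `roc_auc()` uses the
tie-corrected rank statistic — equivalent to the area under the TPR/FPR
curve and more robust than curve interpolation. `aupr()` integrates
precision over recall increments at descending thresholds, which reduces
to prevalence when all scores tie. All three are checked against
independent brute-force oracles to 1e-9.

## The synthetic benchmark

Everything is exercised on planted-bi-clique networks
(`generate_planted_network()`): a union of uniformly sampled complete
bi-cliques plus independent add-only noise edges. The standard instance
(50 objects × 40 attributes, 15 bi-cliques of side 3–6, noise rate 0.01,
seed 7) mimics the block structure of a small metabolite–reaction
context: overlapping modules, heavy-tailed concept sizes, a few spurious
edges. Noise is add-only so the planted structure remains a sub-relation;
with zero noise every planted bi-clique is contained in some concept, a
property the tests check.

Growth splits (`generate_growth_pair()`) plant extra bi-cliques that only
exist in the target network. Their object sets are sampled *inside
existing communities*: a seed object plus objects that share no attribute
with it yet but lie in its 2-hop neighborhood. This mirrors how real
bipartite networks grow — new co-authorships form between researchers in
the same community, new reactions connect metabolites of the same pathway
— and it is precisely this correlation between current structure and
future links that makes link prediction a learnable problem. (Uniformly
random growth would make future links statistically independent of the
observed network, so no predictor could beat chance on it.)

What the generator does **not** emulate: scale-free degree distributions,
degree-corrected block structure, edge deletion, temporal ordering of
edges, and the sheer scale of real datasets. Passing tests on planted
networks therefore demonstrate correctness of the machinery and the
learnability direction of the method's claims, not real-data effect sizes.

## Numerical and schedule choices

* Layer-norm epsilon 1e-5; weight init truncated normal (sd 0.02, clipped
  at 2 sd), seeded; dropout 0.1 in training, disabled in evaluation and
  during benchmark fine-tuning.
* Optimizer Adam ($\beta_1$ 0.9, $\beta_2$ 0.999, $\epsilon$ 1e-8), with
  optional decoupled weight decay on weight matrices (off by default).
  Pre-training uses lr 3e-3: 25 epochs when the pre-trained model is the
  object of study (held-out neighbor prediction), 10 epochs when the
  encoder is pre-trained for transfer — longer pre-training
  over-specializes the representation to the pre-text heads and measurably
  hurts downstream fine-tuning. Fine-tuning uses lr 1e-3.
* Fixed-epoch training, no early stopping, single-threaded determinism:
  two runs with the same configuration and seed are bit-identical.
* Fine-tuning supports two variance-control devices used by the
  benchmarks: stochastic weight averaging (`swa_start`: the returned model
  averages the weights of the tail epochs), and, for the edge-recovery
  task, per-epoch redrawing of the negative training pairs from the input
  network's non-edges (`resample_negatives_from`). On a 50 × 40 network a
  fixed negative sample of a few hundred pairs is memorized within a few
  epochs; redrawing negatives each epoch exposes the whole non-edge
  manifold, recovering the generalization behaviour of matrix-completion
  methods while keeping every epoch's class balance exact. Group-task
  fine-tuning instead runs few (4) epochs so that pre-trained structure is
  refined rather than overwritten.
* The growth (object–object) benchmark runs on a larger instance
  (`oo_benchmark_config()`: 120 × 60, 30 bi-cliques, noise 0.005, 6 extra
  bi-cliques) than the edge-recovery benchmark. With only 50 objects the
  group space (1225 pairs) is smaller than the balanced negative sample,
  so every future link would also be a training negative and the test
  would measure memorization noise; 120 objects keep the sampled negatives
  a small fraction of the group space, as in real networks. Training
  groups and the pre-training corpus are capped by seeded subsampling
  (4000 and 1200) to bound runtime.
* Benchmark sequence length is capped at 32 tokens; the few extents longer
  than the cap (a planted network's top concepts) are subsampled at
  encoding time with a logged message.
* The masked-token output projection is tied to the token embedding matrix
  by default (configurable off).
* The Katz baseline sums path contributions from length 1; for same-side
  pairs odd powers vanish, so the first contributing term is the two-hop
  count, and the truncated sum converges to $(I-\beta A)^{-1}-I$ within
  the spectral radius. Group scores aggregate pairwise Katz by mean
  (configurable min) — the aggregation is this package's choice. The
  common-neighbors analogue for O-A pairs is the 3-path count
  $(AA^TA)[u,v]$, the standard projection form, again a documented choice.

## Known limitations

* Concept enumeration and the $O(n^2)$ order computation are comfortable
  to roughly 20k concepts; beyond that, lattice construction dominates.
* The O-O test protocol labels as negative any group unlinked in the
  target, so a "future" link later than the target horizon counts against
  the predictor — inherent to the split construction.
* Training-set supervision for growth-type O-O tasks is intrinsically
  noisy: test positives are close-but-unlinked groups, which resemble the
  sampled training negatives. Pre-training is what injects the structural
  prior; the ablation direction (pre-trained ≥ from-scratch) is asserted
  with a small one-sided margin over three seeds rather than as a fixed
  effect size, because at benchmark scale the improvement fluctuates
  between seeds.
* Checkpoints are R serializations of plain arrays; no GPU path exists,
  and none is planned for the supported problem sizes.
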