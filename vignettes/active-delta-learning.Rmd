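---
title: "Active learning on molecular pairs: models, design choices, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning on molecular pairs: models, design choices, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
design is the way it is. It states no empirical result that the test suite
or the acceptance script does not itself compute.

## The acquisition problem

Exploitative active learning for potency optimization acquires one compound
per iteration from a *learning pool*, aiming to accumulate the most potent
compounds as quickly as possible. The campaign cold-starts from two randomly
chosen labeled molecules; after each acquisition the chosen molecule's true
potency is revealed and the model is refit from scratch on the grown
training set. Labels of unacquired pool molecules are never visible to the
policy — `run_active_learning()` passes the pool with potencies blanked, and
a test corrupts unacquired labels and asserts identical trajectories.

Three policies share this loop:

* **`single_exploit`** — fit $\hat f(x) \approx y$ on single-molecule
  fingerprints, acquire $\arg\max_c \hat f(x_c)$.
* **`activedelta`** — fit $\hat g(x_i \oplus x_j) \approx y_j - y_i$ on the
  cross-merged training pairs; pair the current best training compound (the
  *anchor*) with every candidate and acquire
  $\arg\max_c \hat g(x_a \oplus x_c)$.
* **`random`** — a seeded uniform draw; the screening baseline whose
  expected hit count is hypergeometric ($kH/N$ after $k$ draws), which the
  test suite verifies by simulation over 500 seeds.

### Pairing conventions

`cross_merge()` produces **all $n^2$ ordered pairs including self-pairs**.
Self-pairs carry an exact zero label and anchor the regression at
$\Delta y = 0$; a config switch (`include_self = FALSE`) covers the
$n(n-1)$ reading for ablation. The direction convention is fixed everywhere:
first = reference, second = candidate, $\Delta y = y_\text{second} -
y_\text{first}$, so a positive prediction means "candidate improves on the
reference". No post-hoc averaging of the two orientations is done at
acquisition time; symmetric averaging is a possible extension, not part of
the protocol.

The difference labels cancel any constant assay offset *algebraically*. In
floating point, the cancellation is exact only when the additions
themselves are exact, so the bit-identity test places potencies and shifts
on a dyadic grid; the end-to-end generator test asserts the same property at
`1e-12`. The pairing code introduces no error of its own.

### The anchor

The anchor is recomputed **every iteration** from the current training set
("currently best" is present tense — a newly acquired molecule may dethrone
the previous best). Argmax ties break to the earliest training position, so
anchors are deterministic. When scoring an *external test set* with a paired
model (`evaluate_on_test()`), the anchor of the finished run — the best
compound in the final training set — is used; the choice of test-time anchor
is a genuinely open point and is only a rank-shift away from any other fixed
anchor for ranking purposes.

## Models

Two fingerprint families implement both modes with **library-default
hyperparameters**, snapshot into each `fit_report`:

| family | backend | defaults |
|---|---|---|
| `gradient_boosted_trees` | xgboost | `eta` 0.3, `max_depth` 6, `nrounds` 100, 1 thread |
| `random_forest` | randomForest | `ntree` 500 |

Features are Morgan fingerprints, radius 2, 2048 bits; paired mode
concatenates the two fingerprints (4096 columns, sparse). Models are refit
from scratch at every iteration — no warm starts — so a trajectory is fully
determined by `(policy, dataset, seed)`. A degenerate constant-label
training set short-circuits to an exact constant predictor (some
randomForest versions refuse zero-variance responses).

`oracle_perfect` and `oracle_noisy` expose ground truth (a potency lookup
supplied as `hyperparams$truth`) for protocol tests: with a perfect oracle,
the paired and single policies are both greedy-on-truth and must produce
identical acquisition sets — verified against an independent greedy
simulation over 20 seeds. The noisy oracle draws one deterministic
perturbation per (seed, molecule), so its predictions converge to the
perfect oracle as `noise_sd` goes to zero regardless of call order.

`dmpnn_adapter` is a recorded slot for an external two-molecule
message-passing network (epochs 5 in paired mode, 50 in single mode,
aggregation `"sum"`); fitting errors informatively when the backend is not
installed. The acquisition strategy is model-agnostic by design, so the
package's contribution does not depend on that backend.

## Chemistry layer

SMILES handling (parsing, canonicalization) is delegated to Open Babel via
ChemmineOB/ChemmineR; all identity decisions (deduplication, scaffold
comparison, self-exclusion) operate on canonical SMILES, so different string
renderings of one molecule compare equal.

**Morgan and atom-pair fingerprints are computed natively** on the molecular
graph with a fixed integer polynomial hash (modulus $2^{31}-1$): no
run-dependent hashing, identical bits across sessions and platforms, which
the suite pins with frozen on-bit indices. Implicit hydrogens are inferred
from standard neutral valences; formal charges are not modeled (the shipped
generator is charge-free; charged user input is featurized deterministically
under the neutral-valence heuristic). Bit positions are
implementation-defined per kind — only identity, determinism and Tanimoto
geometry are meaningful, which is all the analyses use. MACCS keys (166
bits) come from Open Babel. Tanimoto similarity of two all-zero fingerprints
is defined as 1 (identical, if featureless, bit sets), keeping
nearest-neighbor maxima NaN-free.

**Bemis–Murcko scaffolds** keep ring systems plus connecting linkers:
terminal non-ring atoms are pruned iteratively, then atoms multiple-bonded
to the surviving framework (e.g. an amide linker's carbonyl oxygen) are
restored. Frameworks are atom-typed (not reduced to carbon skeletons).
Acyclic molecules have an empty scaffold and count as one shared "acyclic"
class in diversity counts. The implementation matches an independent
cheminformatics toolkit on a frozen 14-molecule oracle fixture spanning
fused rings, linkers, exocyclic double bonds and attachment isomers.

## Evaluation suite

* **Hits** are the top ten percentile: exactly $\lceil 0.1N \rceil$
  molecules, threshold ties broken by dataset position so the set size is
  deterministic and exact.
* **Retrieval curves** count the fraction of hits held at $t = 0..T$, with
  cold-start hits counting at $t = 0$; they are nondecreasing, bounded in
  $[0,1]$ and reach 1 at pool exhaustion.
* **Similarity windows** average each acquisition's nearest-neighbor
  Tanimoto against the training set *as it stood before that acquisition*
  (the acquisition cannot be its own neighbor), over windows 1–15, 16–30,
  31–45 by default, for Morgan, MACCS and atom-pair fingerprints.
* **Strategy comparisons** use the two-sided Wilcoxon signed-rank test on
  per-dataset paired values (`stats::wilcox.test`), zero differences
  dropped; an all-zero comparison is degenerate and reported with $p = 1$.
  Exactness is verified against full $2^n$ sign-assignment enumeration for
  $n \le 12$. Mean ± SD of differences is the text-reporting convention,
  SE the plotting convention.

### Chemical-space embedding and jump/stay counts

`embed_chemical_space()` reduces Morgan fingerprints to 50 principal
components (skipped with a warning at $\le 50$ molecules), then to 2-D by an
exact $O(n^2)$ t-SNE written for this package: perplexity-calibrated
Gaussian affinities (binary search per point, 64 iterations, entropy
tolerance $10^{-5}$, with underflow-safe bandwidth shrinking), Student-t
output kernel, gradient descent with momentum 0.5→0.8 (switch at iteration
250), gain adaptation, early exaggeration 12 for 100 iterations, and the
"auto" learning rate $\max(n/48, 50)$. Initialization is the scaled leading
principal-component plane — the reproducibility-friendly choice — which
also guarantees that duplicate molecules start, and by symmetry remain,
coincident; the implementation was validated against a reference t-SNE on
Gaussian-mixture data. Coordinates are qualitative: they support trajectory
plots and jump/stay counting and are never used for acceptance thresholds.

Cluster labels for jump/stay analysis come from single-linkage grouping of
the embedding cut at 8% of its diameter — a density-connectivity rule with
recorded parameters. Any grouping changes the individual counts, so only
the conservation law (jumps + stays = transitions) is asserted as a
property; the counts themselves are descriptive.

## The synthetic landscape

`generate_library()` assembles molecules from a fixed fragment grammar —
6 substituted ring cores × 8 prefix substituents × (10 terminal tails,
9 linkers × 6 second rings, 2 N-linked saturated rings) ≈ 3,100 unique
valid molecules — and samples a library under one seed. Every generated
SMILES parses in two independent toolkits by construction, scaffolds are
diverse by construction, and sampling uses byte-order (radix) sorting so
results are locale-independent.

Potency follows
$y(m) = w \cdot \mathrm{fp}(m) + \text{offset} + \mathcal N(0, \sigma)$,
with $w$ supported on 40 Morgan bits of intermediate frequency (5–60%),
weights $\mathcal N(0,1)$; `hit_skew` (default 2, in potency units) adds
weight on 3 rarer bits (2–15% frequency) so the top decile separates into a
small hit set spanning several scaffolds. The default offset of 6 centers
the landscape on a p$K_i$-like scale; `noise_sd` defaults to 0.3, a typical
inter-assay spread on that log scale. Because the signal acts on the same
fingerprint kind the models consume, the landscape is learnable by
construction — passing tests show the machinery works, **not** that the
method performs equivalently on real assay data, where the structure–potency
relationship is not linear in fingerprint bits, activity cliffs exist, and
time-split distribution shift applies. The scaffold-disjoint split mode
mimics the *character* of time-based splits, not their chronology.

## Problem sizes and benchmark conditions

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every code path with meaningful statistics: 30–120-molecule
fixtures for exact oracles, a 300-molecule landscape (noise 0.3, 80:20
split) with three repeats of 50-iteration campaigns for the policy
benchmark, 500 seeds for the hypergeometric calibration of the random
baseline, and repeat seeds {101, 202, 303} fixed a priori. On a benchmark
of this size a three-repeat comparison between the paired and single
tree-based policies has limited power — the two are close performers — so
individual repeats can order either way; the random baseline is dominated
by both by a wide margin.

## Known limitations

* Formal charges and stereochemistry are ignored by the native
  fingerprints; aromatic systems are processed in kekulized form
  (deterministic per canonical SMILES).
* Exact t-SNE is $O(n^2)$ memory and time: fine to a few thousand
  molecules, not for full screening decks.
* Exhaustive $n^2$ pairing makes ActiveDelta training quadratic in the
  acquired set; the protocol targets early, small-data campaign phases.
  Subsampled pairing is deliberately out of scope.
* Batch acquisition, explorative/uncertainty-driven policies and early
  stopping are out of scope; one molecule per iteration, exploitative only.
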