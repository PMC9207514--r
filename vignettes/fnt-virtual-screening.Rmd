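---
title: "Screening disease-related compounds with evolved flexible neural trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening disease-related compounds with evolved flexible neural trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fntscreen)
```

## The problem

Ligand-based virtual screening asks: given a handful of compounds known to
be active against a disease and a numerical description of chemical
structure, which other compounds are likely related?  `fntscreen`
implements a complete pipeline for this: featurization of SMILES into
fingerprints or descriptors, principled selection of negative training
examples from a decoy pool, a tree-shaped neural classifier whose topology
and parameters are both learned, and stratified cross-validated
evaluation.

## The flexible neural tree

A flexible neural tree (FNT) is a tree whose leaves are input features and
whose internal nodes are *flexible neurons*.  A neuron of arity $n$ with
child outputs $x_1,\dots,x_n$ computes

$$net = \sum_{j=1}^{n} w_j x_j, \qquad
  y = \exp\!\left(-\left(\frac{net - a}{b}\right)^2\right),$$

a weighted sum through a two-parameter Gaussian.  Every neuron output lies
in $(0,1]$ mathematically (the implementation returns exactly 0 when the
Gaussian argument is so extreme that `exp()` underflows — only relevant
for unscaled inputs).  The root is always a neuron, never a bare feature:
the output layer of the network is a neuron, and the root score is the
probability-like output used for classification.  A compound is called
related when its score is **strictly** greater than the threshold
(default 0.5); a score exactly at the threshold is unrelated.

Because the activation is a Gaussian in $net$, the tree benefits from
inputs on a common scale.  Features are min-max scaled to $[0,1]$ inside
`fnt_fit()`, with the scaling fitted on the training rows only and stored
for reuse at prediction time; values outside the training range are
clipped.  Constant training columns map to 0.  $b$ sits in a denominator,
so it is guarded away from zero: any $|b| < 10^{-8}$ is replaced by
$\pm 10^{-8}$, both at node construction and at parameter injection.

The tunable parameters of a tree are flattened in pre-order traversal
(per neuron: its $n$ weights, then $a$, then $b$) into a single vector, so
a continuous optimizer can treat any fixed topology as a box-constrained
problem.  `fnt_params()` / `fnt_set_params()` round-trip losslessly, and
models serialize to versioned JSON at 17 significant digits, which is
exact for IEEE doubles.

## Structure search: grammar-guided genetic programming

Tree topologies are sampled and recombined as derivation trees of the
context-free grammar $G = \{N, T, P, \Sigma\}$ with
$N = \{s, exp, var, op_k\}$, $T = \{+_k\} \cup \{x_1,\dots,x_n\}$ and the
prefix productions

```
s    -> exp
exp  -> op_k exp ... exp     (one rule per arity k)
exp  -> var
op_k -> +_k
var  -> x_1 | ... | x_n
```

Working on derivation trees rather than raw node trees means replication,
crossover and mutation are closed over the grammar: every individual ever
produced parses, and induces a structurally valid FNT.

**Generation.**  Non-terminals expand top-down, left-to-right, with the
production drawn uniformly among those whose expansion can still complete
within the depth budget: at the last allowed level only `exp -> var` is
eligible.  This depth-aware masking is used instead of blind
generate-and-reject because with arities up to 5 the probability that an
unconstrained draw respects depth 5 vanishes for larger subtrees, and a
rejection loop would routinely exhaust any sane retry cap.  A draw whose
root expands directly to a bare feature *is* rejected and redrawn (the
root must be a neuron), with the loop capped at 1000 attempts.  Depth is
always accounted in induced-FNT levels (root = 1, terminals count), so
"maximum depth 5" binds the model users see, not the derivation
bookkeeping.

**Crossover** picks a non-terminal label present in both parents, one node
with that label in each, uniformly, and swaps the subtrees.  An offspring
that would exceed the depth bound — or whose root would become a bare
feature — is discarded and the corresponding parent returned unchanged, so
the operator is total.  **Mutation** regrows a uniformly chosen
non-terminal within its remaining depth budget.  **Selection** is
tournament of size 3 (ties to the lowest population index), with the
single best individual copied unchanged into the next generation
(elitism), which makes the best-fitness trace non-increasing by
construction.  Crossover probability 0.8 and mutation probability 0.2 are
package defaults.

## Parameter search: the salp swarm algorithm

For a fixed topology the parameter vector is optimized by the salp swarm
algorithm.  The population initializes uniformly in the box
(`rand()·(Xmax − Xmin) + Xmin` per entry).  Each iteration $t$ of $T$:

* the convergence factor $c_1 = 2 e^{-(4t/T)^2}$ decays from 2 to
  $2e^{-16}$;
* the leader (first salp) moves, per dimension $i$ with fresh uniform
  $c_2, c_3$, to $F_i \pm c_1\,((X^{max}_i - X^{min}_i)\,c_2 + X^{min}_i)$
  — sign positive when $c_3 \ge 0.5$ — around the food position $F$ (the
  best solution seen so far);
* each follower $j \ge 2$ moves to the midpoint of itself and its
  already-updated predecessor, in order.  The published follower update
  renders ambiguously; the derivation from the underlying
  equations-of-motion argument gives the midpoint, which is what the
  package implements, with the sequential (chain) order.
* positions are clamped to the box (not reflected), refitnessed, and the
  food updated as best-so-far — hence a monotone non-increasing fitness
  trace.

$c_2, c_3$ are redrawn per dimension; only the first salp is a leader.
Search boxes per parameter kind default to weights $[-1, 1]$, $a \in
[0, 1]$ (the scaled-feature range a neuron's $net$ typically occupies) and
$b \in [0.01, 1]$ (bounded away from degenerate widths).

## The hybrid schedule

How the two layers interleave is a genuine design choice; the package
uses: during the GP phase every new individual's parameters get a *cheap*
SSA polish (default 10 salps, 15 iterations) before its fitness is read,
so structure comparison is not hostage to one random initialization; after
the last generation the best structure gets a *deep* SSA run (default 30
salps — the GP population size — for 100 iterations).  The individual's
current parameter vector is seeded into each swarm, so a polish can never
make it worse.  Both budgets are exposed in `fnt_control()`.

The training objective is the RMSE of the continuous root output against
the 0/1 labels — the standard choice in the FNT literature, bounded in
$[0,1]$, and smoother than error rate for the optimizer.  Inside the SSA
loop the tree is evaluated through a flattened schedule compiled once per
structure (identical arithmetic to `fnt_evaluate()`, property-tested to
agree to $10^{-14}$); this matters because a fit performs tens of
thousands of fitness calls.

With a fixed seed the whole fit — structure, parameters, predictions — is
reproducible end to end; all randomness flows through R's RNG.

## Negative sample selection

Given $m$ positives and a candidate decoy pool (in practice DUD-E-style
decoys; the package consumes any fingerprint set), each decoy $g_i$ is
scored by $sum_i = \sum_j T(g_i, c_j)$ with the Tanimoto index
$T(A,B) = |A \cap B| / |A \cup B|$, the pool is sorted ascending (stable,
ties by input order), and the first $ratio \cdot m$ decoys are taken as
negatives.  Two empty fingerprints get similarity 0 (avoiding $0/0$).
The default ratio 2 gives the 1:2 class balance — 134 negatives for 67
positives, 248 for 124, 176 for 88 — and `ratio_experiment()` sweeps
ratios 1:1 through 1:10 with cross-validation at each.

## Featurization

Three descriptor families are computed from SMILES via OpenBabel
(ChemmineOB):

* **ECFP6** — circular fingerprint of radius 3.  The backend emits 4096
  bits; the two halves are OR-folded to the conventional 2048.
* **MACCS** — the 166 structural keys.  The backend stores keys in a
  padded 256-bit container with the conventional unused key 0; positions
  1–166 are taken, so the vector length is exactly 166.  (Verified
  against an independent implementation's on-bit numbering on reference
  molecules.)
* **physchem** — an 8-descriptor 2D physicochemical panel (MW, logP,
  TPSA, H-bond donors/acceptors, molar refractivity, fluorine count).

Richer panels (e.g. a 1613-feature macrocycle-oriented table or a
208-descriptor panel) are backend- and version-dependent, so they enter
through `load_feature_csv()` rather than being chased bit-for-bit.
Unparseable SMILES produce per-record warnings naming the id and string,
and are dropped; an all-failed input errors.

## Evaluation

`classification_metrics()` builds the confusion table from the strict
threshold rule and reports TPR, FPR, precision, specificity ($= 1 -$ FPR),
F1 and AUC.  AUC is the rank-based (Mann–Whitney) statistic with midrank
ties — equal to trapezoidal ROC integration on tie-free scores, a
cross-checked property.  Metrics with zero denominators are reported as 0
and flagged, keeping reports machine-readable.  `fnt_cv()` runs seeded
stratified $k$-fold CV (per-fold class counts within one of an even
split), refitting the scaling per training fold; `rank_methods()`
average-ranks a methods-by-datasets table with midrank ties.

## Synthetic data

Real disease-compound lists are literature-curated and not distributable,
so the package ships seeded generators producing data with the structure
the method assumes:

* `sim_fingerprints()` — binary fingerprints from per-class Bernoulli bit
  profiles (disjoint high-probability blocks by default), giving
  within-class Tanimoto similarity above between-class, as real chemical
  series show.
* `sim_blobs()` — two Gaussian blobs at 4 sd separation (default) scaled
  to $[0,1]$: clearly separable, the regime in which an adequate trainer
  must reach AUC $\ge 0.95$.
* `sim_decoy_pool()` — decoys spanning a controllable gradient of summed
  similarity to a positive set; at dissimilarity 1 they are bit-disjoint
  from every positive.

These fixtures exercise every contract but are idealized: bits are
independent given the class, blobs are spherical and noise-free relative
to real assay data, and no property matching between actives and decoys
is attempted.  Passing on them demonstrates correctness of the machinery
and adequacy of the optimizer, not screening performance on real
chemistry.

## Problem sizes and numerical choices

The shipped tests run the trainer at the published study conditions
(population 30, depth 5, arities 2–5) with 10 GP generations and a
20-iteration screening polish on 120-sample, 8-feature data — about 12 s
per fit — and full 10-fold CV on top; property sweeps use 200–1000 seeded
draws per invariant.  Other choices worth knowing: positions clamp (not
reflect) at bounds; fold assignment, fold metrics and every generator are
deterministic under a seed; decoy ties break by input order; JSON model
files carry a format tag and full double precision.

## Limitations

* The interleaving budgets (screen/deep SSA iterations) trade runtime for
  fit quality; hard problems will want larger budgets than the defaults.
* RMSE against hard labels can be conservative under heavy class
  imbalance; the decoy-ratio sweep is the tool for studying that.
* OpenBabel's descriptor panel is small; for modern 2D panels use an
  external tool and `load_feature_csv()`.
* No structural regularization beyond the depth bound: trees near the
  depth limit can be large (a hundred parameters), and the optimizer
  budget, not a penalty, is what limits overfitting.
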