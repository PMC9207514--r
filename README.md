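# fntscreen

Ligand-based virtual screening with evolved flexible neural trees.

In network-pharmacology studies the compounds of a prescription must be
triaged for relevance to a disease before any target-level analysis.
`fntscreen` trains a classifier that takes a molecular feature vector
(fingerprint or descriptor panel) and scores a compound's probability of
being disease-related, given a small set of literature-curated actives and
a pool of presumed-inactive decoys.

## The model

The classifier is a **flexible neural tree (FNT)**: a tree-shaped neural
network whose leaves are input features x_i and whose every internal node
is a flexible neuron of arity n computing

    net = Σ_{j=1..n} w_j x_j ,    y = exp( −((net − a) / b)² )

so each neuron output lies in (0, 1]. A compound is called *related* when
the root output is strictly greater than 0.5.

Training co-evolves structure and parameters:

* **Structure** — grammar-guided genetic programming (GGGP). Candidate
  trees are derivation trees of the context-free grammar
  `s → exp`, `exp → op_k exp^k | var`, `op_k → +_k`, `var → x_1 | … | x_n`,
  so replication, tournament crossover and subtree mutation can never
  produce a syntactically invalid tree. Defaults: population 30, arity set
  {2,3,4,5}, maximum depth 5.
* **Parameters** — the salp swarm algorithm (SSA). One leader salp searches
  globally around the best-known ("food") position with step size governed
  by the convergence factor c₁ = 2·exp(−(4t/T)²); followers move to
  sequential midpoints, contracting the chain. Every GP individual gets a
  short SSA polish before its fitness (RMSE of tree output against the 0/1
  labels) is read; the best final structure gets a deep SSA run.

Negative examples are chosen by the **Tanimoto decoy selection** rule: each
pool decoy is scored by its summed Tanimoto similarity Σ_j |A∩B|/|A∪B| to
all m positives, and the `ratio·m` least similar decoys (default ratio 2)
become the negative set.

## Worked example

```r
library(fntscreen)

## seeded synthetic data: two separable Gaussian blobs, 60 + 60 compounds
blobs <- sim_blobs(n_pos = 60, n_neg = 60, d = 8, separation = 4, seed = 42)

fit <- fnt_fit(blobs$x, blobs$y, seed = 42,
               control = fnt_control(gp_generations = 10,
                                     ssa_screen_iter = 20))
fit
#> Flexible neural tree classifier (GGGP structure + SSA parameters)
#>   training samples : 120 (60 related / 60 unrelated)
#>   tree depth       : 4 of max 5
#>   parameters       : 104
#>   training RMSE    : 0.0224315

auc_score(blobs$y, predict(fit, blobs$x))
#> [1] 1
```

The print shows the evolved topology (depth 4 of the allowed 5, 104 free
parameters) and the final training RMSE; AUC 1 means every related
compound outranks every unrelated one. `predict(fit, x, type = "label")`
applies the strict `score > 0.5` rule; `fnt_cv()` runs stratified 10-fold
cross-validation and `ratio_experiment()` repeats CV across
positive:negative ratios.

For real compounds:

```r
pos  <- featurize(read_smiles("actives.smi"), descriptor = "maccs")  # 166 keys
pool <- featurize(read_smiles("decoys.smi"),  descriptor = "maccs")
sel  <- select_decoys(fp_from_matrix(pos), fp_from_matrix(pool), ratio = 2)
```

A command-line driver with the same pipeline (subcommands `featurize`,
`select-decoys`, `train`, `predict`, `cv`, `rank`, `ratio-exp`,
`synthdata`) is installed at `system.file("cli", "fntscreen", package =
"fntscreen")`.

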