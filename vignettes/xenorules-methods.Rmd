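---
title: "Methods: feature ranking and rule learning for PDX versus original tumor cells"
author: "xenorules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature ranking and rule learning for PDX versus original tumor cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-derived xenografts (PDX) are grown by transplanting human tumor
tissue into immunodeficient mice. The murine microenvironment reshapes the
transplanted cells' transcriptome, so genes that separate PDX cells from
the original human tumor cells are of direct biological and practical
interest: they flag processes that drift under passage and bound what a
PDX model can say about the patient's tumor.

`xenorules` implements a three-stage pipeline for finding such genes in a
cells × genes expression matrix (continuous log-scale values, e.g.
single-cell Biomark qPCR measurements) with a binary cell label
(human-tumor vs PDX):

1. **Monte Carlo feature selection (MCFS)** ranks genes by relative
   importance accumulated over thousands of small decision trees built on
   random feature projections.
2. **Incremental forward selection (IFS)** walks down the ranking,
   evaluating each nested candidate gene set with a cross-validated random
   forest scored by the Matthews correlation coefficient (MCC), and keeps
   the set with the best mean MCC.
3. **Rough-set rule learning** turns the optimal gene set into an ordered
   list of human-readable threshold rules: a discernibility analysis
   yields a near-minimal attribute subset (Johnson reduct), and RIPPER
   induces IF–THEN rules for the minority class on the reduct, with a
   condition-free default rule for the majority class.

Every stage is driven by explicit seeds and reproduces bit-identically.

## Data preparation

Genes missing in strictly more than half of the cells are removed, then
cells missing in strictly more than half of the retained genes; fractions
are configurable (`gene_frac`, `cell_frac`, both 0.5 by default). Ties at
exactly the threshold are kept — the rule is "more than half". The
gene-then-cell pair of steps is repeated until nothing more is removed, so
the filter is a projection (applying it twice equals applying it once);
on realistic missingness the first pass already reaches the fixed point,
and the iteration only matters in adversarial corner cases where removing
cells pushes a retained gene back over the threshold.

Remaining gaps are imputed by nearest-neighbor averaging: the distance
between two cells is the root-mean-square difference over the genes
observed in both (dividing by the number of shared genes corrects the
scale bias that raw Euclidean distance has under unequal support), and a
missing entry becomes the mean of its gene over the `k = 10` nearest cells
that observed that gene, skipping neighbors that did not. Neighbor ties
break by input row order, which keeps the result deterministic. Neither
the neighbor count nor the distance treatment is canonical; both are
package decisions and configurable.

## Monte Carlo feature selection

`s` random subsets of `m` genes are drawn (defaults `s = 1000`,
`m = max(⌈0.05·d⌉, 2)`); for each subset, `t = 5` binary classification
trees are grown, each on its own stratified train/test split
(`train_fraction = 0.66`). Trees are CART-style, use base-2 information
gain as the split criterion, place numeric thresholds at midpoints
between consecutive observed values, and grow until node purity or fewer
than 2 samples, without pruning. A gene `g` accumulates relative
importance

RI(g) = Σ_τ (wAcc_τ)^u · Σ_{nodes of τ splitting on g} IG(node) · (n_node / n_tree)^v

with `u = v = 1` by default and wAcc the mean of per-class accuracies of
tree τ on its *held-out* cells — weighting by accuracy on the fit set
would be meaningless, since unpruned trees fit their training data nearly
perfectly. Genes never drawn into a projection score 0, as does any gene
constant across cells.

Numerical choices worth knowing:

* Split-gain ties are common in small nodes (the gain depends only on the
  label counts of the induced partition), so the tie-break matters. Ties
  resolve to the smaller threshold *value*, not the smaller column index,
  which makes the ranking invariant to gene column order; the column
  index is only the last resort for exact (gain, threshold) double ties.
* Per-tree seeds derive deterministically from (seed, subset index, tree
  index), so results do not depend on execution order.
* Equal-RI genes rank by ascending original column index.

A permutation cutoff (`ri_cutoff()`) is available: the observed RI is
compared with the chosen quantile (default 0.95) of per-permutation
maximum RI over label-permuted copies, giving a family-wise significance
screen for the ranking.

## Incremental forward selection

The candidate sets are the nested prefixes F1 ⊂ F2 ⊂ … ⊂ FN of the
ranking. Each is evaluated with a 500-tree random forest (`ranger`,
`√p` features per split) under stratified 10-fold cross-validation. One
fold assignment is shared by all candidate sets, so differences along the
curve reflect the features rather than fold noise; the assignment
distributes every class across folds as evenly as possible, with the fold
counter continuing across classes so all folds are used even for classes
smaller than the fold count.

Performance is the mean over folds of the covariance-form MCC computed
from one-hot prediction and truth matrices,

MCC = cov(X, Y) / √(cov(X, X) · cov(Y, Y)),

which for two classes equals the classical binary MCC; the population
1/N prefactors in the covariances cancel in the ratio. MCC was chosen as
the primary score because the two classes are strongly imbalanced
(roughly 1:3.8 in the motivating design) and MCC is insensitive to that
imbalance; per-class recalls (reported as sensitivity and specificity of
a stated positive class, the minority by default) and accuracy are
carried alongside. A constant prediction or constant truth makes the MCC
denominator zero; the package returns 0 with a warning, the standard
convention, which also keeps IFS curves finite when a fold degenerates.
Mean-of-per-fold-MCCs is the default summary; pooling out-of-fold
predictions first is available via `mcc_labels()` on the pooled vectors.

The optimum is the candidate set maximizing mean MCC, ties going to the
smaller set (parsimony). Random-forest vote ties (possible with an even
tree count) are broken under a per-fold pinned RNG, so the whole IFS
stage is bit-reproducible.

## Rough-set rule learning

The optimal genes form a decision system: objects (cells), condition
attributes (genes), decision attribute (class). For the discernibility
stage each gene is discretized by supervised entropy partitioning with
the MDL stopping rule (Fayyad–Irani); genes where no cut passes MDL
collapse to a single bin and can never discern anything. The
*generalized decision* of an object is the set of labels occurring among
objects with an identical attribute profile; only pairs with different
generalized decisions are discernible, which is how inconsistent
(identical-profile, different-label) records are handled. The
discernibility function — a product over object pairs of sums of the
attributes separating the pair — is simplified by idempotence (duplicate
sums removed) and absorption (a sum that is a superset of another sum is
removed), and the Johnson reduct is extracted greedily: repeatedly take
the attribute hitting the most remaining sums (ties to the lowest
attribute index) and drop the sums it covers. The greedy set-cover bound
guarantees the reduct is within a factor (1 + ln #sums) of minimal, and
the package verifies reduct validity (every pair discerned by all
attributes is discerned by the reduct) in its tests.

RIPPER then learns rules for the minority class on the *continuous*
values restricted to the reduct — thresholds in the emitted rules are
midpoints of observed expression values, not bin edges. Each rule is
grown on a stratified 2:1 growing/pruning split by greedily adding the
(gene, ≥/≤, threshold) condition with the highest FOIL gain until no
negatives remain covered, then pruned back to the condition prefix
maximizing (p − n)/(p + n) on the pruning set. A rule is admitted only if
its pruning-set precision exceeds one half, and rule search stops when
the ruleset's description length exceeds the best seen by more than
`dl_budget = 64` bits. Two optimization passes re-grow
replacement/revision variants per rule and keep the MDL-best; a final
global pruning deletes any rule whose removal lowers the description
length — this is the step that discards rules fitted to noise, and on
label-permuted data it empties the rule list entirely, leaving only the
default rule. The description length is a per-condition theory cost plus
binomially coded exception bits; it is a simplified form of the usual
RIPPER MDL, sufficient for the stop/prune decisions it drives. Each rule
reports its support (matching training cells of its outcome class) and
coverage (support over class size).

If the discretized system is wholly inconsistent (no pair of objects has
different generalized decisions — e.g. heavy label noise over coarse
bins), the discernibility function is empty and no reduct constrains
anything; the pipeline then falls back to offering RIPPER the full
optimal feature set rather than aborting.

Rule-interaction network edges connect genes co-occurring in a rule,
weighted by the summed support × coverage of the rules containing the
pair and normalized by the largest edge; the edge list is a plain TSV
ready for network tools.

## The synthetic-data generator

Because the motivating single-cell dataset is not redistributable, the
package ships a generator whose defaults mirror the study conditions:
831 cells (174 human, 657 PDX), 69 genes, 15 informative genes with a
+1.5·σ mean shift in the human class, Gaussian background
(mean 1, σ 1.5 — a scale on which the planted thresholds resemble
log-expression values), no missingness unless requested. Optional
features: planted threshold rules (condition genes sampled from
truncated normals so the conjunction holds for a stated fraction of the
target class and is force-violated elsewhere, making satisfying cells
almost surely members of the stated class), correlated gene blocks
sharing a latent factor (pairwise correlation ≈ 0.5, mimicking
co-expressed keratin families), uniform completely-at-random
missingness, and binary label flips. Values can be clipped to a bounded
window (off by default) to imitate the bounded range of qPCR-derived
expression.

What the generator does *not* emulate: qPCR chemistry, expression-
dependent dropout, patient-level structure, heavy-tailed noise. Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration under a Gaussian mixture design, not performance on real
Biomark data.

## Problem sizes used in validation

The test suite and the acceptance script validate at the full simulated
study scale — 831 × 69 with `s = 200` projections × `t = 5` trees for the
ranking stage and 69 candidate sets × 10 folds × 500 trees for IFS —
which keeps a complete run in the minutes range on a single core while
using enough trees for stable recovery (the planted genes are recovered
in the top 20 essentially always at these settings). The
reduct-correctness checks use exhaustive brute-force minimal reducts,
which is why they run on systems of at most 10 objects and 6 attributes;
the end-to-end determinism check uses a 300 × 25 configuration, since
determinism is scale-free.

## Known limitations

* Rule induction is two-class only; the ranking and MCC stages are
  multi-class ready.
* The discernibility stage materializes per-object discernibility
  functions; beyond a few thousand cells this becomes the memory
  bottleneck.
* `ri_cutoff()` re-runs the full ranking per permutation; at default
  `s` it is the most expensive operation in the package.
* The RIPPER description length is a simplification of the original
  formulation; absolute DL values are not comparable to other
  implementations, though the induced rules agree on clean designs.
* No normalization or batch correction is performed: inputs are assumed
  preprocessed, and the missingness filter plus imputation are the only
  data-cleaning steps.
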