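---
title: "Reconstructing regulatory networks through a hidden activity layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing regulatory networks through a hidden activity layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtrnet)
```

## The model

Classic relevance networks link a transcription factor (TF) to a gene when
their mRNA profiles co-vary across conditions. That misses a central fact
of bacterial regulation: a TF's *activity* — its ability to engage its
operators — is set largely post-translationally (ligand binding, covalent
modification, sequestration), so the TF's own transcript is only a partial
proxy for what its regulon sees. `gtrnet` inserts the hidden activity
layer explicitly. Writing $[Er]$ for the $N \times M$ matrix of log2
expression ratios ($N$ genes, $M$ conditions), $[TFAr]$ for the $L \times
M$ matrix of relative TF activities, and $[CS]$ for the $N \times L$
control-strength matrix supported on the known topology, the log-linear
model is

$$\log_2 [Er] \;=\; [CS] \cdot \log_2 [TFAr].$$

Reconstruction proceeds in two steps. First the hidden activities are
estimated from $[Er]$ and a *partial* TF–gene topology (e.g. a RegulonDB
export) by constrained matrix decomposition. Second, the relevance of
every estimated activity profile to the expression profile of **every**
gene — including genes absent from the input topology, which is where new
links come from — is scored, background-corrected, and thresholded to a
requested network size $S$.

## Identifiability and the activity estimators

The decomposition is unique (up to a per-TF diagonal rescaling) only when
(i) $[CS]$ has full column rank, (ii) removing any TF together with all
its targets leaves a matrix that still has full column rank — which forces
every column to carry at least $L-1$ zeros — and (iii) the activity matrix
has full row rank. `check_nca_criteria()` tests (i) and (ii);
(iii) depends on the unknown activities and is checked on the estimate.
`reduce_to_compliance()` enforces (i)–(ii) by greedily dropping the worst
offending TF (fewest zeros; ties broken lexicographically so reduction is
reproducible), then any gene left without a regulator, and re-checking.
The greedy rule is our choice; any rule satisfying the criteria would do,
but determinism matters for reproducible benchmarks. Note that reduction
can never fail outright: a single remaining TF is always compliant, since
a lone column needs $L - 1 = 0$ zeros.

Three estimators (plus a baseline) stand behind the variant code's first
letter:

* **E** — alternating least squares on the support-constrained
  factorization. Given $[CS]$, each condition's activity column is an
  exact least-squares solve; given the activities, each gene's nonzero
  control strengths are re-fit on its own support. The residual is
  non-increasing by construction. Initialisation is deterministic
  ($[CS]$ = topology entries), so repeated runs agree bit-for-bit. The
  iteration stops when the relative residual change drops below `tol`
  (default 1e-6, `max_iter` 1000) or the residual hits an absolute floor
  of $10^{-12}\,\lVert Er\rVert_F$ — at machine-precision residuals the
  relative-change test is dominated by floating-point noise and would
  never fire.
* **S** — an SVD subspace projection. The rank-$L$ truncated SVD of
  $[Er]$ estimates the signal subspace; each TF's control-strength column
  is the direction of that subspace closest to vanishing on the column's
  structural zeros (the smallest right singular vector of the zero-row
  block), and activities follow by least squares. On noiseless compliant
  data both E and S recover the planted activities exactly.
* **P** — SIMPLS partial least squares of the condition profiles on the
  binary topology columns; TF $j$'s activity under condition $m$ is the
  fitted coefficient of predictor $j$ for response $m$. The regression
  runs **through the origin**: log-ratio space has a fixed origin (the
  reference condition), so zero activity implies zero log-ratio and an
  intercept has no meaning. Centring would also cost one rank whenever
  the target blocks tile the gene set, making $L$ components
  unattainable in exactly the designs PLS handles best. The component
  count defaults to $\min(L, M-1, \operatorname{rank} X)$. PLS needs no
  identifiability criteria, which is its niche: it keeps regulators the
  NCA reduction would discard.
* **N** — no activity layer: each TF's own expression row is copied in,
  reducing the pipeline to a classic two-layer relevance network. This
  is the baseline the activity layer is measured against.

All estimators fix the diagonal ambiguity the same way: unit Euclidean
norm per control-strength column, the inverse scale absorbed into the
activity row, and the sign set so each column's largest-magnitude entry
is positive. Any convention is equally consistent with the model; fixing
one makes estimates comparable across methods and runs.

## Relevance scores

The score letter selects Pearson correlation (**C**) or adaptive-partition
mutual information (**A**) between each activity row and each gene's
expression row. Correlation is fast and sharp for monotone, roughly
linear coupling; MI also sees non-linear, non-monotone dependence.

The MI estimator works on the rank-transformed sample (hence is invariant
under strictly monotone transforms of either variable) and recursively
refines a rectangular partition of rank space. A cell is split at its
marginally equiprobable midpoints into four sub-cells; under the
independence null the expected counts are proportional to sub-rectangle
areas, and the split is accepted when a chi-square test rejects
uniformity, either first-order on the 4 sub-cells (`chi2_threshold`,
default 7.81 = the 3-df, 5% point) or second-order on the 4×4
refinement (fixed at the 15-df, 5% point, 25.0). The second-order test
matters: near-diagonal cells under strong dependence can look uniform at
one split level while carrying substantial fine-scale structure, and
stopping there biases the estimate down by 20–30%. Two details are
deliberate:

* split points are rectangle midpoints, not the within-cell coordinate
  medians — medians adapt to the conditional marginals and make the
  four counts balanced almost by construction, blinding the test;
* `min_cell` (minimum points per occupied sub-cell) defaults to 1: any
  stricter value vetoes entire high-evidence splits whenever a sparse
  off-diagonal corner holds a single point, which stalls the recursion
  exactly where dependence is strongest.

With these settings the estimator is within a few percent of the
closed-form Gaussian value $-\tfrac12\ln(1-\rho^2)$ at $n = 5000$ for
$\rho = 0.9$, within ~15% for $\rho = 0.5$, and returns 0 on independent
samples of $n = 2000$ (the chi-square gates almost never open under the
null). MI is reported in nats; the base cancels in any size-thresholded
network.

## Background correction and assembly

Expression noise differs per gene and per TF, so a raw score is judged
against its own backgrounds (**C** in the third letter): entry $(j, i)$
is standardised against the distribution of TF $j$'s row and of gene
$i$'s column (sample SD; zero-variance slices score 0), negative marginal
z-scores are clipped at zero, and the two are combined in quadrature,
$Z = \sqrt{\max(z_{tf},0)^2 + \max(z_{gene},0)^2}$. The joint score is
invariant under a global positive-slope affine transform of the score
matrix, and each marginal under per-row (respectively per-column) affine
maps; a per-row map does change the other marginal, which is not a bug
but the correction doing its job. **N** skips correction, shifting
scores by the global minimum so downstream thresholding sees
nonnegative values with the ranking untouched.

The threshold $T$ for a requested size $S$ is the $(S+1)$-th largest
entry of $[Z]$, so exactly $S$ entries exceed it when values are
distinct; ties at the boundary are resolved lexicographically by
(tf, gene) so the edge list is reproducible. Edges already present in
the input topology are kept but flagged `in_training`; evaluation
excludes them. If an operon table is supplied, every predicted target
pulls its operon mates under the same regulator (provenance
`from_operon`, score inherited from the strongest trigger); such edges
do not count toward $S$. The whole pipeline is deterministic — no stage
draws random numbers — so identical inputs give bit-identical edge
lists.

## The synthetic study

The paper-scale inputs (a 4279-gene compendium, RegulonDB) are external;
the generator supplies self-contained ground truth instead, and its
defaults define the study conditions used throughout the tests: 200
genes, 10 TFs with 15 targets each, 50 conditions, noise SD 0.1 on the
log2 scale. Topologies are drawn by rejection sampling until the
identifiability criteria verify. Control strengths have magnitude
Uniform(0.5, 1.5) and random sign — bounded away from zero so every
planted link is detectable in principle; mixed signs model activation
and repression even though link prediction ignores sign. Activities are
i.i.d. standard normal rows, and expression is the model product plus
i.i.d. Gaussian noise. Each TF autoregulates with probability 0.5
(roughly the share of autoregulated *E. coli* TFs); autoregulation is
the only channel coupling a TF's mRNA to its own activity, so this
probability sets how strong the no-TFA baseline can be. Operons are
consecutive blocks with sizes 1 + Poisson(mean − 1).

What the generator does **not** emulate: probe effects, batch structure,
uneven condition sampling, TF–TF combinatorial logic, and time-series
dependence. Passing benchmarks here show the machinery is correct and
that the activity layer adds signal under the stated model; they do not
by themselves predict precision on a real compendium.

## Evaluation protocol

`knockout_links()` hides a fraction of the known links (uniformly at
random, deterministic per seed) and the pipeline is run on the rest.
Precision is the fraction of *new* predictions (edges not in the visible
training topology) that fall in the hidden set; recall is the fraction
of the hidden set recovered; with no new predictions precision is 0.
PR curves re-threshold one z-score matrix over a size grid (activities
and scores are computed once), so the networks are nested and recall is
monotone. AUPRC integrates trapezoidally over the achieved recall
range, anchored at recall 0 with the first point's precision, without
extrapolation to recall 1. The benchmark harness runs the full
factorial of variants × knockout fractions × replicates (default 5
replicates, matching the protocol the testing design follows) and
reports per-cell AUPRC.

Problem sizes in the shipped tests and acceptance script (200×10×50,
sizes up to a few hundred edges, 5 replicates) were chosen so the whole
suite completes in well under a minute while leaving the expected
orderings stable across seeds.

## Known limitations

* The NCA estimators require $M \ge L$ and criteria-compliant
  topologies; heavily overlapping regulons lose TFs to reduction (the
  PLS variant is the fallback, at a precision cost).
* MI scores need enough conditions to partition; below a few dozen
  samples the estimator is conservative (often exactly 0), which mutes
  the A-variants on small designs.
* Recall is measured against the hidden links only; truly novel links
  (absent from the database altogether) count against precision even
  when biologically real, so measured precision is a lower bound.
* Regulation sign is not predicted.
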