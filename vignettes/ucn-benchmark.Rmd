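---
title: "Substructure-aware training and atom-attribution benchmarking"
author: "ucnbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure-aware training and atom-attribution benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Graph neural networks (GNNs) are now routine for molecular property
prediction, and per-atom feature attribution is the standard way to ask
*why* a model predicts what it does. In lead optimization the natural unit
of evidence is not a single molecule but a **matched pair**: two analogs of
a congeneric series that share a common core and differ at one or more
substitution sites. When such a pair shows a large potency difference (an
**activity cliff**, here at least one pIC50 log unit), medicinal-chemistry
reasoning assigns the difference to the differing substituents. That
reasoning yields an objective, chemistry-grounded ground truth for
attribution methods — atoms outside the pair's maximum common substructure
(MCS) of the more potent compound should carry positive attribution, those
of the less potent compound negative — without requiring any belief about
what the "true" explanation of a single prediction is.

`ucnbench` implements this benchmark end to end, together with the
**uncommon-node (UCN) auxiliary loss**, a training objective that
explicitly ties the model's internal representation of the differing
substituents to the observed potency difference.

## Models and objectives

The regressor is a message-passing GNN. With node features
$x_v \in \mathbb{R}^{F}$, edge features $e_{uv}$, and hidden width $d$:

$$h_v^{(0)} = \sigma(W_0 x_v + b_0), \qquad
  h_v^{(t)} = \sigma\Big(W_s h_v^{(t-1)}
    + W_n \sum_{u \in N(v)} h_u^{(t-1)}
    + W_e \sum_{u \in N(v)} e_{uv} + b\Big)$$

with $\sigma = \tanh$ and $T$ message passes. The prediction head is a
two-layer perceptron on the **mean** over all node embeddings,
$\hat y = g\big(\tfrac1N \sum_v h_v^{(T)}\big)$, so inference needs no pair
or scaffold information: the model predicts single compounds, including
compounds from series never seen in training.

Training always samples **pairs** of compounds that share a scaffold
(MCS fraction at least 0.5) and differ by at least one log unit. Three
objectives are compared, differing only in the auxiliary term:

* **MSE** — $\lVert y_i-\hat y_i\rVert^2 + \lVert y_j-\hat y_j\rVert^2$
  per pair. Pair batching makes the data exposure identical across
  objectives, which is exactly why the activity-cliff control exists:
  sampling pairs is itself a form of data augmentation that must be
  separated from the substructure-aware signal.
* **MSE + AC** — adds $\lambda\,\big((y_i-y_j)-(\hat y_i-\hat y_j)\big)^2$,
  a relative-potency (activity-cliff) term.
* **MSE + UCN** — adds $\lambda\,\big((u_i-u_j)-(y_i-y_j)\big)^2$ where
  $u = \xi\big(\varphi(M(h))\big)$ is the **uncommon-node readout**:
  $M$ selects the embedding rows of the atoms outside the pair's MCS,
  $\varphi$ is the mean over those rows, and $\xi$ a dedicated linear
  multilayer perceptron. The term asks the substituent atoms alone to
  explain the potency difference.

$\lambda$ defaults to 1. $\xi$ is deliberately a *separate* head from the
prediction head: the absolute-activity path ("aggregate over all available
nodes") stays untouched by the masked path, and with $\lambda = 0$ both
auxiliary modes reproduce plain MSE training exactly (this is tested
bit-for-bit on the training trace).

Batch aggregation is the mean over pairs, so $\lambda$ keeps its meaning at
any batch size. The optimizer is Adam with a fixed step size and a fixed
number of epochs — no early stopping — so a seed fully determines a run.
Forward and reverse passes are written in matrix form over a block-diagonal
sparse graph; the same analytic gradients drive training, the gradient
check (numerical agreement to 1e-4 relative), and the gradient-based
attribution methods.

A random-forest regressor on ECFP4 fingerprints (2048 bits, radius 2,
500 trees) is the non-GNN comparator.

## Ground truth and metrics

For each qualifying pair, atoms are colored $+1$ (uncommon atoms of the
more potent compound), $-1$ (uncommon atoms of the less potent one), $0$
(common atoms). Two metrics score an attribution method:

* **Global direction** ($g_{dir}$, per pair, binary): does the difference
  of the mean attribution over the two uncommon-atom sets have the same
  sign as the experimental potency difference? Chance level is 0.5, which
  the random-attribution baseline verifies empirically.
* **Color agreement** ($\bar g_{atom}$, per compound): the fraction of
  uncommon atoms whose attribution sign matches their $\pm 1$ color.
  Evaluated on uncommon atoms only — the shared core has no defined color.

Sign comparisons use a tolerance: $|x| < 10^{-12}$ counts as sign 0, which
matches neither ground-truth sign. Counting exact zeros as failures is the
conservative choice for a case the metric definitions leave open.

Predictive quality is tracked alongside as test-set RMSE and Pearson
correlation. Per-target values are aggregated both as simple means and as
means weighted by test-pair counts; both are reported.

## Attribution methods and conventions

CAM, Grad-CAM, GradInput, and Integrated Gradients (gradient-based) plus
node masking (perturbation) for the GNN; atom masking for the random
forest. Conventions, uniformly applied:

* Feature-to-atom aggregation is the **mean over the feature dimension**.
* Only node features are attributed; edge features are held fixed. The
  benchmark colors atoms, not bonds.
* Scores are signed and **not** normalized per molecule; the metrics
  consume raw signs and relative magnitudes.
* Grad-CAM omits the usual rectifier — the benchmark explicitly needs
  negative contributions.
* CAM excludes the head bias (a constant per-graph offset cannot be
  attributed to atoms). With a purely linear head the mean CAM score
  equals $\hat y - b$ exactly; with the default hidden head layer CAM
  applies the final linear layer to per-node hidden activations, a
  documented approximation.
* Integrated Gradients uses the all-zero node-feature matrix as baseline —
  the natural "absent atom" reference, consistent with node masking — and
  a midpoint quadrature with 128 steps by default. Completeness (sum of
  terms $\approx \hat y(x) - \hat y(0)$) is monitored and tested to 1e-3
  relative.
* RF atom masking substitutes **xenon** for the masked atom and
  re-fingerprints: a concrete realization of "an atom type absent from the
  training chemistry".

## The synthetic benchmark

Real pair-based benchmarks need large curated bioactivity collections and
cluster-scale training. To make every stage testable on one CPU, the
package generates **synthetic congeneric series with planted additive
substituent effects**: a scaffold template with marked attachment sites, a
substituent library with per-fragment potency contributions (in pIC50 log
units), and

$$y = \text{base} + \textstyle\sum_{\text{sites}} w(\text{fragment})
      + \mathcal{N}(0, \sigma).$$

The truth table records each substituent's atoms (in canonical order) and
weight, so the pairing module's MCS-derived coloring can be checked against
the construction, and attribution quality has a known planted signal.
Sites are sampled independently, so pairs naturally differ at one or
several substitution sites, enabling the single- versus multi-site
stratification.

Default study conditions: **5 targets x 80 compounds, noise SD 0.1 log
units**, substituent weights uniform in $[-1.05, 1.05]$ and base activities
in $[6.6, 7.4]$ (keeping pIC50 in a realistic 4-10 band), two-site
scaffolds of 9-13 heavy atoms with heteroatom anchors (cheap, unambiguous
MCS). Weight draws are resampled (bounded retries) until a series yields at
least 100 qualifying pairs, so an 80/20 compound split keeps comfortably
more than 50 training pairs per target. The default GNN for benchmark runs
at this scale is d = 32, 2 message passes, 100 epochs, learning rate 3e-3,
batch 32 — sizes chosen so a full three-objective, five-method run over
five targets completes in minutes on one CPU.

What the generator does **not** emulate: real chemical diversity (one
scaffold per target, a 12-fragment library), correlated or heteroscedastic
assay noise, non-additive structure-activity relationships (no
interaction terms between sites), stereochemistry, and tautomerism.
Passing tests on this data show that the machinery recovers planted,
additive, single-mechanism signal; they do not show that any method
explains real SAR, where additivity routinely breaks.

One consequence of the clean synthetic signal is a **ceiling effect**: on
several targets plain-MSE models already direction-classify nearly every
test pair correctly for the strongest methods (CAM in particular), so a
strict per-target improvement from the UCN objective is not always
observable even when aggregate direction scores move up. Comparisons
between objectives are therefore most informative on the targets and
methods below ceiling (node masking, GradInput).

## Data preparation rules

Given a SMILES/activity table (CSV or SDF; raw molar IC50 is transformed
as $-\log_{10}$ on request), per target:

1. enumerate unordered compound pairs; keep those with
   $|\Delta \mathrm{pIC50}| \ge 1$ (inclusive) **and** MCS fraction
   $\ge 0.5$;
2. the MCS fraction is $\min(s/N_a,\ s/N_b)$ for MCS size $s$ — the
   strictest reading of "a minimum fraction of their structure", so the
   threshold guarantees coverage of *both* compounds;
3. split **compounds** 80/20 at random; a pair is train iff both members
   are train compounds, test iff both are test; straddling pairs are
   dropped (counted). No compound can appear on both sides — the no-leakage
   rule by construction, property-tested over 50 seeds;
4. drop targets with fewer than 50 training pairs (inclusive threshold).

The activity filter runs before the MCS computation; the result is
identical and the expensive step runs only on cliff candidates.

## Numerical and design choices

* **Atom indices are 1-based** everywhere (R convention); masks,
  attributions, and CSV outputs are consistent.
* **MCS semantics**: connected maximum common *induced* subgraph under
  element identity and bond-order class (single/double/triple/aromatic);
  ring atoms never match acyclic atoms. One embedding is returned,
  determined by a fixed search order (candidate atoms ascending, partners
  ascending), so runs are reproducible. A per-pair wall-clock budget
  (default 10 s) returns the best mapping found with a timeout flag;
  timed-out pairs are dropped with a warning and counted. Correctness is
  tested against an exhaustive enumeration oracle on molecules of up to 10
  heavy atoms.
* **Pairs with an empty uncommon set** (one compound a substructure of the
  other) are flagged: they are excluded from the explainability metrics
  (their sign is undefined) and contribute only their squared-error term
  during UCN training.
* **Murcko scaffolds** (for the diversity statistic) iteratively prune
  terminal non-ring atoms, leaving rings plus linkers; acyclic molecules
  map to a shared "none" scaffold. Exocyclic double-bonded atoms are
  pruned too — a simpler variant than some toolkits; the diversity ratio
  is insensitive to this detail within a congeneric series.
* **Fingerprints** are Morgan-style circular fingerprints with sorted
  neighbor hashing and standard duplicate-environment removal; bit
  positions are hash-specific to this package (set-bit counts are tested
  against an environment-enumeration oracle, not against other toolkits'
  bit layouts).
* **Parsing**: structure perception (canonicalization, aromaticity, rings)
  is OpenBabel's, via ChemmineOB. OpenBabel silently repairs unbalanced
  parentheses, so a light syntax check rejects such input explicitly;
  unparseable records in tables are skipped with a warning and counted,
  never fatal.
* **Determinism**: every stochastic step (weight init, batch shuffling,
  splits, noise, random baseline, forest) is keyed to an explicit seed,
  and the caller's RNG state is restored afterwards. Pipeline outputs are
  byte-reproducible under fixed seeds.

## Known limitations

* The synthetic data's additivity makes absolute metric levels optimistic;
  see the ceiling-effect note above.
* The exact MCS search is exponential in the worst case; highly symmetric
  molecules rely on the timeout path. The built-in templates avoid this by
  construction.
* CAM on a hidden-layer head is an approximation (exact only for linear
  heads); Grad-CAM is exact but the two coincide only in the linear case.
* The GNN is intentionally compact; no attention, no 3D geometry, no
  hyperparameter search. The point of the package is the benchmark and the
  loss, not architecture engineering.
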