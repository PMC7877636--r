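---
title: "Network-constrained latent feature selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-constrained latent feature selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model behind each stage, the tunable parameters and why their defaults are
what they are, the choices made where the method is genuinely
under-determined, and what the synthetic benchmarks do and do not
demonstrate.

## The ranking model

The core object is a weighted feature graph over a candidate gene set
`T`. Gene relevance is modelled generatively: each gene's expression
profile is compressed into a bag of class-annotated tokens, and a
two-topic probabilistic latent semantic analysis (PLSA) model explains the
gene-token co-occurrence counts as a mixture of a *relevant* and an
*irrelevant* topic. The posterior `p(rel | f_i)` is the probability that
gene *i*'s profile is drawn from the relevant topic, and the graph weight
`(A_p)_ij = p(rel|f_i) p(rel|f_j)` is the joint probability that a pair is
relevant. The biological prior enters as a Hadamard mask: `A = A_p ∘ A_F`,
where `A_F` is the binary directed adjacency of the functional-interaction
network restricted to `T`. A path of length `l` through `A` has energy
equal to the product of its edge weights — the joint relevance of the
traversed subset — and the score of a gene marginalizes the energies of
*all* paths of *all* lengths leaving it:

```
Č = Σ_{l ≥ 1} r^l A^l = (I − rA)⁻¹ − I,      š(i) = [Č e]_i
```

The interpretation is that a gene matters if it participates in many
high-relevance subsets, and the mask restricts those subsets to ones
realizable as walks through known regulatory structure. Genes with no
retained interaction are structurally outside the model and score exactly
zero.

### Regularization

The series converges iff `r · ρ(A) < 1`. Rather than fixing `r` as an
absolute constant — which would diverge or vanish depending on the mask's
density — the package sets `r = α / ρ(|A|)` with `α = 0.9` by default, so
the geometric decay per step is the same fraction of the convergence limit
for every input. `ρ` is computed on `|A|` because the mask is directed and
`A` may be asymmetric; the bound must hold for the series of magnitudes
actually summed. `α` trades locality against path length: values near 0
approach degree-like scoring (one-step paths dominate), values near 1
weight long paths heavily and amplify the dominant connected component.
`α = 0.9` keeps long paths influential without numerical trouble; the unit
checks verify the closed form against a 200-term truncated series at
`r·ρ = 0.9` to 1e-8.

### Numerical choices in the ranking

* The inversion is performed on the sub-matrix of non-isolated genes
  (rows/columns with any retained arc); isolated genes are assigned score
  0 exactly, not approximately, so the "masked-out genes score zero"
  property is an identity rather than a tolerance.
* Ties — all isolated genes tie at zero, and symmetric graphs can tie
  connected genes — are broken by |paired-t statistic| descending, then
  gene identifier ascending. The ranking is therefore a deterministic
  total order, which file round-trips preserve (scores are printed at 12
  significant digits).
* The diagonal of `A_p` is forced to zero. Self-loops would contribute
  `p(rel|f_i)²` at every step and dominate the geometric series while
  carrying no subset information, and the interaction adjacency defines no
  self-regulation.
* The mask is applied as-is (directed) by default. The adjacency formula
  is directed, while the graph-weighting narrative treats the graph as
  undirected; both readings are honored via `symmetrize_mask` (default
  `FALSE`), which ORs `A_F` with its transpose before the product.

## Tokenization

The quantization of profiles into tokens is deliberately simple and fully
specified: each gene is standardized to zero mean and unit variance across
samples; bin edges are the `Q`-quantiles of the *pooled* standardized
values of all genes (global edges, so bins are comparable across genes);
each sample contributes the token *(bin, condition)*. With the default
`Q = 6` the vocabulary has 12 tokens, far fewer than the number of samples,
which is the regime the topic model needs. Class annotation is what lets a
topic become class-asymmetric: the *relevant* topic is identified after
fitting as the one maximizing `Σ_bins |p((bin,tumor)|z) − p((bin,normal)|z)|`.
Constant genes cannot be standardized; their mass is placed in the middle
bin and flagged, which renders them maximally uninformative rather than
erroring a whole run.

## PLSA fitting protocol

EM on the standard PLSA decomposition `p(w|f) = Σ_z p(w|z) p(z|f)` with
exactly two topics. Choices that matter:

* **Initialization.** Topic mixtures `p(z|f)` start uniform (0.5/0.5);
  only the token distributions `p(w|z)` are randomized (normalized
  exponential draws, i.e. uniform-Dirichlet). Starting the mixtures
  uniform means feature symmetry is broken only by the data — genes with
  identical token counts keep identical posteriors at every iteration —
  while the random token distributions break the topic symmetry.
* **Responsibilities** are computed for each topic directly
  (`n·mix_z/denom`) rather than by complementation, which keeps them
  non-negative under floating point; complement subtraction can produce
  tiny negative masses that corrupt later iterations.
* **Restarts.** EM converges to local optima; the best of 3 seeded
  restarts by final log-likelihood is kept (`plsa_restarts`). The
  log-likelihood trace is recorded and is non-decreasing — an EM identity
  the tests check on random count matrices.
* **Stopping.** `plsa_tol = 1e-6` absolute log-likelihood gain per
  iteration, `plsa_max_iter = 200`; non-convergence returns the best
  iterate with a warning rather than failing, since the posterior ordering
  stabilizes long before the likelihood tail does.

## Preprocessing decisions

* The paired t-test runs on `log2(TPM + 1)`. Log transformation is the
  standard variance-stabilizing choice for abundance-scale RNA-seq values
  and makes the `|log2FC| > 1` screen coherent with the test; the
  pseudocount (default 1) guards zeros. The transform is configurable.
* The log2 fold change is the mean of per-pair log differences — the same
  quantity whose mean the t statistic tests — not the log of the ratio of
  means.
* Genes whose pair differences have zero variance get `p = 0` when the
  mean difference is non-zero (the effect is exact under the model) and
  `p = 1` otherwise, with a message; `t.test` would error.
* Both screen inequalities are strict (`q < 0.05`, `|lfc| > 1`), and the
  hub threshold is strict (`degree > 100`). Degree counts distinct
  partners, so a bidirectional edge contributes once per endpoint; the
  alternative (counting arcs) would double-count bidirectional records.
* Multiplicity is Benjamini–Hochberg step-up, cross-checked against an
  independent literal implementation to 1e-12.

## The evaluation harness

The classifier study follows a two-partition design: feature selection
sees only the selection partition (paired samples), and the classifier is
trained and tested by cross-validation inside the validation partition.
Within each fold iteration, ADASYN rebalancing is applied to the training
folds only; the test fold is scored untouched, and the implementation
asserts structurally that no synthetic record can reach a test fold.

* **ADASYN** (`k = 5`, `β = 1`, Euclidean): the synthetic budget
  `G = (n_maj − n_min)·β` is allocated to minority points proportionally
  to the majority share of their k-neighborhoods, and each synthetic point
  interpolates toward a random minority neighbor with `λ ~ U(0,1)`.
  `β = 1` targets a near-1:1 class ratio. When no minority point borders
  the majority the budget is spread uniformly (the degenerate `Σr = 0`
  case).
* **Folds are stratified.** With minority fractions around 4%, plain
  5-fold splits frequently produce one-class folds; stratification is the
  only reading under which the design is routinely executable. If a fold
  still ends up one-class the repeat is re-seeded once, then errors.
* **SVM**: linear kernel, cost 1, features standardized by training-fold
  statistics. AUC is computed from decision values oriented toward the
  tumor class (fixed `direction` — an auto-oriented AUC can never fall
  below 0.5 and would bias null calibrations upward); F1 uses tumor as the
  positive class at decision threshold 0, defined as 0 when precision and
  recall both vanish. A repeat's AUC/F1 is the mean over its folds; means
  over repeats are reported.
* **Null calibration.** Repeats of CV on one label-permuted dataset are
  strongly correlated — they share that dataset's chance structure — so a
  meaningful chance-level check spreads its repeats over several
  independent permutations of a cohort large enough for the permutation
  AUC to concentrate. The package's calibration check uses 10 permutations
  × 10 repeats of a 200-sample cohort and expects the grand mean in
  [0.45, 0.55]; small cohorts additionally show the well-known downward
  (pessimistic) bias of cross-validated performance under the null.

## The synthetic benchmark

The generator emulates the input regime the pipeline is built for: paired
tumor/normal FPKM matrices with planted, network-coherent signal.
Defaults: 200 genes, 40 paired patients, 20 unpaired tumors, a 20-gene
signal module with true effect 2 (log2-TPM units), unit log2-scale noise,
5 hubs wired to ≥ 120 partners, background edge probability 0.02, and a
70/30 selection/validation split of the pairs.

* **Expression model**: per-gene baseline `N(5, 2)` on the log2 scale,
  a per-patient-per-gene random effect `N(0, 0.5)` shared by the tumor and
  normal sample of a pair (this is what makes the *paired* test the right
  analysis and gives it analyzable power), the condition effect on
  signal genes, and i.i.d. Gaussian noise, exponentiated to FPKM. Values
  of that form are log-normal, matching the log-scale t-test assumptions
  by construction.
* **Network model**: the signal module is a random spanning tree plus
  extra within-module edges (p = 0.3), so the planted genes are always
  connected; hubs get `hub_degree` random partners; everything else is
  Erdős–Rényi background. Directions are uniform over
  forward/backward/bidirectional, as no direction statistics are assumed.
* **Decoys** (`n_decoys`, default 0) are differential genes deliberately
  excluded from all wiring. They pass the statistical screen but are
  invisible to the masked ranking — the discriminating scenario between
  the network-constrained and the unmasked method, used by the recovery
  checks with `n_decoys = 20`.

What passing benchmarks does *not* show: the generator does not mimic real
library-size variation, batch effects, count-level noise (mean–variance
dependence), correlated co-expression outside the planted module, or the
topology of curated interaction databases (degree distributions, pathway
overlap). Recovery results on it certify the machinery — screening,
masking, ranking, rebalanced evaluation — under a model where truth is
known, not performance on real cohorts.

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations to run
comfortably on a laptop: path-enumeration oracles up to 6 nodes and length
4 (enumeration is exponential and hard-capped at 8 nodes); series
truncation at 200 terms on 20-node graphs; a 2000-gene global-null
uniformity check of the paired test; 100 random count matrices for the EM
monotonicity identity; 10 benchmark replicates for end-to-end recovery;
and 25–100 CV repeats in the evaluation checks.

## Known limitations

* PLSA relevance is a two-topic model; expression programs with more than
  one tumor-associated pattern are folded into a single relevant topic.
* The score favors well-connected candidates by construction; a true
  driver with no curated interactions cannot outrank connected genes
  (it ties at zero and falls back to |t| ordering). This is the intended
  bias of the method, but it inherits the incompleteness of the
  interaction database.
* The paired screen requires ≥ 2 complete pairs and has no unpaired or
  moderated (shrinkage) variant.
* ADASYN interpolates in feature space; with very few minority samples the
  synthetics lie on a small set of segments and the rebalancing is close
  to duplication.
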