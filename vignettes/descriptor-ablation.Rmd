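---
title: "Measuring what descriptors contribute to enzyme-chemical activity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring what descriptors contribute to enzyme-chemical activity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eciml)
```

## The problem

Enzyme families are screened against chemical libraries to map substrate
promiscuity: which enzymes act on which chemicals. Machine-learning models
are routinely trained on such activity matrices, with enzymes represented
by sequence-derived descriptors and chemicals by structure-derived
descriptors. The question this package is built around is not "how well
does the model predict?" but "which descriptor actually carries the
signal?" — a question that matters because the answer differs by use
case: predicting unscreened pairs among known objects, transferring to
novel enzymes, or transferring to novel chemicals.

`eciml` answers it with a controlled ablation design. The same Random
Forest is trained four times on concatenated enzyme + chemical descriptor
vectors; the variants differ only in which descriptor block has been
deliberately destroyed by *permutation* (rows of a descriptor table are
reassigned to objects by a random bijection, so descriptors still exist
but carry no transferable object information):

| variant       | enzyme block | chemical block |
|---------------|--------------|----------------|
| `rf_all`      | intact       | intact         |
| `rf_protein`  | intact       | permuted       |
| `rf_chemical` | permuted     | intact         |
| `rf_none`     | permuted     | permuted       |

Performance differences between variants, evaluated under a splitting
scheme matched to the intended use, isolate each block's contribution.
Two non-ML baselines anchor the scale: a *random model* that draws
Bernoulli labels at the training activity ratio, and an *activity model*
that predicts, for any new enzyme, activity on the top-k chemicals ranked
by total training activity, with k = round(n_chemicals x training
activity ratio).

## Evaluation scenarios and filters

Three cross-validation schemes simulate the three use cases:

* **LOOT** (leave-object-out): assayed pairs are split into 10 random
  folds — new relationships among known objects.
* **LPOT** (leave-protein-out): enzymes are split into 10 folds; all of a
  held-out enzyme's pairs are validation — novel enzymes.
* **LCOT** (leave-chemical-out): symmetric on chemicals — novel
  chemicals.

For LPOT the chemicals are first filtered to those active on between 10%
and 90% of the enzymes (bounds inclusive) and on more than one enzyme;
LCOT applies the mirror rule to enzymes. The filter is computed once on
the full binary matrix, as dataset preparation for the scenario, not per
fold. "Between" is read inclusively; this only matters when a count sits
exactly on a boundary, and the choice is fixed here for reproducibility.

Each configuration is run with 10 folds under 5 fixed seeds (defaults
`101, 211, 307, 401, 503`), and per-fold metrics are aggregated as mean,
SD and standard error. Classification uses AUPR (baseline: positive
prevalence) and rank-based AUROC with ties counted 0.5 (baseline: 0.5);
regression uses squared Pearson correlation and MAE. Folds whose
validation labels collapse to a single class leave AUPR/AUROC undefined;
they are skipped and logged rather than imputed, because silent
substitution biases the aggregates. Models are compared with the
standard (pooled-variance) independent two-sample t-test on per-fold
values — fold-level rather than seed-level, which is the more
conservative and better-powered of the two readings — with the usual
star convention (0.05 / 0.01 / 0.001); Welch's variant is available via
`var_equal = FALSE`.

## Dataset statistics

Seven indicators characterize a dataset per scenario: numbers of enzymes
and chemicals after the scenario's filter, activity ratio (fraction of
active pairs, or mean activity for continuous data), the two activity
order indices, and mean top-5 similarities.

**AOIE / AOIC.** The Activity Order Index at the Enzyme axis asks: does
each individual chemical rank the enzymes the way the family is ranked
globally? For each chemical, every pair of enzymes with observed values
is scored concordant (1), discordant (0) or tied (0.5) against the
global enzyme ordering, and the per-chemical fractions are averaged
unweighted; AOIC is the mirror statistic on the chemical axis. A subtle
numerical choice: the global ordering for a given chemical is computed
from the row sums *excluding that chemical's own column*. If the focal
column is included, its own values leak into the reference ordering and
the index is biased upward on random data (about 0.556 instead of 0.5 on
50x20 Bernoulli(0.3) matrices); the leave-one-out form is unbiased at
0.5 for i.i.d. data and still exactly 1 on rank-consistent matrices,
which are the two defining anchors of the statistic. Chemicals with
fewer than two observed values contribute no pairs and are dropped from
the average; all-constant columns contribute 0.5.

**Similarities.** Protein similarity is the Smith-Waterman local
alignment score normalized by the geometric mean of the self-scores,
`SW(a,b)/sqrt(SW(a,a) SW(b,b))`, under BLOSUM62 with gap open 11 and gap
extend 1 (a length-k gap costs 11 + k) — the most common protein
defaults; the normalization maps scores onto (0, 1] so they are
comparable across sequence lengths. Chemical similarity is the Tanimoto
coefficient of 2048-bit radius-2 circular (Morgan) fingerprints. The
fingerprint is computed in-package on the molecular graph parsed from
SMILES by OpenBabel: atom invariants combine element, heavy-atom degree,
total bond order, ring membership and tetrahedral parity when the parsed
structure records it (structures converted from stereo-free SMILES
usually do not, so in practice enantiomers typically collide — a known
limitation). Top-5 similarity averages each object's five largest
off-diagonal similarities, then averages over objects; self-similarity
is excluded, and objects with fewer than five neighbours use all they
have.

## Descriptors

The in-repo sequence descriptor is `composition50`: amino acid
composition (20), grouped amino acid composition (5) and grouped
dipeptide composition (25), concatenated. The five residue groups are
the standard physicochemical classes (aliphatic GAVLMI, aromatic FYW,
positive KRH, negative DE, uncharged STCPNQ). `X` residues are accepted
in sequences but excluded from compositions; any other non-standard
letter is a validation error, because silently accepting arbitrary
characters corrupts descriptors. Composition descriptors are what makes
the *shuffle* ablation informative: shuffling residues within a sequence
destroys order information but leaves AAC/GAAC exactly invariant, so a
shuffled-descriptor model retains compositional signal while a permuted
one retains none.

Chemical descriptors are the 2048-bit fingerprint above or a fixed
8-property 2D physicochemical vector (molecular weight, logP, TPSA,
H-bond donors/acceptors, ring count, rotatable bonds, heavy atoms).
Pre-computed embeddings of any provenance enter through the `external`
descriptor spec (CSV or in-memory matrix keyed by object id, aligned to
dataset order); that seam is deliberately descriptor-agnostic so the
ablation logic never depends on how a vector was produced.

Permutation draws one bijection per (table, seed) and is applied to the
whole dataset before splitting: a model may memorize which objects were
in training but gains nothing transferable. Inside `run_cv()` the
ablation is re-drawn per split seed, so every replicate uses an
independent corruption.

## Models and tuning

The workhorse is a Random Forest (`ranger`), 500 trees, unlimited depth,
sqrt-fraction feature sampling, one thread, seeded — deterministic and
sized for matrices of tens to hundreds of objects. Classification
forests are probability forests and return the active-class probability.
An optional random-search tuner samples a documented grid (trees
100-1000, depth unlimited/5/10/20, min node size 1/5/10, mtry fraction
0.1-1) and scores configurations by cross-validated precision
(classification, maximized) or MAE (regression, minimized).

The random baseline draws Bernoulli(activity ratio) labels. The source
text for this model admits either a Bernoulli label or a continuous
draw; Bernoulli is the simplest distribution that both takes the ratio
as its single parameter and respects the "active if above 0.5" decision
rule, and it yields the correct AUPR baseline at prevalence. The
activity baseline's k is rounded half-up, floored at 0 and capped at the
number of chemicals, since the ratio product is generally non-integer.

## The synthetic generator

Real screens of this kind cannot be bundled, so every stage is exercised
on generated data whose structure mirrors what the statistics assume:

* **Sequences**: one random template per family; members mutate each
  position independently with probability mu to a different residue.
  mu directly controls within-family similarity (mu = 0 gives identical
  members; mu = 1 collapses within-family identity to the between-family
  level).
* **Chemicals**: Gaussian class centroids in d dimensions with isotropic
  member noise (default), or draws from a packaged synthetic library of
  ~96 simple molecules in six scaffold classes when the fingerprint path
  is wanted. Numeric mode is the default so core pipeline tests carry no
  cheminformatics dependency.
* **Activity**: latent `A(e,c) = B[f(e), g(c)] + alpha u_e + beta v_c +
  sigma eps`, binarized at the latent quantile so that exactly
  round(target x cells) cells are active. Quantile binarization (rather
  than a fixed threshold) makes the activity ratio an exact input knob,
  which the baseline-model tests rely on; latent ties are broken by
  deterministic cell order with a warning.

Defaults are 4 families x 10 enzymes (length 200, mu = 0.05), 4 classes
x 5 chemicals (d = 8), a diagonal-dominant block matrix `B = diag(3)`,
alpha = beta = sigma = 0.3 and target ratio 0.3 — a 40 x 20 screen with
strong family/class structure and low noise, the regime in which
descriptor ablation has a clean expected signature: the
protein-descriptor model should beat the activity baseline on LPOT, the
chemical-descriptor model should do so on LCOT, and the mismatched
descriptor should be statistically indistinguishable from no descriptor.
Generation is a pure function of (config, seed); family and class labels
and the latent matrix are returned as ground truth for recovery tests.

What the generator does *not* emulate: realistic kinetics, assay noise
with heavy tails, correlated missingness, homologous-domain mosaics, or
chemistry beyond scaffold-level similarity. Passing the synthetic suite
therefore certifies the machinery (statistics, splits, leakage-freedom,
ablation logic, baselines), not performance on any real enzyme family.

## Post-hoc analyses

Across several datasets, `correlate_statistics_with_performance()`
correlates each dataset statistic with each aggregated metric (Pearson r
with the two-sided t-distribution p-value on n - 2 degrees of freedom,
plus the least-squares slope/intercept for plotting) and reports the
statistic-vs-statistic correlation matrix alongside.

`embed_2d()` runs t-SNE (exact O(n^2) implementation, suitable for the
few hundred enzymes such datasets contain; perplexity 30, auto-reduced
to (n-1)/3 for small n; 400 iterations; seeded initialization) to
visualize enzymes in descriptor space. Cluster quality against known
family labels is quantified by `per_cluster_silhouette()`: the mean
silhouette of each cluster's members, computed with Euclidean distances
in the *original descriptor space*, not the 2D embedding — the
embedding distorts distances and depends on its own hyperparameters, so
feature-space values are the reproducible choice (the embedding remains
purely visual). Near-zero coefficients for permuted descriptors against
true family labels are the expected signature of destroyed information.

## Numerical choices and degenerate inputs

* Missing activity cells are never imputed; they are excluded from
  statistics, training pairs and metrics.
* Binarization is strict (`value > threshold`); re-binarizing a binary
  dataset warns and is a no-op. The log transform is
  `log10(v + pseudocount)` and rejects negatives.
* AUPR is the average-precision step form evaluated at every distinct
  score threshold (no trapezoidal smoothing).
* Single-object descriptor tables permute to themselves; empty pair
  lists produce well-formed 0-row feature matrices.
* All randomized operations (shuffle, permutation, splits, forests,
  baselines, generation) are pure functions of their seed; the RNG state
  of the caller is never disturbed.

## Problem sizes

The shipped tests run the full pipeline at the generator's default 40 x
20 scale with 5 seeds x 10 folds for the scenario-recovery checks, and
use small enumerable instances (matrices up to 6 x 6, sequences up to
length 12, score vectors up to n = 50) wherever an exact brute-force
oracle is compared against — sizes chosen so each oracle is trivially
auditable.

## Known limitations

* Fingerprints are heavy-atom, kekulized-graph based; aromatic
  perception follows the OpenBabel conversion, and stereochemistry is
  captured only when the converter records parity.
* The Smith-Waterman normalization bounds similarity away from 0 for
  any pair with a positive local score; values are comparable within a
  scoring scheme, not across schemes.
* The t-SNE implementation is exact and quadratic; it is not intended
  for more than a few thousand points.
* Regression evaluation assumes the metadata-declared scale is the one
  to model; no automatic transformation is applied.
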