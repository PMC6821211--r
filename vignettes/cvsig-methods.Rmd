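---
title: "Cell viability signatures from perturbation transcriptomics: models and methods"
author: "cvsig maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell viability signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large perturbation-transcriptomics screens (L1000-style landmark-gene
profiling of compound and shRNA treatments) overlap with large viability
screens (fraction-surviving readouts for compounds, shRNA abundance log fold
changes for pooled knockdown screens). When a treated cell population is
dying or proliferating, that phenotype itself leaves a transcriptional
footprint that is largely independent of the perturbing agent. This package
implements a pipeline around that observation:

1. match signatures to viability records by cell line, perturbagen and dose;
2. learn the common **cell viability signature** (CVS) with a ridge model and
   validate it within and across screen types;
3. quantify how the viability footprint confounds mechanism-of-action (MoA)
   inference from signature similarity, and remove it;
4. apply the CVS model screen-wide to classify compounds as toxic or
   proliferative and benchmark against an external sensitivity screen;
5. use MODZ consensus signatures as drug-level features in random-forest
   models of drug sensitivity.

All stages are exercised against a synthetic-data generator with planted
ground truth, so the whole pipeline is testable offline.

## Models

### MODZ consensus

For a group of $n$ signatures, the pairwise Spearman correlation matrix is
computed; its diagonal is set to 0 and negative entries are clamped to 0.01.
Weights are the normalized row sums and the consensus is the weighted
average. Ties in ranks use average ranks. A pathological all-negative group
degenerates to equal weights (every off-diagonal entry becomes 0.01); this is
accepted and documented rather than special-cased. A constant signature row
has no defined rank correlation; it is treated as correlation 0 (then
clamped) with a warning.

### Matching

Dose matching works in log10 micromolar: a viability record pairs with the
candidate signature instance minimizing $|\Delta \log_{10} d|$, accepted iff
that minimum is strictly below the tolerance (default 0.2, roughly a 1.5-fold
concentration difference). Ties are broken by the lower signature dose, then
lexicographic instance id, which makes matching deterministic and
order-independent. shRNA records match on exact (cell, perturbagen) keys. One
signature may serve several time points because the phenotype is measured
once per condition; matching is viability-record-driven, so each record pairs
with at most one instance per time point.

### Ridge CVS model

The model is $y = X\beta + b$ with an L2 penalty $\alpha\lVert\beta\rVert^2$
($\alpha = 1$), an unpenalized intercept, and **no feature standardization**
(landmark z-scores already share a scale). The intercept is handled by
centering $X$ and $y$; the coefficient path is solved through the SVD of the
centered design, which is stable for both $n > G$ and $n < G$. Predictions
align columns by gene id and refuse silently missing genes. Validation uses
random sub-sampling: 50/50 splits repeated 20 times within a dataset;
across datasets the model is trained on a random half of the training set
and evaluated on the entire test set, with Pearson correlation between
predicted and observed viability as the only metric — correlation, not
absolute error, because fraction viability and log fold change live on
different scales and the models are deliberately trained across that
mismatch. The "standard" reference model uses one-hot cell and perturbagen
IDs (plus log10 dose for compound data) with the same solver; unseen IDs
encode to zeros.

### De-confounded similarity

Signature similarity is Spearman correlation. The toxicity threshold is
derived from a two-component Gaussian mixture on fraction viability (the
nontoxic component's mean minus twice its SD; with a nontoxic mode near 1.0
and SD near 0.1 this lands at the conventional 0.8). Confounder removal
offers two routes: dropping the $n$ genes with the largest absolute
viability correlation — computed on the *shRNA* screen while similarity is
assessed on the *compound* screen, to prevent leakage — or per-gene
regression of expression on viability, keeping residuals. Similarity fusion
z-normalizes each matrix's off-diagonal entries before summation. ROC and
precision-recall curves group tied scores, so the ROC area equals the
Mann-Whitney U statistic.

### Screen-wide classification and benchmarking

Per compound, predictions are restricted to that compound's own maximum
tested dose and the extremes across cells/times are kept. A compound is
toxic when its minimum prediction crosses the toxic threshold
(general vs selective depending on whether the maximum also crosses it) and
proliferative when its maximum crosses the proliferative threshold. The
fixed defaults (-3, 1.5) are on the shRNA log-fold-change scale; the general
path computes thresholds as the 5th/95th percentiles of a supplied viability
vector. The external benchmark scores each (cell, compound) pair with its
lowest prediction and evaluates against a delta-concentration truth: a
log10 sensitivity metric minus the maximal tested log10 concentration, with
strictly negative values marking effective drugs.

### Drug-sensitivity machine learning

Cell features are per-gene standardized baseline expression scored against
weighted gene sets (TF regulons, pathway sets) plus a tissue one-hot block.
Drug features are one variant per run: nominal-target one-hot, targeted
pathway one-hot, fingerprint bits, or PCA scores of MODZ consensus
signatures (components to 95% explained variance, capped at 40). The PCA is
fit on training-fold drugs only and applied to the test fold — fitting on
all drugs would leak fold information. Random forests use 50 trees;
evaluation is the per-cell Pearson correlation over test drugs, averaged
over cells, across 20 resampled splits. Cells with fewer than three test
drugs are excluded; constant predictions (e.g. all-zero drug encodings for
held-out target classes) count as $r = 0$, i.e. "no information" rather than
missing.

## The synthetic world

The generator plants:

* a unit-norm sparse loading vector $w$ (30% of 300 genes) — the true CVS;
* 10 unit-norm MoA components orthogonal to $w$, amplitude 1.5;
* per-cell offset vectors (SD 0.15) for 12 cell lines — small enough that
  the leading principal component of the compound screen is the viability
  axis rather than a cell-identity direction, matching the structure the
  analysis assumes;
* a pIC50 hierarchy (class means $N(1.0, 1.5^2)$ in log10 µM, drug-level SD
  1.0, cell-level SD 0.3) over 60 compounds in 10 classes, so some classes
  are toxic within the 0.37-10 µM dose grid and others inert, with
  substantial *within-class* potency spread;
* logistic dose-response with slope 3 per log10 unit (close to a Hill
  coefficient of one on the natural-log scale): burden
  $u = \kappa\,\sigma(3(\log_{10} d - \mathrm{pIC50}))$, $\kappa = 3$;
  fraction viability $1 - u/\kappa$ plus noise (SD 0.05), clipped at 0;
* compound signatures $X = -g(\tau)\,u\,w + 1.5\,m_{k} + c_{\mathrm{cell}} +
  \varepsilon$ with maturation $g(3h, 6h, 24h) = 0.2, 0.5, 1.0$ and unit
  noise — early signatures carry a weak viability component, which is what
  makes 3 h and 6 h models predict poorly;
* 150 shRNAs with knockdown efficiencies in (0.4, 1], essentiality for 40%
  of them, LFC $= -e$ plus noise (SD 0.3), signatures sharing the same $w$
  axis plus a target-gene knockdown and a reproducible per-shRNA off-target
  component (amplitude 1.5), mirroring seed-sequence effects;
* a baseline panel in which each cell's expression carries $\rho_c w$, a
  doubling time decreasing in $\rho_c$ with tissue structure, GLDS offsets
  correlated 0.5 with $\rho_c$, and a sensitivity table
  $\mathrm{AUC} = 0.5 + 0.1\,\mathrm{GLDS}_c - 0.3\,\mathrm{tox}_p +
  0.1\,\mathrm{state}_{c,k(p)} + \varepsilon$.

The drug-level toxicity main effect in the AUC model deserves a note: under
per-cell correlation evaluation, cell-only terms cancel, and a pure
class-by-cell interaction is unlearnable for *held-out* target classes by
any drug encoding. What transfers to unseen classes is the drug's toxicity,
which consensus signatures carry along the $w$ axis while class one-hots do
not — this is the designed mechanism behind the consensus-versus-pathway
comparison, and it mirrors the scientific claim that the viability signature
is what generalizes.

Seeds: the world is drawn from one seeded stream in a fixed order; each
simulation operation reseeds deterministically from the world seed, so a
fixed (config, seed) pins every downstream number.

### What the generator does not emulate

No gene-regulatory network structure, no batch or plate effects, no
realistic chemistry behind the fingerprints, a single shared noise scale per
assay, and cell-line offsets that are exactly additive. Passing tests
demonstrate that the estimators recover what was planted under the assumed
structure — they do not certify performance on real screens, where the
viability axis is itself an abstraction.

## Numerical and design choices

* Ridge oracle: the closed form used in tests centers $X$ as well as $y$,
  the semantics of an unpenalized intercept; the implementation route (SVD)
  and the test oracle (direct normal-equation solve) are independent.
* GLDS identifiability: the two-way additive model is identified up to
  constants; sum-to-zero constraints pin the cell effects, so only
  differences between cells are meaningful.
* Silhouette: singleton clusters score 0 (the common convention).
* Spearman ties: average ranks throughout.
* Constant genes: correlation statistics flag them with $r = 0$; z-scoring
  maps them to 0 rather than NaN.
* GMM threshold: mclust, 2 unequal-variance components, seeded; if the
  component means collapse within half the larger SD, the conventional 0.8
  falls back in with a warning.
* "Random" pair group: all cross-perturbagen pairs outside the two defined
  groups; same-perturbagen pairs are excluded everywhere.
* Within- versus across-screen performance: the native compound model beats
  transferred models on compound data (the MoA components are
  compound-screen-specific signal). The shRNA screen has no analogous
  class-level structure — its perturbagen-specific components are one
  direction per shRNA, too thin for a ridge model to exploit — so a
  compound-trained model can match the native shRNA model on shRNA data.
  The suite asserts the native advantage where its mechanism exists.
* Problem sizes in the test suite are the generator defaults (300 genes, 12
  cells, 60 compounds, 150 shRNAs); the association-power analysis
  (null-signature comparison) uses a 40-cell panel because partial
  correlations over 12 cells carry too little information for any null
  comparison to be meaningful.

## Known limitations

The package operates purely in the landmark gene space and does not infer
non-landmark expression. Identifier harmonization across vendors is out of
scope — inputs arrive pre-harmonized. The permutation set z-score is the
in-repo scoring path for weighted gene sets; it is not claimed to equal the
normalized enrichment scores of external engines (GSEA/viper/PROGENy), whose
gene-set content is consumed as user-supplied input when needed.
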