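---
title: "Methods: quantile-regression expression deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantile-regression expression deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk RNA-seq measures the aggregate expression of a tissue: a mixture of
cell types whose proportions are themselves of clinical interest (the
immune contexture of a sample). Expression deconvolution infers those
proportions from the mixture profile. `nnice` implements a deep
quantile-regression estimator for this task: instead of a single point
estimate per cell type, it fits one single-output network per (cell
type, quantile) pair, so each prediction comes with an uncertainty band
spanned by the lower and upper quantile outputs.

## The estimator

For six pooled immune lineages (B cell, CD4 T cell, CD8 T cell,
Myeloid, NK cell, Other) and the quantile set
$\{0.10, 0.25, 0.50, 0.75, 0.90\}$, the model holds $6 \times 5 = 30$
independent networks. Each network maps the (normalized) expression
vector $x \in \mathbb{R}^{G}$ of a sample to one scalar: the estimated
fraction of its cell type at its quantile level. The architecture is an
input layer of $G$ features (default 3000) densely connected to a
hidden layer of 300 units with linear activations, then a 1-unit linear
output whose bias is constrained non-negative after every optimizer
step; the weight kernels carry an L2 penalty with
$\lambda = 10^{-4}$. With the defaults each network has
$3000 \times 300 + 300 + 300 + 1 = 900{,}601$ parameters.

Because every activation is linear, each network is an
over-parameterized linear model; what makes the estimator non-trivial
is the objective. Two metrics are combined into a composite loss

$$\mathrm{Loss} = \alpha\,(1 - R) + (1 - \alpha)\,\mathrm{RMSE},$$

with $R$ the minibatch Pearson correlation between true and estimated
fractions and $\alpha$ (default 0.8, `alpha_mix`) trading
correlation against scale accuracy. Quantile behavior comes from the
tilted (pinball) loss

$$\mathrm{TiltedLoss}(q, \xi) = \max\!\big(q\,\xi,\ (q - 1)\,\xi\big),$$

whose minimizer over a conditional distribution is its $q$-th quantile.

### Two readings of the nested objective

The phrase "the composite loss nested inside the tilted loss" admits
two constructions, and the package implements both
(`model_config(loss_mode = ...)`):

* **`signed`** (the default): the pinball loss is applied to the signed
  per-sample residual $\xi_i = y_i - \hat y_i$ and averaged, plus
  $\alpha (1 - R)$ on the batch as a correlation regularizer. Because
  the correlation term is shift- and scale-invariant, the location of
  the prediction is governed by the pinball term alone, so the $q$-net
  estimates the $q$-th conditional quantile; under-prediction costs
  $q/(1-q)$ times more than over-prediction.
* **`literal`**: $\mathrm{TiltedLoss}(q, \mathrm{Loss})$ applied to the
  scalar batch loss. Since the composite loss is non-negative, the max
  always takes the positive branch and the objective collapses to
  $q \times \mathrm{Loss}$ — all five quantile levels then optimize
  proportional objectives and the quantile spread carries no
  distributional meaning. The mode is kept for fidelity experiments,
  and the degeneracy is asserted exactly in the test suite.

The signed residual is defined as $y - \hat y$ (not $\hat y - y$):
that orientation is the one under which empirical coverage below the
$q$-net's prediction converges to $q$, which the test suite verifies on
a held-out noisy regression (coverage within $\pm 0.1$ of each $q$ at
$n = 500$).

### Training

Each net is trained independently with hand-rolled minibatch Adam
(learning rate $10^{-3}$, batch 64, up to 30 epochs, early stopping
with patience 5 on validation loss and best-weight restore). Gradients
of both objectives are analytic — including the Pearson term — and are
checked against central finite differences to $10^{-4}$ relative
tolerance in the tests. Inputs are log1p counts-per-million, then
per-feature standardized with statistics fitted on the training split
only. Minibatches with fewer than two samples are skipped (the batch
correlation is undefined there); a constant batch falls back to the
RMSE-only part of the composite loss. Training aborts with a diagnostic
on a non-finite loss. All randomness (initialization, batching,
validation split) derives from the configuration seed, so training is
bit-reproducible single-threaded.

### Prediction and aggregation

Raw net outputs are clipped to $[0, 1]$. The point estimate is the
unweighted mean of the five quantile outputs — averaging across
quantiles gives a less biased point estimate than any single net — and
the uncertainty interval is the (q10, q90) pair. The per-type nets are
independent by design (multicollinearity across cell types is the
stated reason for per-type sub-models), so point-estimate rows are
*not* renormalized to sum to one unless `renormalize = TRUE` is
requested. Quantile crossing (a lower net predicting above a higher
one) is reported as-is; `sort_quantiles = TRUE` applies an optional
post-hoc monotone repair.

## The synthetic reference generator

The package ships a generator so the whole pipeline is testable without
any downloads. It emulates the statistical structure the estimator
assumes in real FACS-sorted single-cell references:

* ten fine-grained immune populations (named after the classic sorted
  PBMC panels) that pool into the six lineages;
* per-gene baseline rates from a long-tailed log-normal
  ($\sigma_{\log} = 1.2$), with a configurable fraction of marker genes
  dealt round-robin across types and boosted `marker_fold`-fold
  (default 5) in their owning type;
* negative-binomial counts (dispersion `nb_dispersion`, default size 2)
  with mean `depth × rate`, per-cell depth uniform in `[0.5, 2]`,
  followed by independent dropout zeroing (default rate 0.2);
* mitochondrial genes flagged by the `MT-` ID prefix (default 2% of
  genes) whose rates can be boosted to produce cells failing the 5%
  mitochondrial QC rule.

Default fixture scale is 10 types × 300 cells × 1000 genes — a
desk-scale stand-in for references with ~10,000 cells per type. Under
these defaults a nearest-centroid classifier on log counts recovers
over 95% of labels, mirroring the clear cluster separation of sorted
populations.

What the generator does **not** model: ambient RNA, doublets, batch
effects, UMI-vs-read distinctions, or platform differences between
summed single-cell counts and true bulk chemistry. Passing tests
therefore demonstrate correctness of the pipeline's statistics and
learning behavior on NB-with-dropout data, not performance on any real
cohort.

## Quality control and pooling

Cells are retained when they express between 200 and 3000 features
with positive counts (inclusive bounds) and have a mitochondrial count
percentage strictly under 5. "Between" is read as inclusive and
"under" as strict — both are configurable. Zero-total cells are
assigned 0% mitochondrial content and removed by the minimum-genes rule
anyway. Two pooling maps ship with the package: the ten sorted PBMC
populations, and a fourteen-type whole-blood flow panel (plasmablasts
pooled with B cells, dendritic cells with monocytes into Myeloid,
basophils into Other). The whole-blood assignments for plasmablasts and
basophils are conventions, not measurements, and any map can be
overridden with a two-column table. CD34+ progenitors map to "Other".
Gene matching is exact string match; no alias resolution is attempted.

## Feature selection

The fixed input space (default 3000 genes) is the top of a
variance-stabilized variability ranking *within* the pool of genes
that pass all eligibility criteria: membership in an immune-related
gene list, presence in every dataset the model must serve, and presence
in the reference. Intersecting first guarantees the advertised feature
count exactly; taking the top of the ranking first could not. The
ranking scores each gene by the variance of clipped Pearson residuals
$(x_{gc} - \mu_{gc}) / \sqrt{\mu_{gc} + \mu_{gc}^2/\theta}$ with
$\mu_{gc} = \mathrm{depth}_c \, p_g$, fixed $\theta = 100$, and
clipping at $\pm\sqrt{n_\mathrm{cells}}$ — an analytic approximation of
the regularized-NB highly-variable-gene criterion. The full
regularized regression is intentionally out of scope; the provenance
table records each selected gene's rank and score so selections are
auditable. Ties break lexicographically on gene ID, making the ranking
a deterministic total order; zero-count genes rank last. Variability is
computed after QC filtering.

A known limitation, documented because the tests exercise it: with
strong overdispersion plus dropout, dimly expressed marker genes can be
outranked by strongly expressed noisy non-markers. This is inherent to
any variance-based criterion, and is why the marker-dominance property
is verified in a moderate-noise regime (NB size 10, no dropout) while
the end-to-end benchmark — which does not depend on every marker being
selected — runs at the noisier generator defaults.

## Pseudo-bulk simulation

Ground-truth fraction vectors are i.i.d. Dirichlet draws (symmetric
$\alpha = 1$ by default: uniform on the simplex, the least-informative
choice; the concentration is configurable). Cell counts per type are
the largest-remainder rounding of $C \times$ fractions (default
$C = 500$ cells per sample), which is deterministic and sums exactly
to $C$; ties in the fractional parts break by cell-type order. The
stored ground truth is the *continuous* Dirichlet draw, not the
post-rounding realized proportion; under largest-remainder rounding the
two differ by at most $1/C$ per type. Cells are subsampled uniformly
without replacement — falling back to with-replacement only when a
type's pool is smaller than the request, with a message — and their
count vectors are summed feature-wise. Profiles stay raw count sums;
normalization is the model's concern. Cells used for feature selection
are split off (stratified by type) before any mixture is simulated, so
marker selection never leaks into the simulation pool. No sequencing
noise is added on top of the summed counts.

## Evaluation

Reports carry Pearson $R$, RMSE, and the composite loss (same
$\alpha$ as training, echoed in the report metadata) at four
granularities: overall, per cell type (quantile-averaged), per
quantile (types pooled), and per (type, quantile). "Overall" is the
metric on the *concatenation* of all (sample, type) pairs, not the mean
of per-type values — the tests pin this down on a fixture where the two
disagree. A constant truth column leaves $R$ undefined; it is reported
as missing, never as zero. Cross-validation uses a seeded shuffle and
contiguous chunking into $k$ folds (sizes differing by at most one,
unstratified); each fold's model trains on the complement and predicts
the fold, and pooled out-of-fold estimates are evaluated in the
original sample order. Scatter reports annotate each panel with the
least-squares slope and intercept alongside $R$, because a high
correlation with a slope far from 1 would overstate accuracy.

## Problem sizes

The bundled end-to-end benchmark (`run_benchmark()`, also what
`scripts/acceptance.R` runs) uses a 1000-gene, 10-type, 300-cells/type
reference, 300 selected features, 2000 training and 500 held-out
mixtures of 500 cells each, and 64 hidden units — sizes chosen so the
whole pipeline completes in well under a minute on one CPU while
leaving the learning problem non-trivial (pooled held-out $R$ is
typically 0.96–0.98, comfortably above the 0.9 the full-scale method
reports on simulated mixtures). The test suite uses smaller fixtures
still, sized to keep the default run fast.

## Known limitations

* Summed single-cell counts are not bulk RNA-seq; no platform
  transfer is attempted or claimed.
* Independent per-type nets mean estimated fractions need not sum
  to one; renormalization is available but off by default.
* The literal objective mode is degenerate by construction (see
  above) and exists for comparison only.
* The generator's NB-plus-dropout law is a modeling convention; no
  claim is made that it matches any particular instrument beyond
  overdispersion and zero inflation.
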