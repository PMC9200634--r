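---
title: "Methods: cell types of origin for cell-free RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell types of origin for cell-free RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cforigin)
```

## The problem

Cell-free RNA (cfRNA) circulating in blood plasma is a pooled readout of
transcripts released by cells throughout the body. If the transcriptome of
each contributing cell type is known, a plasma sample can be modelled as a
linear mixture

$$ A\theta = b $$

where $A$ is a genes $\times$ cell-types *basis matrix* of reference
expression profiles (CPM scale), $b$ is the measured plasma expression of
those genes, and $\theta$ is the vector of fractional cell-type
contributions we want: non-negative and summing to one. `cforigin`
implements this model end to end — sample QC, normalization, basis-matrix
construction from a labeled single-cell atlas, nu-support-vector-regression
(nu-SVR) deconvolution, derivation of cell-type-specific gene profiles in
whole-body context, and signature-score cohort comparisons — together with
a synthetic-data generator that produces every input with known ground
truth.

## Sample quality control

Three per-sample metrics are computed from derived count tables (upstream
alignment tooling is out of scope):

* **3' bias fraction** — the fraction of detected genes whose reads all
  fall on their 3'-most (highest-numbered) exon; a proxy for RNA
  degradation. Duplicated exon rows are summed first; genes with zero total
  reads are not "detected".
* **Ribosomal fraction** — ribosomal reads over total reads.
* **Intron-to-exon ratio** — a DNA-contamination proxy.

A sample is excluded when *any* metric is strictly greater than its
threshold (0.4, 0.2 and 3 respectively); values exactly at a threshold are
retained. All three metrics are invariant to uniform count scaling.

## Normalization

Counts are first adjusted to counts per million and per millilitre of
plasma:

$$ \eta_{ij} = \frac{10^6 \; \mathrm{Gene}_{ij}}
   {\mathrm{LibrarySize}_j \times \mathrm{mL\ plasma}_j} $$

When a plasma volume is unknown it defaults to 1 mL with a warning. For all
analyses except deconvolution, trimmed-mean-of-M-values (TMM) scaling
factors are then computed and divided out, and values are
log(1 + x)-transformed. The TMM procedure is implemented in the package:
per gene, M is the log2 expression ratio against a reference sample and A
the average log abundance; genes absent from either sample are dropped; M
is trimmed 30% two-sided and A 5% two-sided; the factor is
$2^{\bar M_w}$ with inverse-delta-method-variance weights; factors are
geometric-mean-centred so they multiply to one. The reference defaults to
the sample whose upper-quartile ratio is closest to the mean. The test
suite verifies this implementation against edgeR's `calcNormFactors` and
against a brute-force oracle to $10^{-9}$.

Technical replicates are averaged arithmetically on the *linear* scale:
at stage `cpm_ml` for deconvolution inputs, and at stage `cpm_ml_tmm` —
before the log transform — for scoring inputs. Batch labels are carried as
metadata for stratified reporting only; no batch correction model is
applied.

## Basis-matrix construction

From a labeled atlas (sparse cells $\times$ genes counts with cell type,
compartment and tissue annotations):

1. **Exclusions** — overly broad cell-type labels, unreliable tissues and
   dissociation-induced genes can be dropped up front.
2. **Coarse-graining** — transcriptionally similar cell types are merged to
   protect the linear independence of the basis columns. Per compartment,
   cells are CPM-normalized and logged, projected onto the first 50
   principal components, cell types are averaged in PC space and clustered
   with complete linkage on Euclidean distance, and the dendrogram is cut
   at a fraction of its highest node (defaults: epithelial 0.20, stromal
   0.10). The endothelial compartment collapses to a single column; the
   immune compartment keeps a curated label list with erythrocyte and
   erythroid progenitor merged. Clustering per-type mean positions in
   cell-level PC space (rather than linking individual cells) was a design
   choice; it is the granularity at which labels are merged.
3. **Subsampling** — at most 30 cells per grouped type (all cells when
   fewer), sampled without replacement.
4. **Signature selection** — per grouped type, a two-sided Wilcoxon
   rank-sum test of that type's cells against the rest (BH q < 0.01,
   positive enrichment, direction consistent across 5 random half-samples
   of the cells) yields candidates ranked by fold change (ties broken by
   ascending q then gene id, for determinism). For each per-type barcode
   count in a configurable range, the candidate matrix of per-type mean CPM
   over the union of top genes is formed; the matrix minimizing the 2-norm
   condition number $\kappa$, subject to $\kappa \le 999$, is selected.
   Quantile normalization is never applied. The half-sampling consistency
   rule is an explicit, documented stand-in for replicate-stability
   schemes whose internals are not public.

At desk scale the default barcode range is tens of genes per type (the
production-scale analogue selects thousands in total); tests sweep small
ranges exhaustively so the $\kappa$-minimization can be checked against an
independent enumeration.

## nu-SVR deconvolution

`deconvolve()` is the package's model-fitting function:

* The mixture is restricted to basis genes measured at $\ge 1$ CPM; counts
  are *not* log-transformed (the concavity of the log would destroy the
  linearity of the mixture model and bias $\theta$ downward).
* Mixture and basis are standardized to zero mean and unit variance. The
  basis is standardized as one matrix (global mean/sd) rather than per
  column, preserving the between-column magnitude differences that carry
  cell-type abundance signal; this granularity is not externally specified,
  so it is recorded in the fitted object.
* One linear-kernel nu-SVR is fit per point of the grid
  $\nu \in \{0.05, 0.1, 0.15, 0.25, 0.5, 0.75\}$,
  $C \in \{0.1, 0.5, 0.75, 1, 10\}$ (30 fits). For a linear kernel the raw
  cell-type weights are recovered from the support vectors as
  $w = \mathrm{coefs}^\top \mathrm{SV}$.
* Weights are projected to the simplex by truncation: negatives are zeroed
  and the remainder renormalized; an all-non-positive fit is flagged
  degenerate and excluded from model selection rather than renormalized.
* For each candidate, predicted expression $A^\ast \theta$ is compared with
  the measured standardized values; the candidate with the smallest RMSE
  wins (ties: smaller $\nu$, then smaller $C$ — preferring sparser
  support). RMSE and Pearson r are computed in the standardized space where
  the fit occurs, and the standardization parameters are stored so either
  convention can be reported.

The solver is libsvm via `e1071::svm` with its standard stopping tolerance
of $10^{-3}$ (the same default as the scikit-learn NuSVR implementation of
this model family). Tightening the tolerance to $10^{-6}$ changes recovered
fractions at the $10^{-5}$ level on synthetic mixtures — three orders of
magnitude below the accuracy bands used anywhere in this package — while
occasionally sending individual grid points into near-degenerate SMO
cycling that costs seconds per fit, so the standard tolerance is the
default and a `tolerance` argument is exposed.

Fraction estimates are scale-invariant in $b$ (standardization absorbs the
scale) and land on the simplex unless every raw weight is non-positive, in
which case the fit is flagged rather than silently patched.

## Cell-type-specific gene profiles

For cell types unique to one tissue, a gene enters the cell type's profile
when it passes single-cell differential expression *and* whole-body tissue
specificity:

* **DE within the atlas** — counts per cell normalized to $10^4$
  (counts-per-ten-thousand) and logged; Wilcoxon rank-sum target-vs-rest;
  BH-adjusted p < 0.01; expression-space fold change $\ge 1.5$ (expm1 of
  group means of logged values, the convention of the standard single-cell
  toolchain); in-group expression fraction $\ge 0.2$; out-group fraction
  $\le 0.5$; and the highest per-other-type percent expressed divided by
  the in-group percent expressed must be below 0.5.
* **Tissue specificity** — against a tissue consensus expression table
  (NX-like units): Gini coefficient $\ge 0.6$, the gene listed as specific
  to the cell type's native tissue, and category one of *Tissue enriched*,
  *Group enriched*, *Tissue enhanced*. Genes absent from the tissue table
  are dropped (counted, not imputed).

The inequality indices, with $x$ the gene's expression across $n$ tissues:

$$ \mathrm{Gini} = \frac{n+1}{n} -
   \frac{2 \sum_{i=1}^{n} (n+1-i)\, x_{(i)}}{n \sum_i x_i}
   \qquad
   \tau = \frac{\sum_i \left(1 - x_i/\max(x)\right)}{n-1} $$

with $x_{(i)}$ sorted ascending. Gini is 0 for a uniform vector and
$(n-1)/n$ for a one-hot vector; both are scale- and permutation-invariant.
When a tissue is represented by several sub-regions (as brain often is),
profile genes legitimately expressed across those sub-regions receive
systematically lower Gini values; the threshold is deliberately kept at
0.6 rather than tuned per tissue.

`profile_foldchange_check()` mirrors the bulk-tissue validation: the
profile's summed expression (log counts-per-ten-thousand scale) in its
native tissue, relative to the mean across other tissues, should exceed 1.

## Signature scores and cohort statistics

The signature score of profile $G$ in sample $j$ is
$\sum_{i \in G} \log(1 + \eta^{TMM}_{ij})$ — a plain sum of logged CPM-TMM
values. Missing genes contribute 0, keeping scores comparable across
samples with different detected gene sets; for shallow cohorts
`dropout_filter()` first removes profile genes with no non-zero measurement
in either cohort.

Cohort scores are compared with a Mann–Whitney U-test (exact enumeration
for tie-free groups of at most 8; tie-corrected normal approximation
otherwise). P-values are calibrated by permutation: group labels are
shuffled `n_perm` times (default 10,000) and

$$ p = \frac{\#\{\text{permuted } \Delta \ge \Delta_{\text{observed}}\}}
            {n_{\text{perm}} + 1} $$

with $\Delta$ the difference in group means; the +1 in the denominator
accounts for the original unpermuted comparison. The same rule drives the
Gini permutation test that asks whether disease DEGs overlapping a
cell-type profile are more cell-type-specific than DEGs that are merely
tissue-specific ($T = (B \cap U) \cup (B \cap D) - C$, with $C \subseteq B$
enforced). Gene-set overlaps use the upper-tail hypergeometric
distribution. Degenerate all-equal scores yield exactly
$n_{\text{perm}}/(n_{\text{perm}}+1)$.

Two accounting utilities complete the module: a per-tissue tally of
tissue-specific genes measured in a sample ($\ge 1$ CPM) but absent from
the basis rows (categories as above, NX $\ge 10$), which is anti-monotone
in the basis row space; and marker-database detection (sensitivity
$\ge 0.9$, specificity $\le 0.2$ — specificity being a
not-expressed-elsewhere rate, so small is stringent), counting markers with
logged expression > 0 and reporting cell types averaging more than 5
detected markers.

## The synthetic-data generator

The generators exist so that every pipeline stage can be tested against
known ground truth, with no external downloads:

* **Atlas** — negative-binomial counts (the overdispersion typical of
  droplet scRNA-seq; dispersion is a parameter). Each cell type owns a
  disjoint marker set whose mean is `marker_fold_change` times the gene's
  baseline in that type only; baselines vary log-normally around
  `base_mean`. Setting the fold change to 1 yields a null atlas on which
  no downstream DE fires.
* **Mixtures** — expected counts proportional to $A\theta_{\text{true}}$
  at a chosen depth, with a noise menu of none / Poisson / multiplicative
  log-normal; sufficient to probe deconvolution robustness without
  read-level simulation.
* **Exon tables** — exactly `round(frac * n_genes)` genes carry all reads
  on their last exon; ribosomal and intronic totals match requested
  fractions within integer rounding.
* **Tissue tables** — planted markers are high in their native tissue only
  (category assigned by rule: a dominant top tissue is *Tissue enriched*;
  uniform rows are *Low tissue specificity*), so the exact one-hot Gini
  value $(n-1)/n$ is planted by construction.
* **Cohorts** — Poisson counts around log-normal baselines; cohort B's
  profile genes are shifted by `exp(log_effect)`; non-profile genes remain
  exchangeable, so non-profile scores stay null-distributed regardless of
  the planted effect.

Two default regimes are used throughout tests: a *deconvolution-grade*
atlas (10 types, 600 genes, 50 markers per type, fold change 8, baseline
mean 2) whose signature matrix has a few hundred rows and
$\kappa \approx 2.5$, and a *profile-grade* atlas (sparse background:
baseline mean 0.15, fold change 30) in which planted markers satisfy the
in/out-group expression-fraction DE filters the way genuine cell-type
markers do. These sizes keep a full test run in minutes on one core while
leaving every planted quantity recoverable by the stage that should
recover it.

What the generators do *not* emulate: ambient-RNA contamination, doublets,
batch structure within the atlas, fragment-level coverage bias, or
realistic gene-gene correlation. Passing tests therefore demonstrate that
the estimators recover what their models assume — not that those models
capture every pathology of real plasma data.

## Numerical choices and edge cases

* Condition numbers are 2-norm (ratio of extreme singular values); a
  singular candidate yields $\kappa = \infty$ and can never be selected.
* Fold-change ranking ties break by ascending q then lexicographic gene id.
* RMSE ties in model selection break by smaller $\nu$, then smaller $C$.
* Zero-variance mixtures, all-zero Gini/Tau inputs, empty profiles, empty
  QC denominators and zero library sizes all raise informative errors
  rather than propagating NaN.
* All generators and both permutation procedures are pure functions of
  their seed.

## Known limitations

* nu-SVR leans on highly expressed genes as support vectors, so cell types
  with low-magnitude profiles are systematically under-weighted; fractions
  are relative RNA contributions, not cell counts.
* The basis standardization granularity (global vs per-column) changes the
  meaning of the learned weights; only the global convention is the
  default, with the alternative left to the caller.
* Profiles are only derived for cell types unique to one tissue; shared
  cell types (e.g. macrophages) are out of scope by construction.
* The coarse-graining cut fractions are compartment-specific constants,
  not data-adaptive.
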