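# cforigin

Cell types of origin for cell-free RNA (cfRNA) by nu-SVR deconvolution.

Plasma cfRNA is a mixture of transcripts shed by cells across the body.
`cforigin` estimates, for each plasma sample, the fractional contribution of
each cell type by solving the linear mixture model

```
A θ = b,    θ ≥ 0,  Σ θ = 1
```

where `A` is a genes × cell-types **basis matrix** of reference expression
profiles built from a labeled single-cell atlas, `b` is the sample's
measured expression (CPM per mL plasma), and `θ` is learned by
nu-support-vector regression with a linear kernel over a grid of
(ν, C) hyperparameters, followed by non-negative truncation,
renormalization, and smallest-RMSE model selection.

Around that core the package provides the full analysis pipeline:

* **QC** — 3' bias fraction, ribosomal read fraction, intron-to-exon ratio,
  with strict exclusion thresholds (0.4 / 0.2 / 3).
* **Normalization** — CPM per mL plasma, TMM scaling factors
  (trimmed mean of M-values, implemented and cross-checked against edgeR),
  technical-replicate averaging, log transform.
* **Basis construction** — exclusion lists, compartment-wise coarse-graining
  of cell-type labels by dendrogram cutting in PC space, per-type
  subsampling, and barcode-gene selection by Wilcoxon DE plus
  condition-number (κ) minimization.
* **Profiles** — cell-type-specific gene profiles in whole-body context via
  single-cell DE filters and Gini / Tau tissue-specificity indices against
  a tissue consensus table.
* **Scoring** — signature scores (sum of logged CPM-TMM values over a
  profile), Mann–Whitney cohort comparisons, permutation calibration,
  hypergeometric overlaps, basis-coverage accounting and marker-database
  detection.
* **Synthetic data** — generators for every input (atlas, mixtures, exon
  tables, tissue tables, cohorts, marker DB) with planted ground truth, so
  the whole pipeline is testable offline.

## Worked example

Simulate an atlas, build a basis matrix, mix nine cell types in known
proportions, and deconvolve:

```r
library(cforigin)

spec  <- atlas_spec(n_cell_types = 10, n_genes = 600, cells_per_type = 40,
                    markers_per_type = 50, marker_fold_change = 8, seed = 3)
atlas <- subsample_cells(coarse_grain(generate_atlas(spec), seed = 3),
                         n_max = 30, seed = 3)
basis <- build_signature_matrix(atlas, barcode_range = c(50, 50), seed = 3)
basis
#> basis matrix: 500 barcode genes x 10 cell types, kappa = 2.54

truth <- mixture_truth(c(0.35, 0.25, 0.15, 0.10, 0.05,
                         0.04, 0.03, 0.02, 0.01, 0),
                       depth = 1e6, noise_model = "poisson")
mix <- generate_mixture(basis, truth, seed = 42)
fit <- deconvolve(cpm_per_ml(mix), basis)
fit
#> nu-SVR deconvolution fit
#>   genes used: 500; selected nu = 0.05, C = 0.1; RMSE = 0.6041; Pearson r = 0.999
#>   top fractions:
#>     CT01                                     0.352
#>     CT02                                     0.252
#>     CT03                                     0.153
#>     CT04                                     0.098
#>     CT05                                     0.049

round(coef(fit), 3)
#>  CT01  CT02  CT03  CT04  CT05  CT06  CT07  CT08  CT09  CT10
#> 0.352 0.252 0.153 0.098 0.049 0.040 0.027 0.018 0.010 0.000
```

The recovered fractions match the planted θ to within ~0.003 per cell type
under Poisson sampling noise at a depth of 10^6 counts; the absent tenth
cell type is correctly assigned zero. `summary(fit)` shows the full
(ν, C) grid with per-candidate RMSE and Pearson r; `predict(fit)` returns
the fitted expression values, in the standardized space of the fit or
back-transformed to CPM.

Downstream, `single_cell_de()` + `derive_profile()` turn an atlas plus a
tissue consensus table into cell-type-specific gene profiles, and
`signature_score()` + `compare_cohorts()` + `calibrate_pvalues()` compare
those profiles between cohorts.

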