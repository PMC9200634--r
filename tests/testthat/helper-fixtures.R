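# Shared synthetic fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Deconvolution-grade atlas + basis: 10 well-separated types, enough planted
# markers for a few-hundred-gene basis.
decon_basis <- function() fixture("decon_basis", function() {
  spec <- atlas_spec(n_cell_types = 10, n_genes = 600, cells_per_type = 40,
                     markers_per_type = 50, marker_fold_change = 8, seed = 3)
  atl <- subsample_cells(coarse_grain(generate_atlas(spec), seed = 3),
                         30, seed = 3)
  build_signature_matrix(atl, barcode_range = c(30, 50), seed = 3)
})

# Profile-grade atlas: sparse background so planted markers satisfy the
# in/out-group expression-fraction filters.
profile_atlas <- function() fixture("profile_atlas", function() {
  spec <- atlas_spec(n_cell_types = 8, n_genes = 400, cells_per_type = 40,
                     markers_per_type = 15, marker_fold_change = 30,
                     base_mean = 0.15, seed = 4)
  generate_atlas(spec)
})

profile_tissue_table <- function() fixture("profile_tissue_table", function() {
  generate_tissue_table(profile_atlas(), n_extra_tissues = 2, seed = 4)
})

profile_ct01 <- function() fixture("profile_ct01", function() {
  atl <- profile_atlas()
  de <- single_cell_de(atl, "CT01")
  derive_profile(de, profile_tissue_table(), "CT01",
                 atl$tissue_of_type[["CT01"]])
})

# Quiet deconvolution wrapper: libsvm prints max-iteration notes to the
# console; they are not R conditions and are irrelevant at test tolerances.
quiet_deconvolve <- function(...) {
  out <- NULL
  capture.output(out <- deconvolve(...))
  out
}
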