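small_atlas <- function() fixture("small_atlas", function() {
  spec <- atlas_spec(n_cell_types = 6, n_genes = 240, cells_per_type = 25,
                     markers_per_type = 8, marker_fold_change = 10, seed = 5)
  generate_atlas(spec)
})

test_that("exclusion lists drop cells, tissues and genes and nothing else", {
  atl <- small_atlas()
  expect_identical(apply_exclusions(atl), atl)

  no_ct1 <- apply_exclusions(atl, drop_labels = "CT01")
  expect_false("CT01" %in% no_ct1$cells$cell_type)
  expect_equal(nrow(no_ct1$counts), nrow(atl$counts) - sum(atl$cells$cell_type == "CT01"))

  tis <- atl$cells$tissue[1]
  no_tis <- apply_exclusions(atl, drop_tissues = tis)
  expect_false(tis %in% no_tis$cells$tissue)

  g <- colnames(atl$counts)[1:10]
  no_g <- apply_exclusions(atl, drop_genes = g)
  expect_false(any(g %in% colnames(no_g$counts)))

  expect_error(apply_exclusions(atl, drop_labels = unique(atl$cells$cell_type)),
               "no cells remain")
})

test_that("dendrogram cutting merges similar types and respects cut extremes", {
  atl <- small_atlas()
  # cut at 0: every type its own group
  g0 <- coarse_grain(atl, cut_fraction = c(epithelial = 0, stromal = 0), seed = 1)
  expect_equal(sort(unique(g0$cells$cell_type)), sort(unique(atl$cells$cell_type)))
  # cut at 1: one group per compartment
  g1 <- coarse_grain(atl, cut_fraction = c(epithelial = 1, stromal = 1), seed = 1)
  per_comp <- tapply(g1$cells$cell_type, g1$cells$compartment,
                     function(v) length(unique(v)))
  expect_true(all(per_comp == 1))
  # grouped labels partition the original labels
  expect_equal(anyDuplicated(unlist(lapply(split(g1$cells$base_type,
                                                 g1$cells$cell_type), unique))), 0)
})

test_that("types simulated from one profile merge at 20%; disjoint-marker types do not", {
  # two clones of the same profile plus two marker-disjoint types
  spec <- atlas_spec(n_cell_types = 4, n_genes = 200, cells_per_type = 60,
                     markers_per_type = 20, marker_fold_change = 30,
                     nb_dispersion = 0.1,
                     compartment_of_type = setNames(rep("epithelial", 4),
                                                    sprintf("CT%02d", 1:4)),
                     seed = 9)
  atl <- generate_atlas(spec)
  # make CT02 a clone of CT01: same mean profile, independent noise
  set.seed(99)
  idx2 <- atl$cells$cell_type == "CT02"
  idx1 <- which(atl$cells$cell_type == "CT01")
  m <- as.matrix(atl$counts)
  mu1 <- colMeans(m[idx1, ])
  m[idx2, ] <- matrix(rnbinom(sum(idx2) * ncol(m), mu = rep(mu1, each = sum(idx2)),
                              size = 10), sum(idx2), ncol(m))
  atl$counts <- Matrix::Matrix(m, sparse = TRUE)
  cg <- coarse_grain(atl, cut_fraction = c(epithelial = 0.20), seed = 9)
  grp <- unique(cg$cells[, c("base_type", "cell_type")])
  g <- setNames(grp$cell_type, grp$base_type)
  expect_equal(g[["CT01"]], g[["CT02"]])   # clones merged
  expect_false(g[["CT03"]] == g[["CT04"]]) # disjoint markers kept apart
})

test_that("endothelial collapses and immune keeps its list with erythroid merge", {
  types <- c("endo art", "endo cap", "t cell", "erythrocyte",
             "erythroid progenitor", "granulocyte")
  spec <- atlas_spec(n_cell_types = 6, n_genes = 150, cells_per_type = 12,
                     markers_per_type = 5, seed = 11,
                     compartment_of_type = setNames(
                       c("endothelial", "endothelial", "immune", "immune",
                         "immune", "immune"), sprintf("CT%02d", 1:6)))
  atl <- generate_atlas(spec)
  atl$cells$cell_type <- types[match(atl$cells$cell_type, sprintf("CT%02d", 1:6))]
  names(atl$markers) <- types
  names(atl$tissue_of_type) <- types
  cg <- coarse_grain(atl,
                     immune_keep = c("t cell", "erythrocyte", "erythroid progenitor"),
                     seed = 1)
  labs <- unique(cg$cells$cell_type)
  expect_true("endothelial cell" %in% labs)
  expect_false("granulocyte" %in% cg$cells$base_type)  # dropped, not relabeled
  expect_true("erythrocyte/erythroid progenitor" %in% labs)
  expect_true("t cell" %in% labs)
})

test_that("subsampling caps cells per type without replacement, deterministically", {
  atl <- small_atlas()   # 25 cells per type
  s30 <- subsample_cells(atl, 30, seed = 2)
  expect_equal(nrow(s30$counts), nrow(atl$counts))  # fewer than cap: all kept
  s10 <- subsample_cells(atl, 10, seed = 2)
  expect_true(all(table(s10$cells$cell_type) == 10))
  expect_equal(anyDuplicated(s10$cells$cell_id), 0)
  expect_identical(subsample_cells(atl, 10, seed = 2)$cells$cell_id,
                   s10$cells$cell_id)
})

test_that("signature matrix keeps planted markers and minimizes kappa over the sweep", {
  spec <- atlas_spec(n_cell_types = 5, n_genes = 150, cells_per_type = 30,
                     markers_per_type = 3, marker_fold_change = 12, seed = 7)
  atl <- subsample_cells(generate_atlas(spec), 30, seed = 7)
  basis <- build_signature_matrix(atl, barcode_range = c(2, 5), seed = 7)
  # every planted marker is among the selected rows
  expect_true(all(unlist(atl$markers) %in% rownames(basis$A)))
  # chosen kappa is the minimum over the examined candidate sweep
  sweep_tab <- attr(basis, "sweep")
  expect_equal(basis$kappa, min(sweep_tab$kappa))
  expect_true(all(basis$A >= 0))
  # provenance rows carry q-passing associations
  expect_true(all(basis$provenance$qval < 0.01))
  expect_true(all(basis$provenance$fold_change > 1))
})

test_that("near-singular candidate sets trip the kappa warning path", {
  spec <- atlas_spec(n_cell_types = 3, n_genes = 90, cells_per_type = 20,
                     markers_per_type = 4, marker_fold_change = 10, seed = 8)
  atl <- generate_atlas(spec)
  basis <- build_signature_matrix(atl, barcode_range = c(2, 3), seed = 8)
  # duplicated cell-type column -> condition number blows up
  A2 <- cbind(basis$A, dup = basis$A[, 1])
  expect_gt(kappa_2norm(A2), 1e6)
  # no candidate can meet an absurdly small kappa limit -> min-kappa + warning
  expect_warning(
    b2 <- build_signature_matrix(atl, barcode_range = c(2, 3),
                                 kappa_limit = 1.0001, seed = 8),
    "no candidate meets")
  expect_equal(b2$kappa, min(attr(b2, "sweep")$kappa))
})

test_that("an orthogonal equal-scale basis has near-unit condition number", {
  A <- diag(5) * 100
  expect_equal(kappa_2norm(A), 1)
  A2 <- diag(c(100, 50, 25, 10, 5))
  expect_equal(kappa_2norm(A2), 20)   # ratio of extreme column norms
})

test_that("basis similarity is a valid ordered Spearman matrix with planted structure", {
  basis <- decon_basis()
  rho <- basis_similarity(basis)
  expect_equal(unname(diag(rho)), rep(1, ncol(rho)))
  expect_true(all(rho >= -1 & rho <= 1))
  expect_equal(rho, t(rho))

  # duplicated column: rho = 1 off-diagonal
  b2 <- basis_matrix(cbind(basis$A[, 1:2], dup = basis$A[, 1]))
  r2 <- basis_similarity(b2)
  expect_equal(r2["dup", colnames(basis$A)[1]], 1)

  # independent random columns: rho near 0
  set.seed(42)
  br <- basis_matrix(matrix(runif(4000), 1000, 4,
                            dimnames = list(NULL, paste0("c", 1:4))))
  expect_lt(max(abs(basis_similarity(br)[upper.tri(diag(4))])), 0.1)
})
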