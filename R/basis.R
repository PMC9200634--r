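# Basis-matrix construction from a labeled single-cell atlas:
# exclusion lists -> compartment-wise coarse-graining by dendrogram cutting
# -> per-type subsampling -> barcode-gene signature selection by rank-test DE
# plus condition-number minimization over a barcode-gene count sweep.

#' Drop cells and genes by label, tissue or gene id
#'
#' Removes cells whose cell-type label or tissue is listed (e.g. annotations
#' that are too broad, or a tissue with unreliable annotations) and removes
#' listed genes (e.g. dissociation-induced genes).
#'
#' @param atlas \code{\link{cell_atlas}}.
#' @param drop_labels,drop_tissues,drop_genes character vectors (may be empty).
#' @return filtered \code{cell_atlas}.
#' @export
apply_exclusions <- function(atlas, drop_labels = character(),
                             drop_tissues = character(),
                             drop_genes = character()) {
  stopifnot(inherits(atlas, "cell_atlas"))
  keep_cell <- !(atlas$cells$cell_type %in% drop_labels) &
               !(atlas$cells$tissue %in% drop_tissues)
  keep_gene <- !(colnames(atlas$counts) %in% drop_genes)
  if (!any(keep_cell)) stop("no cells remain after exclusions")
  if (!any(keep_gene)) stop("no genes remain after exclusions")
  out <- atlas
  out$counts <- atlas$counts[keep_cell, keep_gene, drop = FALSE]
  out$cells <- atlas$cells[keep_cell, , drop = FALSE]
  if (!is.null(out$markers))
    out$markers <- lapply(out$markers, intersect, colnames(out$counts))
  out
}

# log1p-CPM of a cells x genes sparse matrix (dense result; desk scale).
.log_cpm_cells <- function(counts) {
  m <- as.matrix(counts)
  log1p(m / pmax(rowSums(m), 1) * 1e6)
}

#' Coarse-grain cell-type labels per compartment by dendrogram cutting
#'
#' Per compartment: cells are CPM-normalized and log(1+x)-transformed,
#' projected onto the first \code{n_pcs} principal components, cell types are
#' averaged in PC space and clustered (complete linkage, Euclidean distance),
#' and the dendrogram is cut at \code{cut_fraction} times the height of its
#' highest node; labels within a cluster are merged into a "/"-joined group
#' name. The endothelial compartment collapses to a single "endothelial cell"
#' group (its types are transcriptionally near-identical). The immune
#' compartment keeps only the labels in \code{immune_keep} (when given), with
#' "erythrocyte" and "erythroid progenitor" merged.
#'
#' @param atlas \code{\link{cell_atlas}}.
#' @param cut_fraction named numeric, compartment -> fraction of the maximum
#'   node height at which to cut (defaults: epithelial 0.20, stromal 0.10;
#'   unlisted compartments use \code{default_cut}).
#' @param immune_keep immune labels to keep (NULL keeps all).
#' @param n_pcs number of principal components (capped at the data rank).
#' @param default_cut cut fraction for compartments not named in
#'   \code{cut_fraction}.
#' @param seed integer seed (clustering is deterministic; kept for interface
#'   stability).
#' @return \code{cell_atlas} with grouped labels in \code{cells$cell_type};
#'   original labels are kept in \code{cells$base_type}.
#' @export
coarse_grain <- function(atlas, cut_fraction = c(epithelial = 0.20, stromal = 0.10),
                         immune_keep = NULL, n_pcs = 50, default_cut = 0.20,
                         seed = 1) {
  stopifnot(inherits(atlas, "cell_atlas"))
  set.seed(seed)
  cells <- atlas$cells
  cells$base_type <- cells$cell_type
  keep <- rep(TRUE, nrow(cells))
  group_of <- list()   # per compartment: named map base label -> group label

  for (comp in unique(cells$compartment)) {
    in_comp <- cells$compartment == comp
    labs <- unique(cells$cell_type[in_comp])
    if (comp == "endothelial") {
      group_of[[comp]] <- setNames(rep("endothelial cell", length(labs)), labs)
      next
    }
    if (comp == "immune") {
      if (!is.null(immune_keep)) {
        drop <- in_comp & !(cells$cell_type %in% immune_keep)
        keep <- keep & !drop
        labs <- intersect(labs, immune_keep)
      }
      map <- setNames(labs, labs)
      ery <- intersect(c("erythrocyte", "erythroid progenitor"), labs)
      if (length(ery) == 2) map[ery] <- paste(sort(ery), collapse = "/")
      group_of[[comp]] <- map
      next
    }
    if (length(labs) < 2) {
      message("compartment '", comp, "' has <2 cell types; passed through")
      group_of[[comp]] <- setNames(labs, labs)
      next
    }
    expr <- .log_cpm_cells(atlas$counts[in_comp, , drop = FALSE])
    k <- min(n_pcs, nrow(expr) - 1, ncol(expr))
    pc <- prcomp(expr, center = TRUE, scale. = FALSE, rank. = k)$x
    centers <- do.call(rbind, lapply(labs, function(l)
      colMeans(pc[cells$cell_type[in_comp] == l, , drop = FALSE])))
    rownames(centers) <- labs
    hc <- hclust(dist(centers), method = "complete")
    frac <- if (comp %in% names(cut_fraction)) cut_fraction[[comp]] else default_cut
    cl <- cutree(hc, h = frac * max(hc$height))
    map <- vapply(labs, function(l) {
      mem <- sort(labs[cl == cl[l]])
      paste(mem, collapse = "/")
    }, character(1))
    group_of[[comp]] <- map
  }

  out <- atlas
  out$counts <- atlas$counts[keep, , drop = FALSE]
  out$cells <- cells[keep, , drop = FALSE]
  map_all <- unlist(unname(group_of))
  out$cells$cell_type <- unname(map_all[out$cells$base_type])
  # carry planted markers and tissue map under the grouped names
  regroup <- split(names(map_all), unname(map_all))
  if (!is.null(atlas$markers))
    out$markers <- lapply(regroup, function(mem)
      unique(unlist(atlas$markers[mem])))
  if (!is.null(atlas$tissue_of_type))
    out$tissue_of_type <- vapply(regroup, function(mem)
      paste(sort(unique(atlas$tissue_of_type[mem])), collapse = "/"),
      character(1))
  out
}

#' Subsample cells per cell type
#'
#' Per (grouped) cell type, keeps \code{min(n_max, available)} cells sampled
#' without replacement; when fewer than \code{n_max} cells are available all
#' are kept. Deterministic given the seed.
#'
#' @param atlas \code{\link{cell_atlas}}.
#' @param n_max maximum cells per type (default 30).
#' @param seed integer seed.
#' @return subsampled \code{cell_atlas}.
#' @export
subsample_cells <- function(atlas, n_max = 30, seed = 1) {
  stopifnot(inherits(atlas, "cell_atlas"), n_max >= 1)
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(atlas$cells)), atlas$cells$cell_type),
                       function(i) if (length(i) <= n_max) i else sample(i, n_max)))
  idx <- sort(idx)
  out <- atlas
  out$counts <- atlas$counts[idx, , drop = FALSE]
  out$cells <- atlas$cells[idx, , drop = FALSE]
  out
}

# Two-sided Wilcoxon rank-sum p-values, one gene at a time, target cells vs
# rest, on a dense expression matrix (cells x genes).
.wilcox_by_gene <- function(expr, in_group) {
  vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[in_group, j]; y <- expr[!in_group, j]
    if (all(x == x[1]) && all(y == x[1])) return(1)
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }, numeric(1))
}

#' Build the barcode-gene signature (basis) matrix
#'
#' Per grouped cell type, candidate barcode genes are found by a two-sided
#' Wilcoxon rank-sum test of that type's cells against all others on CPM
#' expression, kept at Benjamini-Hochberg q < \code{qval} with positive
#' enrichment, and required to show a consistent direction across
#' \code{replicates} random half-samples of the cells (rate \code{sampling}).
#' Candidates are ranked by fold change (ties: ascending q, then gene id).
#' For each per-type gene count from \code{barcode_range[1]} to
#' \code{barcode_range[2]}, the candidate matrix of per-type mean CPM over
#' the union of top genes is formed and its 2-norm condition number computed;
#' the matrix minimizing the condition number, subject to it not exceeding
#' \code{kappa_limit}, is selected. Quantile normalization is not applied.
#'
#' @param atlas \code{\link{cell_atlas}} (grouped, subsampled).
#' @param qval BH q-value threshold (default 0.01).
#' @param barcode_range integer pair (gmin, gmax): per-type barcode-gene
#'   counts to sweep.
#' @param kappa_limit maximum acceptable condition number (default 999).
#' @param replicates,sampling stability half-sampling scheme.
#' @param seed integer seed (half-sampling).
#' @return \code{\link{basis_matrix}} with selection provenance and the full
#'   sweep recorded in attribute \code{"sweep"} (data.frame n_top, kappa).
#' @export
build_signature_matrix <- function(atlas, qval = 0.01, barcode_range = c(3, 10),
                                   kappa_limit = 999, replicates = 5,
                                   sampling = 0.5, seed = 1) {
  stopifnot(inherits(atlas, "cell_atlas"))
  types <- sort(unique(atlas$cells$cell_type))
  if (length(types) < 2) stop("need at least 2 grouped cell types")
  set.seed(seed)
  m <- as.matrix(atlas$counts)
  cpm <- m / pmax(rowSums(m), 1) * 1e6
  genes <- colnames(cpm)

  half_idx <- lapply(seq_len(replicates), function(r)
    sample(nrow(cpm), max(2, round(sampling * nrow(cpm)))))

  cand <- list()
  for (ct in types) {
    in_g <- atlas$cells$cell_type == ct
    p <- .wilcox_by_gene(cpm, in_g)
    q <- p.adjust(p, "BH")
    mu_in <- colMeans(cpm[in_g, , drop = FALSE])
    mu_out <- colMeans(cpm[!in_g, , drop = FALSE])
    fc <- (mu_in + 1e-9) / (mu_out + 1e-9)
    stable <- rep(TRUE, length(genes))
    for (idx in half_idx) {
      ing <- in_g[idx]
      if (!any(ing) || all(ing)) next
      d <- colMeans(cpm[idx[ing], , drop = FALSE]) >
           colMeans(cpm[idx[!ing], , drop = FALSE])
      stable <- stable & d
    }
    ok <- which(q < qval & fc > 1 & stable)
    if (length(ok) == 0)
      stop("no gene passes q < ", qval, " for cell type '", ct, "'")
    ord <- ok[order(-fc[ok], q[ok], genes[ok])]
    cand[[ct]] <- data.frame(gene = genes[ord], cell_type = ct,
                             qval = q[ord], fold_change = fc[ord])
  }

  type_means <- vapply(types, function(ct)
    colMeans(cpm[atlas$cells$cell_type == ct, , drop = FALSE]),
    numeric(ncol(cpm)))
  rownames(type_means) <- genes

  gmin <- barcode_range[1]; gmax <- barcode_range[2]
  stopifnot(gmin >= 1, gmax >= gmin)
  sweep_tab <- data.frame(n_top = gmin:gmax, kappa = NA_real_)
  best <- NULL
  for (i in seq_len(nrow(sweep_tab))) {
    n_top <- sweep_tab$n_top[i]
    rows <- unique(unlist(lapply(cand, function(d) head(d$gene, n_top))))
    A <- type_means[rows, , drop = FALSE]
    k <- kappa_2norm(A)
    sweep_tab$kappa[i] <- k
    if (is.null(best) || k < best$kappa)
      best <- list(A = A, kappa = k, n_top = n_top)
  }
  if (!is.finite(best$kappa))
    stop("all candidate matrices are singular")
  if (best$kappa > kappa_limit)
    warning(sprintf("no candidate meets kappa <= %g; returning minimum (kappa = %.3g)",
                    kappa_limit, best$kappa))
  prov <- do.call(rbind, lapply(cand, function(d) head(d, best$n_top)))
  prov <- prov[prov$gene %in% rownames(best$A), , drop = FALSE]
  rownames(prov) <- NULL
  members <- if (!is.null(atlas$cells$base_type))
    lapply(split(atlas$cells$base_type, atlas$cells$cell_type), unique)
  out <- basis_matrix(best$A, provenance = prov, members = members,
                      n_top = best$n_top)
  attr(out, "sweep") <- sweep_tab
  out
}

#' Spearman similarity of basis columns with hierarchical ordering
#'
#' @param basis \code{\link{basis_matrix}} with >= 2 columns.
#' @return symmetric correlation matrix (unit diagonal) whose rows/columns
#'   are ordered by complete-linkage clustering of 1 - rho.
#' @export
basis_similarity <- function(basis) {
  stopifnot(inherits(basis, "basis_matrix"))
  if (ncol(basis$A) < 2) stop("need at least 2 basis columns")
  rho <- cor(basis$A, method = "spearman")
  hc <- hclust(stats::as.dist(1 - rho), method = "complete")
  rho[hc$order, hc$order]
}
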