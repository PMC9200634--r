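# Cell-type-specific gene profiles in whole-body context: single-cell DE
# within an atlas, then tissue-specificity filters (Gini >= 0.6, listed
# specific to the native tissue) against a tissue consensus table.

#' Single-cell differential expression for one target cell type
#'
#' Counts are normalized to 10,000 per cell and log(1 + x)-transformed, then
#' each gene is tested target-vs-rest with a Wilcoxon rank-sum test. A gene
#' passes when: BH-adjusted p < \code{alpha}; expression-space fold change
#' >= \code{min_fold_change}; fraction of target cells expressing it >=
#' \code{min_in_frac}; fraction of other cells expressing it <=
#' \code{max_out_frac}; and the ratio of the highest per-other-type percent
#' expressed to the in-group percent expressed < \code{max_out_in_ratio}.
#' Fold change is computed as expm1 of the group means of logged values
#' (with a small pseudo-count), i.e. an expression-space ratio.
#'
#' @param atlas \code{\link{cell_atlas}}.
#' @param target_type cell-type label to profile (>= 3 cells required).
#' @param alpha BH-adjusted p threshold (default 0.01).
#' @param min_fold_change,min_in_frac,max_out_frac,max_out_in_ratio filters
#'   (defaults 1.5, 0.2, 0.5, 0.5).
#' @return data.frame with one row per gene: p, q, fold_change, in_frac,
#'   out_frac, max_other_frac, and logical \code{pass}.
#' @export
single_cell_de <- function(atlas, target_type, alpha = 0.01,
                           min_fold_change = 1.5, min_in_frac = 0.2,
                           max_out_frac = 0.5, max_out_in_ratio = 0.5) {
  stopifnot(inherits(atlas, "cell_atlas"))
  in_g <- atlas$cells$cell_type == target_type
  if (sum(in_g) < 3) stop("cell type '", target_type, "' has fewer than 3 cells")
  m <- as.matrix(atlas$counts)
  expr <- log1p(m / pmax(rowSums(m), 1) * 1e4)   # log CPTT
  p <- .wilcox_by_gene(expr, in_g)
  q <- p.adjust(p, "BH")
  mu_in <- colMeans(expr[in_g, , drop = FALSE])
  mu_out <- colMeans(expr[!in_g, , drop = FALSE])
  fc <- (expm1(mu_in) + 1e-9) / (expm1(mu_out) + 1e-9)
  in_frac <- colMeans(expr[in_g, , drop = FALSE] > 0)
  out_frac <- colMeans(expr[!in_g, , drop = FALSE] > 0)
  other_types <- setdiff(unique(atlas$cells$cell_type), target_type)
  per_other <- vapply(other_types, function(ct)
    colMeans(expr[atlas$cells$cell_type == ct, , drop = FALSE] > 0),
    numeric(ncol(expr)))
  max_other <- if (length(other_types) == 1) per_other else
    apply(per_other, 1, max)
  out <- data.frame(gene = colnames(expr), p = p, q = q, fold_change = fc,
                    in_frac = in_frac, out_frac = out_frac,
                    max_other_frac = max_other, row.names = NULL)
  out$pass <- out$q < alpha & out$fold_change >= min_fold_change &
    out$in_frac >= min_in_frac & out$out_frac <= max_out_frac &
    out$in_frac > 0 & (out$max_other_frac / out$in_frac) < max_out_in_ratio
  out
}

#' Gini coefficient of expression inequality
#'
#' With x sorted ascending over n tissues:
#' Gini = (n + 1)/n - 2 * sum_i (n + 1 - i) x_i / (n * sum_i x_i).
#' 0 for a uniform vector; (n - 1)/n for a one-hot vector.
#'
#' @param x non-negative numeric vector, length >= 2, positive sum.
#' @return real in [0, (n - 1)/n].
#' @export
gini <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (any(x < 0)) stop("negative values")
  s <- sum(x)
  if (s == 0) stop("all-zero vector; Gini undefined")
  x <- sort(x)
  n <- length(x)
  (n + 1) / n - 2 * sum((n + 1 - seq_len(n)) * x) / (n * s)
}

#' Tau tissue-specificity index
#'
#' tau = sum_i (1 - x_i / max(x)) / (n - 1): 0 for a uniform vector, 1 for a
#' one-hot vector.
#'
#' @param x non-negative numeric vector, length >= 2, positive maximum.
#' @return real in [0, 1].
#' @export
tau <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (any(x < 0)) stop("negative values")
  m <- max(x)
  if (m == 0) stop("all-zero vector; Tau undefined")
  sum(1 - x / m) / (length(x) - 1)
}

#' Derive a cell-type-specific gene profile in whole-body context
#'
#' From the DE-passing genes of \code{\link{single_cell_de}}, retains those
#' whose tissue-table expression row has Gini >= \code{gini_min}, whose
#' listed specific tissues include the cell type's native tissue, and whose
#' specificity category is one of "Tissue enriched", "Group enriched",
#' "Tissue enhanced". Genes absent from the tissue table are dropped (their
#' count is reported in attribute \code{"n_missing"}).
#'
#' @param de_stats output of \code{\link{single_cell_de}}.
#' @param tt \code{\link{tissue_table}}.
#' @param cell_type,native_tissue identity of the profile.
#' @param gini_min Gini threshold (default 0.6).
#' @return \code{\link{cell_type_profile}} whose \code{genes} table carries
#'   the DE stats plus per-gene Gini, Tau and category.
#' @export
derive_profile <- function(de_stats, tt, cell_type, native_tissue,
                           gini_min = 0.6) {
  stopifnot(inherits(tt, "tissue_table"))
  de <- de_stats[de_stats$pass, , drop = FALSE]
  n_missing <- sum(!de$gene %in% rownames(tt$nx))
  de <- de[de$gene %in% rownames(tt$nx), , drop = FALSE]
  if (nrow(de) == 0)
    stop("no DE-passing gene found in the tissue table for ", cell_type,
         "; review thresholds")
  de$gini <- apply(tt$nx[de$gene, , drop = FALSE], 1, gini)
  de$tau <- apply(tt$nx[de$gene, , drop = FALSE], 1, tau)
  de$category <- unname(tt$category[de$gene])
  listed <- vapply(de$gene, function(g)
    native_tissue %in% tt$specific_tissues[[g]], logical(1))
  ok <- de$gini >= gini_min & listed &
    de$category %in% c("Tissue enriched", "Group enriched", "Tissue enhanced")
  if (!any(ok))
    stop("profile for ", cell_type,
         " is empty after tissue-specificity filters; review thresholds")
  out <- cell_type_profile(cell_type, native_tissue, de[ok, , drop = FALSE])
  attr(out, "n_missing") <- n_missing
  out
}

#' Native-tissue fold change of a profile's signature score
#'
#' Validation check: in bulk tissue data (log counts-per-ten-thousand + 1
#' scale) the summed expression of a profile's genes should be higher in the
#' native tissue than elsewhere. Returns the native tissue's median score
#' divided by the mean of the per-tissue mean scores across the other
#' tissues.
#'
#' @param profile \code{\link{cell_type_profile}}.
#' @param bulk list with \code{values} (genes x samples, log CPTT scale) and
#'   \code{tissue} (per-sample labels), as from
#'   \code{\link{generate_tissue_bulk}}.
#' @param native_tissue overrides the profile's native tissue if given.
#' @return fold change (> 1 indicates native-tissue specificity).
#' @export
profile_foldchange_check <- function(profile, bulk, native_tissue = NULL) {
  stopifnot(inherits(profile, "cell_type_profile"))
  if (is.null(native_tissue)) native_tissue <- profile$native_tissue
  g <- intersect(profile$genes$gene, rownames(bulk$values))
  if (length(g) == 0) stop("no profile gene present in the bulk table")
  score <- colSums(bulk$values[g, , drop = FALSE])
  native <- bulk$tissue == native_tissue
  if (!any(native)) stop("native tissue absent from bulk table")
  other_means <- tapply(score[!native], bulk$tissue[!native], mean)
  median(score[native]) / mean(other_means)
}

#' Intersect two profiles of the same cell type
#'
#' Used when the same cell type is profiled from two independent atlases:
#' only genes present in both profiles are kept; statistics from both
#' sources are carried with suffixes.
#'
#' @param profile_a,profile_b \code{\link{cell_type_profile}} objects for
#'   the same cell type.
#' @return \code{\link{cell_type_profile}} on the gene intersection.
#' @export
intersect_profiles <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "cell_type_profile"),
            inherits(profile_b, "cell_type_profile"))
  if (profile_a$cell_type != profile_b$cell_type)
    stop("profiles are for different cell types")
  common <- intersect(profile_a$genes$gene, profile_b$genes$gene)
  if (length(common) == 0) stop("profiles share no genes")
  ga <- profile_a$genes[match(common, profile_a$genes$gene), , drop = FALSE]
  gb <- profile_b$genes[match(common, profile_b$genes$gene), , drop = FALSE]
  names(gb) <- paste0(names(gb), "_b")
  cell_type_profile(profile_a$cell_type, profile_a$native_tissue,
                    cbind(ga, gb[setdiff(names(gb), "gene_b")]))
}
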