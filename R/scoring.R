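# Signature scoring and cohort statistics: per-sample signature scores (sum
# of log CPM-TMM counts over a profile), Mann-Whitney cohort comparisons,
# permutation calibration with the "#\{permuted >= observed\} / (n + 1)"
# rule, hypergeometric gene-set overlap, the Gini permutation test on DEG
# specificity, basis-uncaptured tissue accounting and marker-database
# detection.

#' Signature score of a cell-type profile in each sample
#'
#' Sum over the profile's genes of the log-transformed CPM-TMM values.
#' Profile genes missing from the matrix contribute 0 (scores stay
#' comparable across samples with different detected gene sets).
#'
#' @param x \code{cf_norm} at stage \code{log_cpm_tmm}.
#' @param profile \code{\link{cell_type_profile}} or character vector of
#'   genes.
#' @param cell_type label carried into the result (taken from the profile
#'   when available).
#' @return data.frame: sample, cell_type, score, n_genes_scored.
#' @export
signature_score <- function(x, profile, cell_type = NULL) {
  stopifnot(inherits(x, "cf_norm"))
  if (x$stage != "log_cpm_tmm")
    stop("signature scores are computed at stage log_cpm_tmm; got ", x$stage)
  genes <- if (inherits(profile, "cell_type_profile")) profile$genes$gene else profile
  if (is.null(cell_type))
    cell_type <- if (inherits(profile, "cell_type_profile")) profile$cell_type else "gene_set"
  present <- intersect(genes, rownames(x$values))
  if (length(present) == 0) {
    warning("no profile gene present in the matrix; scores are 0")
    score <- rep(0, ncol(x$values))
  } else {
    score <- colSums(x$values[present, , drop = FALSE])
  }
  data.frame(sample = colnames(x$values), cell_type = cell_type,
             score = score, n_genes_scored = length(present),
             row.names = NULL)
}

#' Drop profile genes undetected in either cohort
#'
#' Dropout remedy for shallow cohorts: keeps profile genes with at least one
#' non-zero measurement in each cohort.
#'
#' @param profile \code{\link{cell_type_profile}}.
#' @param cohort_a,cohort_b \code{cf_norm} objects at a common stage.
#' @return filtered \code{cell_type_profile}.
#' @export
dropout_filter <- function(profile, cohort_a, cohort_b) {
  stopifnot(inherits(profile, "cell_type_profile"),
            inherits(cohort_a, "cf_norm"), inherits(cohort_b, "cf_norm"))
  if (cohort_a$stage != cohort_b$stage) stop("cohorts at different stages")
  seen <- function(co, g) {
    p <- intersect(g, rownames(co$values))
    s <- setNames(rep(FALSE, length(g)), g)
    s[p] <- rowSums(co$values[p, , drop = FALSE] > 0) >= 1
    s
  }
  g <- profile$genes$gene
  keep <- seen(cohort_a, g) & seen(cohort_b, g)
  if (!any(keep)) stop("no profile gene detected in both cohorts")
  cell_type_profile(profile$cell_type, profile$native_tissue,
                    profile$genes[keep, , drop = FALSE])
}

#' Mann-Whitney comparison of two cohorts' signature scores
#'
#' Rank-sum U statistic and p-value: exact enumeration for small untied
#' groups (both sizes <= 8), tie-corrected normal approximation otherwise.
#'
#' @param scores_a,scores_b numeric score vectors (>= 3 each).
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}
#'   (of cohort A relative to cohort B).
#' @return list of class \code{cohort_comparison}: U, p, sidedness, group
#'   sizes and the scores.
#' @export
compare_cohorts <- function(scores_a, scores_b,
                            alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(scores_a) < 3 || length(scores_b) < 3)
    stop("each cohort needs at least 3 scores")
  small <- length(scores_a) <= 8 && length(scores_b) <= 8
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0
  wt <- suppressWarnings(
    wilcox.test(scores_a, scores_b, alternative = alternative,
                exact = small && !ties, correct = !(small && !ties)))
  structure(list(U = unname(wt$statistic), p = wt$p.value,
                 sidedness = alternative,
                 n_a = length(scores_a), n_b = length(scores_b),
                 scores_a = scores_a, scores_b = scores_b),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), %s p = %.4g\n",
              x$U, x$n_a, x$n_b, x$sidedness, x$p))
  invisible(x)
}

#' Permutation calibration of a two-group score comparison
#'
#' The observed statistic is the difference in mean scores between the two
#' label groups (first level minus second). Labels are shuffled
#' \code{n_perm} times and the empirical p-value is
#' \code{#\{permuted >= observed\} / (n_perm + 1)}; the +1 counts the
#' unpermuted comparison.
#'
#' @param scores numeric vector.
#' @param labels two-level factor or character vector aligned with
#'   \code{scores}.
#' @param n_perm number of label shuffles (default 10,000).
#' @param seed integer seed.
#' @return list: p_perm, observed statistic, vector of permuted statistics,
#'   n_perm.
#' @export
calibrate_pvalues <- function(scores, labels, n_perm = 10000, seed = 1) {
  stopifnot(n_perm >= 100)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must have exactly 2 levels")
  set.seed(seed)
  stat <- function(lab) mean(scores[lab == lev[1]]) - mean(scores[lab == lev[2]])
  observed <- stat(labels)
  permuted <- vapply(seq_len(n_perm), function(i) stat(sample(labels)),
                     numeric(1))
  list(p_perm = sum(permuted >= observed) / (n_perm + 1),
       observed = observed, permuted = permuted, n_perm = n_perm)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of at least the observed overlap between a DEG set and a
#' profile's genes drawn from a common universe.
#'
#' @param deg_set,profile_genes character vectors (subsets of the universe).
#' @param universe_size size of the gene universe.
#' @return p-value in (0, 1].
#' @export
hypergeom_overlap <- function(deg_set, profile_genes, universe_size) {
  deg_set <- unique(deg_set); profile_genes <- unique(profile_genes)
  if (length(deg_set) > universe_size || length(profile_genes) > universe_size)
    stop("sets exceed the universe")
  k <- length(intersect(deg_set, profile_genes))
  phyper(k - 1, length(profile_genes), universe_size - length(profile_genes),
         length(deg_set), lower.tail = FALSE)
}

#' Gini permutation test of cell-type vs tissue-specific DEGs
#'
#' Compares the mean Gini coefficient (computed per gene across cell types
#' from mean log counts-per-ten-thousand expression) of genes labeled
#' "cell type specific" against genes labeled "tissue specific". Labels are
#' shuffled \code{n_perm} times; p = #\{permuted difference >= observed\} /
#' (n_perm + 1).
#'
#' @param ct_genes,tissue_genes disjoint character vectors; both non-empty.
#' @param mean_expr_by_celltype genes x cell types matrix of mean
#'   log-transformed CPTT expression.
#' @param n_perm number of shuffles (default 10,000).
#' @param seed integer seed.
#' @return list: p, observed mean difference (cell type minus tissue),
#'   per-gene Gini values, permuted differences.
#' @export
gini_permutation_test <- function(ct_genes, tissue_genes,
                                  mean_expr_by_celltype, n_perm = 10000,
                                  seed = 1) {
  if (length(ct_genes) == 0 || length(tissue_genes) == 0)
    stop("both gene groups must be non-empty")
  if (length(intersect(ct_genes, tissue_genes)) > 0)
    stop("cell-type and tissue gene sets must be disjoint")
  genes <- c(ct_genes, tissue_genes)
  miss <- setdiff(genes, rownames(mean_expr_by_celltype))
  if (length(miss) > 0) stop("genes missing from expression matrix: ",
                             paste(head(miss, 3), collapse = ", "))
  g <- apply(mean_expr_by_celltype[genes, , drop = FALSE], 1, gini)
  is_ct <- c(rep(TRUE, length(ct_genes)), rep(FALSE, length(tissue_genes)))
  observed <- mean(g[is_ct]) - mean(g[!is_ct])
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(i) {
    s <- sample(is_ct)
    mean(g[s]) - mean(g[!s])
  }, numeric(1))
  list(p = sum(permuted >= observed) / (n_perm + 1), observed = observed,
       gini = g, permuted = permuted)
}

#' Derive the "tissue specific" gene set for the Gini permutation test
#'
#' T = ((B intersect U) union (B intersect D)) minus C: tissue-specific
#' genes that are differentially expressed in the disease but not claimed by
#' any cell-type profile.
#'
#' @param B initial tissue-specific gene set.
#' @param C_set union of cell-type-specific genes (must be a subset of B).
#' @param U_set,D_set up- and down-regulated DEG sets.
#' @return character vector T (disjoint from C).
#' @export
tissue_specific_set <- function(B, C_set, U_set, D_set = character()) {
  if (length(setdiff(C_set, B)) > 0)
    stop("cell-type-specific genes must be a subset of the tissue-specific set")
  setdiff(union(intersect(B, U_set), intersect(B, D_set)), C_set)
}

#' Tally tissue-specific cfRNA genes not captured by the basis matrix
#'
#' For each sample, the genes measured at >= 1 CPM minus the basis row space,
#' intersected with the tissue table's specific genes (categories Tissue
#' enriched / Group enriched / Tissue enhanced with NX >= \code{nx_min} in
#' their specific tissue), tallied per tissue.
#'
#' @param x \code{cf_norm} at stage \code{cpm_ml} (or any linear CPM matrix
#'   wrapped in \code{cf_norm}).
#' @param basis \code{\link{basis_matrix}}.
#' @param tt \code{\link{tissue_table}}.
#' @param nx_min minimum NX in the gene's specific tissue (default 10).
#' @return list with \code{counts} (tissues x samples matrix), \code{mean}
#'   and \code{sd} per tissue across samples.
#' @export
uncaptured_tissue_genes <- function(x, basis, tt, nx_min = 10) {
  stopifnot(inherits(x, "cf_norm"), inherits(basis, "basis_matrix"),
            inherits(tt, "tissue_table"))
  specific <- names(tt$category)[
    tt$category %in% c("Tissue enriched", "Group enriched", "Tissue enhanced")]
  specific <- specific[vapply(specific, function(g) {
    ts <- tt$specific_tissues[[g]]
    length(ts) > 0 && max(tt$nx[g, ts]) >= nx_min
  }, logical(1))]
  tissues <- colnames(tt$nx)
  counts <- vapply(colnames(x$values), function(s) {
    G <- rownames(x$values)[x$values[, s] >= 1]
    hits <- intersect(setdiff(G, rownames(basis$A)), specific)
    tab <- setNames(rep(0L, length(tissues)), tissues)
    for (g in hits) for (ts in tt$specific_tissues[[g]])
      tab[ts] <- tab[ts] + 1L
    tab
  }, integer(length(tissues)))
  counts <- matrix(counts, nrow = length(tissues),
                   dimnames = list(tissues, colnames(x$values)))
  list(counts = counts, mean = rowMeans(counts),
       sd = apply(counts, 1, sd))
}

#' Count detected cell-type markers from a marker database
#'
#' The database is filtered to human entries with sensitivity >=
#' \code{sens_min} and specificity <= \code{spec_max}; a marker counts as
#' detected in a sample when its logged CPM-TMM expression is greater than
#' zero. Cell types are flagged \code{shown} when their mean detected-marker
#' count across samples exceeds \code{mean_min}.
#'
#' @param x \code{cf_norm} at stage \code{log_cpm_tmm}.
#' @param marker_db data.frame with columns cell_type, gene, sensitivity,
#'   specificity and optionally species.
#' @param sens_min,spec_max,mean_min filter parameters (defaults 0.9, 0.2, 5).
#' @return list with \code{counts} (cell types x samples detected-marker
#'   counts) and \code{summary} (data.frame cell_type, mean_detected, shown).
#' @export
detect_markers <- function(x, marker_db, sens_min = 0.9, spec_max = 0.2,
                           mean_min = 5) {
  stopifnot(inherits(x, "cf_norm"))
  if (x$stage != "log_cpm_tmm")
    stop("marker detection uses stage log_cpm_tmm; got ", x$stage)
  db <- marker_db
  if (!is.null(db$species)) db <- db[db$species == "Hs", , drop = FALSE]
  db <- db[db$sensitivity >= sens_min & db$specificity <= spec_max, , drop = FALSE]
  if (nrow(db) == 0) stop("no marker passes the sensitivity/specificity filter")
  types <- sort(unique(db$cell_type))
  counts <- vapply(colnames(x$values), function(s) {
    expressed <- rownames(x$values)[x$values[, s] > 0]
    vapply(types, function(ct)
      length(intersect(db$gene[db$cell_type == ct], expressed)), integer(1))
  }, integer(length(types)))
  counts <- matrix(counts, nrow = length(types),
                   dimnames = list(types, colnames(x$values)))
  mean_det <- rowMeans(counts)
  list(counts = counts,
       summary = data.frame(cell_type = types, mean_detected = mean_det,
                            shown = mean_det > mean_min, row.names = NULL))
}
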