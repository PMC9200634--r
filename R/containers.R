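#' Gene count matrix with per-sample plasma metadata
#'
#' Container for a genes-by-samples count matrix together with the per-sample
#' metadata the normalization stages need: plasma volume (mL), sequencing
#' batch and biological-replicate grouping.
#'
#' @param counts numeric matrix, genes in rows, samples in columns; must have
#'   row and column names. Non-negative; each column must have positive sum.
#' @param meta data.frame with one row per sample and columns \code{sample},
#'   \code{plasma_ml}, \code{batch}, \code{bio_replicate}. Missing columns are
#'   filled with defaults; a missing \code{plasma_ml} defaults to 1 mL with a
#'   warning, matching the convention used when volumes are unknown.
#' @return object of class \code{cf_counts}.
#' @export
cf_counts <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(meta)) meta <- data.frame(sample = colnames(counts))
  if (!"sample" %in% names(meta)) meta$sample <- colnames(counts)
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("meta is missing rows for some samples")
  if (is.null(meta$plasma_ml) || all(is.na(meta$plasma_ml))) {
    warning("plasma_ml not provided; assuming 1 mL per sample")
    meta$plasma_ml <- 1
  }
  if (anyNA(meta$plasma_ml)) {
    warning("missing plasma_ml for some samples; assuming 1 mL")
    meta$plasma_ml[is.na(meta$plasma_ml)] <- 1
  }
  if (any(meta$plasma_ml <= 0)) stop("plasma_ml must be positive")
  if (is.null(meta$batch)) meta$batch <- "batch1"
  if (is.null(meta$bio_replicate)) meta$bio_replicate <- meta$sample
  rownames(meta) <- meta$sample
  structure(list(counts = counts, meta = meta), class = "cf_counts")
}

#' @export
print.cf_counts <- function(x, ...) {
  cat(sprintf("cfRNA counts: %d genes x %d samples (%d batches, %d biological replicates)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$batch)), length(unique(x$meta$bio_replicate))))
  invisible(x)
}

#' Normalized cfRNA expression matrix
#'
#' Internal constructor for a normalized matrix tagged with its stage:
#' \code{cpm_ml} (counts per million per mL plasma), \code{cpm_ml_tmm}
#' (after TMM division) or \code{log_cpm_tmm} (log(1 + x) of the former).
#'
#' @param values numeric matrix genes x samples.
#' @param stage one of \code{"cpm_ml"}, \code{"cpm_ml_tmm"}, \code{"log_cpm_tmm"}.
#' @param meta per-sample metadata data.frame.
#' @param tmm per-sample TMM factors, when applicable.
#' @return object of class \code{cf_norm}.
#' @keywords internal
new_cf_norm <- function(values, stage, meta, tmm = NULL) {
  stage <- match.arg(stage, c("cpm_ml", "cpm_ml_tmm", "log_cpm_tmm"))
  structure(list(values = values, stage = stage, meta = meta, tmm_factors = tmm),
            class = "cf_norm")
}

#' @export
print.cf_norm <- function(x, ...) {
  cat(sprintf("normalized cfRNA matrix: %d genes x %d samples, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Labeled single-cell atlas
#'
#' Sparse cells-by-genes count matrix with per-cell annotations (cell type,
#' compartment, tissue, assay). The deconvolution basis matrix is built from
#' such an atlas.
#'
#' @param counts cells x genes matrix (coerced to \code{dgCMatrix});
#'   non-negative.
#' @param cells data.frame with columns \code{cell_id}, \code{cell_type},
#'   \code{compartment}, \code{tissue} and optionally \code{assay}.
#' @param markers optional named list, cell type -> planted marker gene ids
#'   (carried by the synthetic generator; ground-truth bookkeeping only).
#' @param tissue_of_type optional named character, cell type -> native tissue.
#' @return object of class \code{cell_atlas}.
#' @export
cell_atlas <- function(counts, cells, markers = NULL, tissue_of_type = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(counts) == nrow(cells))
  req <- c("cell_id", "cell_type", "compartment", "tissue")
  if (!all(req %in% names(cells)))
    stop("cells must have columns: ", paste(req, collapse = ", "))
  if (is.null(cells$assay)) cells$assay <- "10x"
  if (any(!nzchar(cells$cell_type))) stop("empty cell type labels")
  rownames(counts) <- cells$cell_id
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%05d", seq_len(ncol(counts)))
  structure(list(counts = counts, cells = cells, markers = markers,
                 tissue_of_type = tissue_of_type),
            class = "cell_atlas")
}

#' @export
print.cell_atlas <- function(x, ...) {
  cat(sprintf("cell atlas: %d cells x %d genes; %d cell types, %d compartments, %d tissues\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$cell_type)),
              length(unique(x$cells$compartment)),
              length(unique(x$cells$tissue))))
  invisible(x)
}

#' Cell-type basis matrix
#'
#' The genes-by-cell-types reference expression matrix A (CPM scale) used for
#' deconvolution, with selection provenance and its 2-norm condition number.
#'
#' @param A numeric matrix, selected barcode genes x grouped cell types.
#' @param provenance data.frame of per-gene selection statistics (gene,
#'   cell_type, qval, fold_change).
#' @param members named list: grouped column label -> original labels.
#' @param n_top per-type barcode-gene count the selected matrix used.
#' @return object of class \code{basis_matrix}. Element \code{kappa} holds the
#'   2-norm condition number.
#' @export
basis_matrix <- function(A, provenance = NULL, members = NULL, n_top = NA_integer_) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("basis entries must be non-negative")
  if (anyDuplicated(colnames(A))) stop("basis column labels must be unique")
  k <- kappa_2norm(A)
  if (!is.finite(k)) stop("basis condition number is not finite")
  structure(list(A = A, provenance = provenance, members = members,
                 n_top = n_top, kappa = k),
            class = "basis_matrix")
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat(sprintf("basis matrix: %d barcode genes x %d cell types, kappa = %.3g\n",
              nrow(x$A), ncol(x$A), x$kappa))
  invisible(x)
}

#' 2-norm condition number
#'
#' Ratio of the largest to smallest singular value of a matrix.
#'
#' @param A numeric matrix.
#' @return non-negative real; \code{Inf} when the smallest singular value is 0.
#' @export
kappa_2norm <- function(A) {
  d <- svd(A, nu = 0, nv = 0)$d
  if (min(d) == 0) return(Inf)
  max(d) / min(d)
}

#' Cell-type-specific gene profile
#'
#' Genes asserted specific to one cell type in whole-body context, with the
#' per-gene statistics that justified each: single-cell DE stats, Gini / Tau
#' across tissues and the tissue-table specificity category.
#'
#' @param cell_type character scalar.
#' @param native_tissue tissue the cell type is unique to.
#' @param genes data.frame with one row per retained gene (column \code{gene}
#'   plus statistics).
#' @return object of class \code{cell_type_profile}.
#' @export
cell_type_profile <- function(cell_type, native_tissue, genes) {
  if (nrow(genes) == 0) stop("profile for ", cell_type, " is empty")
  structure(list(cell_type = cell_type, native_tissue = native_tissue,
                 genes = genes), class = "cell_type_profile")
}

#' @export
print.cell_type_profile <- function(x, ...) {
  cat(sprintf("cell-type profile '%s' (native tissue %s): %d genes\n",
              x$cell_type, x$native_tissue, nrow(x$genes)))
  invisible(x)
}

#' Tissue consensus expression table
#'
#' Genes-by-tissues matrix of NX-like consensus expression values with
#' per-gene specificity category and listed specific tissues, emulating the
#' Human Protein Atlas consensus table.
#'
#' @param nx numeric genes x tissues matrix, non-negative, named dimensions.
#' @param category named character: gene -> one of "Tissue enriched",
#'   "Group enriched", "Tissue enhanced", "Low tissue specificity".
#' @param specific_tissues named list: gene -> character vector of the
#'   tissue(s) the gene is listed as specific to (empty for low specificity).
#' @return object of class \code{tissue_table}.
#' @export
tissue_table <- function(nx, category, specific_tissues) {
  nx <- as.matrix(nx)
  if (ncol(nx) < 2) stop("need at least 2 tissues")
  if (any(nx < 0)) stop("NX values must be non-negative")
  stopifnot(all(rownames(nx) %in% names(category)),
            all(rownames(nx) %in% names(specific_tissues)))
  structure(list(nx = nx, category = category[rownames(nx)],
                 specific_tissues = specific_tissues[rownames(nx)]),
            class = "tissue_table")
}

#' @export
print.tissue_table <- function(x, ...) {
  cat(sprintf("tissue expression table: %d genes x %d tissues\n",
              nrow(x$nx), ncol(x$nx)))
  invisible(x)
}
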