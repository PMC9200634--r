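# Plain-text readers/writers for the pipeline's interchange formats:
# MatrixMarket + TSV for atlases, TSV for counts/metadata, basis matrices,
# exon tables, tissue tables and marker databases.

#' Write / read a cell atlas as MTX + TSV
#'
#' Writes \code{matrix.mtx} (cells x genes, MatrixMarket), \code{cells.tsv}
#' (cell_id, cell_type, compartment, tissue, assay) and \code{genes.tsv}
#' into a directory.
#'
#' @param atlas \code{\link{cell_atlas}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "cell_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(atlas$counts, file.path(dir, "matrix.mtx"))
  write.table(atlas$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = colnames(atlas$counts)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cells <- read.delim(file.path(dir, "cells.tsv"))
  genes <- read.delim(file.path(dir, "genes.tsv"))
  colnames(counts) <- genes$gene
  cell_atlas(counts, cells)
}

#' Write / read a basis matrix as TSV
#'
#' First column \code{gene}, remaining columns the grouped cell-type names.
#'
#' @param basis \code{\link{basis_matrix}}.
#' @param path output file.
#' @return \code{path} invisibly / a \code{basis_matrix}.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "basis_matrix"))
  df <- data.frame(gene = rownames(basis$A), basis$A, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df$gene
  basis_matrix(A)
}

#' Write / read a gene count matrix with sample metadata as TSV
#'
#' \code{counts.tsv} holds genes x samples (first column \code{gene});
#' \code{meta.tsv} holds sample, plasma_ml, batch, bio_replicate.
#'
#' @param x \code{\link{cf_counts}}.
#' @param dir output directory.
#' @return \code{dir} invisibly / a \code{cf_counts}.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "cf_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(gene = rownames(x$counts), x$counts,
                         check.names = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  df <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  cf_counts(m, read.delim(file.path(dir, "meta.tsv")))
}

#' Read an htseq-style exon count table
#'
#' TSV with columns gene, exon, count.
#'
#' @param path input file.
#' @return data.frame suitable for \code{\link{three_prime_bias}}.
#' @export
read_exon_table <- function(path) {
  df <- read.delim(path)
  stopifnot(all(c("gene", "exon", "count") %in% names(df)))
  df
}

#' Write / read a tissue expression table as long-format TSV
#'
#' Columns: gene, tissue, nx, category, specific_tissues (comma-joined).
#'
#' @param tt \code{\link{tissue_table}}.
#' @param path output file.
#' @return \code{path} invisibly / a \code{tissue_table}.
#' @export
write_tissue_table <- function(tt, path) {
  stopifnot(inherits(tt, "tissue_table"))
  long <- data.frame(
    gene = rep(rownames(tt$nx), ncol(tt$nx)),
    tissue = rep(colnames(tt$nx), each = nrow(tt$nx)),
    nx = as.numeric(tt$nx))
  long$category <- tt$category[long$gene]
  long$specific_tissues <- vapply(tt$specific_tissues[long$gene],
                                  paste, character(1), collapse = ",")
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tissue_table
#' @export
read_tissue_table <- function(path) {
  long <- read.delim(path)
  genes <- unique(long$gene); tissues <- unique(long$tissue)
  nx <- matrix(0, length(genes), length(tissues),
               dimnames = list(genes, tissues))
  nx[cbind(match(long$gene, genes), match(long$tissue, tissues))] <- long$nx
  first <- long[!duplicated(long$gene), ]
  category <- setNames(first$category, first$gene)
  specific <- setNames(lapply(strsplit(as.character(first$specific_tissues), ","),
                              function(v) v[nzchar(v)]), first$gene)
  tissue_table(nx, category, specific)
}
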