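# Per-sample quality filtering of cfRNA count data.
#
# Three metrics, each a degradation / contamination proxy computed from
# derived count tables (not alignments): the 3' bias fraction, the ribosomal
# read fraction and the intron-to-exon read ratio. A sample is excluded when
# ANY metric is strictly greater than its threshold.

#' QC thresholds for cfRNA samples
#'
#' A sample is low quality when 3' bias fraction > 0.4, ribosomal read
#' fraction > 0.2 or intron-to-exon ratio > 3. Comparisons are strict: a
#' value exactly at a threshold is retained.
#' @export
qc_thresholds <- function() {
  c(three_prime_bias = 0.4, ribosomal_fraction = 0.2, intron_exon_ratio = 3)
}

#' 3' bias fraction (RNA degradation proxy)
#'
#' Fraction of detected genes whose reads all fall on their 3'-most exon
#' (the highest exon number present for that gene). Genes with zero total
#' reads are not detected. Duplicated (gene, exon) rows are summed first.
#'
#' @param exon_table data.frame with columns \code{gene}, \code{exon}
#'   (positive integer exon number) and \code{count} (non-negative integer).
#' @return real in [0, 1].
#' @export
three_prime_bias <- function(exon_table) {
  stopifnot(all(c("gene", "exon", "count") %in% names(exon_table)))
  if (any(exon_table$count < 0)) stop("negative read counts")
  # collapse duplicated exon rows before the all-on-last-exon test
  key <- paste(exon_table$gene, exon_table$exon, sep = "\r")
  cnt <- tapply(exon_table$count, key, sum)
  gene <- sub("\r.*$", "", names(cnt))
  exon <- as.integer(sub("^.*\r", "", names(cnt)))
  total <- tapply(cnt, gene, sum)
  detected <- names(total)[total > 0]
  if (length(detected) == 0) stop("no detected genes; 3' bias undefined")
  last_exon <- tapply(exon, gene, max)
  on_last <- tapply(cnt * (exon == last_exon[gene]), gene, sum)
  all_on_last <- detected[on_last[detected] == total[detected]]
  length(all_on_last) / length(detected)
}

#' Ribosomal read fraction
#'
#' @param summary list or data.frame row with fields \code{ribosomal_reads}
#'   and \code{total_reads}.
#' @return ribosomal_reads / total_reads.
#' @export
ribosomal_fraction <- function(summary) {
  if (summary$total_reads <= 0) stop("total_reads is 0; ribosomal fraction undefined")
  if (summary$ribosomal_reads > summary$total_reads)
    stop("ribosomal_reads exceeds total_reads")
  summary$ribosomal_reads / summary$total_reads
}

#' Intron-to-exon read ratio (DNA contamination proxy)
#'
#' @param summary list or data.frame row with fields \code{intronic_reads}
#'   and \code{exonic_reads}.
#' @return intronic_reads / exonic_reads.
#' @export
intron_exon_ratio <- function(summary) {
  if (summary$exonic_reads <= 0) stop("exonic_reads is 0; intron/exon ratio undefined")
  summary$intronic_reads / summary$exonic_reads
}

#' Compute all three QC metrics for one sample
#'
#' @param exon_table see \code{\link{three_prime_bias}}.
#' @param read_summary see \code{\link{ribosomal_fraction}} and
#'   \code{\link{intron_exon_ratio}}.
#' @param sample sample identifier carried into the result.
#' @return one-row data.frame with the three metrics and logical \code{pass}.
#' @export
qc_metrics <- function(exon_table, read_summary, sample = "sample") {
  m <- data.frame(
    sample = sample,
    three_prime_bias = three_prime_bias(exon_table),
    ribosomal_fraction = ribosomal_fraction(read_summary),
    intron_exon_ratio = intron_exon_ratio(read_summary)
  )
  th <- qc_thresholds()
  m$pass <- m$three_prime_bias <= th["three_prime_bias"] &
    m$ribosomal_fraction <= th["ribosomal_fraction"] &
    m$intron_exon_ratio <= th["intron_exon_ratio"]
  m
}

#' Partition samples into retained and excluded by QC
#'
#' A sample is excluded when any metric is strictly greater than its
#' threshold; every violated metric is listed as a reason.
#'
#' @param metrics data.frame with columns \code{sample},
#'   \code{three_prime_bias}, \code{ribosomal_fraction},
#'   \code{intron_exon_ratio} (one row per sample), e.g. rbind-ed output of
#'   \code{\link{qc_metrics}}.
#' @return list with \code{retained} (character), \code{excluded} (character)
#'   and \code{reasons} (named list sample -> violated metric names).
#' @export
filter_samples <- function(metrics) {
  th <- qc_thresholds()
  reasons <- lapply(seq_len(nrow(metrics)), function(i) {
    v <- unlist(metrics[i, names(th)])
    names(th)[v > th]
  })
  names(reasons) <- metrics$sample
  bad <- lengths(reasons) > 0
  list(retained = metrics$sample[!bad],
       excluded = metrics$sample[bad],
       reasons = reasons[bad])
}
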