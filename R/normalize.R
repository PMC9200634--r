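# Normalization of cfRNA counts: counts per million per mL plasma, TMM
# between-sample scaling, technical-replicate averaging, log transform.
#
# Stages are tagged so downstream code can refuse inputs at the wrong stage
# (deconvolution wants linear cpm_ml; signature scoring wants log_cpm_tmm).

#' Counts per million per milliliter of plasma
#'
#' eta_ij = 1e6 * Gene_ij / (LibrarySize_j * plasma_ml_j), where the library
#' size is the column sum. Column j of the result sums to 1e6 / plasma_ml_j.
#'
#' @param x \code{\link{cf_counts}} object.
#' @return \code{cf_norm} object at stage \code{cpm_ml}.
#' @export
cpm_per_ml <- function(x) {
  stopifnot(inherits(x, "cf_counts"))
  lib <- colSums(x$counts)
  if (any(lib <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(x$counts)[lib <= 0], collapse = ", "))
  eta <- sweep(x$counts, 2, lib * x$meta$plasma_ml, "/") * 1e6
  new_cf_norm(eta, "cpm_ml", x$meta)
}

# Robinson-Oshlack TMM factor of one sample against the reference column.
# M = log2 ratio, A = average log abundance; genes with a zero in either
# sample drop out (non-finite M/A); double trim 30% on M and 5% on A by rank;
# weighted mean of retained M with inverse asymptotic (delta-method) variance
# weights; factor = 2^f.
.tmm_one <- function(obs, ref) {
  nO <- sum(obs); nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0) {
    warning("sample shares no expressed genes with the reference; factor 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * 0.30) + 1; hiL <- n + 1 - loL
  loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  2^f
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample scaling factors computed on the CPM-per-mL matrix by the
#' trimmed-mean-of-M-values procedure: per gene, M is the log2 expression
#' ratio against a reference sample and A the average log abundance; genes
#' absent from either sample are dropped; M is trimmed 30% two-sided and A 5%
#' two-sided; the factor is 2 to the precision-weighted mean of the retained
#' M values. Factors are mean-centered in log space so they multiply to 1.
#' The default reference is the sample whose upper-quartile expression ratio
#' is closest to the mean across samples.
#'
#' @param cpm \code{cf_norm} at stage \code{cpm_ml}.
#' @param reference optional sample id to use as reference.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(cpm, reference = NULL) {
  stopifnot(inherits(cpm, "cf_norm"))
  if (cpm$stage != "cpm_ml") stop("TMM factors are computed at stage cpm_ml")
  x <- cpm$values
  if (ncol(x) < 2) stop("need at least 2 samples")
  lib <- colSums(x)
  if (is.null(reference)) {
    f75 <- apply(x, 2, quantile, p = 0.75) / lib
    ref_j <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_j <- match(reference, colnames(x))
    if (is.na(ref_j)) stop("reference sample not found: ", reference)
  }
  f <- vapply(seq_len(ncol(x)), function(j) .tmm_one(x[, j], x[, ref_j]),
              numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}

#' Divide each sample by its TMM factor
#'
#' @param cpm \code{cf_norm} at stage \code{cpm_ml}.
#' @param factors per-sample positive factors, as from
#'   \code{\link{tmm_factors}}; matched by name when named.
#' @return \code{cf_norm} at stage \code{cpm_ml_tmm}.
#' @export
apply_tmm <- function(cpm, factors) {
  stopifnot(inherits(cpm, "cf_norm"), cpm$stage == "cpm_ml")
  if (!is.null(names(factors))) factors <- factors[colnames(cpm$values)]
  if (anyNA(factors) || any(factors <= 0)) stop("factors must be positive, one per sample")
  new_cf_norm(sweep(cpm$values, 2, factors, "/"), "cpm_ml_tmm", cpm$meta,
              tmm = factors)
}

#' Average technical replicates within biological replicates
#'
#' Arithmetic mean on the current stage's (linear) scale, one output column
#' per biological-replicate group. For deconvolution inputs this is applied
#' at stage \code{cpm_ml}; for scoring it is applied at \code{cpm_ml_tmm},
#' before the log transform.
#'
#' @param x \code{cf_norm} at a linear stage.
#' @return \code{cf_norm} with one column per biological replicate.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "cf_norm"))
  if (x$stage == "log_cpm_tmm")
    stop("replicates are averaged on the linear scale, before the log transform")
  grp <- as.character(x$meta$bio_replicate)
  if (anyNA(grp) || any(!nzchar(grp))) stop("empty biological-replicate group")
  ugrp <- unique(grp)
  vals <- vapply(ugrp, function(g)
    rowMeans(x$values[, grp == g, drop = FALSE]), numeric(nrow(x$values)))
  colnames(vals) <- ugrp
  meta <- x$meta[!duplicated(grp), , drop = FALSE]
  meta$sample <- ugrp
  rownames(meta) <- ugrp
  tmm <- if (!is.null(x$tmm_factors)) {
    vapply(ugrp, function(g) mean(x$tmm_factors[grp == g]), numeric(1))
  }
  new_cf_norm(vals, x$stage, meta, tmm = tmm)
}

#' log(1 + x) transform of CPM-TMM values
#'
#' @param x \code{cf_norm} at stage \code{cpm_ml_tmm}.
#' @return \code{cf_norm} at stage \code{log_cpm_tmm}.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "cf_norm"))
  if (x$stage != "cpm_ml_tmm")
    stop("log transform is applied at stage cpm_ml_tmm only")
  new_cf_norm(log1p(x$values), "log_cpm_tmm", x$meta, tmm = x$tmm_factors)
}

#' One-call normalization pipeline
#'
#' Convenience wrapper running CPM-per-mL, then (optionally) TMM, replicate
#' averaging and the log transform, to the requested stage. For
#' deconvolution use \code{stage = "cpm_ml"} (replicates averaged, no TMM, no
#' log); for signature scoring use \code{stage = "log_cpm_tmm"}.
#'
#' @param x \code{\link{cf_counts}}.
#' @param stage target stage.
#' @param average average technical replicates (default TRUE).
#' @return \code{cf_norm}.
#' @export
normalize_cfrna <- function(x, stage = c("cpm_ml", "cpm_ml_tmm", "log_cpm_tmm"),
                            average = TRUE) {
  stage <- match.arg(stage)
  out <- cpm_per_ml(x)
  if (stage == "cpm_ml") {
    if (average) out <- average_replicates(out)
    return(out)
  }
  out <- apply_tmm(out, tmm_factors(out))
  if (average) out <- average_replicates(out)
  if (stage == "log_cpm_tmm") out <- log_transform(out)
  out
}
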