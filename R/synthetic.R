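# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth, so all stages are testable without downloads. All generators
# are pure functions of their seed.
#
# Atlas counts are negative binomial (the overdispersion typical of
# droplet scRNA-seq); marker structure is planted as disjoint per-type gene
# sets whose mean is marker_fold_change times the gene's baseline in the
# owning type only.

#' Specification of a synthetic single-cell atlas
#'
#' @param n_cell_types,n_genes,cells_per_type,markers_per_type positive
#'   integers; \code{markers_per_type * n_cell_types} must not exceed
#'   \code{n_genes}.
#' @param marker_fold_change mean multiplier of a marker in its own type
#'   (> 1; exactly 1 gives a null atlas with no marker structure).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); > 0.
#' @param base_mean baseline mean expression per gene per cell (> 0).
#' @param gene_mean_sdlog log-normal spread of per-gene baselines around
#'   \code{base_mean} (0 = identical baselines).
#' @param compartment_of_type,tissue_of_type optional named character maps,
#'   cell type -> compartment / native tissue. Defaults: types alternate
#'   between the epithelial and stromal compartments, and each type is native
#'   to its own tissue (so every type is unique to one tissue).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return list of class \code{atlas_spec}.
#' @export
atlas_spec <- function(n_cell_types = 10, n_genes = 500, cells_per_type = 40,
                       markers_per_type = 20, marker_fold_change = 8,
                       nb_dispersion = 0.4, base_mean = 2,
                       gene_mean_sdlog = 0.25,
                       compartment_of_type = NULL, tissue_of_type = NULL,
                       seed = 1) {
  stopifnot(n_cell_types >= 1, n_genes >= 1, cells_per_type >= 1,
            markers_per_type >= 0, marker_fold_change >= 1,
            nb_dispersion > 0, base_mean > 0, gene_mean_sdlog >= 0)
  if (markers_per_type * n_cell_types > n_genes)
    stop("infeasible spec: markers_per_type * n_cell_types > n_genes")
  types <- sprintf("CT%02d", seq_len(n_cell_types))
  if (is.null(compartment_of_type))
    compartment_of_type <- setNames(
      rep(c("epithelial", "stromal"), length.out = n_cell_types), types)
  if (is.null(tissue_of_type))
    tissue_of_type <- setNames(sprintf("tissue%02d", seq_len(n_cell_types)), types)
  stopifnot(all(types %in% names(compartment_of_type)),
            all(types %in% names(tissue_of_type)))
  structure(list(n_cell_types = n_cell_types, n_genes = n_genes,
                 cells_per_type = cells_per_type,
                 markers_per_type = markers_per_type,
                 marker_fold_change = marker_fold_change,
                 nb_dispersion = nb_dispersion, base_mean = base_mean,
                 gene_mean_sdlog = gene_mean_sdlog,
                 types = types,
                 compartment_of_type = compartment_of_type[types],
                 tissue_of_type = tissue_of_type[types], seed = seed),
            class = "atlas_spec")
}

#' Generate a labeled synthetic single-cell atlas
#'
#' Draws negative-binomial counts for \code{cells_per_type} cells per type.
#' Marker sets of distinct types are disjoint; a marker's mean is
#' \code{marker_fold_change} times its baseline in the owning type.
#'
#' @param spec \code{\link{atlas_spec}}.
#' @return \code{\link{cell_atlas}} carrying the planted marker map in
#'   \code{$markers} and the type-to-tissue map in \code{$tissue_of_type}.
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  base <- spec$base_mean *
    exp(rnorm(spec$n_genes, -spec$gene_mean_sdlog^2 / 2, spec$gene_mean_sdlog))
  names(base) <- genes
  markers <- split(genes[seq_len(spec$markers_per_type * spec$n_cell_types)],
                   rep(spec$types, each = spec$markers_per_type))
  markers <- markers[spec$types]
  n_cells <- spec$cells_per_type * spec$n_cell_types
  type_of_cell <- rep(spec$types, each = spec$cells_per_type)
  size <- 1 / spec$nb_dispersion
  counts <- matrix(0L, n_cells, spec$n_genes, dimnames = list(NULL, genes))
  for (k in seq_along(spec$types)) {
    mu <- base
    mu[markers[[k]]] <- mu[markers[[k]]] * spec$marker_fold_change
    idx <- which(type_of_cell == spec$types[k])
    counts[idx, ] <- matrix(
      rnbinom(length(idx) * spec$n_genes, mu = rep(mu, each = length(idx)),
              size = size),
      length(idx), spec$n_genes)
  }
  cells <- data.frame(
    cell_id = sprintf("cell%05d", seq_len(n_cells)),
    cell_type = type_of_cell,
    compartment = unname(spec$compartment_of_type[type_of_cell]),
    tissue = unname(spec$tissue_of_type[type_of_cell]),
    assay = "10x")
  cell_atlas(counts, cells, markers = markers,
             tissue_of_type = spec$tissue_of_type)
}

#' Ground truth for one synthetic cfRNA mixture
#'
#' @param theta_true non-negative vector summing to 1 (within 1e-9), one
#'   entry per basis cell type.
#' @param depth expected total counts of the mixture.
#' @param noise_model one of \code{"none"}, \code{"poisson"},
#'   \code{"lognormal"} (multiplicative log-normal noise per gene).
#' @param noise_scale standard deviation of the log-normal noise (ignored by
#'   the other models).
#' @return list of class \code{mixture_truth}.
#' @export
mixture_truth <- function(theta_true, depth = 1e6,
                          noise_model = c("none", "poisson", "lognormal"),
                          noise_scale = 0) {
  noise_model <- match.arg(noise_model)
  if (any(theta_true < 0)) stop("theta_true entries must be non-negative")
  if (abs(sum(theta_true) - 1) > 1e-9) stop("theta_true must sum to 1 (within 1e-9)")
  stopifnot(depth > 0, noise_scale >= 0)
  structure(list(theta_true = theta_true, depth = depth,
                 noise_model = noise_model, noise_scale = noise_scale),
            class = "mixture_truth")
}

#' Generate a synthetic cfRNA mixture from a basis matrix
#'
#' Expected counts are proportional to \code{A \%*\% theta_true}, scaled to
#' the requested depth; noise is applied per the truth's noise model.
#'
#' @param basis \code{\link{basis_matrix}}.
#' @param truth \code{\link{mixture_truth}}; \code{length(theta_true)} must
#'   equal \code{ncol(basis$A)}.
#' @param plasma_ml plasma volume recorded for the sample.
#' @param seed integer seed.
#' @param sample sample id.
#' @return \code{\link{cf_counts}} with one column; the truth is attached as
#'   attribute \code{"truth"}.
#' @export
generate_mixture <- function(basis, truth, plasma_ml = 1, seed = 1,
                             sample = "mix1") {
  stopifnot(inherits(basis, "basis_matrix"), inherits(truth, "mixture_truth"))
  if (length(truth$theta_true) != ncol(basis$A))
    stop("theta_true length must match basis columns")
  set.seed(seed)
  expected <- as.numeric(basis$A %*% truth$theta_true)
  expected <- expected / sum(expected) * truth$depth
  b <- switch(truth$noise_model,
    none = expected,
    poisson = rpois(length(expected), expected),
    lognormal = expected * rlnorm(length(expected),
                                  -truth$noise_scale^2 / 2, truth$noise_scale))
  m <- matrix(b, ncol = 1, dimnames = list(rownames(basis$A), sample))
  out <- cf_counts(m, data.frame(sample = sample, plasma_ml = plasma_ml,
                                 batch = "sim", bio_replicate = sample))
  attr(out, "truth") <- truth
  out
}

#' Generate an exon count table and read-category summary with planted QC
#'
#' Exactly \code{round(frac_three_prime_only * n_genes)} genes have all
#' their reads on their highest-numbered exon; the read-category summary
#' carries ribosomal and intronic counts matching the requested fractions
#' within integer rounding.
#'
#' @param n_genes number of detected genes.
#' @param frac_three_prime_only target 3' bias fraction, in [0, 1].
#' @param ribo_frac target ribosomal read fraction, in [0, 1).
#' @param intron_exon_ratio target intron-to-exon ratio, >= 0.
#' @param seed integer seed.
#' @return list with \code{exons} (data.frame gene/exon/count) and
#'   \code{summary} (list with ribosomal_reads, total_reads, intronic_reads,
#'   exonic_reads).
#' @export
generate_exon_table <- function(n_genes, frac_three_prime_only, ribo_frac,
                                intron_exon_ratio, seed = 1) {
  stopifnot(n_genes >= 1,
            frac_three_prime_only >= 0, frac_three_prime_only <= 1,
            ribo_frac >= 0, ribo_frac < 1, intron_exon_ratio >= 0)
  set.seed(seed)
  n3 <- round(frac_three_prime_only * n_genes)
  rows <- lapply(seq_len(n_genes), function(g) {
    n_exon <- sample(2:4, 1)
    cnt <- sample(5:50, n_exon, replace = TRUE)
    if (g <= n3) cnt[-n_exon] <- 0L      # all reads on the 3'-most exon
    data.frame(gene = sprintf("G%05d", g), exon = seq_len(n_exon), count = cnt)
  })
  exons <- do.call(rbind, rows)
  exonic <- sum(exons$count)
  intronic <- round(intron_exon_ratio * exonic)
  mapped <- exonic + intronic
  total <- if (ribo_frac > 0) ceiling(mapped / (1 - ribo_frac)) else mapped
  ribosomal <- round(ribo_frac * total)
  list(exons = exons,
       summary = list(ribosomal_reads = ribosomal, total_reads = total,
                      intronic_reads = intronic, exonic_reads = exonic))
}

#' Generate a tissue consensus expression table from a synthetic atlas
#'
#' Planted marker genes receive a high NX value in their native tissue and 0
#' elsewhere (category "Tissue enriched", listed specific to that tissue);
#' all other genes get a flat row across tissues (category "Low tissue
#' specificity"). Extra tissues with no native cell type can be appended.
#'
#' @param atlas \code{\link{cell_atlas}} from \code{\link{generate_atlas}}
#'   (must carry planted markers).
#' @param n_extra_tissues tissues to append beyond the atlas tissues.
#' @param marker_nx NX value of a marker in its native tissue.
#' @param seed integer seed.
#' @return \code{\link{tissue_table}}.
#' @export
generate_tissue_table <- function(atlas, n_extra_tissues = 2, marker_nx = 40,
                                  seed = 1) {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (is.null(atlas$markers)) stop("atlas carries no planted marker map")
  set.seed(seed)
  genes <- colnames(atlas$counts)
  tissues <- unique(atlas$cells$tissue)
  if (n_extra_tissues > 0)
    tissues <- c(tissues, sprintf("extra%02d", seq_len(n_extra_tissues)))
  nx <- matrix(0, length(genes), length(tissues),
               dimnames = list(genes, tissues))
  flat <- runif(length(genes), 1, 10)
  nx[] <- flat                                 # uniform rows by default
  category <- setNames(rep("Low tissue specificity", length(genes)), genes)
  specific <- setNames(vector("list", length(genes)), genes)
  specific[] <- list(character(0))
  for (ct in names(atlas$markers)) {
    tis <- atlas$tissue_of_type[[ct]]
    for (g in atlas$markers[[ct]]) {
      nx[g, ] <- 0
      nx[g, tis] <- marker_nx
      category[g] <- "Tissue enriched"
      specific[[g]] <- tis
    }
  }
  tissue_table(nx, category, specific)
}

#' Generate two cohorts with a planted effect on a gene profile
#'
#' Both cohorts draw Poisson counts around per-gene log-normal baselines;
#' in cohort B the profile genes' means are multiplied by
#' \code{exp(log_effect)}. Non-profile genes are exchangeable between groups.
#'
#' @param profile \code{\link{cell_type_profile}} whose genes receive the
#'   effect.
#' @param n_per_group samples per cohort.
#' @param log_effect natural-log fold change planted in cohort B's profile
#'   genes (0 = null).
#' @param n_background background genes added around the profile genes.
#' @param depth expected library size per sample.
#' @param seed integer seed.
#' @return list with \code{a} and \code{b}, each a \code{\link{cf_counts}}.
#' @export
generate_cohorts <- function(profile, n_per_group = 20, log_effect = 0,
                             n_background = 300, depth = 2e5, seed = 1) {
  stopifnot(inherits(profile, "cell_type_profile"), n_per_group >= 1)
  set.seed(seed)
  pg <- profile$genes$gene
  genes <- c(pg, sprintf("BG%04d", seq_len(n_background)))
  base <- exp(rnorm(length(genes), 0, 1))
  base <- base / sum(base) * depth
  names(base) <- genes
  draw <- function(mult, tag) {
    mu <- base
    mu[pg] <- mu[pg] * mult
    m <- matrix(rpois(length(genes) * n_per_group, rep(mu, n_per_group)),
                length(genes), n_per_group,
                dimnames = list(genes, sprintf("%s%02d", tag, seq_len(n_per_group))))
    cf_counts(m, data.frame(sample = colnames(m), plasma_ml = 1,
                            batch = tag, bio_replicate = colnames(m)))
  }
  list(a = draw(1, "A"), b = draw(exp(log_effect), "B"))
}

#' Generate a marker database table from a synthetic atlas
#'
#' Planted markers get sensitivity / specificity values that pass the
#' detection filter (sensitivity >= 0.9, specificity <= 0.2); an equal number
#' of decoy entries fail it. Emulates a PanglaoDB-style table.
#'
#' @param atlas \code{\link{cell_atlas}} with planted markers.
#' @param seed integer seed.
#' @return data.frame with columns cell_type, gene, sensitivity, specificity,
#'   species.
#' @export
generate_marker_db <- function(atlas, seed = 1) {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (is.null(atlas$markers)) stop("atlas carries no planted marker map")
  set.seed(seed)
  good <- do.call(rbind, lapply(names(atlas$markers), function(ct) {
    g <- atlas$markers[[ct]]
    data.frame(cell_type = ct, gene = g,
               sensitivity = runif(length(g), 0.9, 1),
               specificity = runif(length(g), 0, 0.2),
               species = "Hs")
  }))
  pool <- setdiff(colnames(atlas$counts), good$gene)
  n_decoy <- min(length(pool), nrow(good))
  decoy <- data.frame(cell_type = sample(names(atlas$markers), n_decoy, TRUE),
                      gene = sample(pool, n_decoy),
                      sensitivity = runif(n_decoy, 0, 0.85),
                      specificity = runif(n_decoy, 0.3, 1),
                      species = "Hs")
  rbind(good, decoy)
}

#' Generate pseudo-bulk tissue samples from a tissue table
#'
#' Draws log-normal noise around each tissue's NX column and returns
#' log(counts-per-ten-thousand + 1)-scale values, the input expected by
#' \code{\link{profile_foldchange_check}}.
#'
#' @param tt \code{\link{tissue_table}}.
#' @param n_per_tissue samples per tissue.
#' @param noise_sdlog log-normal noise sd.
#' @param floor_nx baseline expression added to every gene in every tissue
#'   (keeps genes detectable at a low level outside their specific tissue).
#' @param seed integer seed.
#' @return list with \code{values} (genes x samples matrix, log CPTT scale)
#'   and \code{tissue} (per-sample tissue labels).
#' @export
generate_tissue_bulk <- function(tt, n_per_tissue = 5, noise_sdlog = 0.2,
                                 floor_nx = 0.5, seed = 1) {
  stopifnot(inherits(tt, "tissue_table"))
  set.seed(seed)
  tissues <- colnames(tt$nx)
  cols <- lapply(tissues, function(ts) {
    raw <- (tt$nx[, ts] + floor_nx) *
      matrix(rlnorm(nrow(tt$nx) * n_per_tissue, 0, noise_sdlog),
             nrow(tt$nx), n_per_tissue)
    # scale each sample to counts-per-ten-thousand, then log
    log1p(sweep(raw, 2, colSums(raw), "/") * 1e4)
  })
  values <- do.call(cbind, cols)
  rownames(values) <- rownames(tt$nx)
  tissue <- rep(tissues, each = n_per_tissue)
  colnames(values) <- sprintf("%s_s%02d", tissue, seq_len(n_per_tissue))
  list(values = values, tissue = tissue)
}
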