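# nu-SVR deconvolution: solve A theta = b per cfRNA sample with a linear
# kernel over the (nu, C) grid, keep non-negative renormalized weights, and
# select the candidate with the smallest RMSE between the predicted and
# measured expression in the standardized space where the fit occurs.

#' Restrict a mixture to basis genes at CPM >= 1
#'
#' Only genes present in the basis rows and measured at >= 1 CPM enter the
#' mixture vector b; the basis rows are subset accordingly. Inputs must be on
#' the linear CPM-per-mL scale (not TMM-divided, not logged).
#'
#' @param x a \code{cf_norm} at stage \code{cpm_ml} (use \code{sample} to
#'   pick the column) or a named numeric vector of linear CPM values.
#' @param basis \code{\link{basis_matrix}}.
#' @param sample column to use when \code{x} is a matrix-like object.
#' @return list with \code{b} (named numeric) and \code{A} (aligned basis
#'   submatrix).
#' @export
prepare_mixture <- function(x, basis, sample = NULL) {
  stopifnot(inherits(basis, "basis_matrix"))
  if (inherits(x, "cf_norm")) {
    if (x$stage != "cpm_ml")
      stop("deconvolution expects stage cpm_ml (linear, not TMM-divided, not logged); got ",
           x$stage)
    if (is.null(sample)) sample <- colnames(x$values)[1]
    v <- x$values[, sample]
  } else {
    v <- x
    if (is.null(names(v))) stop("mixture vector must be named by gene")
  }
  common <- intersect(rownames(basis$A), names(v))
  keep <- common[v[common] >= 1]
  if (length(keep) < 2) stop("fewer than 2 basis genes at CPM >= 1 in the mixture")
  list(b = v[keep], A = basis$A[keep, , drop = FALSE])
}

#' Standardize a mixture and basis to zero mean, unit variance
#'
#' b is standardized by its own mean and sd; A is standardized as one matrix
#' (global mean and sd over all entries), preserving between-column magnitude
#' differences. Transformation parameters are recorded in the result.
#'
#' @param b named numeric mixture vector.
#' @param A aligned basis submatrix.
#' @return list with \code{b_std}, \code{A_std} and the four transformation
#'   parameters.
#' @export
standardize_mixture <- function(b, A) {
  stopifnot(length(b) == nrow(A))
  if (sd(b) == 0) stop("mixture has zero variance; cannot standardize")
  sA <- sd(as.numeric(A))
  if (sA == 0) stop("basis has zero variance; cannot standardize")
  list(b_std = (b - mean(b)) / sd(b),
       A_std = (A - mean(A)) / sA,
       b_center = mean(b), b_scale = sd(b),
       A_center = mean(A), A_scale = sA)
}

#' Fit the nu-SVR hyperparameter grid
#'
#' One linear-kernel nu-SVR fit per (nu, C) pair; the raw cell-type weight
#' vector of each fit is recovered from the support vectors (for a linear
#' kernel the primal weights are \code{t(coefs) \%*\% SV}). Non-converging
#' fits are flagged and skipped.
#'
#' @param b_std,A_std standardized mixture and basis.
#' @param nu_grid,C_grid hyperparameter grids (defaults: the 6 x 5 = 30-fit
#'   grid nu in \{0.05, 0.1, 0.15, 0.25, 0.5, 0.75\}, C in \{0.1, 0.5, 0.75,
#'   1, 10\}).
#' @param tolerance solver stopping tolerance (default 1e-3, the libsvm /
#'   scikit-learn NuSVR default).
#' @return list of candidates, each with nu, C, raw weights and the support
#'   vector count.
#' @export
fit_svr_grid <- function(b_std, A_std,
                         nu_grid = c(0.05, 0.1, 0.15, 0.25, 0.5, 0.75),
                         C_grid = c(0.1, 0.5, 0.75, 1, 10),
                         tolerance = 1e-3) {
  stopifnot(length(nu_grid) >= 1, length(C_grid) >= 1)
  out <- list()
  for (nu in sort(nu_grid)) for (C in sort(C_grid)) {
    fit <- tryCatch(
      e1071::svm(x = A_std, y = b_std, type = "nu-regression",
                 kernel = "linear", nu = nu, cost = C, scale = FALSE,
                 tolerance = tolerance),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      out[[length(out) + 1]] <- list(nu = nu, C = C, raw = NULL,
                                     n_sv = NA_integer_, failed = TRUE)
      next
    }
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    names(w) <- colnames(A_std)
    out[[length(out) + 1]] <- list(nu = nu, C = C, raw = w,
                                   n_sv = nrow(fit$SV), failed = FALSE)
  }
  out
}

#' Project raw SVR weights onto the simplex by truncation
#'
#' Negative weights are set to zero and the remainder divided by its sum,
#' yielding relative cell-type proportions. If no weight is positive a zero
#' vector is returned with attribute \code{degenerate = TRUE}.
#'
#' @param raw numeric weight vector.
#' @return non-negative vector summing to 1 (or all zeros, flagged
#'   degenerate).
#' @export
normalize_weights <- function(raw) {
  w <- pmax(raw, 0)
  s <- sum(w)
  if (s <= 0) {
    out <- w * 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- w / s
  attr(out, "degenerate") <- FALSE
  out
}

#' Select the smallest-RMSE candidate
#'
#' For each non-degenerate candidate, predicted expression is the basis dot
#' product with the normalized weights, \code{A_std \%*\% theta}; RMSE and
#' Pearson r against the measured standardized values decide the winner
#' (ties: smaller nu, then smaller C).
#'
#' @param candidates output of \code{\link{fit_svr_grid}}.
#' @param b_std,A_std standardized mixture and basis.
#' @return list with the selected candidate's theta, nu, C, rmse, pearson_r,
#'   support-vector count and the full grid table.
#' @export
select_model <- function(candidates, b_std, A_std) {
  grid <- data.frame(nu = numeric(0), C = numeric(0), rmse = numeric(0),
                     pearson_r = numeric(0), degenerate = logical(0))
  best <- NULL
  for (cand in candidates) {
    if (isTRUE(cand$failed)) next
    theta <- normalize_weights(cand$raw)
    degen <- isTRUE(attr(theta, "degenerate"))
    rmse <- r <- NA_real_
    if (!degen) {
      pred <- as.numeric(A_std %*% theta)
      rmse <- sqrt(mean((pred - b_std)^2))
      r <- cor(pred, b_std)
    }
    grid <- rbind(grid, data.frame(nu = cand$nu, C = cand$C, rmse = rmse,
                                   pearson_r = r, degenerate = degen))
    if (degen) next
    if (is.null(best) || rmse < best$rmse ||
        (rmse == best$rmse && (cand$nu < best$nu ||
                               (cand$nu == best$nu && cand$C < best$C)))) {
      best <- list(theta = theta, raw = cand$raw, nu = cand$nu, C = cand$C,
                   rmse = rmse, pearson_r = r, n_sv = cand$n_sv)
    }
  }
  if (is.null(best)) stop("all grid candidates are degenerate (no positive weights)")
  best$grid <- grid
  best
}

#' Deconvolve a cfRNA mixture into cell-type fractions
#'
#' Fits the linear mixture model \eqn{A\theta = b} by nu-support-vector
#' regression over the (nu, C) hyperparameter grid. The mixture is restricted
#' to basis genes at CPM >= 1, mixture and basis are standardized to zero
#' mean and unit variance (the basis as one matrix), one linear-kernel nu-SVR
#' is fit per grid point, weights are truncated to the non-negative simplex,
#' and the candidate with the smallest RMSE between predicted
#' (\code{A \%*\% theta}) and measured standardized expression is returned.
#'
#' @param x mixture: a \code{cf_norm} at stage \code{cpm_ml} or a named
#'   numeric vector of linear CPM values.
#' @param basis \code{\link{basis_matrix}}.
#' @param sample column of \code{x} to deconvolve (when matrix-like).
#' @param nu_grid,C_grid hyperparameter grids (see
#'   \code{\link{fit_svr_grid}}).
#' @param ... passed to \code{\link{fit_svr_grid}}.
#' @return object of class \code{cf_deconv} with elements \code{theta}
#'   (named fractions), \code{nu}, \code{C}, \code{rmse}, \code{pearson_r},
#'   \code{n_genes_used}, \code{support_vector_count}, \code{grid} (all
#'   candidates), \code{std} (standardization parameters) and
#'   \code{genes_used}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{fitted}, \code{predict}, \code{residuals}, \code{plot}.
#' @examples
#' spec <- atlas_spec(n_cell_types = 4, n_genes = 160, cells_per_type = 25,
#'                    markers_per_type = 10, seed = 7)
#' atl <- subsample_cells(generate_atlas(spec), 30, seed = 7)
#' basis <- build_signature_matrix(atl, barcode_range = c(2, 6), seed = 7)
#' truth <- mixture_truth(c(0.4, 0.3, 0.2, 0.1))
#' mix <- generate_mixture(basis, truth, seed = 11)
#' fit <- deconvolve(cpm_per_ml(mix), basis)
#' coef(fit)
#' @export
deconvolve <- function(x, basis, sample = NULL,
                       nu_grid = c(0.05, 0.1, 0.15, 0.25, 0.5, 0.75),
                       C_grid = c(0.1, 0.5, 0.75, 1, 10), ...) {
  prep <- prepare_mixture(x, basis, sample = sample)
  std <- standardize_mixture(prep$b, prep$A)
  cands <- fit_svr_grid(std$b_std, std$A_std, nu_grid = nu_grid,
                        C_grid = C_grid, ...)
  sel <- select_model(cands, std$b_std, std$A_std)
  structure(list(theta = sel$theta, nu = sel$nu, C = sel$C, rmse = sel$rmse,
                 pearson_r = sel$pearson_r,
                 n_genes_used = length(prep$b),
                 support_vector_count = sel$n_sv,
                 raw_weights = sel$raw, grid = sel$grid,
                 std = std, genes_used = names(prep$b),
                 b_std = std$b_std, A_std = std$A_std,
                 call = match.call()),
            class = "cf_deconv")
}

#' @export
print.cf_deconv <- function(x, digits = 3, ...) {
  cat("nu-SVR deconvolution fit\n")
  cat(sprintf("  genes used: %d; selected nu = %g, C = %g; RMSE = %.4g; Pearson r = %.4g\n",
              x$n_genes_used, x$nu, x$C, x$rmse, x$pearson_r))
  th <- sort(x$theta, decreasing = TRUE)
  top <- head(th[th > 0], 5)
  cat("  top fractions:\n")
  for (nm in names(top)) cat(sprintf("    %-40s %.*f\n", nm, digits, top[nm]))
  invisible(x)
}

#' @export
coef.cf_deconv <- function(object, ...) {
  th <- object$theta
  attr(th, "degenerate") <- NULL
  th
}

#' @export
fitted.cf_deconv <- function(object, ...) {
  as.numeric(object$A_std %*% object$theta)
}

#' @export
residuals.cf_deconv <- function(object, ...) {
  object$b_std - fitted(object)
}

#' Predicted gene expression from a deconvolution fit
#'
#' @param object \code{cf_deconv} fit.
#' @param space \code{"standardized"} (the space the fit occurred in) or
#'   \code{"cpm"} (back-transformed to the linear CPM scale).
#' @param ... unused.
#' @return numeric vector named by gene.
#' @export
predict.cf_deconv <- function(object, space = c("standardized", "cpm"), ...) {
  space <- match.arg(space)
  pred <- as.numeric(object$A_std %*% object$theta)
  names(pred) <- object$genes_used
  if (space == "cpm")
    pred <- pred * object$std$b_scale + object$std$b_center
  pred
}

#' @export
summary.cf_deconv <- function(object, ...) {
  structure(list(fit = object,
                 n_nonzero = sum(object$theta > 0),
                 grid = object$grid), class = "summary.cf_deconv")
}

#' @export
print.summary.cf_deconv <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  non-zero cell types: %d of %d\n",
              x$n_nonzero, length(x$fit$theta)))
  cat("  grid (best 5 by RMSE):\n")
  g <- x$grid[!x$grid$degenerate, ]
  print(head(g[order(g$rmse), ], 5), row.names = FALSE)
  invisible(x)
}

#' Simulate new mixtures from a deconvolution fit
#'
#' Draws mixtures whose expected composition is the fitted theta: the basis
#' submatrix used in the fit is reconstructed on the CPM scale, multiplied
#' by \code{coef(object)}, scaled to \code{depth} and sampled with Poisson
#' noise. Useful for parametric-bootstrap checks of the fit.
#'
#' @param object \code{cf_deconv} fit.
#' @param nsim number of simulated mixtures.
#' @param seed integer seed.
#' @param depth expected total counts per simulated mixture.
#' @param ... unused.
#' @return genes x nsim matrix of simulated counts.
#' @export
simulate.cf_deconv <- function(object, nsim = 1, seed = 1, depth = 1e6, ...) {
  set.seed(seed)
  A_cpm <- object$A_std * object$std$A_scale + object$std$A_center
  mu <- as.numeric(A_cpm %*% object$theta)
  mu <- pmax(mu, 0)
  mu <- mu / sum(mu) * depth
  out <- matrix(rpois(length(mu) * nsim, rep(mu, nsim)), length(mu), nsim,
                dimnames = list(object$genes_used,
                                sprintf("sim%02d", seq_len(nsim))))
  out
}

#' @export
plot.cf_deconv <- function(x, ...) {
  th <- sort(coef(x), decreasing = TRUE)
  th <- th[th > 0]
  op <- graphics::par(mar = c(10, 4, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(th, las = 2, ylab = "fraction",
                    main = "cell-type contributions", ...)
  invisible(x)
}

#' Deconvolve every sample of a cohort
#'
#' Applies \code{\link{deconvolve}} to each column of a QC-passed,
#' replicate-averaged CPM matrix and summarizes: a long fractions table, mean
#' fractions per batch, and the pairwise Pearson similarity of the learned
#' theta across samples.
#'
#' @param norm \code{cf_norm} at stage \code{cpm_ml}.
#' @param basis \code{\link{basis_matrix}}.
#' @param ... passed to \code{\link{deconvolve}}.
#' @return list with \code{fits} (per-sample \code{cf_deconv}),
#'   \code{fractions} (long data.frame), \code{batch_means} (cell type x
#'   batch matrix) and \code{sample_similarity} (samples x samples Pearson
#'   correlation of theta).
#' @export
deconvolve_cohort <- function(norm, basis, ...) {
  stopifnot(inherits(norm, "cf_norm"))
  samples <- colnames(norm$values)
  fits <- lapply(samples, function(s) deconvolve(norm, basis, sample = s, ...))
  names(fits) <- samples
  fractions <- do.call(rbind, lapply(samples, function(s) {
    f <- fits[[s]]
    data.frame(sample = s, cell_type = names(f$theta),
               fraction = as.numeric(f$theta), nu = f$nu, C = f$C,
               rmse = f$rmse, pearson_r = f$pearson_r, row.names = NULL)
  }))
  theta_mat <- vapply(fits, function(f) as.numeric(f$theta),
                      numeric(ncol(basis$A)))
  rownames(theta_mat) <- colnames(basis$A)
  batch <- norm$meta[samples, "batch"]
  batch_means <- vapply(unique(batch), function(b)
    rowMeans(theta_mat[, batch == b, drop = FALSE]),
    numeric(nrow(theta_mat)))
  sim <- if (length(samples) > 1) cor(theta_mat) else
    matrix(1, 1, 1, dimnames = list(samples, samples))
  list(fits = fits, fractions = fractions, batch_means = batch_means,
       sample_similarity = sim)
}
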