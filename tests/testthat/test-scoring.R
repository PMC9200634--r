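log_norm_fixture <- function(mat) {
  x <- cf_counts(mat, data.frame(sample = colnames(mat), plasma_ml = 1,
                                 batch = "b", bio_replicate = colnames(mat)))
  normalize_cfrna(x, "log_cpm_tmm")
}

test_that("signature scores sum logged values, missing genes contribute 0", {
  vals <- matrix(c(2, 3, 1, 0, 5, 4), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  x <- cforigin:::new_cf_norm(vals, "log_cpm_tmm",
                              data.frame(sample = c("s1", "s2")))
  sc <- signature_score(x, c("g1", "g2"), "ct")
  expect_equal(sc$score, c(5, 5))
  sc2 <- signature_score(x, c("g1", "g2", "absent"), "ct")
  expect_equal(sc2$score, c(5, 5))
  expect_equal(sc2$n_genes_scored, c(2, 2))
  expect_warning(s0 <- signature_score(x, c("absent1", "absent2"), "ct"),
                 "no profile gene")
  expect_equal(s0$score, c(0, 0))
  # stage guard
  y <- cforigin:::new_cf_norm(vals, "cpm_ml", data.frame(sample = c("s1", "s2")))
  expect_error(signature_score(y, "g1"), "log_cpm_tmm")
})

test_that("raising a profile gene's expression raises the score by about log fc", {
  set.seed(61)
  m <- matrix(rpois(400, 50) + 1, 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  m2 <- m; m2["g1", ] <- m2["g1", ] * 2L
  s1 <- signature_score(log_norm_fixture(m), "g1", "ct")$score
  s2 <- signature_score(log_norm_fixture(m2), "g1", "ct")$score
  expect_equal(mean(s2 - s1), log(2), tolerance = 0.05)
})

test_that("dropout filter keeps genes detected at least once in both cohorts", {
  set.seed(62)
  ma <- matrix(rpois(300, 5), 30, 10, dimnames = list(paste0("g", 1:30), paste0("a", 1:10)))
  mb <- matrix(rpois(300, 5), 30, 10, dimnames = list(paste0("g", 1:30), paste0("b", 1:10)))
  mb["g1", ] <- 0L            # zero everywhere in B
  ma["g2", ] <- 0L; ma["g2", 3] <- 4L   # non-zero once in A
  mb["g2", ] <- 0L; mb["g2", 7] <- 2L   # non-zero once in B
  prof <- cell_type_profile("ct", "t", data.frame(gene = c("g1", "g2", "g3")))
  out <- dropout_filter(prof, log_norm_fixture(ma), log_norm_fixture(mb))
  expect_false("g1" %in% out$genes$gene)
  expect_true(all(c("g2", "g3") %in% out$genes$gene))
})

test_that("Mann-Whitney agrees with exhaustive enumeration for small groups", {
  # the canonical separated case: U = 0, one-sided p = 1/20
  cmp <- compare_cohorts(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p, 1 / 20)

  set.seed(63)
  for (i in 1:12) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- sample(100, n1); b <- sample(200:300, n2) / 7  # tie-free
    for (alt in c("less", "greater", "two.sided")) {
      got <- compare_cohorts(a, b, alt)
      want <- oracle_mwu(a, b, alt)
      expect_equal(got$U, want$U)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }

  # identical groups: U near n1 n2 / 2, two-sided p near 1
  cmp2 <- compare_cohorts(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(cmp2$U, 8)
  expect_gt(cmp2$p, 0.9)
  expect_error(compare_cohorts(1:2, 1:5), "at least 3")
})

test_that("U stays within [0, n1 n2] on random inputs", {
  set.seed(64)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    cmp <- compare_cohorts(a, b)
    expect_gte(cmp$U, 0)
    expect_lte(cmp$U, length(a) * length(b))
    expect_lte(cmp$p, 1)
  }
})

test_that("permutation calibration follows the (>= observed)/(n+1) rule", {
  # all scores equal: every permuted difference >= the observed 0
  cal <- calibrate_pvalues(rep(4, 12), rep(c("x", "y"), 6), n_perm = 500, seed = 1)
  expect_equal(cal$p_perm, 500 / 501)

  # deterministic given the seed
  set.seed(2); sc <- rnorm(20)
  c1 <- calibrate_pvalues(sc, rep(c("x", "y"), 10), n_perm = 200, seed = 9)
  c2 <- calibrate_pvalues(sc, rep(c("x", "y"), 10), n_perm = 200, seed = 9)
  expect_identical(c1, c2)
  expect_error(calibrate_pvalues(sc, rep("x", 20), n_perm = 200), "2 levels")
  expect_error(calibrate_pvalues(sc, rep(c("x", "y"), 10), n_perm = 10), "n_perm")
})

test_that("hypergeometric overlap matches combinatorial arithmetic", {
  u <- paste0("g", 1:20)
  expect_equal(hypergeom_overlap(u[1:5], u[1:5], 20), 1 / choose(20, 5))
  expect_equal(hypergeom_overlap(u, u, 20), 1)
  expect_equal(hypergeom_overlap(u[1:3], u[10:12], 1e5), 1, tolerance = 1e-3)

  set.seed(65)
  for (i in 1:15) {
    universe <- sample(8:15, 1)
    genes <- paste0("g", seq_len(universe))
    deg <- sample(genes, sample(2:universe, 1))
    prof <- sample(genes, sample(2:universe, 1))
    got <- hypergeom_overlap(deg, prof, universe)
    want <- oracle_hyper(length(intersect(deg, prof)), length(prof),
                         length(deg), universe)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(hypergeom_overlap(paste0("g", 1:30), "g1", 20), "exceed")
})

test_that("the Gini permutation test separates planted specificity", {
  set.seed(66)
  n_ct <- 6
  expr <- rbind(
    # cell-type-specific genes: one-hot across cell types
    t(vapply(1:20, function(i) { v <- rep(0, n_ct); v[1 + i %% n_ct] <- 5; v },
             numeric(n_ct))),
    # tissue-specific genes: uniform across cell types
    matrix(3, 20, n_ct))
  rownames(expr) <- paste0("g", 1:40)
  ct <- paste0("g", 1:20); ts <- paste0("g", 21:40)
  res <- gini_permutation_test(ct, ts, expr, n_perm = 999, seed = 5)
  expect_equal(res$observed, (n_ct - 1) / n_ct)   # max Gini gap: 5/6 - 0
  expect_lt(res$p, 0.005)                         # near the 1/(n+1) floor

  # exchangeable groups: p is not extreme
  set.seed(67)
  expr2 <- matrix(rexp(40 * n_ct), 40, n_ct,
                  dimnames = list(paste0("h", 1:40), NULL))
  res2 <- gini_permutation_test(paste0("h", 1:20), paste0("h", 21:40), expr2,
                                n_perm = 999, seed = 5)
  expect_gt(res2$p, 0.01)
  expect_error(gini_permutation_test(character(0), ts, expr), "non-empty")
  expect_error(gini_permutation_test(ct, ct, expr), "disjoint")
})

test_that("tissue-specific set construction follows the set algebra", {
  B <- paste0("g", 1:10)
  C_set <- paste0("g", 1:3)
  U_set <- paste0("g", c(2, 4, 5, 20))
  D_set <- paste0("g", c(3, 6))
  T_set <- tissue_specific_set(B, C_set, U_set, D_set)
  expect_setequal(T_set, paste0("g", c(4, 5, 6)))
  expect_length(intersect(T_set, C_set), 0)
  expect_error(tissue_specific_set(B, c(C_set, "g99"), U_set, D_set), "subset")
})

test_that("uncaptured-tissue tally counts only specific genes off the basis rows", {
  atl <- profile_atlas()
  tt <- profile_tissue_table()
  # a small basis claiming CT01's markers only
  A <- matrix(runif(30, 10, 20), 15, 2,
              dimnames = list(atl$markers$CT01, c("x", "y")))
  basis <- basis_matrix(A)
  # sample expressing CT01 and CT02 markers plus background
  genes <- rownames(tt$nx)
  v <- setNames(rep(5, length(genes)), genes)
  mat <- matrix(v, ncol = 1, dimnames = list(genes, "s1"))
  x <- cforigin:::new_cf_norm(mat, "cpm_ml", data.frame(sample = "s1"))
  res <- uncaptured_tissue_genes(x, basis, tt)
  t01 <- atl$tissue_of_type[["CT01"]]; t02 <- atl$tissue_of_type[["CT02"]]
  expect_equal(unname(res$counts[t02, 1]), 15)  # CT02 markers not in basis
  expect_equal(unname(res$counts[t01, 1]), 0)   # CT01 markers captured
  # NX below the floor is excluded
  tt2 <- tt
  mk <- atl$markers$CT03[1]
  tt2$nx[mk, atl$tissue_of_type[["CT03"]]] <- 9
  res2 <- uncaptured_tissue_genes(x, basis, tt2)
  expect_equal(unname(res2$counts[atl$tissue_of_type[["CT03"]], 1]), 14)
  # anti-monotone in the basis row space
  bigger <- basis_matrix(rbind(A, matrix(runif(30, 10, 20), 15, 2,
                               dimnames = list(atl$markers$CT02, c("x", "y")))))
  res3 <- uncaptured_tissue_genes(x, bigger, tt)
  expect_true(all(res3$counts <= res$counts))
})

test_that("marker detection filters the database and applies the >5 display rule", {
  atl <- profile_atlas()
  db <- generate_marker_db(atl, seed = 8)
  # sample expressing exactly 10 of CT01's markers and nothing else
  genes <- colnames(atl$counts)
  mat <- matrix(0, length(genes), 2, dimnames = list(genes, c("s1", "s2")))
  mat[atl$markers$CT01[1:10], ] <- 50
  mat["G00399", ] <- 1e4   # filler so library sizes are positive
  x <- log_norm_fixture(mat)
  res <- detect_markers(x, db)
  expect_equal(unname(res$counts["CT01", ]), c(10, 10))
  expect_true(res$summary$shown[res$summary$cell_type == "CT01"])
  expect_false(any(res$summary$shown[res$summary$cell_type != "CT01"]))

  # a type averaging exactly 5 markers is not shown (strict >5)
  mat2 <- mat
  mat2[atl$markers$CT01, ] <- 0
  mat2[atl$markers$CT01[1:5], ] <- 50
  res2 <- detect_markers(log_norm_fixture(mat2), db)
  expect_equal(unname(res2$counts["CT01", 1]), 5)
  expect_false(res2$summary$shown[res2$summary$cell_type == "CT01"])

  # decoy entries (low sensitivity / high specificity) are filtered out
  expect_lt(nrow(res$counts), length(unique(db$cell_type)) + 1)
})
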